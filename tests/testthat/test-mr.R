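wald_pair <- function(gamma, se_gamma, Gamma, se_Gamma) {
  data.frame(variant_id = "v1", beta_exposure = gamma, se_exposure = se_gamma,
             beta_outcome = Gamma, se_outcome = se_Gamma,
             eaf_exposure = 0.3, eaf_outcome = 0.3,
             n_exposure = 5000, n_outcome = 5000, status = "aligned",
             stringsAsFactors = FALSE)
}

test_that("the Wald ratio matches its closed form and contracts", {
  res <- wald_ratio(wald_pair(0.5, 0.02, 0.10, 0.05))
  expect_equal(res$estimate, 0.20)
  expect_equal(res$se, 0.10)
  expect_equal(res$pval, 2 * pnorm(-2))
  expect_equal(wald_ratio(wald_pair(0.5, 0.02, 0, 0.05))$estimate, 0)
  expect_error(wald_ratio(wald_pair(0, 0.02, 0.1, 0.05)), "zero")
  # second-order SE is never smaller than the first-order one
  res2 <- wald_ratio(wald_pair(0.5, 0.02, 0.10, 0.05), second_order = TRUE)
  expect_gte(res2$se, res$se)
})

test_that("IVW reduces to the Wald ratio for one instrument, exactly", {
  p <- wald_pair(0.537, 0.03, 0.123, 0.045)
  w <- wald_ratio(p)
  i <- ivw(p, min_instruments = 1)
  expect_identical(w$estimate, i$estimate)
  expect_identical(w$se, i$se)
  expect_identical(w$pval, i$pval)
})

test_that("IVW averages symmetric instruments and enforces its preconditions", {
  p <- rbind(wald_pair(0.5, 0.02, 0.05, 0.05),
             wald_pair(0.5, 0.02, 0.15, 0.05))
  p$variant_id <- c("v1", "v2")
  expect_equal(ivw(p)$estimate, 0.2) # equal weights, ratios 0.1 and 0.3
  expect_error(ivw(p[1, , drop = FALSE]), "at least 2")
  p$beta_exposure[2] <- 0
  expect_error(ivw(p), "zero")
})

test_that("IVW equals the weighted least-squares slope through the origin", {
  for (seed in 1:200) {
    pairs <- make_pairs(sample(2:10, 1), seed = seed)
    expect_lt(abs(ivw(pairs)$estimate - wls_slope_oracle(pairs)), 1e-10)
  }
})

test_that("MR estimates are sign-equivariant in either study's effects", {
  pairs <- make_pairs(6, seed = 31)
  base <- ivw(pairs)$estimate
  neg_exp <- pairs
  neg_exp$beta_exposure <- -neg_exp$beta_exposure
  expect_equal(ivw(neg_exp)$estimate, -base)
  neg_out <- pairs
  neg_out$beta_outcome <- -neg_out$beta_outcome
  expect_equal(ivw(neg_out)$estimate, -base)
})

test_that("leave-one-out reproduces reduced-set IVW fits and flags outliers", {
  pairs <- make_pairs(5, seed = 12)
  loo <- leave_one_out(pairs)
  expect_equal(nrow(loo), 5)
  expect_equal(loo$left_out_id, pairs$variant_id)
  for (i in 1:5) {
    direct <- ivw(pairs[-i, , drop = FALSE])
    expect_identical(loo$estimate[i], direct$estimate)
    expect_identical(loo$se[i], direct$se)
  }

  # three exchangeable instruments: every reduced estimate equals the full one
  same <- rbind(wald_pair(0.5, 0.02, 0.1, 0.05),
                wald_pair(0.5, 0.02, 0.1, 0.05),
                wald_pair(0.5, 0.02, 0.1, 0.05))
  same$variant_id <- c("v1", "v2", "v3")
  full <- ivw(same)$estimate
  expect_true(all(abs(leave_one_out(same)$estimate - full) < 1e-12))

  # a gross outlier is exposed by its own exclusion
  outl <- rbind(wald_pair(0.5, 0.02, 0.10, 0.05),
                wald_pair(0.5, 0.02, 0.11, 0.05),
                wald_pair(0.5, 0.02, 0.09, 0.05),
                wald_pair(0.5, 0.02, 1.50, 0.05))
  outl$variant_id <- sprintf("v%d", 1:4)
  full <- ivw(outl)$estimate
  shifts <- abs(leave_one_out(outl)$estimate - full)
  expect_equal(which.max(shifts), 4L)

  expect_error(leave_one_out(pairs[1:2, ]), "at least 3")
})

test_that("the Steiger test compares variance explained via Fisher's z", {
  # exact tie: no directional information
  tie <- wald_pair(0.1, 0.02, 0.1, 0.02)
  st <- steiger_test(tie)
  expect_equal(st$z, 0)
  expect_equal(st$pval, 1)
  expect_false(st$correct_direction)

  # r2_exposure = 0.04 vs r2_outcome = 0.0004 at n = 5000:
  # build betas giving those r2 under the t-statistic estimator
  n <- 5000
  t_exp <- sqrt(0.04 * (n - 2) / (1 - 0.04))
  t_out <- sqrt(4e-4 * (n - 2) / (1 - 4e-4))
  p <- wald_pair(t_exp * 0.01, 0.01, t_out * 0.01, 0.01)
  st <- steiger_test(p)
  expect_equal(st$r2_exposure, 0.04, tolerance = 1e-12)
  expect_equal(st$r2_outcome, 4e-4, tolerance = 1e-12)
  expect_true(st$correct_direction)
  z_expected <- (atanh(sqrt(0.04)) - atanh(sqrt(4e-4))) /
    sqrt(1 / (n - 3) + 1 / (n - 3))
  expect_equal(st$z, z_expected, tolerance = 1e-12)
  expect_lt(st$pval, 1e-10)

  # more variance explained in the outcome: wrong direction
  rev <- wald_pair(t_out * 0.01, 0.01, t_exp * 0.01, 0.01)
  expect_false(steiger_test(rev)$correct_direction)

  missing_n <- tie
  missing_n$n_outcome <- NA
  expect_error(steiger_test(missing_n), "sample sizes")
})

test_that("reverse MR flags underpowered outcomes instead of crashing", {
  weak <- make_sumstats(c("v1", "v2"), "A", "G", eaf = 0.3,
                        beta = c(0.01, 0.02), se = 0.05, trait_id = "D")
  expo <- make_sumstats(c("v1", "v2"), "A", "G", eaf = 0.3,
                        beta = c(0.3, 0.2), se = 0.02, trait_id = "C")
  ld <- diag(2)
  dimnames(ld) <- list(c("v1", "v2"), c("v1", "v2"))
  res <- reverse_mr(weak, expo, ld)
  expect_equal(res$status, "underpowered")
  expect_true(is.na(res$estimate))
})

test_that("reverse MR with swapped roles reproduces a forward analysis", {
  sim <- simulate_traits_and_sumstats(mr_recovery_scenario(0.3, seed = 21))
  manual_inst <- ld_clump(sim$sumstats$EXP, sim$ld)
  manual <- ivw(usable_pairs(harmonize(manual_inst, sim$sumstats$OUT)))
  swapped <- reverse_mr(sim$sumstats$EXP, sim$sumstats$OUT, sim$ld,
                        steiger_filter = FALSE)
  expect_equal(swapped$estimate, manual$estimate)
  expect_equal(swapped$se, manual$se)
})

test_that("in a genotype->exposure->disease chain only the forward effect shows", {
  # exposure with three strong instruments; outcome inherits them through a
  # true slope of 0.3 and has one strong causal variant of its own
  sc <- sim_scenario(
    n_variants = 30, maf = 0.3, ld_rho = 0.3,
    cohort_sizes = c(EXP = 10000L, OUT = 10000L),
    causal_map = list(
      EXP = data.frame(index = c(5L, 15L, 25L), beta = 0.3),
      OUT = data.frame(index = 20L, beta = 0.5)
    ),
    trait_types = c(EXP = "quantitative", OUT = "quantitative"),
    causal_beta_exposure_to_outcome = 0.3,
    exposure_trait = "EXP", outcome_trait = "OUT", seed = 17
  )
  sim <- simulate_traits_and_sumstats(sc)
  fwd_inst <- ld_clump(sim$sumstats$EXP, sim$ld)
  fwd <- ivw(usable_pairs(harmonize(fwd_inst, sim$sumstats$OUT)))
  expect_gt(fwd$estimate - 1.96 * fwd$se, 0) # forward CI excludes zero
  expect_lt(abs(fwd$estimate - 0.3), 3 * fwd$se)

  rev <- reverse_mr(sim$sumstats$OUT, sim$sumstats$EXP, sim$ld)
  expect_equal(rev$status, "ok")
  expect_lt(abs(rev$estimate), 1.96 * rev$se) # reverse CI covers zero
})

test_that("the Bonferroni threshold matches the published corrections", {
  expect_equal(signif(bonferroni_threshold(9, 9), 3), 6.17e-4)
  expect_equal(signif(bonferroni_threshold(8, 9), 3), 6.94e-4)
  expect_equal(bonferroni_threshold(1, 1), 0.05)
  expect_error(bonferroni_threshold(0, 9), ">= 1")
})

test_that("p-values stay finite on the log10 scale far below underflow", {
  p <- wald_pair(0.5, 0.001, 2.0, 0.001) # z = 2000
  res <- wald_ratio(p)
  expect_gt(res$pval, 0) # clamped, never exactly zero
  expect_true(is.finite(res$log10_pval))
  expect_lt(res$log10_pval, -300000)
})
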