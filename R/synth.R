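# Synthetic GWAS generator: LD-structured genotypes and two-sample summary
# statistics for expression, protein and disease traits with controlled
# causal-variant sharing. Stands in for the immune-cell eQTL, cytokine pQTL
# and disease GWAS panels the framework is designed to consume.

#' Specify a simulation scenario
#'
#' A scenario fixes one LD region (variant panel, allele frequencies,
#' AR(1) LD decay, coordinates) and the causal wiring of an arbitrary set
#' of traits, each measured in its own independent cohort (the two-sample
#' design). A trait's phenotype is built from its own causal variants and,
#' for the designated outcome trait, optionally from the exposure trait's
#' genetic score scaled by `causal_beta_exposure_to_outcome` — the true MR
#' slope when the outcome is generated from the exposure rather than
#' directly from genotype.
#'
#' @param n_variants number of variants in the region.
#' @param maf per-variant minor-allele frequencies in (0, 0.5], recycled.
#' @param ld_rho AR(1) adjacent-variant latent correlation in \[0, 1).
#' @param cohort_sizes named integer vector, trait id -> cohort size.
#' @param causal_map named list, trait id -> data.frame with columns
#'   `index` (variant index) and `beta` (per-allele effect: phenotype units
#'   for quantitative traits, log odds for binary traits). Traits may be
#'   omitted or given zero rows (null traits).
#' @param trait_types named character vector, trait id ->
#'   `"quantitative"`/`"binary"`.
#' @param noise_sd named numeric vector of residual SDs for quantitative
#'   traits (default 1).
#' @param disease_prevalence prevalence in (0, 1) used to calibrate the
#'   intercept of the logistic liability model for binary traits.
#' @param causal_beta_exposure_to_outcome true causal effect of the
#'   exposure trait on the outcome trait (0 = no mediation).
#' @param exposure_trait,outcome_trait trait ids linked by the mediated
#'   effect; `exposure_trait` also names the cohort whose genotypes define
#'   the reported LD matrix.
#' @param positions 1-based base-pair positions (default 25 kb spacing).
#' @param chromosome chromosome label for the region.
#' @param seed integer seed controlling all randomness in the scenario.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_variants, maf, ld_rho, cohort_sizes, causal_map,
                         trait_types, noise_sd = NULL,
                         disease_prevalence = 0.1,
                         causal_beta_exposure_to_outcome = 0,
                         exposure_trait = NULL, outcome_trait = NULL,
                         positions = NULL, chromosome = "1", seed = 1L) {
  stopifnot(n_variants >= 1)
  maf <- rep_len(maf, n_variants)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)", call. = FALSE)
  traits <- names(cohort_sizes)
  if (is.null(traits) || any(!nzchar(traits))) {
    stop("cohort_sizes must be a named vector of trait ids", call. = FALSE)
  }
  if (any(cohort_sizes <= 0)) stop("cohort sizes must be positive", call. = FALSE)
  trait_types <- trait_types[traits]
  if (anyNA(trait_types) || !all(trait_types %in% c("quantitative", "binary"))) {
    stop("trait_types must label every trait quantitative/binary", call. = FALSE)
  }
  for (tr in names(causal_map)) {
    cm <- causal_map[[tr]]
    if (nrow(cm) && (any(cm$index < 1) || any(cm$index > n_variants))) {
      stop("causal indices out of range for trait ", tr, call. = FALSE)
    }
  }
  if (is.null(noise_sd)) noise_sd <- stats::setNames(rep(1, length(traits)), traits)
  if (disease_prevalence <= 0 || disease_prevalence >= 1) {
    stop("disease_prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (causal_beta_exposure_to_outcome != 0 &&
      (is.null(exposure_trait) || is.null(outcome_trait))) {
    stop("mediated effects need exposure_trait and outcome_trait", call. = FALSE)
  }
  if (is.null(positions)) positions <- 10000 + (seq_len(n_variants) - 1L) * 25000
  structure(list(
    n_variants = as.integer(n_variants), maf = maf, ld_rho = ld_rho,
    cohort_sizes = cohort_sizes, causal_map = causal_map,
    trait_types = trait_types, noise_sd = noise_sd,
    disease_prevalence = disease_prevalence,
    causal_beta_exposure_to_outcome = causal_beta_exposure_to_outcome,
    exposure_trait = exposure_trait %||% traits[[1L]],
    outcome_trait = outcome_trait,
    positions = positions, chromosome = chromosome,
    variant_id = sprintf("v%0*d", nchar(n_variants), seq_len(n_variants)),
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

# draw one haplotype matrix by thresholding a latent AR(1) normal field
.sim_haplotypes <- function(n, maf, rho) {
  m <- length(maf)
  z <- matrix(0, n, m)
  z[, 1L] <- stats::rnorm(n)
  if (m > 1L) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1L] + s * stats::rnorm(n)
  }
  thr <- stats::qnorm(maf)
  (z < rep(thr, each = n)) + 0
}

.sim_geno <- function(n, maf, rho) {
  .sim_haplotypes(n, maf, rho) + .sim_haplotypes(n, maf, rho)
}

#' Simulate LD-structured genotypes
#'
#' Haplotypes are drawn by thresholding a latent AR(1)-correlated standard
#' normal vector at the quantile matching each minor-allele frequency; a
#' genotype is the sum of two independent haplotypes, so dosages are 0/1/2
#' with expectation `2 * maf` and LD decaying geometrically with distance.
#'
#' @param n_individuals cohort size.
#' @param maf per-variant minor-allele frequencies in (0, 0.5].
#' @param ld_rho AR(1) adjacent-variant latent correlation in \[0, 1).
#' @param seed optional seed; the result is deterministic given the seed and
#'   the caller's RNG state is untouched.
#' @return integer-valued matrix, individuals x variants.
#' @export
simulate_genotypes <- function(n_individuals, maf, ld_rho, seed = NULL) {
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)", call. = FALSE)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]", call. = FALSE)
  with_seed(seed, .sim_geno(n_individuals, maf, ld_rho))
}

# marginal single-variant linear regressions, vectorized across variants
.marginal_linear <- function(G, y) {
  n <- length(y)
  gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- as.numeric(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  list(beta = beta, se = se)
}

# marginal single-variant logistic regressions (per-variant glm fit)
.marginal_logistic <- function(G, y) {
  m <- ncol(G)
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    x <- cbind(1, G[, j])
    fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
    v <- chol2inv(qr.R(fit$qr))
    beta[j] <- fit$coefficients[2L]
    se[j] <- sqrt(v[2L, 2L])
  }
  list(beta = beta, se = se)
}

# fixed, non-palindromic allele pairs cycled along the panel
.assign_alleles <- function(m) {
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), nrow = 2L)
  idx <- ((seq_len(m) - 1L) %% ncol(pairs)) + 1L
  list(effect = pairs[1L, idx], other = pairs[2L, idx])
}

.causal_vector <- function(scenario, trait) {
  b <- numeric(scenario$n_variants)
  cm <- scenario$causal_map[[trait]]
  if (!is.null(cm) && nrow(cm)) b[cm$index] <- b[cm$index] + cm$beta
  b
}

#' Simulate phenotypes and two-sample GWAS summary statistics
#'
#' Each trait is simulated in its own freshly drawn cohort from the shared
#' LD region. Quantitative phenotypes are the genetic score plus Gaussian
#' noise; binary phenotypes follow a logistic liability model with the
#' intercept calibrated numerically to the requested prevalence, and their
#' effects are reported on the log-odds scale. Marginal per-variant summary
#' statistics come from single-variant linear regression (quantitative) or
#' per-variant logistic regression (binary); p-values are two-sided normal
#' on `beta/se`, so every emitted record satisfies the summary-statistics
#' invariants. The reported LD matrix is estimated from the exposure
#' cohort's genotypes.
#'
#' @param scenario a [sim_scenario()].
#' @return object of class `sim_output`: `sumstats` (named list of
#'   summary-statistics data.frames covering the identical variant set),
#'   `ld` (estimated signed correlation matrix), and `truth` (causal map,
#'   true MR slope, exposure/outcome trait ids, seed) — sufficient to score
#'   recovery.
#' @export
simulate_traits_and_sumstats <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  alleles <- .assign_alleles(sc$n_variants)
  with_seed(sc$seed, {
    sumstats <- list()
    ld <- NULL
    for (trait in names(sc$cohort_sizes)) {
      n <- sc$cohort_sizes[[trait]]
      G <- .sim_geno(n, sc$maf, sc$ld_rho)
      eta <- as.numeric(G %*% .causal_vector(sc, trait))
      if (!is.null(sc$outcome_trait) && trait == sc$outcome_trait &&
          sc$causal_beta_exposure_to_outcome != 0) {
        eta <- eta + sc$causal_beta_exposure_to_outcome *
          as.numeric(G %*% .causal_vector(sc, sc$exposure_trait))
      }
      type <- sc$trait_types[[trait]]
      if (type == "quantitative") {
        y <- eta + stats::rnorm(n, 0, sc$noise_sd[[trait]] %||% 1)
        fit <- .marginal_linear(G, y)
      } else {
        k <- sc$disease_prevalence
        c0 <- stats::uniroot(function(b0) mean(stats::plogis(b0 + eta)) - k,
                             c(-30, 30))$root
        y <- stats::rbinom(n, 1L, stats::plogis(c0 + eta))
        if (sum(y) == 0L || sum(y) == n) {
          stop("binary trait '", trait, "' produced no cases (or no controls) ",
               "at prevalence ", k, "; use a larger cohort", call. = FALSE)
        }
        fit <- .marginal_logistic(G, y)
      }
      z <- fit$beta / fit$se
      sumstats[[trait]] <- data.frame(
        variant_id = sc$variant_id,
        chr = sc$chromosome,
        pos = sc$positions,
        effect_allele = alleles$effect,
        other_allele = alleles$other,
        eaf = colMeans(G) / 2,
        beta = fit$beta,
        se = fit$se,
        pval = two_sided_p(z),
        n = n,
        trait_id = trait,
        trait_type = type,
        stringsAsFactors = FALSE
      )
      if (trait == sc$exposure_trait) {
        ld <- stats::cor(G)
        dimnames(ld) <- list(sc$variant_id, sc$variant_id)
      }
    }
    if (is.null(ld)) {
      stop("exposure_trait must name one of the simulated traits", call. = FALSE)
    }
    structure(list(
      sumstats = sumstats,
      ld = ld,
      truth = list(
        causal_map = sc$causal_map,
        causal_beta_exposure_to_outcome = sc$causal_beta_exposure_to_outcome,
        exposure_trait = sc$exposure_trait,
        outcome_trait = sc$outcome_trait,
        maf = sc$maf,
        seed = sc$seed
      ),
      scenario = sc
    ), class = "sim_output")
  })
}

#' Write a simulation to disk in the package's file formats
#'
#' Emits one tab-separated summary-statistics file per trait, the LD matrix,
#' and a YAML truth record.
#'
#' @param sim a `sim_output` from [simulate_traits_and_sumstats()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (trait in names(sim$sumstats)) {
    p <- file.path(dir, paste0(trait, ".tsv"))
    write_sumstats(sim$sumstats[[trait]], p)
    paths[[trait]] <- p
  }
  paths$ld <- file.path(dir, "ld_matrix.tsv")
  write_ld_matrix(sim$ld, paths$ld)
  paths$truth <- file.path(dir, "truth.yaml")
  truth <- sim$truth
  truth$causal_map <- lapply(truth$causal_map, function(cm) {
    list(index = as.integer(cm$index), beta = as.numeric(cm$beta))
  })
  yaml::write_yaml(truth, paths$truth)
  invisible(paths)
}
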