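# Two-sample MR estimators and sensitivity analyses: Wald ratio, fixed-effect
# IVW, leave-one-out, reverse MR, Steiger directionality, Bonferroni control.

.mr_result <- function(method, estimate, se, instrument_ids,
                       exposure_id = NA_character_, outcome_id = NA_character_,
                       status = "ok") {
  z <- if (is.na(estimate) || is.na(se)) NA_real_ else estimate / se
  data.frame(
    exposure_id = exposure_id, outcome_id = outcome_id,
    method = method,
    estimate = estimate, se = se,
    pval = if (is.na(z)) NA_real_ else two_sided_p(z),
    log10_pval = if (is.na(z)) NA_real_ else log10_two_sided_p(z),
    n_instruments = length(instrument_ids),
    instrument_ids = paste(instrument_ids, collapse = ","),
    status = status,
    stringsAsFactors = FALSE
  )
}

.pair_ids <- function(pairs) {
  list(
    exposure = if (!is.null(pairs$exposure_id)) pairs$exposure_id[1L] else NA_character_,
    outcome = if (!is.null(pairs$outcome_id)) pairs$outcome_id[1L] else NA_character_
  )
}

#' Wald ratio causal estimate from a single instrument
#'
#' For one harmonized variant the causal effect of the exposure on the
#' outcome is the ratio of the variant-outcome to the variant-exposure
#' association, `estimate = beta_outcome / beta_exposure`. The standard
#' error is the first-order delta-method approximation
#' `se_outcome / |beta_exposure|`, which ignores uncertainty in the
#' exposure association; `second_order = TRUE` adds the second-order term
#' propagating it.
#'
#' @param pair one usable harmonized pair (one-row data.frame from
#'   [harmonize()]).
#' @param second_order logical; use the second-order delta-method SE.
#' @return one-row MR result data.frame (`method = "wald_ratio"`).
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  pair <- usable_pairs(pair)
  if (nrow(pair) != 1L) stop("wald_ratio needs exactly one usable pair", call. = FALSE)
  g <- pair$beta_exposure
  if (g == 0) stop("undefined Wald ratio: exposure effect is zero", call. = FALSE)
  est <- pair$beta_outcome / g
  se <- pair$se_outcome / abs(g)
  if (second_order) {
    se <- sqrt(pair$se_outcome^2 / g^2 +
                 pair$beta_outcome^2 * pair$se_exposure^2 / g^4)
  }
  ids <- .pair_ids(pair)
  .mr_result("wald_ratio", est, se, pair$variant_id, ids$exposure, ids$outcome)
}

#' Inverse-variance-weighted causal estimate from multiple instruments
#'
#' Fixed-effect meta-analysis of per-instrument Wald ratios with weights
#' `w_j = beta_exposure_j^2 / se_outcome_j^2`:
#' `estimate = sum(w_j * ratio_j) / sum(w_j)`, `se = 1 / sqrt(sum(w_j))`.
#' Only the outcome-side standard error enters the weights, so the estimate
#' equals the slope of a weighted least-squares regression of outcome on
#' exposure effects through the origin with weights `1 / se_outcome^2`.
#'
#' @param pairs harmonized pairs ([harmonize()] output).
#' @param min_instruments minimum number of usable instruments (default 2;
#'   with 1 the result coincides exactly with [wald_ratio()]).
#' @return one-row MR result data.frame (`method = "ivw"`).
#' @export
ivw <- function(pairs, min_instruments = 2L) {
  pairs <- usable_pairs(pairs)
  if (nrow(pairs) < min_instruments) {
    stop("ivw needs at least ", min_instruments, " usable instruments, got ",
         nrow(pairs), call. = FALSE)
  }
  if (any(pairs$beta_exposure == 0)) {
    stop("undefined Wald ratio: exposure effect is zero", call. = FALSE)
  }
  w <- pairs$beta_exposure^2 / pairs$se_outcome^2
  ratio <- pairs$beta_outcome / pairs$beta_exposure
  if (nrow(pairs) == 1L) {
    # one term: the weighted mean collapses to the Wald ratio exactly
    est <- ratio
    se <- pairs$se_outcome / abs(pairs$beta_exposure)
  } else {
    est <- sum(w * ratio) / sum(w)
    se <- 1 / sqrt(sum(w))
  }
  ids <- .pair_ids(pairs)
  .mr_result("ivw", est, se, pairs$variant_id, ids$exposure, ids$outcome)
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Re-estimates the IVW effect excluding each instrument in turn, to check
#' that no single variant drives the causal estimate.
#'
#' @param pairs harmonized pairs with at least 3 usable instruments.
#' @return data.frame with one row per excluded instrument (`left_out_id`
#'   plus the IVW result on the remaining set), in input order.
#' @export
leave_one_out <- function(pairs) {
  pairs <- usable_pairs(pairs)
  k <- nrow(pairs)
  if (k < 3L) stop("leave-one-out needs at least 3 usable instruments", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    res <- ivw(pairs[-i, , drop = FALSE], min_instruments = 2L)
    cbind(left_out_id = pairs$variant_id[i], res, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Steiger directionality test
#'
#' Compares the variance an instrument set explains in the exposure against
#' the variance it explains in the outcome. Per-variant variance explained
#' is computed from summary statistics; the default estimator is
#' `r2 = t^2 / (t^2 + n - 2)` with `t = beta/se`, which needs no unit
#' assumptions and is applied on the log-odds scale for binary traits. For
#' quantitative traits with effects in phenotype-SD units,
#' `r2_method = "eaf"` uses `r2 = 2 * eaf * (1 - eaf) * beta^2`. Per-variant
#' contributions are summed over the (clumped, hence independent)
#' instruments. The test statistic compares the two dependent-sample
#' correlations via Fisher's z transform:
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp - 3) + 1/(n_out - 3))`.
#'
#' @param pairs harmonized pairs (usable rows are used).
#' @param r2_method `"tstat"` (default) or `"eaf"`.
#' @return one-row data.frame: `r2_exposure`, `r2_outcome`,
#'   `correct_direction` (`r2_exposure > r2_outcome`), `z`, `pval`.
#' @export
steiger_test <- function(pairs, r2_method = c("tstat", "eaf")) {
  r2_method <- match.arg(r2_method)
  pairs <- usable_pairs(pairs)
  if (!nrow(pairs)) stop("no usable pairs for Steiger test", call. = FALSE)
  if (anyNA(pairs$n_exposure) || anyNA(pairs$n_outcome)) {
    stop("Steiger test needs sample sizes on both sides", call. = FALSE)
  }
  r2_one <- function(beta, se, n, eaf) {
    if (r2_method == "eaf") {
      2 * eaf * (1 - eaf) * beta^2
    } else {
      t2 <- (beta / se)^2
      t2 / (t2 + n - 2)
    }
  }
  r2_exp <- min(sum(r2_one(pairs$beta_exposure, pairs$se_exposure,
                           pairs$n_exposure, pairs$eaf_exposure)), 1)
  r2_out <- min(sum(r2_one(pairs$beta_outcome, pairs$se_outcome,
                           pairs$n_outcome, pairs$eaf_outcome)), 1)
  n_exp <- min(pairs$n_exposure)
  n_out <- min(pairs$n_outcome)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  data.frame(
    r2_exposure = r2_exp, r2_outcome = r2_out,
    correct_direction = r2_exp > r2_out,
    z = z, pval = two_sided_p(z),
    stringsAsFactors = FALSE
  )
}

#' Reverse-direction MR
#'
#' Tests whether genetic liability to the outcome (e.g. disease) influences
#' the original exposure (e.g. a circulating cytokine). Instruments are
#' selected from the outcome's GWAS by LD clumping at the genome-wide
#' threshold, harmonized toward the original exposure as the new outcome,
#' and estimated by Wald ratio (one instrument) or IVW. By default,
#' candidate instruments that explain more variance in the original
#' exposure than in the disease (Steiger-discordant variants, which proxy
#' the forward causal path rather than disease liability) are excluded
#' before estimation; set `steiger_filter = FALSE` for the unfiltered
#' analysis. With no eligible instruments an `underpowered` result row is
#' returned rather than an error.
#'
#' @param outcome_sumstats disease GWAS summary statistics (instrument
#'   source).
#' @param exposure_sumstats original exposure summary statistics (now the
#'   outcome).
#' @param ld signed LD correlation matrix covering the outcome GWAS.
#' @param p_threshold,r2_threshold clumping thresholds (defaults 5e-8,
#'   0.001).
#' @param steiger_filter logical; drop directionality-discordant
#'   instruments (default `TRUE`).
#' @return one-row MR result data.frame; `status` is `"ok"` or
#'   `"underpowered"`.
#' @export
reverse_mr <- function(outcome_sumstats, exposure_sumstats, ld,
                       p_threshold = 5e-8, r2_threshold = 0.001,
                       steiger_filter = TRUE) {
  ids <- list(
    exposure = if (!is.null(outcome_sumstats$trait_id)) outcome_sumstats$trait_id[1L] else NA_character_,
    outcome = if (!is.null(exposure_sumstats$trait_id)) exposure_sumstats$trait_id[1L] else NA_character_
  )
  underpowered <- function() {
    .mr_result("none", NA_real_, NA_real_, character(0),
               ids$exposure, ids$outcome, status = "underpowered")
  }
  instruments <- ld_clump(outcome_sumstats, ld, p_threshold, r2_threshold)
  if (!nrow(instruments)) return(underpowered())
  pairs <- usable_pairs(harmonize(instruments, exposure_sumstats))
  if (steiger_filter && nrow(pairs)) {
    keep <- vapply(seq_len(nrow(pairs)), function(i) {
      st <- steiger_test(pairs[i, , drop = FALSE])
      st$correct_direction
    }, logical(1))
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) return(underpowered())
  if (nrow(pairs) == 1L) {
    res <- wald_ratio(pairs)
  } else {
    res <- ivw(pairs, min_instruments = 2L)
  }
  res$exposure_id <- ids$exposure
  res$outcome_id <- ids$outcome
  res
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / (n_exposures * n_outcomes)`, the multiple-testing threshold for
#' a grid of exposure-outcome MR tests.
#'
#' @param n_exposures,n_outcomes counts of exposures and outcomes actually
#'   analyzed (both >= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return the corrected p-value threshold.
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes, alpha = 0.05) {
  if (n_exposures < 1 || n_outcomes < 1) {
    stop("exposure and outcome counts must be >= 1", call. = FALSE)
  }
  alpha / (n_exposures * n_outcomes)
}
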