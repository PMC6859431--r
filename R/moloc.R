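# Multiple-trait Bayesian colocalization: Wakefield approximate Bayes
# factors, enumeration of sharing configurations, exact injective
# causal-variant placement sums, priors and posterior probabilities of
# association. All Bayes-factor arithmetic is carried in log space.

#' Wakefield approximate Bayes factor (log scale)
#'
#' For a marginal association estimate with variance `V = se^2` and a
#' `N(0, W = prior_sd^2)` effect prior, the approximate Bayes factor
#' against the null is `log ABF = 0.5 * log(1 - r) + 0.5 * z^2 * r` with
#' `r = W / (V + W)` and `z = beta / se`. A zero `prior_sd` collapses the
#' prior to a point mass at zero and returns `log ABF = 0`.
#'
#' @param beta,se association estimate and its standard error (`se > 0`);
#'   vectorized.
#' @param prior_sd prior standard deviation of the true effect
#'   (`prior_sd >= 0`).
#' @return log Bayes factor(s).
#' @export
wakefield_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (any(prior_sd < 0)) stop("prior_sd must be non-negative", call. = FALSE)
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

# all set partitions of a vector, as lists of blocks
.set_partitions <- function(x) {
  if (length(x) == 0L) return(list(list()))
  if (length(x) == 1L) return(list(list(x)))
  first <- x[1L]
  out <- list()
  for (p in .set_partitions(x[-1L])) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

.config_label <- function(groups) {
  if (!length(groups)) return("null")
  labels <- sort(vapply(groups, function(g) paste(sort(g), collapse = ""),
                        character(1)))
  paste(labels, collapse = ",")
}

#' Enumerate colocalization sharing configurations
#'
#' A configuration chooses which traits are associated in the region and
#' partitions the associated traits into groups sharing a causal variant;
#' distinct groups have distinct causal variants. For 3 traits there are
#' exactly 15 configurations including the null. Traits are labelled
#' `a`, `b`, `c`, `d` in order.
#'
#' @param n_traits number of traits (1 to 4).
#' @return named list in a canonical deterministic order; each element is a
#'   list of character vectors (the sharing groups; the null configuration
#'   is the empty list). Names are labels such as `"null"`, `"a"`,
#'   `"ab,c"`, `"abc"`.
#' @export
enumerate_configurations <- function(n_traits) {
  if (n_traits < 1 || n_traits > 4) {
    stop("n_traits must lie between 1 and 4", call. = FALSE)
  }
  traits <- letters[seq_len(n_traits)]
  configs <- list(list())
  for (k in seq_len(n_traits)) {
    subsets <- utils::combn(traits, k, simplify = FALSE)
    for (s in subsets) {
      configs <- c(configs, .set_partitions(s))
    }
  }
  labels <- vapply(configs, .config_label, character(1))
  n_assoc <- vapply(configs, function(g) length(unlist(g)), integer(1))
  n_groups <- lengths(configs)
  ord <- order(n_assoc, n_groups, labels)
  configs <- configs[ord]
  names(configs) <- labels[ord]
  configs
}

# m x n_traits matrix of per-variant log ABFs
.region_labf <- function(region, prior_sds) {
  traits <- names(region$traits)
  out <- vapply(traits, function(tr) {
    t <- region$traits[[tr]]
    wakefield_abf(t$beta, t$se, prior_sds[[tr]])
  }, numeric(length(region$variant_id)))
  matrix(out, ncol = length(traits), dimnames = list(region$variant_id, traits))
}

# exact log of the sum over injective placements of groups onto variants,
# via inclusion-exclusion on the partition lattice of the groups
.injective_log_sum <- function(lg) {
  k <- ncol(lg)
  if (nrow(lg) < k) {
    if (nrow(lg) < 2L) {
      stop("region has fewer variants than sharing groups", call. = FALSE)
    }
    return(-Inf) # more groups than variants: no injective placement exists
  }
  if (k == 1L) return(logsumexp(lg[, 1L]))
  pos <- neg <- numeric(0)
  for (p in .set_partitions(seq_len(k))) {
    sizes <- lengths(p)
    sign_neg <- sum(sizes - 1L) %% 2L == 1L
    log_coef <- sum(lgamma(sizes)) # log prod (|B|-1)!
    val <- log_coef + sum(vapply(p, function(block) {
      logsumexp(rowSums(lg[, block, drop = FALSE]))
    }, numeric(1)))
    if (sign_neg) neg <- c(neg, val) else pos <- c(pos, val)
  }
  logdiffexp(logsumexp(pos), logsumexp(neg))
}

#' Regional log Bayes factor of one sharing configuration
#'
#' For each sharing group the per-variant group evidence is the product of
#' its member traits' Wakefield ABFs at the same variant; the regional
#' Bayes factor sums, over all placements assigning each group its own
#' distinct causal variant, the product of group evidences. The sum is
#' exact (no independence approximation across groups) and computed fully
#' in log space. The null configuration has log BF 0.
#'
#' @param region a [region_data()] object.
#' @param config a configuration (list of character-vector groups, or its
#'   label as produced by [enumerate_configurations()]).
#' @param prior_sds named per-trait effect prior SDs; defaults to 0.15 for
#'   quantitative and 0.2 for binary traits.
#' @return log regional Bayes factor against the null.
#' @export
configuration_likelihood <- function(region, config, prior_sds = NULL) {
  stopifnot(inherits(region, "region_data"))
  if (is.character(config)) {
    configs <- enumerate_configurations(length(region$traits))
    if (!config %in% names(configs)) {
      stop("unknown configuration label: ", config, call. = FALSE)
    }
    config <- configs[[config]]
  }
  if (!length(config)) return(0)
  prior_sds <- prior_sds %||% default_prior_sds(region)
  labf <- .region_labf(region, prior_sds)
  lg <- vapply(config, function(g) {
    rowSums(labf[, g, drop = FALSE])
  }, numeric(nrow(labf)))
  lg <- matrix(lg, nrow = nrow(labf))
  .injective_log_sum(lg)
}

#' Default per-trait effect prior standard deviations
#'
#' The coloc-family convention: 0.15 (phenotype-SD units) for quantitative
#' traits, 0.2 (log-odds units) for binary traits.
#'
#' @param region a [region_data()] object.
#' @return named numeric vector.
#' @export
default_prior_sds <- function(region) {
  vapply(region$traits, function(t) {
    if (identical(t$trait_type, "binary")) 0.2 else 0.15
  }, numeric(1))
}

#' Run multiple-trait colocalization over one region
#'
#' Enumerates every sharing configuration, computes its regional Bayes
#' factor and combines it with a prior built from per-variant prior
#' probabilities: a group of `s` traits sharing a causal variant
#' contributes a factor `priors[s]` (defaults `p1 = 1e-4`, `p2 = 1e-6`,
#' `p3 = 1e-7`, `p4 = 1e-8`). Posteriors are normalized over all
#' configurations; `ppa_abc` is the posterior that every trait shares a
#' single causal variant, and `decision` flags `ppa_abc >= ppa_threshold`.
#'
#' @param region a [region_data()] object with at least 2 variants.
#' @param priors per-group-size per-variant prior probabilities.
#' @param prior_sds named per-trait effect prior SDs (default
#'   [default_prior_sds()]).
#' @param ppa_threshold colocalization decision threshold (default 0.8).
#' @return object of class `moloc_result`: `posteriors` (named, summing to
#'   1), `ppa_abc`, `best_snp` (per trait, the variant with the largest
#'   ABF), `priors`, `prior_sds`, `decision`, `n_variants`.
#' @export
run_moloc <- function(region, priors = c(1e-4, 1e-6, 1e-7, 1e-8),
                      prior_sds = NULL, ppa_threshold = 0.8) {
  stopifnot(inherits(region, "region_data"))
  if (length(region$variant_id) < 2L) {
    stop("colocalization needs at least 2 variants in the region", call. = FALSE)
  }
  if (any(priors <= 0)) stop("priors must be positive", call. = FALSE)
  n_traits <- length(region$traits)
  prior_sds <- prior_sds %||% default_prior_sds(region)
  configs <- enumerate_configurations(n_traits)
  log_post <- vapply(names(configs), function(lbl) {
    groups <- configs[[lbl]]
    lbf <- configuration_likelihood(region, groups, prior_sds)
    if (is.nan(lbf) || lbf == Inf) {
      stop("non-finite Bayes factor for configuration '", lbl, "'",
           call. = FALSE)
    }
    lprior <- sum(log(priors[lengths(groups)]))
    lprior + lbf
  }, numeric(1))
  posteriors <- exp(log_post - logsumexp(log_post))
  labf <- .region_labf(region, prior_sds)
  best_snp <- apply(labf, 2L, function(col) region$variant_id[which.max(col)])
  all_label <- paste(letters[seq_len(n_traits)], collapse = "")
  ppa <- unname(posteriors[[all_label]])
  structure(list(
    posteriors = posteriors,
    ppa_abc = ppa,
    best_snp = best_snp,
    priors = priors,
    prior_sds = prior_sds,
    ppa_threshold = ppa_threshold,
    decision = ppa >= ppa_threshold,
    n_variants = length(region$variant_id)
  ), class = "moloc_result")
}

#' @export
print.moloc_result <- function(x, ...) {
  cat("Multiple-trait colocalization over", x$n_variants, "variants\n")
  cat(sprintf("PPA (all traits share one causal variant): %.4f  [decision: %s at %.2f]\n",
              x$ppa_abc, if (x$decision) "colocalized" else "not colocalized",
              x$ppa_threshold))
  cat("Top configurations:\n")
  top <- sort(x$posteriors, decreasing = TRUE)
  top <- top[top > 0.001 | seq_along(top) <= 3L]
  for (i in seq_len(min(5L, length(top)))) {
    cat(sprintf("  %-10s %.4f\n", names(top)[i], top[i]))
  }
  cat("Best variant per trait:",
      paste(names(x$best_snp), x$best_snp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' eQTL pre-filter for a region
#'
#' `TRUE` iff the trait's smallest p-value in the region is strictly below
#' `p_threshold` — the rule used to restrict colocalization to tissues or
#' cell types with at least one eQTL for the target gene.
#'
#' @param region a [region_data()] object.
#' @param trait trait label within the region (e.g. `"a"`).
#' @param p_threshold strict upper bound (default 1e-4).
#' @return logical.
#' @export
eqtl_prefilter <- function(region, trait, p_threshold = 1e-4) {
  t <- region$traits[[trait]]
  if (is.null(t)) stop("unknown trait label: ", trait, call. = FALSE)
  min(two_sided_p(t$beta / t$se)) < p_threshold
}
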