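# Region containers for colocalization: aligned per-trait beta/se vectors
# over one shared, ordered variant list.

#' Construct colocalization region data
#'
#' Bundles, for one genomic region, the aligned per-trait association
#' vectors used by [run_moloc()]. Every trait must cover the identical
#' ordered variant list with finite effects and positive standard errors.
#' Wakefield ABFs depend on the association only through `(beta/se)^2` and
#' `se`, so allele orientation need not be shared across traits.
#'
#' @param variant_id ordered character vector of variant identifiers.
#' @param traits named list (conventionally `a` = expression, `b` =
#'   protein, `c` = disease); each element a list or data.frame with
#'   vectors `beta` and `se` (length matching `variant_id`), scalar or
#'   vector `n`, and a `trait_type` of `"quantitative"`/`"binary"`.
#' @param positions optional base-pair positions (for plotting).
#' @return object of class `region_data`.
#' @export
region_data <- function(variant_id, traits, positions = NULL) {
  if (length(variant_id) < 1L) stop("empty region", call. = FALSE)
  if (is.null(names(traits)) || any(!nzchar(names(traits)))) {
    stop("traits must be a named list", call. = FALSE)
  }
  m <- length(variant_id)
  traits <- lapply(traits, function(t) {
    t <- as.list(t)
    if (length(t$beta) != m || length(t$se) != m) {
      stop("every trait must cover the identical variant set", call. = FALSE)
    }
    if (anyNA(t$beta) || anyNA(t$se) || any(!is.finite(t$beta)) ||
        any(t$se <= 0)) {
      stop("missing or invalid beta/se within the region", call. = FALSE)
    }
    t$n <- rep_len(t$n %||% NA_real_, m)
    t$trait_type <- t$trait_type[1L] %||% "quantitative"
    t[c("beta", "se", "n", "trait_type")]
  })
  structure(list(variant_id = variant_id, traits = traits,
                 positions = positions),
            class = "region_data")
}

#' Assemble a colocalization region from summary-statistics tables
#'
#' Restricts each trait's table to the variants shared by all traits
#' (optionally within a cis window around a gene), aligns them in a common
#' order, and returns a [region_data()] object with traits relabelled
#' `a`, `b`, `c`, ... in the order given.
#'
#' @param sumstats_list list of summary-statistics data.frames; the
#'   conventional order is expression, protein, disease.
#' @param gene optional one-row gene annotation (`chr`, `start`, `end`);
#'   when supplied, only variants cis to the gene enter the region.
#' @param window cis window in base pairs (default 1 Mb).
#' @return a `region_data` object; errors if no variants are shared.
#' @export
assemble_region <- function(sumstats_list, gene = NULL, window = 1e6) {
  stopifnot(length(sumstats_list) >= 2L)
  shared <- Reduce(intersect, lapply(sumstats_list, function(s) s$variant_id))
  first <- sumstats_list[[1L]]
  if (!is.null(gene)) {
    sub <- first[first$variant_id %in% shared, , drop = FALSE]
    cis <- classify_cis_trans(sub, gene, window) == "cis"
    shared <- sub$variant_id[cis]
  }
  if (!length(shared)) stop("no shared variants in region", call. = FALSE)
  ref <- first[match(shared, first$variant_id), , drop = FALSE]
  shared <- shared[order(ref$pos, ref$variant_id)]
  traits <- lapply(sumstats_list, function(s) {
    rows <- s[match(shared, s$variant_id), , drop = FALSE]
    list(beta = rows$beta, se = rows$se, n = rows$n,
         trait_type = rows$trait_type[1L] %||% "quantitative")
  })
  names(traits) <- letters[seq_along(traits)]
  region_data(shared, traits,
              positions = first$pos[match(shared, first$variant_id)])
}

#' Stacked regional association plot
#'
#' Plots -log10 p-values per trait, stacked, across the region — the
#' standard way of eyeballing whether association peaks line up before
#' trusting a colocalization posterior.
#'
#' @param region a [region_data()] object with positions.
#' @param highlight optional variant id to mark in every panel.
#' @param trait_names optional display names, one per trait.
#' @return invisibly, the matrix of -log10 p-values.
#' @export
plot_region <- function(region, highlight = NULL, trait_names = NULL) {
  stopifnot(inherits(region, "region_data"))
  x <- region$positions %||% seq_along(region$variant_id)
  traits <- names(region$traits)
  labels <- trait_names %||% traits
  old <- graphics::par(mfrow = c(length(traits), 1L),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  lp <- vapply(traits, function(tr) {
    t <- region$traits[[tr]]
    -log10_two_sided_p(t$beta / t$se)
  }, numeric(length(x)))
  for (i in seq_along(traits)) {
    graphics::plot(x, lp[, i], pch = 16, cex = 0.7,
                   xlab = "", ylab = expression(-log[10](p)),
                   main = labels[i])
    if (!is.null(highlight)) {
      j <- match(highlight, region$variant_id)
      if (!is.na(j)) graphics::points(x[j], lp[j, i], pch = 18,
                                      cex = 1.4, col = "red")
    }
  }
  invisible(lp)
}

#' Leave-one-out forest plot
#'
#' @param loo leave-one-out table from [leave_one_out()].
#' @param full full-set MR result (one row, e.g. from [ivw()]) drawn as a
#'   reference line.
#' @return invisibly, `loo`.
#' @export
plot_leave_one_out <- function(loo, full = NULL) {
  k <- nrow(loo)
  ci_lo <- loo$estimate - 1.96 * loo$se
  ci_hi <- loo$estimate + 1.96 * loo$se
  xlim <- range(c(ci_lo, ci_hi, 0, if (!is.null(full)) full$estimate))
  graphics::plot(loo$estimate, seq_len(k), xlim = xlim, pch = 15,
                 yaxt = "n", xlab = "causal estimate (excluding variant)",
                 ylab = "", main = "Leave-one-out sensitivity")
  graphics::axis(2, at = seq_len(k), labels = loo$left_out_id, las = 1,
                 cex.axis = 0.7)
  graphics::segments(ci_lo, seq_len(k), ci_hi, seq_len(k))
  graphics::abline(v = 0, lty = 3)
  if (!is.null(full)) graphics::abline(v = full$estimate, col = "red", lty = 2)
  invisible(loo)
}
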