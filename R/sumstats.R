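# GWAS summary-statistics data model: file I/O, validation, harmonization,
# cis/trans classification, MAF filtering and greedy LD clumping.

.sumstats_cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")
.numeric_cols <- c("pos", "eaf", "beta", "se", "pval", "n")

#' Validate a summary-statistics table
#'
#' Checks the per-variant invariants of a GWAS summary-statistics table:
#' positive standard errors, allele frequencies strictly inside (0, 1),
#' distinct A/C/G/T alleles, p-values in (0, 1], positive sample sizes, and
#' (optionally) agreement between the reported p-value and the two-sided
#' normal p-value implied by `beta/se`, to within 10% on the -log10 scale
#' (or 0.1 absolute near p = 1).
#'
#' @param x data.frame with columns `variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param check_pval logical; also check p-value/Z consistency.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending rule and rows.
#' @export
validate_sumstats <- function(x, check_pval = TRUE) {
  missing <- setdiff(.sumstats_cols, names(x))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(rule, bad) {
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      rows <- which(bad | is.na(bad))
      stop("invalid summary statistics (", rule, ") in row(s): ",
           paste(utils::head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) " ..." else "", call. = FALSE)
    }
  }
  fail("se > 0 required", !(x$se > 0))
  fail("eaf must lie in (0, 1)", !(x$eaf > 0 & x$eaf < 1))
  fail("alleles must be A/C/G/T", !(x$effect_allele %in% c("A", "C", "G", "T") &
                                      x$other_allele %in% c("A", "C", "G", "T")))
  fail("effect and other allele must differ", x$effect_allele == x$other_allele)
  fail("pval must lie in (0, 1]", !(x$pval > 0 & x$pval <= 1))
  fail("n > 0 required", !(x$n > 0))
  if (check_pval && nrow(x)) {
    lp_rep <- -log10(x$pval)
    lp_z <- -log10_two_sided_p(x$beta / x$se)
    fail("pval inconsistent with beta/se under the normal approximation",
         abs(lp_rep - lp_z) > pmax(0.1, 0.1 * lp_z))
  }
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Parses a header-bearing tab-separated table into a validated
#' summary-statistics data.frame, preserving row order and attaching trait
#' metadata. Column names can be remapped via `col_map` for files using
#' other naming conventions.
#'
#' @param path path to a tab-separated file with a header row.
#' @param trait_id label attached to every record.
#' @param trait_type `"quantitative"` or `"binary"` (binary effect sizes are
#'   interpreted as log odds ratios downstream).
#' @param col_map optional named character vector mapping the standard names
#'   (`variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the column names used in the file, e.g.
#'   `c(variant_id = "SNP", pval = "p")`.
#' @param check_pval passed to [validate_sumstats()].
#' @return data.frame with the standard columns plus `trait_id` and
#'   `trait_type`.
#' @export
read_sumstats <- function(path, trait_id,
                          trait_type = c("quantitative", "binary"),
                          col_map = NULL, check_pval = TRUE) {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(raw))
      if (!is.na(j)) names(raw)[j] <- std
    }
  }
  missing <- setdiff(.sumstats_cols, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, .sumstats_cols]
  for (cn in .numeric_cols) {
    val <- suppressWarnings(as.numeric(out[[cn]]))
    bad <- is.na(val) & !is.na(out[[cn]]) & out[[cn]] != "NA"
    if (any(bad)) {
      stop("non-numeric value in column '", cn, "' at file line ",
           which(bad)[1L] + 1L, " of ", path, call. = FALSE)
    }
    out[[cn]] <- val
  }
  out$trait_id <- trait_id
  out$trait_type <- trait_type
  validate_sumstats(out, check_pval = check_pval)
  out
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Inverse of [read_sumstats()]: numeric columns are written with 17
#' significant digits so that a write/read round trip is field-identical.
#'
#' @param x summary-statistics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- x[, .sumstats_cols]
  for (cn in .numeric_cols) {
    out[[cn]] <- formatC(x[[cn]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a signed LD correlation matrix
#'
#' The on-disk format is a square tab-separated numeric matrix with variant
#' identifiers as both the header row and the first column. Matrices are
#' checked for symmetry, unit diagonal and entries in \[-1, 1\].
#'
#' @param path file path.
#' @return numeric matrix with variant identifiers as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  r <- as.matrix(raw)
  storage.mode(r) <- "double"
  validate_ld_matrix(r)
  r
}

#' @rdname read_ld_matrix
#' @param r square signed correlation matrix with variant-id dimnames.
#' @export
write_ld_matrix <- function(r, path) {
  validate_ld_matrix(r)
  out <- data.frame(variant_id = rownames(r), r, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ld_matrix
#' @export
validate_ld_matrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    stop("LD matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(r)) || is.null(colnames(r)) ||
      !identical(rownames(r), colnames(r))) {
    stop("LD matrix must carry identical variant-id row and column names",
         call. = FALSE)
  }
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal", call. = FALSE)
  if (max(abs(r)) > 1 + 1e-8) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  invisible(r)
}

#' Read gene coordinate annotations
#'
#' Four-column tab-separated input (`gene_id`, `chr`, `start`, `end`).
#' Coordinates are 1-based inclusive internally; BED-style half-open 0-based
#' input is accepted with `zero_based = TRUE`, which shifts starts by +1.
#'
#' @param path file path.
#' @param zero_based logical; treat input starts as 0-based (BED-style).
#' @return data.frame with columns `gene_id`, `chr`, `start`, `end`.
#' @export
read_gene_annotations <- function(path, zero_based = FALSE) {
  g <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chr", "start", "end")
  missing <- setdiff(need, names(g))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- g[, need]
  g$chr <- as.character(g$chr)
  if (zero_based) g$start <- g$start + 1L
  if (any(g$start > g$end)) stop("gene start must be <= end", call. = FALSE)
  g
}

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(a1, a2) a2 == .complement(a1)

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Aligns the outcome effects to the exposure's effect allele for every
#' variant present in both tables. Alleles are matched directly, after
#' swapping, or after strand complementation; swapped matches negate the
#' outcome beta and replace its allele frequency by one minus itself.
#' Palindromic variants (A/T or C/G) cannot be strand-resolved from alleles
#' alone: they are aligned by allele-frequency concordance when frequencies
#' are informative, and dropped when the minor-allele frequency is within
#' `palindrome_eaf_window` of 0.5 in either study. Allele sets that disagree
#' even after complementation are dropped as incompatible. Dropped records
#' carry `NA` effects so they cannot enter analysis.
#'
#' @param exposure,outcome summary-statistics data.frames sharing variant ids.
#' @param palindrome_eaf_window ambiguity window around MAF 0.5 within which
#'   palindromic variants are dropped (default 0.08).
#' @return data.frame of harmonized pairs with one row per shared variant:
#'   alleles in the exposure orientation, `beta_exposure`/`se_exposure`/
#'   `eaf_exposure`/`n_exposure`, the aligned `beta_outcome`/`se_outcome`/
#'   `eaf_outcome`/`n_outcome`, and a `status` of `aligned`, `flipped`,
#'   `dropped_palindromic` or `dropped_incompatible`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (!length(shared)) stop("no shared instruments", call. = FALSE)
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  n <- length(shared)
  status <- character(n)
  beta_o <- ou$beta
  eaf_o <- ou$eaf
  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    if (.is_palindromic(e1, e2)) {
      same_pair <- setequal(c(o1, o2), c(e1, e2))
      if (!same_pair) {
        status[i] <- "dropped_incompatible"
        next
      }
      maf_ex <- min(ex$eaf[i], 1 - ex$eaf[i])
      maf_ou <- min(ou$eaf[i], 1 - ou$eaf[i])
      if ((0.5 - maf_ex) <= palindrome_eaf_window ||
          (0.5 - maf_ou) <= palindrome_eaf_window) {
        status[i] <- "dropped_palindromic"
        next
      }
      # orient by frequency: the exposure effect allele and the outcome
      # effect allele refer to the same strand-resolved allele iff both
      # frequencies fall on the same side of 0.5
      if ((ex$eaf[i] > 0.5) == (ou$eaf[i] > 0.5)) {
        status[i] <- "aligned"
      } else {
        status[i] <- "flipped"
        beta_o[i] <- -beta_o[i]
        eaf_o[i] <- 1 - eaf_o[i]
      }
    } else {
      if (o1 == e1 && o2 == e2) {
        status[i] <- "aligned"
      } else if (o1 == e2 && o2 == e1) {
        status[i] <- "flipped"
      } else if (.complement(o1) == e1 && .complement(o2) == e2) {
        status[i] <- "aligned"
      } else if (.complement(o1) == e2 && .complement(o2) == e1) {
        status[i] <- "flipped"
      } else {
        status[i] <- "dropped_incompatible"
        next
      }
      if (status[i] == "flipped") {
        beta_o[i] <- -beta_o[i]
        eaf_o[i] <- 1 - eaf_o[i]
      }
    }
  }

  dropped <- startsWith(status, "dropped")
  out <- data.frame(
    variant_id = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ifelse(dropped, NA_real_, ex$beta),
    se_exposure = ifelse(dropped, NA_real_, ex$se),
    eaf_exposure = ex$eaf,
    n_exposure = ex$n,
    beta_outcome = ifelse(dropped, NA_real_, beta_o),
    se_outcome = ifelse(dropped, NA_real_, ou$se),
    eaf_outcome = eaf_o,
    n_outcome = ou$n,
    status = status,
    stringsAsFactors = FALSE
  )
  if (!is.null(ex$trait_id)) out$exposure_id <- ex$trait_id
  if (!is.null(ou$trait_id)) out$outcome_id <- ou$trait_id
  if (!is.null(ex$trait_type)) out$exposure_type <- ex$trait_type
  if (!is.null(ou$trait_type)) out$outcome_type <- ou$trait_type
  rownames(out) <- NULL
  out
}

#' Keep only harmonized pairs usable for analysis
#'
#' @param pairs output of [harmonize()].
#' @return the `aligned`/`flipped` rows.
#' @export
usable_pairs <- function(pairs) {
  pairs[pairs$status %in% c("aligned", "flipped"), , drop = FALSE]
}

#' Classify variants as cis or trans relative to a gene
#'
#' A variant is cis iff it lies on the gene's chromosome within
#' `window` base pairs of either end of the gene body (1-based inclusive
#' coordinates); everything else, including other chromosomes, is trans.
#'
#' @param variants data.frame with `chr` and `pos` columns (one or more rows).
#' @param gene one-row data.frame or list with `chr`, `start`, `end`.
#' @param window flanking distance in base pairs (default 1 Mb).
#' @return character vector of `"cis"`/`"trans"`, one per variant.
#' @export
classify_cis_trans <- function(variants, gene, window = 1e6) {
  ifelse(variants$chr == gene$chr &
           variants$pos >= gene$start - window &
           variants$pos <= gene$end + window,
         "cis", "trans")
}

#' Filter variants by minor-allele frequency
#'
#' Keeps records with `min(eaf, 1 - eaf) >= min_maf` (boundary inclusive),
#' mirroring the exclusion of instruments too rare for two-sample MR.
#'
#' @param records summary-statistics data.frame.
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @return the retained rows.
#' @export
filter_maf <- function(records, min_maf = 0.05) {
  records[pmin(records$eaf, 1 - records$eaf) >= min_maf, , drop = FALSE]
}

#' Greedy LD clumping of summary statistics
#'
#' Discards records with `pval >= p_threshold`, then repeatedly takes the
#' remaining record with the smallest p-value as an index variant and
#' removes every remaining record with squared correlation above
#' `r2_threshold` against it. Ties on p-value are broken by lexicographic
#' variant id, making the output invariant to input ordering. The returned
#' set is mutually independent at `r2_threshold` and genome-wide
#' significant at `p_threshold`.
#'
#' @param records summary-statistics data.frame.
#' @param ld signed LD correlation matrix covering all records.
#' @param p_threshold instrument p-value threshold (default 5e-8).
#' @param r2_threshold squared-correlation independence threshold
#'   (default 0.001).
#' @return the retained rows, ordered by selection (ascending p-value).
#' @export
ld_clump <- function(records, ld, p_threshold = 5e-8, r2_threshold = 0.001) {
  absent <- setdiff(records$variant_id, rownames(ld))
  if (length(absent)) {
    stop("variant(s) absent from LD matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  cand <- records[records$pval < p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  keep <- character(0)
  while (nrow(cand)) {
    index <- cand$variant_id[1L]
    keep <- c(keep, index)
    r2 <- ld[index, cand$variant_id]^2
    cand <- cand[r2 <= r2_threshold, , drop = FALSE]
  }
  out <- records[match(keep, records$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
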