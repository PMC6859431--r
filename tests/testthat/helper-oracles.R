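# Independent oracles kept separate from the implementation paths they
# check: Bayes factors via the marginal-likelihood-ratio form, regional
# Bayes factors via exhaustive placement enumeration in plain space, the
# IVW slope via a weighted regression fit, and greedy clumping re-derived
# from its definition.

abf_oracle <- function(beta, se, prior_sd) {
  exp(dnorm(beta, 0, sqrt(se^2 + prior_sd^2), log = TRUE) -
        dnorm(beta, 0, se, log = TRUE))
}

oracle_config_logbf <- function(abf_mat, groups) {
  if (!length(groups)) return(0)
  m <- nrow(abf_mat)
  total <- 0
  rec <- function(g, used, acc) {
    if (g > length(groups)) {
      total <<- total + acc
      return(invisible())
    }
    for (v in setdiff(seq_len(m), used)) {
      rec(g + 1L, c(used, v), acc * prod(abf_mat[v, groups[[g]]]))
    }
  }
  rec(1L, integer(0), 1)
  log(total)
}

wls_slope_oracle <- function(pairs) {
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = pairs,
            weights = 1 / pairs$se_outcome^2)
  unname(coef(fit))
}

greedy_clump_oracle <- function(records, ld, p_threshold, r2_threshold) {
  cand <- records[records$pval < p_threshold, , drop = FALSE]
  selected <- character(0)
  while (nrow(cand)) {
    cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
    index <- cand$variant_id[1L]
    selected <- c(selected, index)
    cand <- cand[ld[index, cand$variant_id]^2 <= r2_threshold, , drop = FALSE]
  }
  selected
}
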