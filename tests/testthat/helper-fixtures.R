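# In-code fixtures: summary-statistics rows with internally consistent
# p-values, harmonized pairs, colocalization regions, and a lazily cached
# demonstration study shared across test files.

make_sumstats <- function(variant_id, effect_allele, other_allele, eaf, beta,
                          se, n = 10000, chr = "1",
                          pos = seq_along(variant_id) * 1000,
                          trait_id = "T", trait_type = "quantitative") {
  z <- beta / se
  data.frame(
    variant_id = variant_id, chr = chr, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se,
    pval = pmin(pmax(2 * pnorm(-abs(z)), .Machine$double.xmin), 1),
    n = n, trait_id = trait_id, trait_type = trait_type,
    stringsAsFactors = FALSE
  )
}

make_pairs <- function(k, seed = 1) {
  set.seed(seed)
  data.frame(
    variant_id = sprintf("v%02d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = runif(k, 0.05, 0.5) * sample(c(-1, 1), k, replace = TRUE),
    se_exposure = runif(k, 0.01, 0.1),
    eaf_exposure = runif(k, 0.1, 0.9),
    n_exposure = 5000,
    beta_outcome = rnorm(k, 0, 0.2),
    se_outcome = runif(k, 0.01, 0.1),
    eaf_outcome = runif(k, 0.1, 0.9),
    n_outcome = 5000,
    status = "aligned",
    stringsAsFactors = FALSE
  )
}

make_region <- function(m, seed = 1, beta = NULL, se = NULL,
                        types = c("quantitative", "quantitative", "binary")) {
  set.seed(seed)
  if (is.null(beta)) beta <- matrix(rnorm(m * 3, 0, 0.1), m, 3)
  if (is.null(se)) se <- matrix(runif(m * 3, 0.02, 0.08), m, 3)
  ids <- sprintf("v%02d", seq_len(m))
  region_data(ids, list(
    a = list(beta = beta[, 1], se = se[, 1], n = 5000, trait_type = types[1]),
    b = list(beta = beta[, 2], se = se[, 2], n = 5000, trait_type = types[2]),
    c = list(beta = beta[, 3], se = se[, 3], n = 5000, trait_type = types[3])
  ))
}

# demonstration study, simulated and run once per test session
.demo_cache <- new.env(parent = emptyenv())

demo_report_cached <- function() {
  if (is.null(.demo_cache$report)) {
    .demo_cache$dir <- tempfile("mrmoloc_demo_test_")
    config <- demo_study(dir = .demo_cache$dir, seed = 1)
    .demo_cache$report <- run_study(config)
  }
  .demo_cache$report
}
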