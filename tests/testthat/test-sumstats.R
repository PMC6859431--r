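test_that("summary statistics survive a write/read round trip field-identically", {
  x <- make_sumstats(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "T"),
    eaf = c(1 / 3, 0.25, 0.5), beta = c(0.1234567890123, -1 / 7, 0),
    se = c(pi / 30, 0.05, 0.02), n = c(5000, 5000, 4000)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path, trait_id = "T")
  cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  expect_equal(y[, cols], x[, cols], tolerance = 0)
})

test_that("reading rejects malformed files with informative errors", {
  x <- make_sumstats("rs1", "A", "G", 0.3, 0.1, 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")

  write_sumstats(x, path)
  tab <- read.delim(path, colClasses = "character")
  utils::write.table(tab[, setdiff(names(tab), "se")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path, "T"), "se")

  write_sumstats(x, path)
  lines <- readLines(path)
  fields <- strsplit(lines[2], "\t")[[1]]
  fields[which(strsplit(lines[1], "\t")[[1]] == "beta")] <- "not_a_number"
  lines[2] <- paste(fields, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_sumstats(path, "T"), "line 2")

  bad <- x
  bad$eaf <- 1.2
  expect_error(validate_sumstats(bad), "eaf")
  bad <- x
  bad$se <- -0.01
  expect_error(validate_sumstats(bad), "se")
  bad <- x
  bad$pval <- 0.5 # wildly inconsistent with |beta/se|
  bad$beta <- 5
  expect_error(validate_sumstats(bad), "inconsistent")
})

test_that("harmonization aligns, flips, strand-resolves and drops correctly", {
  exp_ss <- make_sumstats(
    c("v1", "v2", "v3", "v4", "v5", "v6", "v7"),
    effect_allele = c("A", "A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "T", "T", "T"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.49, 0.20, 0.20),
    beta = rep(0.1, 7), se = rep(0.02, 7)
  )
  out_ss <- make_sumstats(
    c("v1", "v2", "v3", "v4", "v5", "v6", "v7"),
    effect_allele = c("A", "G", "T", "C", "A", "A", "T"),
    other_allele = c("G", "A", "C", "T", "T", "T", "A"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.49, 0.25, 0.75),
    beta = rep(0.05, 7), se = rep(0.02, 7)
  )
  h <- harmonize(exp_ss, out_ss)
  expect_equal(h$status,
               c("aligned", "flipped", "aligned", "flipped",
                 "dropped_palindromic", "aligned", "flipped"))
  expect_equal(h$beta_outcome[1], 0.05)   # identity orientation untouched
  expect_equal(h$beta_outcome[2], -0.05)  # swapped alleles negate the effect
  expect_equal(h$eaf_outcome[2], 0.7)
  expect_equal(h$beta_outcome[3], 0.05)   # strand flip, same orientation
  expect_equal(h$beta_outcome[4], -0.05)  # strand flip + swap
  expect_true(is.na(h$beta_outcome[5]))   # ambiguous palindromic carries no beta
  expect_equal(h$beta_outcome[6], 0.05)   # palindromic, frequencies concordant
  expect_equal(h$beta_outcome[7], -0.05)  # palindromic, frequencies discordant
  expect_equal(h$eaf_outcome[7], 0.25)

  incompat <- out_ss[1, ]
  incompat$other_allele <- "C" # A/C cannot match A/G on any strand
  expect_equal(harmonize(exp_ss[1, ], incompat)$status, "dropped_incompatible")

  expect_error(harmonize(exp_ss[1:2, ], out_ss[3:4, ] |>
                           transform(variant_id = c("x1", "x2"))),
               "no shared instruments")
})

test_that("harmonizing an already-aligned pair changes nothing", {
  exp_ss <- make_sumstats(c("v1", "v2"), c("A", "C"), c("G", "T"),
                          eaf = c(0.3, 0.4), beta = c(0.1, -0.2),
                          se = c(0.02, 0.03))
  out_ss <- make_sumstats(c("v1", "v2"), c("G", "T"), c("A", "C"),
                          eaf = c(0.6, 0.7), beta = c(0.05, 0.08),
                          se = c(0.02, 0.03))
  h1 <- harmonize(exp_ss, out_ss)
  expect_equal(h1$status, c("flipped", "flipped"))
  # express the harmonized outcome as a sumstats table and harmonize again
  out2 <- out_ss
  out2$effect_allele <- h1$effect_allele
  out2$other_allele <- h1$other_allele
  out2$beta <- h1$beta_outcome
  out2$eaf <- h1$eaf_outcome
  h2 <- harmonize(exp_ss, out2)
  expect_equal(h2$status, c("aligned", "aligned"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
})

test_that("cis/trans classification honours the gene-body window on both ends", {
  gene <- data.frame(gene_id = "G", chr = "1", start = 5e6, end = 5.1e6)
  v <- data.frame(chr = c("1", "1", "1", "1", "2"),
                  pos = c(5e6, 5e6 - 1e6, 5e6 - 1e6 - 1, 5.1e6 + 1e6, 5e6))
  expect_equal(classify_cis_trans(v, gene),
               c("cis", "cis", "trans", "cis", "trans"))
})

test_that("the MAF filter is boundary-inclusive on the minor allele", {
  x <- make_sumstats(c("v1", "v2", "v3", "v4"), "A", "G",
                     eaf = c(0.96, 0.05, 0.50, 0.04),
                     beta = 0.1, se = 0.05)
  kept <- filter_maf(x)
  expect_equal(kept$variant_id, c("v2", "v3"))
})

test_that("LD clumping is greedy on p, tie-broken by id, and order-invariant", {
  ids <- sprintf("s%d", 1:2)
  ld <- diag(2)
  ld[1, 2] <- ld[2, 1] <- 1
  dimnames(ld) <- list(ids, ids)
  x <- make_sumstats(ids, "A", "G", eaf = 0.3, beta = c(0.30, 0.28),
                     se = 0.02, pos = c(1, 2))
  expect_equal(ld_clump(x, ld)$variant_id, "s1") # perfect LD: smaller p wins

  single <- x[1, ]
  expect_equal(ld_clump(single, ld)$variant_id, "s1")

  # equal p-values break lexicographically
  tie <- make_sumstats(c("sB", "sA"), "A", "G", eaf = 0.3, beta = 0.3,
                       se = 0.02, pos = c(1, 2))
  ld_tie <- diag(2) * 0 + 1
  dimnames(ld_tie) <- list(c("sB", "sA"), c("sB", "sA"))
  diag(ld_tie) <- 1
  expect_equal(ld_clump(tie, ld_tie)$variant_id, "sA")

  # six-variant case against the greedy oracle, under row permutations
  set.seed(42)
  ids6 <- sprintf("s%d", 1:6)
  r <- matrix(c(
    1,    0.9,  0.05, 0.02, 0.01, 0.0,
    0.9,  1,    0.04, 0.03, 0.02, 0.0,
    0.05, 0.04, 1,    0.85, 0.02, 0.01,
    0.02, 0.03, 0.85, 1,    0.01, 0.02,
    0.01, 0.02, 0.02, 0.01, 1,    0.2,
    0.0,  0.0,  0.01, 0.02, 0.2,  1), 6, 6,
    dimnames = list(ids6, ids6))
  x6 <- make_sumstats(ids6, "A", "G", eaf = 0.3,
                      beta = c(0.30, 0.32, 0.25, 0.24, 0.28, 0.001),
                      se = 0.02, pos = 1:6)
  expected <- greedy_clump_oracle(x6, r, 5e-8, 0.001)
  got <- ld_clump(x6, r)$variant_id
  expect_equal(got, expected)
  for (perm in list(6:1, c(3, 1, 6, 2, 5, 4))) {
    expect_equal(ld_clump(x6[perm, ], r)$variant_id, expected)
  }

  expect_error(ld_clump(transform(x6, variant_id = sub("s", "z", variant_id)), r),
               "z1")
})

test_that("clump output is always pairwise independent at the r2 threshold", {
  for (seed in 1:5) {
    G <- simulate_genotypes(400, rep(c(0.2, 0.35), 15), ld_rho = 0.7,
                            seed = seed)
    ld <- cor(G)
    ids <- sprintf("v%02d", 1:30)
    dimnames(ld) <- list(ids, ids)
    set.seed(seed)
    x <- make_sumstats(ids, "A", "G", eaf = 0.3,
                       beta = runif(30, 0.1, 0.4), se = 0.02, pos = 1:30)
    kept <- ld_clump(x, ld, p_threshold = 5e-8, r2_threshold = 0.05)
    r2 <- ld[kept$variant_id, kept$variant_id, drop = FALSE]^2
    diag(r2) <- 0
    expect_lte(max(r2), 0.05)
  }
})

test_that("LD matrices and gene annotations round-trip with validation", {
  G <- simulate_genotypes(200, c(0.2, 0.3, 0.4), 0.5, seed = 3)
  r <- cor(G)
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(r, path)
  expect_equal(read_ld_matrix(path), r, tolerance = 1e-12)
  bad <- r
  bad[1, 2] <- 0.9 # breaks symmetry
  expect_error(validate_ld_matrix(bad), "symmetric")

  g <- data.frame(gene_id = "G1", chr = "1", start = 100L, end = 200L)
  gpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(g, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gene_annotations(gpath)$start, 100L)
  expect_equal(read_gene_annotations(gpath, zero_based = TRUE)$start, 101L)
})
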