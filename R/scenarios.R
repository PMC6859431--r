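# Packaged simulation scenarios. These fix the study conditions under which
# the framework is exercised and validated: a full demonstration study (one
# circulating protein, one disease, three cell types with one sharing cell
# type), a slope-recovery scenario for IVW calibration, and shared- vs
# distinct-variant scenarios for colocalization discrimination.

#' Demonstration study scenario
#'
#' One LD region of 120 variants (25 kb spacing, AR(1) latent correlation
#' 0.6) carrying five traits, each in its own cohort:
#' \itemize{
#'   \item expression of the target gene in three cell types (monocyte,
#'     neutrophil, T cell; n = 500 each, per-allele effect 0.8 SD) — the
#'     monocyte eQTL sits on the protein's cis variant, the other two cell
#'     types have their own distinct cis eQTLs;
#'   \item the circulating protein `CYT1` (n = 5000) with one cis variant
#'     (v010, effect 0.35 SD) and two trans variants (v060, v110, 0.30 SD);
#'   \item the disease `IMD1` (binary, n = 25000, prevalence 0.2) with two
#'     causal variants of its own (v078, v098, log-odds 0.4) outside the
#'     cis window, plus a true causal effect of the protein on disease
#'     liability of 0.5 log-odds per protein unit.
#' }
#' The causal chain genotype -> protein -> disease makes the forward MR
#' signal real and colocalizes expression, protein and disease at the
#' shared cis variant in monocytes only. Protein-causal variants may reach
#' genome-wide significance in the disease GWAS through the mediated path;
#' the reverse analysis excludes them via its directionality filter and is
#' instrumented by the disease's own loci.
#'
#' @param seed simulation seed.
#' @return a [sim_scenario()].
#' @export
demo_scenario <- function(seed = 1L) {
  m <- 120L
  maf <- rep(c(0.18, 0.25, 0.32, 0.39, 0.46, 0.22, 0.29, 0.36, 0.43, 0.20),
             length.out = m)
  sim_scenario(
    n_variants = m,
    maf = maf,
    ld_rho = 0.6,
    cohort_sizes = c(expr_mono = 500L, expr_neut = 500L, expr_tcell = 500L,
                     CYT1 = 5000L, IMD1 = 25000L),
    causal_map = list(
      expr_mono = data.frame(index = 10L, beta = 0.8),
      expr_neut = data.frame(index = 25L, beta = 0.8),
      expr_tcell = data.frame(index = 35L, beta = 0.8),
      CYT1 = data.frame(index = c(10L, 60L, 110L), beta = c(0.35, 0.30, 0.30)),
      IMD1 = data.frame(index = c(78L, 98L), beta = c(0.4, 0.4))
    ),
    trait_types = c(expr_mono = "quantitative", expr_neut = "quantitative",
                    expr_tcell = "quantitative", CYT1 = "quantitative",
                    IMD1 = "binary"),
    disease_prevalence = 0.2,
    causal_beta_exposure_to_outcome = 0.5,
    exposure_trait = "CYT1",
    outcome_trait = "IMD1",
    seed = seed
  )
}

#' Gene annotation matching [demo_scenario()]
#'
#' The target gene `GENE1` spans 230-240 kb on chromosome 1, containing the
#' shared causal variant v010; with the default 1 Mb window, variants up to
#' index 50 are cis and the protein's trans variants and the disease's own
#' variants fall outside.
#'
#' @return one-row gene annotation data.frame.
#' @export
demo_gene_annotation <- function() {
  data.frame(gene_id = "GENE1", chr = "1", start = 230000L, end = 240000L,
             stringsAsFactors = FALSE)
}

#' Materialize the demonstration study on disk
#'
#' Simulates [demo_scenario()], writes every input file (per-trait summary
#' statistics, LD matrix, gene annotations, truth record and a YAML study
#' configuration) and returns a ready-to-run [study_config()].
#'
#' @param dir output directory (default a fresh temporary directory).
#' @param seed simulation seed.
#' @return a `study_config` whose `output_dir` points inside `dir`.
#' @export
demo_study <- function(dir = tempfile("mrmoloc_demo_"), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_traits_and_sumstats(demo_scenario(seed))
  paths <- write_sim_output(sim, dir)
  genes_path <- file.path(dir, "genes.tsv")
  utils::write.table(demo_gene_annotation(), genes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  config <- study_config(
    exposures = data.frame(trait_id = "CYT1", gene_id = "GENE1",
                           path = paths$CYT1, trait_type = "quantitative",
                           stringsAsFactors = FALSE),
    outcomes = data.frame(trait_id = "IMD1", path = paths$IMD1,
                          trait_type = "binary", stringsAsFactors = FALSE),
    expression = data.frame(
      cell_type = c("monocyte", "neutrophil", "tcell"),
      gene_id = "GENE1",
      trait_id = c("expr_mono", "expr_neut", "expr_tcell"),
      path = c(paths$expr_mono, paths$expr_neut, paths$expr_tcell),
      stringsAsFactors = FALSE),
    ld_matrix = paths$ld,
    genes = genes_path,
    output_dir = file.path(dir, "results"),
    seed = seed
  )
  yaml::write_yaml(list(
    exposures = list(list(trait_id = "CYT1", gene_id = "GENE1",
                          path = basename(paths$CYT1),
                          trait_type = "quantitative")),
    outcomes = list(list(trait_id = "IMD1", path = basename(paths$IMD1),
                         trait_type = "binary")),
    expression = list(
      list(cell_type = "monocyte", gene_id = "GENE1", trait_id = "expr_mono",
           path = basename(paths$expr_mono)),
      list(cell_type = "neutrophil", gene_id = "GENE1", trait_id = "expr_neut",
           path = basename(paths$expr_neut)),
      list(cell_type = "tcell", gene_id = "GENE1", trait_id = "expr_tcell",
           path = basename(paths$expr_tcell))
    ),
    ld_matrix = basename(paths$ld),
    genes = basename(genes_path),
    output_dir = file.path(dir, "results"),
    seed = as.integer(seed)
  ), file.path(dir, "config.yaml"))
  config
}

#' Slope-recovery scenario for IVW calibration
#'
#' Five mutually independent instruments (LD rho 0), each with a 0.3-SD
#' effect on a quantitative exposure (n = 5000), and a quantitative outcome
#' (n = 5000, separate cohort) generated from the exposure's genetic score
#' scaled by the true slope. The outcome's residual SD is 3, so the
#' exposure explains well under 1% of outcome variance — the regime the
#' fixed-effect IVW targets, since its standard error carries only the
#' outcome-side uncertainty. Used to check that the IVW 95% confidence
#' interval attains nominal coverage.
#'
#' @param slope true causal effect of exposure on outcome.
#' @param seed simulation seed.
#' @return a [sim_scenario()].
#' @export
mr_recovery_scenario <- function(slope, seed = 1L) {
  sim_scenario(
    n_variants = 5L,
    maf = c(0.20, 0.25, 0.30, 0.35, 0.40),
    ld_rho = 0,
    cohort_sizes = c(EXP = 5000L, OUT = 5000L),
    causal_map = list(
      EXP = data.frame(index = 1:5, beta = rep(0.3, 5)),
      OUT = data.frame(index = integer(0), beta = numeric(0))
    ),
    trait_types = c(EXP = "quantitative", OUT = "quantitative"),
    noise_sd = c(EXP = 1, OUT = 3),
    causal_beta_exposure_to_outcome = slope,
    exposure_trait = "EXP",
    outcome_trait = "OUT",
    seed = seed
  )
}

#' Colocalization discrimination scenarios
#'
#' A 24-variant region (AR(1) latent correlation 0.5) with an expression
#' trait, a protein trait (both quantitative, n = 5000, effect 0.25 SD) and
#' a binary disease trait (n = 5000, prevalence 0.3, log-odds 0.35). In the
#' `"shared"` arrangement all three traits are driven by variant 12; in the
#' `"distinct"` arrangement they are driven by the well-separated variants
#' 4, 12 and 20.
#'
#' @param arrangement `"shared"` or `"distinct"`.
#' @param seed simulation seed.
#' @return a [sim_scenario()].
#' @export
coloc_scenario <- function(arrangement = c("shared", "distinct"), seed = 1L) {
  arrangement <- match.arg(arrangement)
  idx <- if (arrangement == "shared") c(12L, 12L, 12L) else c(4L, 12L, 20L)
  sim_scenario(
    n_variants = 24L,
    maf = rep(c(0.20, 0.30, 0.40, 0.25), length.out = 24L),
    ld_rho = 0.5,
    cohort_sizes = c(expr = 5000L, prot = 5000L, disease = 5000L),
    causal_map = list(
      expr = data.frame(index = idx[1L], beta = 0.25),
      prot = data.frame(index = idx[2L], beta = 0.25),
      disease = data.frame(index = idx[3L], beta = 0.35)
    ),
    trait_types = c(expr = "quantitative", prot = "quantitative",
                    disease = "binary"),
    disease_prevalence = 0.3,
    exposure_trait = "expr",
    seed = seed
  )
}

#' Simulate a discrimination scenario and run colocalization on it
#'
#' Convenience wrapper: simulates [coloc_scenario()], assembles the full
#' region over all 24 variants and returns the [run_moloc()] result.
#'
#' @inheritParams coloc_scenario
#' @param ... passed to [run_moloc()].
#' @return a `moloc_result`.
#' @export
run_coloc_scenario <- function(arrangement = c("shared", "distinct"),
                               seed = 1L, ...) {
  sim <- simulate_traits_and_sumstats(coloc_scenario(arrangement, seed))
  region <- assemble_region(sim$sumstats[c("expr", "prot", "disease")])
  run_moloc(region, ...)
}
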