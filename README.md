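# mrmoloc

Two-sample Mendelian randomization (MR) integrated with multiple-trait
Bayesian colocalization, for nominating **cell-specific molecular drivers
of disease** from GWAS-style summary statistics.

The intended user has, for each candidate biomarker (a circulating
cytokine or receptor), summary statistics for: the biomarker itself
(pQTL-style GWAS), one or more diseases, and the expression of the
biomarker's encoding gene in several cell types or tissues (eQTL panels).
`mrmoloc` answers two questions in sequence:

1. **Does the biomarker causally affect the disease?** Two-sample MR with
   genetic instruments, in two modes:
   - *conservative* — a single cis-acting genome-wide-significant variant
     (within 1 Mb of the gene, MAF ≥ 0.05), estimated by the Wald ratio
     $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$;
   - *liberal* — all clumped instruments (cis or trans, $p < 5\times10^{-8}$,
     $r^2 < 0.001$), combined by the fixed-effect inverse-variance-weighted
     estimator
     $\hat\beta_{IVW} = \sum_j \hat\gamma_j^2\sigma_{Yj}^{-2}\hat\beta_j \big/ \sum_j \hat\gamma_j^2\sigma_{Yj}^{-2}$,
     with leave-one-out, reverse-MR and Steiger directionality sensitivity
     analyses and Bonferroni control at
     $\alpha/(\text{exposures}\times\text{outcomes})$.
2. **Through which cell type?** For every MR-supported pair, three-trait
   Bayesian colocalization of cell-type expression (*a*), circulating
   protein (*b*) and disease (*c*) over the cis region: Wakefield
   approximate Bayes factors per variant, exact enumeration of all 15
   sharing configurations, and the posterior probability
   $\mathrm{PPA}_{abc}$ that all three signals share one causal variant
   (colocalized when ≥ 0.8), run once per cell type.

A synthetic-data module simulates LD-structured genotypes and two-sample
summary statistics with controlled causal-variant sharing, so the whole
framework installs, runs and validates with no external downloads. See the
methods vignette (`vignettes/cell-specific-mr-moloc.Rmd`) for the models,
assumptions and design decisions.

## Worked example

The packaged demonstration study simulates one circulating protein
(`CYT1`, its gene on a 120-variant region), one binary disease (`IMD1`,
truly caused by the protein with liability effect 0.5), and the gene's
expression in three cell types — only the monocyte eQTL sits on the
protein's cis variant.

```r
library(mrmoloc)
config <- demo_study(seed = 1)   # writes inputs + config to a temp dir
report <- run_study(config)
print(report)
#> mrmoloc study report
#>   conservative MR: 1 pair(s), threshold 0.05, 1 significant
#>   liberal MR: 1 pair(s), threshold 0.05, 1 significant
#>   reverse MR rows: 1; Steiger rows: 2
#>   moloc rows: 3 (1 colocalized)

report$liberal$table[, c("method", "n_instruments", "estimate", "se", "pval")]
#>  method n_instruments  estimate         se         pval
#>     ivw             3 0.4840499 0.05294004 6.054134e-20
```

The liberal IVW estimate (0.484 ± 0.053, three instruments) recovers the
true causal slope of 0.5 and passes the Bonferroni threshold. The reverse
analysis — instrumented by the disease's own loci — is null, and Steiger
confirms the instruments act through the protein:

```r
report$sensitivity$reverse[, c("estimate", "se", "pval", "status")]
#>    estimate         se      pval status
#>  0.03686003 0.04149054 0.3743279     ok
```

Colocalization then localizes the mechanism to the sharing cell type:

```r
report$moloc[, c("cell_type", "status", "ppa_abc", "decision", "best_snp_a")]
#>   cell_type status      ppa_abc decision best_snp_a
#>    monocyte     ok 9.999988e-01     TRUE       v010
#>  neutrophil     ok 4.365650e-31    FALSE       v025
#>       tcell     ok 1.632588e-22    FALSE       v035
```

$\mathrm{PPA}_{abc} > 0.999$ in monocytes — expression, protein and
disease share the causal variant v010 — while the neutrophil and T-cell
eQTLs (distinct variants) are correctly rejected. All tables are also
written tab-separated to `config$output_dir`, together with a run log
carrying the package version, configuration hash and seed.

A thin command-line wrapper with `simulate`, `mr`, `moloc` and `run`
subcommands is installed at `inst/cli/mrmoloc.R`:

```sh
Rscript inst/cli/mrmoloc.R simulate --out demo --seed 1
Rscript inst/cli/mrmoloc.R run --config demo/config.yaml
```

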