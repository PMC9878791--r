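#!/usr/bin/env Rscript
# Optional integration check against the two published benchmark cohorts
# (Scn10a^G1662S and Scn9a^R185H supplementary tables). The tables are not
# redistributable with this package; download them yourself and run
#
#   Rscript paper_benchmarks.R <scn10a.xlsx|csv> <scn9a.xlsx|csv> \
#       <dependent-col> <sex-col> [id-col]
#
# Expected (published) behaviour:
#   Scn10a: 112 rows; no predictor pair with |r| >= 0.75; sel30 model of
#           9 variables; full-model cumulative variance over 10 dims ~86%;
#           sel30 cumulative variance 100%.
#   Scn9a:  73 rows; sel30 model of 6 variables; full-model cumulative
#           variance ~84%.

suppressPackageStartupMessages(library(phenodisc))
a <- commandArgs(trailingOnly = TRUE)
if (length(a) < 4) stop("need: scn10a-file scn9a-file dependent-col sex-col [id-col]")

check <- function(path, label, n_expect, sel_expect, cumvar_expect) {
  cfg <- pd_config(dependent = a[3], conditioning = a[4],
                   id = if (length(a) >= 5) a[5] else NULL, seed = 1)
  res <- run_pipeline(path, cfg, outdir = file.path("paper_benchmarks", label))
  n <- nrow(res$table$data)
  maxr <- {
    r <- abs(res$selection$r); diag(r) <- NA
    r[res$selection$method == "cramers_v"] <- NA
    max(r, na.rm = TRUE)
  }
  n_sel <- length(res$models$sel30$variables) + 1L  # + dependent, as published
  cv10 <- utils::tail(res$models$full$cumulative_variance$cumulative, 1)
  cv_sel <- utils::tail(res$models$sel30$cumulative_variance$cumulative, 1)
  cat(sprintf("%s: n=%d (expect %d); max |r|=%.3f; sel30=%d vars (expect %d); ",
              label, n, n_expect, maxr, n_sel, sel_expect))
  cat(sprintf("full cumvar10=%.1f%% (expect ~%d%%); sel30 cumvar=%.1f%%\n",
              cv10, cumvar_expect, cv_sel))
}

check(a[1], "scn10a", 112L, 9L, 86L)
check(a[2], "scn9a", 73L, 6L, 84L)
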