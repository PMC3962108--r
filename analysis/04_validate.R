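#!/usr/bin/env Rscript
# Stage 4: self-contained validation report — analytic conversions, planted
# frequency recovery, formula identities, zero-noise invertibility and the
# 200-plate null false-positive suite.

suppressPackageStartupMessages(library(rrmlilt))
val <- run_validate(seed = 1L, n_null_plates = 200L, out_dir = "results")
print(val$checks, right = FALSE)
cat("\nprovenance:\n")
str(val$provenance, give.attr = FALSE)
cat(if (val$pass) "\nALL CHECKS PASSED\n" else "\nSOME CHECKS FAILED\n")
if (!val$checks$pass[val$checks$check == "null_false_positive_rate"])
  cat("note: the null-rate check is a 95% binomial band around alpha and is\n",
      "expected to fail for ~5% of seeds even when the ANOVA stage is exactly\n",
      "calibrated; rerun with other seeds (run_validate(seed = ...)) to see\n",
      "the rate fluctuate around 0.05.\n", sep = "")
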