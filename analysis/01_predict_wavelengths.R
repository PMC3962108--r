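#!/usr/bin/env Rscript
# Stage 1: RRM spectral analysis and therapeutic-wavelength prediction.
#
# The published oncogene / proto-oncogene sequence sets are not deposited, so
# two synthetic groups are generated with spectral components planted at the
# published characteristic frequencies (0.0302 and 0.0576 cycles/residue).
# The pipeline then recovers each group's consensus peak, converts it to a
# wavelength via lambda = 201/f, and selects the nearest LED from the
# 12-wavelength exposure catalog.

suppressPackageStartupMessages(library(rrmlilt))
seed <- 1303L
dir.create("results/predict", showWarnings = FALSE, recursive = TRUE)

tab <- eiip_table()
cat("EIIP table", tab$version_tag, "md5", tab$md5, "\n\n")

groups <- list(
  oncogene_like       = protein_group_spec(n_seqs = 10, f_target = 0.0302,
                                           length_range = c(600L, 900L),
                                           seed = seed),
  proto_oncogene_like = protein_group_spec(n_seqs = 10, f_target = 0.0576,
                                           length_range = c(600L, 900L),
                                           seed = seed + 1L)
)
fasta <- character(0)
for (g in names(groups)) {
  path <- file.path("results/predict", paste0(g, ".fasta"))
  write_fasta_group(generate_protein_group(groups[[g]], tab), path)
  fasta[g] <- path
}

rep <- run_predict(fasta, out_dir = "results/predict", table = tab)
print(rep$predictions, digits = 4)
if (length(rep$warnings)) cat("\nwarnings:\n", paste("-", rep$warnings, collapse = "\n"), "\n")

# the published conversions themselves, plus the therapeutic window they bound
cat("\nPublished characteristic frequencies:\n")
for (f in c(0.0302, 0.0576)) {
  p <- frequency_to_wavelength(f)
  cat(sprintf("  f = %.4f -> %d nm (%.3g Hz, in window: %s)\n",
              f, p$lambda_nm_rounded, p$freq_hz, p$in_window))
}
w <- wavelength_window(0.0302, 0.0576)
cat(sprintf("  therapeutic window: %.0f - %.0f nm\n", w[1], w[2]))
cat(sprintf("  dose over 1.5 h at 15 uW: %.0f uJ; over 3 h at 30 uW: %.0f uJ\n",
            exposure_dose(15, 1.5), exposure_dose(30, 3)))
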