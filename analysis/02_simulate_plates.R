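#!/usr/bin/env Rscript
# Stage 2: simulate the study's plate-reader datasets.
#
# Factorial design: MCF7 and HEM cell lines x LDH and PrestoBlue assays x
# three exposure regimes x 12 wavelengths (6 far-IR, 3 near-IR, 3 visible),
# triplicate wells x three repeats, effect sizes from the shipped
# calibration table. Outputs CSVs matching the assay-analysis input schema
# plus a ground-truth sidecar.

suppressPackageStartupMessages(library(rrmlilt))
seed <- 20131020L
out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

wavelengths <- led_catalog()$nominal_wavelength_nm
runs <- expand.grid(cell_line = c("MCF7", "HEM"),
                    assay = c("LDH", "PrestoBlue"),
                    stringsAsFactors = FALSE)
measurements <- list(); layouts <- list(); truths <- list()
for (i in seq_len(nrow(runs))) {
  sp <- plate_sim_spec(seed = seed + i)
  sim <- simulate_assay_run(runs$cell_line[i], runs$assay[i], regime_ids = 1:3,
                            wavelengths_nm = wavelengths, spec = sp)
  measurements[[i]] <- sim$measurements
  layouts[[i]] <- sim$layout
  truths[[i]] <- sim$truth
}
measurements <- do.call(rbind, measurements)
layouts <- do.call(rbind, layouts)
truths <- do.call(rbind, truths)

write.csv(measurements, file.path(out_dir, "plate_measurements.csv"), row.names = FALSE)
write.csv(layouts, file.path(out_dir, "plate_layout.csv"), row.names = FALSE)
# ground truth as JSON-lines: key, true value, seed
con <- file(file.path(out_dir, "ground_truth.jsonl"), "w")
for (i in seq_len(nrow(truths)))
  writeLines(sprintf('{"plate_id":"%s","cell_line":"%s","assay":"%s","regime_id":%d,"wavelength_nm":%g,"true_viability_pct":%g,"base_seed":%d}',
                     truths$plate_id[i], truths$cell_line[i], truths$assay[i],
                     truths$regime_id[i], truths$wavelength_nm[i],
                     truths$true_viability_pct[i], seed), con)
close(con)
cat("simulated", nrow(measurements), "OD measurements over",
    length(unique(layouts$plate_id)), "plates x 3 repeats\n")
cat("wrote", file.path(out_dir, c("plate_measurements.csv", "plate_layout.csv",
                                  "ground_truth.jsonl")), sep = "\n  ")
cat("\n")
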