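tab <- eiip_table()

test_that("protein group generation is reproducible and validated", {
  spec <- protein_group_spec(seed = 17)
  g1 <- generate_protein_group(spec, tab)
  g2 <- generate_protein_group(spec, tab)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$phases, g2$phases)
  p1 <- tempfile(fileext = ".fasta"); p2 <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(p1, p2)))
  write_fasta_group(g1, p1); write_fasta_group(g2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # phases differ across members (no shared phase shortcut)
  expect_gt(stats::sd(g1$phases), 0)
  expect_error(protein_group_spec(n_seqs = 1), "n_seqs")
  expect_error(protein_group_spec(length_range = c(8, 20)), "length_range")
})

test_that("unrepresentable planted frequencies are rejected by name", {
  expect_error(generate_protein_group(protein_group_spec(f_target = 1e-4), tab),
               "nearest representable frequency is 0.00195")
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(555); before <- runif(3)
  set.seed(555); invisible(generate_protein_group(protein_group_spec(seed = 1), tab))
  expect_identical(runif(3), before)
})

test_that("noiseless planted groups peak exactly at the planted bin", {
  g <- generate_protein_group(protein_group_spec(noise_sd = 0, seed = 3), tab)
  pk <- group_characteristic_frequency(g$sequences, table = tab)$peak
  expect_equal(pk$frequency, g$f_planted)
  expect_true(pk$significant)
})

test_that("amplitude-zero groups rarely reach the significance threshold", {
  nonsig <- 0L
  for (s in 1:100) {
    g <- generate_protein_group(
      protein_group_spec(component_amplitude = 0, seed = 870000 + s), tab)
    pk <- group_characteristic_frequency(g$sequences, table = tab)$peak
    if (!pk$significant) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 90L)
})

test_that("shipped calibration encodes the study's effect structure", {
  cal <- default_calibration()
  expect_true(all(cal$true_viability_pct[cal$cell_line == "HEM"] == 100))
  far <- cal[cal$cell_line == "MCF7" & cal$wavelength_nm >= 3000, ]
  for (a in c("LDH", "PrestoBlue")) {
    by_reg <- vapply(1:3, function(r)
      mean(far$true_viability_pct[far$assay == a & far$regime_id == r]), 0)
    expect_true(all(diff(by_reg) <= 0))  # regime 1 >= 2 >= 3
  }
  # LDH regime means transcribed from the printed summaries
  ldh <- far[far$assay == "LDH", ]
  expect_equal(vapply(1:3, function(r)
    mean(ldh$true_viability_pct[ldh$regime_id == r]), 0), c(90, 80, 70))
  # 3600 nm carries the strongest PrestoBlue regime-1 effect
  pb1 <- far[far$assay == "PrestoBlue" & far$regime_id == 1, ]
  red <- 100 - pb1$true_viability_pct
  expect_gt(red[pb1$wavelength_nm == 3600], red[pb1$wavelength_nm == 3800])
  expect_true(all(red >= 10))
  expect_gt(red[pb1$wavelength_nm == 3600], 20)
})

test_that("plate generation is seed-reproducible and truth-annotated", {
  sp <- plate_sim_spec(seed = 21)
  lay <- default_plate_layout("MCF7", 2, "LDH")
  a <- generate_plate(sp, lay); b <- generate_plate(sp, lay)
  expect_identical(a$measurements, b$measurements)
  expect_equal(nrow(a$measurements), nrow(lay) * sp$n_repeats)
  expect_true(all(a$measurements$od >= 0))
  expect_equal(sort(unique(a$truth$wavelength_nm)),
               c(3400, 3600, 3800, 3900, 4100, 4300))
  # missing calibration row named in the rejection
  bad <- lay; bad$wavelength_nm[bad$role == "treated"][1] <- 1234
  expect_error(generate_plate(sp, bad), "1234")
})

test_that("zero-noise LDH plates invert the cytotoxicity formula exactly", {
  sp <- plate_sim_spec(background_sd = 0, well_noise_sd = 0, seed = 1)
  for (r in 1:3) {
    lay <- default_plate_layout("MCF7", r, "LDH")
    sim <- generate_plate(sp, lay)
    est <- run_assay(sim$measurements, sim$layout)$results
    m <- merge(est, sim$truth,
               by = c("cell_line", "assay", "regime_id", "wavelength_nm"))
    expect_equal(m$mean_viability_pct, m$true_viability_pct, tolerance = 1e-12)
    expect_equal(m$sd_viability_pct, rep(0, nrow(m)), tolerance = 1e-10)
  }
})

test_that("zero-noise PrestoBlue plates recover calibrated viability exactly", {
  sp <- plate_sim_spec(background_sd = 0, well_noise_sd = 0, seed = 1)
  lay <- default_plate_layout("MCF7", 1, "PrestoBlue")
  sim <- generate_plate(sp, lay)
  est <- run_assay(sim$measurements, sim$layout)$results
  m <- merge(est, sim$truth,
             by = c("cell_line", "assay", "regime_id", "wavelength_nm"))
  expect_equal(m$mean_viability_pct, m$true_viability_pct, tolerance = 1e-12)
})

test_that("compliant layouts keep buffer wells around every used well", {
  lay <- default_plate_layout("MCF7", 1, "LDH", compliant = TRUE)
  rows <- match(substr(lay$well, 1, 1), LETTERS)
  cols <- as.integer(substring(lay$well, 2))
  expect_equal(anyDuplicated(lay$well), 0L)
  for (i in seq_along(rows)) {
    adjacent <- abs(rows - rows[i]) + abs(cols - cols[i]) == 1
    expect_false(any(adjacent))  # no edge-adjacent occupied wells
  }
})

test_that("EIIP quantization moves the recovered peak by at most one bin", {
  # component-to-noise ratio 5 (default amplitude 0.05, noise 0.01)
  hits <- 0L
  for (s in 1:100) {
    g <- generate_protein_group(protein_group_spec(seed = 650000 + s), tab)
    pk <- group_characteristic_frequency(g$sequences, table = tab)$peak
    if (abs(pk$frequency - g$f_planted) <= 1 / g$n_points + 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
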