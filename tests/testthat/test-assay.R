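# minimal two-plate fixture built in code
tiny_layout <- function(assay = "LDH") {
  data.frame(plate_id = "p1",
             well = c("A1", "A3", "B2", "B4", "C1", "C3", "D2"),
             role = c("background", "background", "low_control", "low_control",
                      if (assay == "LDH") "high_control" else "low_control",
                      "treated", "treated"),
             cell_line = "MCF7",
             wavelength_nm = c(NA, NA, NA, NA, NA, 3600, 3600),
             regime_id = 1L, assay = assay, stringsAsFactors = FALSE)
}

tiny_measurements <- function(od, read_nm = 492) {
  data.frame(plate_id = "p1", well = c("A1", "A3", "B2", "B4", "C1", "C3", "D2"),
             od = od, read_nm = read_nm, repeat_id = 1L,
             stringsAsFactors = FALSE)
}

test_that("background mean is subtracted, clamped at zero, and required", {
  lay <- tiny_layout()
  m <- tiny_measurements(c(0.10, 0.10, 0.3, 0.3, 1.3, 0.50, 0.05))
  out <- suppressMessages(subtract_background(m, lay))
  expect_false(any(out$role == "background"))
  expect_equal(out$od_corrected[out$well == "C3"], 0.40)
  expect_equal(out$od_corrected[out$well == "D2"], 0)  # 0.05 - 0.10 clamped
  expect_equal(attr(out, "n_clamped"), 1L)
  no_bg <- lay; no_bg$role[no_bg$role == "background"] <- "low_control"
  expect_error(subtract_background(m, no_bg), "no background wells")
})

test_that("LDH cytotoxicity formula hits its endpoints and hand value", {
  expect_equal(ldh_cytotoxicity(0.2, 0.2, 1.2), 0)
  expect_equal(ldh_cytotoxicity(1.2, 0.2, 1.2), 100)
  expect_equal(ldh_cytotoxicity(0.5, 0.2, 1.2), 30)
  expect_error(ldh_cytotoxicity(0.5, 1.2, 1.2), "non-informative")
  expect_error(ldh_cytotoxicity(0.5, 1.3, 1.2), "non-informative")
})

test_that("cytotoxicity is affine increasing in OD and complements viability", {
  set.seed(12)
  x <- sort(runif(20, 0, 1.5))
  ctx <- ldh_cytotoxicity(x, 0.2, 1.2)
  expect_true(all(diff(ctx) > 0))
  # affine: constant slope between every pair of points
  slopes <- diff(ctx) / diff(x)
  expect_equal(slopes, rep(slopes[1], 19), tolerance = 1e-10)
  expect_equal(ctx + (100 - ctx), rep(100, 20))
})

test_that("PrestoBlue viability is the control ratio", {
  expect_equal(prestoblue_viability(0.9, 0.9), 100)
  expect_equal(prestoblue_viability(0, 0.9), 0)
  expect_equal(prestoblue_viability(0.45, 0.90), 50)
  expect_error(prestoblue_viability(0.4, 0), "positive")
})

test_that("per-well viability uses each plate's own controls", {
  lay <- tiny_layout()
  m <- tiny_measurements(c(0.10, 0.10, 0.3, 0.3, 1.3, 0.50, 0.62))
  wt <- plate_viability(m, lay)
  # low = 0.2, high = 1.2 after background; 0.40 -> 20%, 0.52 -> 32%
  expect_equal(wt$cytotoxicity_pct, c(20, 32))
  expect_equal(wt$viability_pct, c(80, 68))
  expect_false(any(wt$flagged))
  expect_error(plate_viability(tiny_measurements(rep(0.5, 7), read_nm = 595), lay),
               "alias set")
})

test_that("out-of-range percentages are flagged, never truncated", {
  lay <- tiny_layout()
  m <- tiny_measurements(c(0.10, 0.10, 0.3, 0.3, 1.3, 1.45, 0.50))
  wt <- plate_viability(m, lay)
  expect_equal(wt$cytotoxicity_pct[1], 115)   # beyond high control, retained
  expect_true(wt$flagged[1])
  expect_false(wt$flagged[2])
})

test_that("replicate aggregation pools triplicates and repeats", {
  base <- data.frame(cell_line = "MCF7", wavelength_nm = 3600, regime_id = 1L,
                     assay = "LDH", repeat_id = rep(1:3, each = 3),
                     viability_pct = c(10, 20, 30, 10, 20, 30, 10, 20, 30))
  agg <- aggregate_replicates(base)
  expect_equal(agg$mean_viability_pct, 20)
  expect_equal(agg$n, 9L)
  one <- aggregate_replicates(base[1:3, ])
  expect_equal(one$mean_viability_pct, 20)
  expect_equal(one$sd_viability_pct, 10)
  singleton <- aggregate_replicates(base[1, , drop = FALSE])
  expect_true(is.na(singleton$sd_viability_pct))
  expect_equal(singleton$n, 1L)
  const <- base; const$viability_pct <- 15
  expect_equal(aggregate_replicates(const)$sd_viability_pct, 0)
  # order invariance
  shuffled <- aggregate_replicates(base[sample(nrow(base)), ])
  expect_equal(shuffled$mean_viability_pct, agg$mean_viability_pct)
  expect_equal(shuffled$sd_viability_pct, agg$sd_viability_pct)
  # repeat-level means surfaced for inspection
  expect_equal(attr(agg, "repeat_means")$mean_viability_pct, rep(20, 3))
})

test_that("one-way ANOVA matches the brute-force sums of squares", {
  set.seed(2024)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:8, 1), sd = runif(1, .5, 2)))
    got <- one_way_anova(groups)
    want <- anova_bruteforce(groups)
    expect_equal(got$f_stat, want$f_stat, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(got$df_between, want$df_between)
    expect_equal(got$df_within, want$df_within)
  }
})

test_that("ANOVA degenerate and identity cases follow their conventions", {
  id <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(id$f_stat, 0)
  expect_equal(id$p_value, 1)
  sep <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_true(is.infinite(sep$f_stat))
  expect_equal(sep$p_value, 0)
  expect_equal(one_way_anova(list(c(2, 2), c(2, 2)))$p_value, 1)
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 values")
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(8)
  for (i in 1:50) {
    a <- rnorm(6); b <- rnorm(5, 0.5)
    f <- one_way_anova(list(a, b))$f_stat
    t2 <- unname(stats::t.test(a, b, var.equal = TRUE)$statistic)^2
    expect_equal(f, t2, tolerance = 1e-10)
  }
})

test_that("regime comparison ranks regimes and needs at least two", {
  sp <- plate_sim_spec(seed = 99)
  run <- simulate_assay_run("MCF7", "LDH", regime_ids = 1:3, spec = sp)
  wells <- plate_viability(run$measurements, run$layout)
  cmp <- regime_comparison(wells)
  far <- cmp[cmp$band == "far_ir", ]
  expect_equal(far$rank_most_cytotoxic[far$regime_id == 3], 1)
  expect_equal(far$rank_most_cytotoxic[far$regime_id == 1], 3)
  expect_false(any(far$ranking_tied))
  single <- wells[wells$regime_id == 1, ]
  expect_error(regime_comparison(single), ">= 2 regimes")
})
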