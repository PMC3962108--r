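#' Predict irradiation wavelengths for protein sequence groups
#'
#' Full prediction stage for one or more FASTA groups: EIIP encoding,
#' shared-grid amplitude spectra, consensus (cross-spectral) product,
#' characteristic-peak scoring, conversion to wavelength and LED selection.
#'
#' @param fasta_groups Character vector of FASTA paths (one file per group)
#'   or a named list of named character vectors of sequences.
#' @param out_dir Optional directory; when given, writes
#'   \code{predictions.tsv} and one \code{consensus_<group>.tsv} per group.
#' @param snr_threshold Peak significance threshold on S/N.
#' @param catalog LED catalog (see [led_catalog()]).
#' @param tolerance_nm LED mismatch tolerance (see [select_led()]).
#' @param table EIIP table.
#' @return List: \code{predictions} data.frame (group_id, f_rrm, snr,
#'   significant, lambda_nm, lambda_nm_rounded, freq_hz, in_window,
#'   chosen_led_nm, mismatch_nm, within_tolerance), \code{consensus} list of
#'   consensus spectra, \code{warnings} character vector.
#' @export
run_predict <- function(fasta_groups, out_dir = NULL, snr_threshold = 20,
                        catalog = led_catalog(), tolerance_nm = 200,
                        table = eiip_table()) {
  groups <- if (is.character(fasta_groups)) {
    g <- lapply(fasta_groups, read_fasta_group)
    names(g) <- sub("\\.[^.]*$", "", basename(fasta_groups))
    g
  } else fasta_groups
  if (length(groups) < 1L) stop("need at least one FASTA group")
  warnings <- character(0)
  rows <- list(); consensus <- list()
  for (gid in names(groups)) {
    res <- withCallingHandlers(
      group_characteristic_frequency(groups[[gid]], group_id = gid,
                                     table = table,
                                     snr_threshold = snr_threshold),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    pred <- frequency_to_wavelength(res$peak$frequency)
    panel <- withCallingHandlers(
      select_led(pred, catalog = catalog, tolerance_nm = tolerance_nm),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    consensus[[gid]] <- res$consensus
    rows[[gid]] <- data.frame(group_id = gid,
                              f_rrm = res$peak$frequency,
                              snr = res$peak$snr,
                              significant = res$peak$significant,
                              lambda_nm = pred$lambda_nm,
                              lambda_nm_rounded = pred$lambda_nm_rounded,
                              freq_hz = pred$freq_hz,
                              in_window = pred$in_window,
                              chosen_led_nm = panel$chosen$nominal_wavelength_nm,
                              mismatch_nm = panel$mismatch_nm,
                              within_tolerance = panel$within_tolerance)
  }
  predictions <- do.call(rbind, rows)
  rownames(predictions) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (gid in names(consensus)) {
      cs <- consensus[[gid]]
      utils::write.table(data.frame(frequency = cs$frequencies,
                                    amplitude = cs$amplitudes),
                         file.path(out_dir, paste0("consensus_", gid, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list(predictions = predictions, consensus = consensus, warnings = unique(warnings))
}

#' Analyse a plate-reader dataset end to end
#'
#' Background subtraction, per-assay viability formulas, replicate
#' aggregation, ANOVA tables, and (when the data span several regimes) the
#' regime comparison.
#'
#' @param plate Measurements data.frame or CSV path (plate_id, well, od,
#'   read_nm, repeat_id).
#' @param layout Layout data.frame or CSV path (plate_id, well, role,
#'   cell_line, wavelength_nm, regime_id, assay).
#' @param out_dir Optional directory; writes \code{results.tsv},
#'   \code{anova.tsv} and (when computed) \code{regime_comparison.tsv}.
#' @param alpha Significance level for ANOVA flags.
#' @param read_aliases Accepted reader wavelengths per assay.
#' @return List: \code{wells} per-well viability table, \code{results}
#'   aggregated table, \code{anova} (condition + across-wavelength tables),
#'   \code{regimes} comparison table or NULL.
#' @export
run_assay <- function(plate, layout, out_dir = NULL, alpha = 0.05,
                      read_aliases = default_read_aliases()) {
  if (is.character(plate)) plate <- utils::read.csv(plate, stringsAsFactors = FALSE)
  if (is.character(layout)) layout <- utils::read.csv(layout, stringsAsFactors = FALSE)
  wells <- plate_viability(plate, layout, read_aliases = read_aliases)
  results <- aggregate_replicates(wells)
  anova_tabs <- plate_anova(plate, layout, alpha = alpha,
                            read_aliases = read_aliases)
  regimes <- NULL
  if (length(unique(wells$regime_id)) >= 2L)
    regimes <- regime_comparison(wells, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(out_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    atab <- rbind(anova_tabs$condition, anova_tabs$across_wavelengths)
    utils::write.table(atab, file.path(out_dir, "anova.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(regimes))
      utils::write.table(regimes, file.path(out_dir, "regime_comparison.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(wells = wells, results = results, anova = anova_tabs, regimes = regimes)
}

#' Self-contained validation run
#'
#' Exercises the whole pipeline against its own synthetic fixtures and
#' reports pass/fail per check (failures are report content, not errors):
#' the two analytic wavelength conversions, planted-frequency recovery,
#' LDH formula endpoint identities, zero-noise generator invertibility,
#' resource checksums, and a seeded null false-positive-rate suite.
#'
#' @param seed Base RNG seed.
#' @param n_null_plates Plates in the null ANOVA false-positive suite.
#' @param out_dir Optional directory for \code{validation.tsv}.
#' @return List: \code{checks} data.frame (check, pass, detail),
#'   \code{provenance} (seed, resource checksums, timestamp), \code{pass}
#'   overall flag.
#' @export
run_validate <- function(seed = 1L, n_null_plates = 200L, out_dir = NULL) {
  checks <- list()
  add <- function(name, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 detail = detail)
  tab <- eiip_table()
  add("wavelength_oncogene_6656nm",
      frequency_to_wavelength(0.0302)$lambda_nm_rounded == 6656,
      "201/0.0302 rounds to 6656 nm")
  add("wavelength_protooncogene_3490nm",
      frequency_to_wavelength(0.0576)$lambda_nm_rounded == 3490,
      "201/0.0576 rounds to 3490 nm")
  grp <- generate_protein_group(protein_group_spec(seed = seed))
  peak <- group_characteristic_frequency(grp$sequences, table = tab)$peak
  add("planted_frequency_recovery",
      abs(peak$frequency - grp$f_planted) <= 1 / grp$n_points + 1e-12,
      sprintf("recovered %.4f vs planted %.4f", peak$frequency, grp$f_planted))
  add("ldh_endpoints",
      ldh_cytotoxicity(0.2, 0.2, 1.2) == 0 && ldh_cytotoxicity(1.2, 0.2, 1.2) == 100,
      "0% at low control, 100% at high control")
  noiseless <- plate_sim_spec(background_sd = 0, well_noise_sd = 0, seed = seed)
  run0 <- simulate_assay_run("MCF7", "LDH", regime_ids = 2, spec = noiseless)
  est0 <- run_assay(run0$measurements, run0$layout)$results
  m0 <- merge(est0, run0$truth,
              by = c("cell_line", "assay", "regime_id", "wavelength_nm"))
  add("zero_noise_invertibility",
      max(abs(m0$mean_viability_pct - m0$true_viability_pct)) < 1e-9,
      "exact viability recovery at zero noise")
  fpr <- null_false_positive_rate(n_plates = n_null_plates, seed = seed)
  add("null_false_positive_rate",
      fpr$rate >= fpr$lower && fpr$rate <= fpr$upper,
      sprintf("rate %.4f in binomial 95%% band [%.4f, %.4f] over %d tests",
              fpr$rate, fpr$lower, fpr$upper, fpr$n_tests))
  checks <- do.call(rbind, checks)
  prov <- list(seed = seed,
               eiip_version = tab$version_tag, eiip_md5 = tab$md5,
               calibration_md5 = unname(tools::md5sum(
                 system.file("extdata", "calibration_default.csv",
                             package = "rrmlilt"))),
               timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(checks, file.path(out_dir, "validation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(checks = checks, provenance = prov, pass = all(checks$pass))
}

#' Null false-positive rate of the per-condition ANOVA stage
#'
#' Simulates HEM (null-calibration) LDH plates and counts how often the
#' treated-vs-control ANOVA flags a wavelength x regime cell at level
#' \code{alpha}. Under the null every flag is a false positive, so the rate
#' should sit inside the binomial 95% band around \code{alpha}.
#'
#' @param n_plates Number of seeded plates (one regime each, cycling 1-3).
#' @param alpha Significance level.
#' @param seed Base seed; plate p uses seed + p.
#' @param spec_template Plate simulation spec providing the noise model.
#' @return List: \code{rate}, \code{n_tests}, \code{n_flagged},
#'   \code{lower}, \code{upper} (binomial 95% band around alpha).
#' @export
null_false_positive_rate <- function(n_plates = 200L, alpha = 0.05, seed = 1L,
                                     spec_template = plate_sim_spec()) {
  n_flagged <- 0L; n_tests <- 0L
  for (p in seq_len(n_plates)) {
    sp <- spec_template
    sp$seed <- (seed + p) %% .Machine$integer.max
    regime <- (p - 1L) %% 3L + 1L
    lay <- default_plate_layout("HEM", regime, "LDH",
                                n_triplicate = sp$n_triplicate,
                                plate_id = sprintf("null_%04d", p))
    sim <- generate_plate(sp, lay)
    tabs <- plate_anova(sim$measurements, sim$layout, alpha = alpha)
    n_flagged <- n_flagged + sum(tabs$condition$significant)
    n_tests <- n_tests + nrow(tabs$condition)
  }
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_tests)
  list(rate = n_flagged / n_tests, n_tests = n_tests, n_flagged = n_flagged,
       lower = alpha - half, upper = alpha + half)
}

#' Load a run configuration file
#'
#' Flat YAML key-value file carrying the tunable analysis parameters:
#' \code{snr_threshold}, \code{mismatch_tolerance_nm}, \code{alpha},
#' \code{seed}, \code{ldh_read_nm} / \code{prestoblue_read_nm} alias
#' vectors, and a free-text \code{metadata} block (e.g. LED driver settings
#' recorded as run notes). Missing keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration values with defaults filled in.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(snr_threshold = 20, mismatch_tolerance_nm = 200,
                   alpha = 0.05, seed = 1L,
                   ldh_read_nm = c(492, 495), prestoblue_read_nm = 595,
                   metadata = "")
  out <- utils::modifyList(defaults, cfg)
  out$read_aliases <- list(LDH = out$ldh_read_nm,
                           PrestoBlue = out$prestoblue_read_nm)
  out
}
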