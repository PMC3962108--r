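#' Default true-effect calibration table
#'
#' True viability (percent) per cell line x assay x regime x wavelength,
#' used by the plate simulator and recovered by the analysis pipeline. The
#' shipped table encodes the study's summary effect structure: MCF7 far-IR
#' LDH viability pooling to 90/80/70% across regimes 1-3 with 3600 nm the
#' most cytotoxic wavelength; MCF7 far-IR PrestoBlue regime 1 with at least
#' a 10 pp reduction at every wavelength and more than 20 pp at 3600 nm;
#' HEM (normal melanocytes) null at 100% throughout; near-IR intermediate
#' and visible small effects (illustrative only — see the \code{source}
#' column). Row-level provenance is documented in the methods vignette.
#'
#' @param path CSV with columns cell_line, assay, regime_id, wavelength_nm,
#'   true_viability_pct, source.
#' @return data.frame calibration table.
#' @export
default_calibration <- function(path = system.file("extdata",
                                                   "calibration_default.csv",
                                                   package = "rrmlilt")) {
  cal <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_line", "assay", "regime_id", "wavelength_nm",
                  "true_viability_pct") %in% names(cal)),
            all(cal$true_viability_pct >= 0 & cal$true_viability_pct <= 120))
  # structural guarantees the simulator and tests rely on
  hem <- cal$true_viability_pct[cal$cell_line == "HEM"]
  stopifnot(all(hem == hem[1]))
  far <- cal[cal$cell_line == "MCF7" & wavelength_band(cal$wavelength_nm) == "far_ir", ]
  for (a in unique(far$assay)) {
    by_reg <- vapply(1:3, function(r)
      mean(far$true_viability_pct[far$assay == a & far$regime_id == r]), 0)
    stopifnot(all(diff(by_reg) <= 0))  # regime severity: 1 >= 2 >= 3
  }
  cal
}

# run expr under a private, seeded RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification for a synthetic protein group with a planted frequency
#'
#' @param n_seqs Number of sequences (>= 2).
#' @param length_range Min/max residues per sequence (min >= 16).
#' @param f_target Planted normalized frequency in (0, 0.5).
#' @param component_amplitude Cosine amplitude, EIIP units (> 0; 0 simulates
#'   a null group with no shared component).
#' @param noise_sd Gaussian noise SD added to each signal point, EIIP units.
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return List of class \code{protein_group_spec}.
#' @export
protein_group_spec <- function(n_seqs = 5L, length_range = c(150L, 400L),
                               f_target = 0.0576, component_amplitude = 0.05,
                               noise_sd = 0.01, seed = 1L) {
  stopifnot(n_seqs >= 2, length(length_range) == 2L,
            length_range[1] >= 16, length_range[2] >= length_range[1],
            f_target > 0, f_target < 0.5,
            component_amplitude >= 0, noise_sd >= 0)
  structure(list(n_seqs = as.integer(n_seqs),
                 length_range = as.integer(length_range),
                 f_target = f_target,
                 component_amplitude = component_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "protein_group_spec")
}

# alphabetically-first residue for each distinct EIIP value
eiip_value_map <- function(table) {
  e <- table$entries[order(names(table$entries))]
  vals <- sort(unique(unname(e)))
  res <- vapply(vals, function(v) names(e)[which(e == v)[1]], "")
  list(values = vals, residues = res)
}

#' Generate a protein group carrying a planted spectral component
#'
#' Each member is built as a real-valued signal
#' \code{A cos(2 pi f_target i + phi_j) + noise}, centred in the EIIP range,
#' with an independent random phase per sequence (a shared phase would make
#' consensus detection unrealistically easy). Every signal point is then
#' quantized to the amino acid with the nearest EIIP value (ties toward the
#' alphabetically first residue), yielding FASTA-ready sequences whose
#' group consensus spectrum peaks near \code{f_target}.
#'
#' @param spec A [protein_group_spec()].
#' @param table An [eiip_table()].
#' @return List: \code{sequences} (named character vector), \code{f_target},
#'   \code{f_planted} (nearest grid frequency at the group transform
#'   length), \code{n_points}, \code{phases}, \code{spec}.
#' @export
generate_protein_group <- function(spec, table = eiip_table()) {
  stopifnot(inherits(spec, "protein_group_spec"))
  n_points <- rrm_transform_length(spec$length_range[2])
  k <- round(spec$f_target * n_points)
  if (k < 1 || k > n_points / 2) {
    nearest <- if (k < 1) 1 / n_points else 0.5
    stop(sprintf("f_target %.6g not representable on the padded grid; nearest representable frequency is %.6g",
                 spec$f_target, nearest))
  }
  vmap <- eiip_value_map(table)
  offset <- (max(vmap$values) + min(vmap$values)) / 2
  with_seed(spec$seed, {
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   spec$n_seqs, replace = TRUE)
    phases <- stats::runif(spec$n_seqs, 0, 2 * pi)
    seqs <- character(spec$n_seqs)
    for (j in seq_len(spec$n_seqs)) {
      i <- seq_len(lens[j]) - 1
      sig <- offset +
        spec$component_amplitude * cos(2 * pi * spec$f_target * i + phases[j]) +
        stats::rnorm(lens[j], 0, spec$noise_sd)
      idx <- vapply(sig, function(x) which.min(abs(vmap$values - x)), 0L)
      seqs[j] <- paste(vmap$residues[idx], collapse = "")
    }
    names(seqs) <- sprintf("synthetic_seq_%02d", seq_len(spec$n_seqs))
    list(sequences = seqs,
         f_target = spec$f_target,
         f_planted = k / n_points,
         n_points = n_points,
         phases = phases,
         spec = spec)
  })
}

#' Write a generated group to FASTA
#' @param group Result of [generate_protein_group()] or a named character
#'   vector of sequences.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_group <- function(group, path) {
  seqs <- if (is.list(group)) group$sequences else group
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Specification for simulated plate-reader datasets
#'
#' OD scale constants are instrument-side choices (the recovered
#' percentages are independent of them by construction): background around
#' 0.1 OD, LDH low/high controls at +0.2/+1.2 OD over background,
#' PrestoBlue untreated control at +0.9 OD, per-well noise SD 0.03 OD.
#'
#' @param calibration Calibration table (see [default_calibration()]).
#' @param background_mean,background_sd Background (medium-only) OD.
#' @param low_control_od,high_control_od LDH control ODs above background;
#'   high must exceed low.
#' @param control_od_prestoblue Untreated-control OD above background.
#' @param well_noise_sd Per-well Gaussian OD noise.
#' @param n_triplicate Treated wells per condition per plate.
#' @param n_repeats Independent experiment repetitions.
#' @param seed RNG seed.
#' @return List of class \code{plate_sim_spec}.
#' @export
plate_sim_spec <- function(calibration = default_calibration(),
                           background_mean = 0.1, background_sd = 0.005,
                           low_control_od = 0.2, high_control_od = 1.2,
                           control_od_prestoblue = 0.9,
                           well_noise_sd = 0.03,
                           n_triplicate = 3L, n_repeats = 3L, seed = 1L) {
  stopifnot(high_control_od > low_control_od, low_control_od > 0,
            background_sd >= 0, well_noise_sd >= 0,
            n_triplicate >= 1, n_repeats >= 1)
  structure(list(calibration = calibration,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 low_control_od = low_control_od,
                 high_control_od = high_control_od,
                 control_od_prestoblue = control_od_prestoblue,
                 well_noise_sd = well_noise_sd,
                 n_triplicate = as.integer(n_triplicate),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "plate_sim_spec")
}

# checkerboard well coordinates on a 96-well plate (rows A-H, columns 1-12),
# so no two used wells are edge-adjacent (buffer wells around every well)
checkerboard_wells <- function(n) {
  rows <- LETTERS[1:8]
  coords <- character(0)
  for (r in seq_along(rows)) {
    cols <- seq(if (r %% 2 == 1) 1 else 2, 12, by = 2)
    coords <- c(coords, paste0(rows[r], cols))
  }
  if (n > length(coords)) stop("layout does not fit on a 96-well checkerboard")
  coords[seq_len(n)]
}

#' Build a study plate layout for one cell line x regime x assay
#'
#' Triplicate treated wells per wavelength plus background, low-control and
#' (for LDH) high-control wells. With \code{compliant = TRUE} wells are
#' placed on a checkerboard so every used well is surrounded by empty
#' buffer wells, mirroring the study's anti-crosstalk layout.
#'
#' @param cell_line,regime_id,assay Condition identifiers.
#' @param wavelengths_nm Exposure wavelengths on this plate.
#' @param n_triplicate Treated wells per wavelength.
#' @param n_background,n_control Control well counts.
#' @param compliant Use buffered checkerboard placement.
#' @param plate_id Plate identifier (default derived from the condition).
#' @return Layout data.frame (plate_id, well, role, cell_line,
#'   wavelength_nm, regime_id, assay).
#' @export
default_plate_layout <- function(cell_line, regime_id, assay,
                                 wavelengths_nm = c(3400, 3600, 3800, 3900, 4100, 4300),
                                 n_triplicate = 3L, n_background = 3L,
                                 n_control = 3L, compliant = TRUE,
                                 plate_id = sprintf("%s_%s_regime%d", cell_line,
                                                    assay, regime_id)) {
  stopifnot(assay %in% c("LDH", "PrestoBlue"), regime_id %in% 1:3 ||
              is.numeric(regime_id))
  roles <- c(rep("background", n_background),
             rep("low_control", n_control),
             if (assay == "LDH") rep("high_control", n_control),
             rep("treated", n_triplicate * length(wavelengths_nm)))
  wl <- c(rep(NA_real_, length(roles) - n_triplicate * length(wavelengths_nm)),
          rep(wavelengths_nm, each = n_triplicate))
  wells <- if (compliant) checkerboard_wells(length(roles)) else
    paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_along(roles)]
  data.frame(plate_id = plate_id, well = wells, role = roles,
             cell_line = cell_line, wavelength_nm = wl,
             regime_id = regime_id, assay = assay,
             stringsAsFactors = FALSE)
}

#' Simulate plate-reader measurements for a layout
#'
#' Draws one OD per well per repeat under the study's generative model:
#' background wells around \code{background_mean}; LDH low/high controls at
#' their control ODs over background; LDH treated wells interpolate between
#' the controls according to the calibrated true viability v (so the LDH
#' cytotoxicity formula recovers 100 - v exactly at zero noise); PrestoBlue
#' treated wells scale the untreated-control OD by v/100. Simulated ODs are
#' truncated at zero before analysis (an instrument cannot report negative
#' absorbance); that truncation is distinct from the analysis-side clamp.
#'
#' @param spec A [plate_sim_spec()].
#' @param layout Layout data.frame (see [default_plate_layout()]).
#' @return List: \code{measurements} (plate_id, well, od, read_nm,
#'   repeat_id), \code{layout}, \code{truth} (calibration rows used, keyed
#'   per condition), \code{spec}.
#' @export
generate_plate <- function(spec, layout) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  cal <- spec$calibration
  treated <- layout[layout$role == "treated", ]
  true_v <- function(row) {
    hit <- cal$cell_line == row$cell_line & cal$assay == row$assay &
      cal$regime_id == row$regime_id & cal$wavelength_nm == row$wavelength_nm
    if (sum(hit) != 1L)
      stop(sprintf("no calibration row for (%s, %s, regime %s, %g nm)",
                   row$cell_line, row$assay, row$regime_id, row$wavelength_nm))
    cal$true_viability_pct[hit]
  }
  v_by_well <- if (nrow(treated) > 0)
    vapply(seq_len(nrow(treated)), function(i) true_v(treated[i, ]), 0)
  else numeric(0)
  read_nm_for <- function(assay) if (assay == "LDH") 492 else 595
  with_seed(spec$seed, {
    out <- vector("list", spec$n_repeats)
    for (r in seq_len(spec$n_repeats)) {
      od <- numeric(nrow(layout))
      eps <- function(n) stats::rnorm(n, 0, spec$well_noise_sd)
      for (i in seq_len(nrow(layout))) {
        role <- layout$role[i]; assay <- layout$assay[i]
        od[i] <- if (role == "background")
          stats::rnorm(1, spec$background_mean, spec$background_sd)
        else if (role == "low_control" && assay == "LDH")
          spec$background_mean + spec$low_control_od + eps(1)
        else if (role == "high_control")
          spec$background_mean + spec$high_control_od + eps(1)
        else if (role == "low_control")  # PrestoBlue untreated control
          spec$background_mean + spec$control_od_prestoblue + eps(1)
        else {
          v <- v_by_well[match(i, which(layout$role == "treated"))]
          if (assay == "LDH")
            spec$background_mean + spec$low_control_od +
              (1 - v / 100) * (spec$high_control_od - spec$low_control_od) + eps(1)
          else
            spec$background_mean + (v / 100) * spec$control_od_prestoblue + eps(1)
        }
      }
      out[[r]] <- data.frame(plate_id = layout$plate_id, well = layout$well,
                             od = pmax(od, 0),
                             read_nm = vapply(layout$assay, read_nm_for, 0),
                             repeat_id = r, stringsAsFactors = FALSE)
    }
    truth <- cbind(treated[c("plate_id", "cell_line", "assay", "regime_id",
                             "wavelength_nm")],
                   true_viability_pct = v_by_well)
    truth <- unique(truth)
    list(measurements = do.call(rbind, out), layout = layout,
         truth = truth, spec = spec)
  })
}

#' Simulate a multi-plate assay run
#'
#' One plate (with repeats) per regime for a cell line and assay, stacked
#' into a single measurements/layout pair ready for [plate_viability()].
#' Per-plate seeds are derived deterministically from the spec seed.
#'
#' @param cell_line,assay Condition identifiers.
#' @param regime_ids Regimes to include.
#' @param wavelengths_nm Wavelengths per plate.
#' @param spec A [plate_sim_spec()]; its seed anchors all plates.
#' @return List with stacked \code{measurements}, \code{layout},
#'   \code{truth}.
#' @export
simulate_assay_run <- function(cell_line, assay, regime_ids = 1:3,
                               wavelengths_nm = c(3400, 3600, 3800, 3900, 4100, 4300),
                               spec = plate_sim_spec()) {
  plates <- lapply(seq_along(regime_ids), function(i) {
    lay <- default_plate_layout(cell_line, regime_ids[i], assay,
                                wavelengths_nm = wavelengths_nm,
                                n_triplicate = spec$n_triplicate)
    sub <- spec
    sub$seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    generate_plate(sub, lay)
  })
  list(measurements = do.call(rbind, lapply(plates, `[[`, "measurements")),
       layout = do.call(rbind, lapply(plates, `[[`, "layout")),
       truth = do.call(rbind, lapply(plates, `[[`, "truth")))
}
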