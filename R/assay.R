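#' Exposure regimes of the study design
#'
#' Three combinations of irradiation duration and post-exposure incubation:
#' regime 1 = 1.5 h exposure, assay immediately; regime 2 = 1.5 h exposure,
#' 24 h incubation; regime 3 = 3 h exposure, 24 h incubation. Other
#' combinations may be supplied explicitly by the user downstream.
#'
#' @return data.frame with \code{regime_id}, \code{exposure_h},
#'   \code{incubation_h}.
#' @export
exposure_regimes <- function() {
  data.frame(regime_id = 1:3,
             exposure_h = c(1.5, 1.5, 3),
             incubation_h = c(0, 24, 24))
}

# plate-reader wavelengths accepted per assay; both 492 and 495 nm LDH
# filters are in circulation, so both are accepted and recorded
default_read_aliases <- function() list(LDH = c(492, 495), PrestoBlue = 595)

#' Classify an exposure wavelength into the study's bands
#' @param wavelength_nm Numeric vector of wavelengths (nm).
#' @return Character vector: "visible" (< 700 nm), "near_ir" (< 3000 nm),
#'   "far_ir" otherwise.
#' @export
wavelength_band <- function(wavelength_nm) {
  ifelse(wavelength_nm < 700, "visible",
         ifelse(wavelength_nm < 3000, "near_ir", "far_ir"))
}

check_plate_schema <- function(measurements, layout) {
  m_cols <- c("plate_id", "well", "od", "read_nm", "repeat_id")
  l_cols <- c("plate_id", "well", "role", "cell_line", "wavelength_nm",
              "regime_id", "assay")
  if (!all(m_cols %in% names(measurements)))
    stop("measurements must have columns: ", paste(m_cols, collapse = ", "))
  if (!all(l_cols %in% names(layout)))
    stop("layout must have columns: ", paste(l_cols, collapse = ", "))
  if (any(!is.finite(measurements$od)) || any(measurements$od < 0))
    stop("optical densities must be finite and non-negative")
  invisible(TRUE)
}

#' Subtract the plate background from every studied well
#'
#' The background control (medium only) mean of each plate/repeat is
#' subtracted from every other well of that plate/repeat. Corrected values
#' that fall below zero are clamped to zero and the clamp count is recorded
#' in the \code{n_clamped} attribute (clamping here is an analysis policy,
#' logged separately from any truncation a simulator applies).
#'
#' @param measurements data.frame with \code{plate_id}, \code{well},
#'   \code{od}, \code{read_nm}, \code{repeat_id}.
#' @param layout data.frame with \code{plate_id}, \code{well}, \code{role},
#'   \code{cell_line}, \code{wavelength_nm}, \code{regime_id}, \code{assay}.
#' @return data.frame of non-background wells with an \code{od_corrected}
#'   column and the layout annotation merged in; attribute \code{n_clamped}.
#' @export
subtract_background <- function(measurements, layout) {
  check_plate_schema(measurements, layout)
  df <- merge(measurements, layout, by = c("plate_id", "well"))
  if (nrow(df) < nrow(measurements))
    stop("measurements contain wells absent from the layout")
  key <- interaction(df$plate_id, df$repeat_id, drop = TRUE)
  out <- vector("list", nlevels(key))
  n_clamped <- 0L
  for (i in seq_len(nlevels(key))) {
    sub <- df[key == levels(key)[i], , drop = FALSE]
    bg <- sub$od[sub$role == "background"]
    if (length(bg) == 0L)
      stop(sprintf("no background wells on plate '%s' repeat %s",
                   sub$plate_id[1], sub$repeat_id[1]))
    sub <- sub[sub$role != "background", , drop = FALSE]
    sub$od_corrected <- sub$od - mean(bg)
    neg <- sub$od_corrected < 0
    n_clamped <- n_clamped + sum(neg)
    sub$od_corrected[neg] <- 0
    out[[i]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (n_clamped > 0L)
    message(n_clamped, " corrected OD value(s) below zero clamped to 0")
  attr(res, "n_clamped") <- n_clamped
  res
}

#' LDH cytotoxicity percentage
#'
#' Scales a background-corrected experimental absorbance between the low
#' control (untreated cells, basal LDH release) and the high control (lysed
#' cells, maximal release):
#' cytotoxicity = 100 x (experimental - low) / (high - low).
#' Values outside [0, 100] are retained, not truncated — truncation would
#' bias null recoveries — and should be flagged by the caller.
#'
#' @param experimental Corrected OD value(s) for treated wells.
#' @param low Mean corrected low-control OD.
#' @param high Mean corrected high-control OD; must exceed \code{low}.
#' @return Cytotoxicity percentage(s).
#' @export
ldh_cytotoxicity <- function(experimental, low, high) {
  if (!(high > low)) stop("non-informative controls: high control must exceed low control")
  100 * (experimental - low) / (high - low)
}

#' PrestoBlue viability percentage
#'
#' Ratio of a treated well's background-corrected absorbance to the mean
#' corrected absorbance of untreated control cells, per the reagent
#' protocol: viability = 100 x treated / control. Values above 100
#' (over-control) are retained and flagged by the caller.
#'
#' @param treated Corrected OD value(s) for treated wells.
#' @param untreated_control Mean corrected untreated-control OD, > 0.
#' @return Viability percentage(s).
#' @export
prestoblue_viability <- function(treated, untreated_control) {
  if (!(untreated_control > 0))
    stop("untreated control must be positive after background subtraction")
  100 * treated / untreated_control
}

#' Per-well viability table from raw plate measurements
#'
#' Full per-well chain: schema checks, reader-wavelength validation against
#' the assay alias set, background subtraction, then the assay formula
#' against that plate/repeat's own controls (LDH: low/high controls and
#' viability = 100 - cytotoxicity; PrestoBlue: untreated control ratio).
#'
#' @param measurements,layout See [subtract_background()].
#' @param read_aliases Accepted reader wavelengths per assay.
#' @return data.frame, one row per treated well: annotation columns,
#'   \code{od_corrected}, \code{cytotoxicity_pct}, \code{viability_pct},
#'   \code{flagged} (TRUE when viability falls outside [0, 100]).
#' @export
plate_viability <- function(measurements, layout,
                            read_aliases = default_read_aliases()) {
  corrected <- subtract_background(measurements, layout)
  for (a in unique(corrected$assay)) {
    if (!a %in% names(read_aliases))
      stop("unknown assay type: ", a)
    bad_nm <- setdiff(unique(corrected$read_nm[corrected$assay == a]),
                      read_aliases[[a]])
    if (length(bad_nm) > 0L)
      stop(sprintf("reader wavelength %s nm not in the %s alias set (%s)",
                   paste(bad_nm, collapse = ","), a,
                   paste(read_aliases[[a]], collapse = "/")))
  }
  key <- interaction(corrected$plate_id, corrected$repeat_id, corrected$assay,
                     drop = TRUE)
  out <- vector("list", nlevels(key))
  for (i in seq_len(nlevels(key))) {
    sub <- corrected[key == levels(key)[i], , drop = FALSE]
    assay <- sub$assay[1]
    low_od <- sub$od_corrected[sub$role == "low_control"]
    if (length(low_od) == 0L)
      stop(sprintf("no low_control wells on plate '%s' repeat %s",
                   sub$plate_id[1], sub$repeat_id[1]))
    treated <- sub[sub$role == "treated", , drop = FALSE]
    if (assay == "LDH") {
      high_od <- sub$od_corrected[sub$role == "high_control"]
      if (length(high_od) == 0L)
        stop(sprintf("LDH layout requires high_control wells (plate '%s' repeat %s)",
                     sub$plate_id[1], sub$repeat_id[1]))
      ctx <- ldh_cytotoxicity(treated$od_corrected, mean(low_od), mean(high_od))
      treated$cytotoxicity_pct <- ctx
      treated$viability_pct <- 100 - ctx
    } else {
      v <- prestoblue_viability(treated$od_corrected, mean(low_od))
      treated$viability_pct <- v
      treated$cytotoxicity_pct <- 100 - v
    }
    out[[i]] <- treated
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$flagged <- res$viability_pct < 0 | res$viability_pct > 100
  res$read_nm_used <- res$read_nm
  res
}

#' Aggregate per-well viabilities over triplicates and repeats
#'
#' Triplicate wells and experiment repeats are pooled into one point
#' estimate per cell line x wavelength x regime x assay (mean, sample SD
#' with n-1 denominator, n). Repeat-level means are also attached (attribute
#' \code{repeat_means}) for inspection; singletons report \code{NA} SD.
#'
#' @param welltab Per-well table from [plate_viability()], or any data.frame
#'   with the key columns plus \code{viability_pct}.
#' @return data.frame keyed by cell_line, wavelength_nm, regime_id, assay
#'   with \code{mean_viability_pct}, \code{sd_viability_pct}, \code{n},
#'   \code{n_flagged}.
#' @export
aggregate_replicates <- function(welltab) {
  stopifnot(nrow(welltab) >= 1L, "viability_pct" %in% names(welltab))
  if (!"flagged" %in% names(welltab)) welltab$flagged <- FALSE
  keys <- list(cell_line = welltab$cell_line,
               wavelength_nm = welltab$wavelength_nm,
               regime_id = welltab$regime_id,
               assay = welltab$assay)
  agg <- function(f) stats::aggregate(welltab$viability_pct, keys, f)$x
  res <- stats::aggregate(welltab$viability_pct, keys, mean)
  names(res)[names(res) == "x"] <- "mean_viability_pct"
  res$sd_viability_pct <- agg(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  res$n <- agg(length)
  res$n_flagged <- stats::aggregate(as.integer(welltab$flagged), keys, sum)$x
  if ("repeat_id" %in% names(welltab)) {
    rkeys <- c(keys, list(repeat_id = welltab$repeat_id))
    rep_means <- stats::aggregate(welltab$viability_pct, rkeys, mean)
    names(rep_means)[names(rep_means) == "x"] <- "mean_viability_pct"
    attr(res, "repeat_means") <- rep_means
  }
  res[order(res$assay, res$cell_line, res$regime_id, res$wavelength_nm), ,
      drop = FALSE]
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test) across k >= 2
#' groups, each with n >= 2 observations. Degenerate separation (zero
#' within-group variance with unequal means) reports an infinite F with
#' p = 0; fully constant data report F = 0, p = 1.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return List: \code{f_stat}, \code{df_between} (k-1), \code{df_within}
#'   (N-k), \code{p_value}.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("every group needs at least 2 values")
  k <- length(groups); N <- sum(n_i)
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  means <- vapply(groups, mean, 0)
  if (within_ss <= .Machine$double.eps * N) {
    degenerate_f <- if (max(means) - min(means) > 0) Inf else 0
    return(list(f_stat = degenerate_f, df_between = k - 1L,
                df_within = N - k,
                p_value = if (is.infinite(degenerate_f)) 0 else 1))
  }
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_len(k), n_i))
  ht <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  list(f_stat = unname(ht$statistic),
       df_between = as.integer(unname(ht$parameter[1])),
       df_within = as.integer(unname(ht$parameter[2])),
       p_value = unname(ht$p.value))
}

#' Per-condition and across-wavelength ANOVA tables
#'
#' Two complementary views, both with raw (uncorrected) p-values:
#' \itemize{
#' \item \code{condition}: for every cell line x assay x regime x
#'   wavelength, treated corrected ODs vs untreated-control corrected ODs
#'   (pooled over repeats) — "did this exposure do anything at all?";
#' \item \code{across_wavelengths}: for every cell line x assay x regime,
#'   per-well viabilities grouped by wavelength — "do wavelengths differ?".
#' }
#'
#' @param measurements,layout Raw plate inputs (see [subtract_background()]).
#' @param alpha Significance level for the \code{significant} flag.
#' @param read_aliases Passed to [plate_viability()].
#' @return List of two data.frames (\code{condition},
#'   \code{across_wavelengths}) with columns comparison, f, df1, df2,
#'   \code{p_uncorrected}, significant.
#' @export
plate_anova <- function(measurements, layout, alpha = 0.05,
                        read_aliases = default_read_aliases()) {
  corrected <- subtract_background(measurements, layout)
  welltab <- plate_viability(measurements, layout, read_aliases = read_aliases)
  cond_rows <- list()
  combos <- unique(welltab[c("cell_line", "assay", "regime_id", "wavelength_nm")])
  for (i in seq_len(nrow(combos))) {
    cc <- combos[i, ]
    tr <- welltab$od_corrected[welltab$cell_line == cc$cell_line &
                               welltab$assay == cc$assay &
                               welltab$regime_id == cc$regime_id &
                               welltab$wavelength_nm == cc$wavelength_nm]
    ctl <- corrected$od_corrected[corrected$role == "low_control" &
                                  corrected$assay == cc$assay &
                                  corrected$cell_line == cc$cell_line &
                                  corrected$regime_id == cc$regime_id]
    if (length(tr) < 2L || length(ctl) < 2L) next
    a <- one_way_anova(list(treated = tr, control = ctl))
    cond_rows[[length(cond_rows) + 1L]] <-
      data.frame(cell_line = cc$cell_line, assay = cc$assay,
                 regime_id = cc$regime_id, wavelength_nm = cc$wavelength_nm,
                 comparison = "treated_vs_control",
                 f = a$f_stat, df1 = a$df_between, df2 = a$df_within,
                 p_uncorrected = a$p_value,
                 significant = a$p_value < alpha)
  }
  wl_rows <- list()
  combos2 <- unique(welltab[c("cell_line", "assay", "regime_id")])
  for (i in seq_len(nrow(combos2))) {
    cc <- combos2[i, ]
    sub <- welltab[welltab$cell_line == cc$cell_line &
                   welltab$assay == cc$assay &
                   welltab$regime_id == cc$regime_id, ]
    groups <- split(sub$viability_pct, sub$wavelength_nm)
    if (length(groups) < 2L || any(lengths(groups) < 2L)) next
    a <- one_way_anova(groups)
    wl_rows[[length(wl_rows) + 1L]] <-
      data.frame(cell_line = cc$cell_line, assay = cc$assay,
                 regime_id = cc$regime_id, wavelength_nm = NA_real_,
                 comparison = "across_wavelengths",
                 f = a$f_stat, df1 = a$df_between, df2 = a$df_within,
                 p_uncorrected = a$p_value,
                 significant = a$p_value < alpha)
  }
  list(condition = do.call(rbind, cond_rows),
       across_wavelengths = do.call(rbind, wl_rows))
}

#' Compare exposure regimes within wavelength bands
#'
#' Per cell line and wavelength band (far-IR / near-IR / visible): mean
#' viability per regime, a ranking from most to least cytotoxic (ties
#' flagged), a one-way ANOVA across regimes on repeat-level mean viabilities
#' (the repeat, not the well, is the independent unit across plates), and a
#' cancer-vs-normal viability delta when two cell lines are present.
#'
#' @param welltab Per-well table from [plate_viability()].
#' @param alpha Significance level.
#' @param tie_tol Viability difference (pp) below which two regimes are
#'   considered tied in the ranking.
#' @return data.frame, one row per cell line x band x regime, with
#'   \code{mean_viability_pct}, \code{rank_most_cytotoxic},
#'   \code{ranking_tied}, ANOVA columns and \code{delta_vs_other_line}.
#' @export
regime_comparison <- function(welltab, alpha = 0.05, tie_tol = 0.5) {
  stopifnot(all(c("cell_line", "wavelength_nm", "regime_id", "viability_pct")
                %in% names(welltab)))
  welltab$band <- wavelength_band(welltab$wavelength_nm)
  lines <- unique(welltab$cell_line)
  out <- list()
  for (cl in lines) {
    for (b in unique(welltab$band[welltab$cell_line == cl])) {
      sub <- welltab[welltab$cell_line == cl & welltab$band == b, ]
      regs <- sort(unique(sub$regime_id))
      if (length(regs) < 2L)
        stop("regime comparison requires results spanning >= 2 regimes per cell line")
      means <- vapply(regs, function(r)
        mean(sub$viability_pct[sub$regime_id == r]), 0)
      rk <- rank(means, ties.method = "min")  # lowest viability = rank 1 = most cytotoxic
      tied <- any(abs(diff(sort(means))) < tie_tol)
      # regimes live on different plates, so wells within a regime share that
      # plate's control noise; the experiment repeat is the independent unit,
      # hence the ANOVA runs on repeat-level means
      if ("repeat_id" %in% names(sub)) {
        rmeans <- stats::aggregate(sub$viability_pct,
                                   list(regime_id = sub$regime_id,
                                        repeat_id = sub$repeat_id), mean)
        groups <- split(rmeans$x, rmeans$regime_id)
      } else {
        groups <- split(sub$viability_pct, sub$regime_id)
      }
      a <- if (all(lengths(groups) >= 2L)) one_way_anova(groups) else
        list(f_stat = NA_real_, df_between = NA_integer_,
             df_within = NA_integer_, p_value = NA_real_)
      other <- setdiff(lines, cl)
      delta <- rep(NA_real_, length(regs))
      if (length(other) == 1L) {
        osub <- welltab[welltab$cell_line == other & welltab$band == b, ]
        delta <- vapply(regs, function(r) {
          ov <- osub$viability_pct[osub$regime_id == r]
          if (length(ov) == 0L) NA_real_
          else mean(ov) - mean(sub$viability_pct[sub$regime_id == r])
        }, 0)
      }
      out[[length(out) + 1L]] <-
        data.frame(cell_line = cl, band = b, regime_id = regs,
                   mean_viability_pct = means,
                   rank_most_cytotoxic = rk,
                   ranking_tied = tied,
                   f = a$f_stat, df1 = a$df_between, df2 = a$df_within,
                   p_uncorrected = a$p_value,
                   significant = !is.na(a$p_value) && a$p_value < alpha,
                   delta_vs_other_line = delta)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
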