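#' Shared transform length for a sequence group
#'
#' All members of a group must share one frequency grid so their amplitude
#' spectra can be multiplied bin by bin. The grid is fixed by zero-padding
#' every member to the smallest power of two at least as long as the longest
#' member, with a floor of 512 points (the RRM literature's convention for
#' unequal lengths).
#'
#' @param lengths Integer vector of member sequence lengths.
#' @param minimum Minimum transform length (default 512).
#' @return Transform length (power of two).
#' @export
rrm_transform_length <- function(lengths, minimum = 512L) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1))
  n <- max(max(lengths), minimum)
  as.integer(2^ceiling(log2(n)))
}

#' Amplitude spectrum of an EIIP-encoded sequence
#'
#' The signal mean is removed (EIIP values are all positive, so the DC term
#' would otherwise dominate every consensus product), the signal is
#' zero-padded to \code{n_points}, and the discrete Fourier transform
#' magnitudes are taken at bins 1..n_points/2. Bin k corresponds to
#' normalized frequency k/n_points (cycles per residue); the DC bin is
#' excluded and the grid tops out at the Nyquist limit 0.5.
#'
#' @param ns A \code{numerical_sequence} from [encode_sequence()].
#' @param n_points Transform length, at least \code{ns$length}; identical for
#'   all members of one group (see [rrm_transform_length()]).
#' @return Object of class \code{rrm_spectrum}: list with \code{seq_id},
#'   \code{frequencies}, \code{amplitudes}, \code{n_points},
#'   \code{degenerate} (TRUE for an all-constant signal, whose spectrum is
#'   identically zero after mean removal).
#' @export
amplitude_spectrum <- function(ns, n_points = rrm_transform_length(ns$length)) {
  stopifnot(inherits(ns, "numerical_sequence"))
  n_points <- as.integer(n_points)
  if (n_points < ns$length)
    stop(sprintf("n_points (%d) smaller than sequence length (%d)",
                 n_points, ns$length))
  x <- ns$values - mean(ns$values)
  padded <- c(x, rep(0, n_points - ns$length))
  amps <- Mod(stats::fft(padded))[2:(n_points / 2 + 1)]
  degenerate <- all(amps < .Machine$double.eps * n_points)
  if (degenerate) amps[] <- 0
  structure(list(seq_id = ns$seq_id,
                 frequencies = seq_len(n_points / 2) / n_points,
                 amplitudes = amps,
                 n_points = n_points,
                 degenerate = degenerate),
            class = "rrm_spectrum")
}

#' Multiple cross-spectral (consensus) function of a protein group
#'
#' The consensus amplitude at each frequency bin is the product over group
#' members of the member amplitude at that bin. Frequency components shared
#' by every member survive the product; components particular to one
#' sequence are suppressed. The surviving peak defines the group's RRM
#' characteristic frequency.
#'
#' @param spectra List of \code{rrm_spectrum} objects on an identical grid.
#' @param group_id Label carried into the result.
#' @return Object of class \code{consensus_spectrum}: \code{group_id},
#'   \code{frequencies}, \code{amplitudes}, \code{n_members},
#'   \code{n_points}.
#' @export
cross_spectrum <- function(spectra, group_id = "group") {
  if (length(spectra) < 2L) stop("fewer than 2 members in group")
  stopifnot(all(vapply(spectra, inherits, TRUE, "rrm_spectrum")))
  n_points <- unique(vapply(spectra, function(s) s$n_points, integer(1)))
  if (length(n_points) != 1L)
    stop("mismatched frequency grids: members transformed at different lengths")
  mat <- vapply(spectra, function(s) s$amplitudes,
                numeric(length(spectra[[1]]$amplitudes)))
  # multiply each bin's factors in sorted order: the consensus is then
  # bitwise identical under any permutation of the members
  amps <- apply(mat, 1L, function(a) prod(sort(a)))
  structure(list(group_id = group_id,
                 frequencies = spectra[[1]]$frequencies,
                 amplitudes = amps,
                 n_members = length(spectra),
                 n_points = n_points),
            class = "consensus_spectrum")
}

#' Locate the characteristic frequency of a consensus spectrum
#'
#' The characteristic frequency is the grid value at the global maximum of
#' the consensus amplitudes. The signal-to-noise ratio is the peak magnitude
#' divided by the mean consensus magnitude; the customary RRM criterion calls
#' a peak significant when S/N is at least 20. Ties at the maximum are broken
#' toward the lowest frequency so results are deterministic.
#'
#' @param cs A \code{consensus_spectrum}.
#' @param snr_threshold Significance threshold on S/N (default 20).
#' @return Object of class \code{characteristic_peak}: \code{frequency},
#'   \code{amplitude}, \code{snr}, \code{significant}, \code{group_id}.
#' @export
find_characteristic_frequency <- function(cs, snr_threshold = 20) {
  stopifnot(inherits(cs, "consensus_spectrum"), snr_threshold > 0)
  if (all(cs$amplitudes <= 0)) stop("degenerate consensus: all amplitudes zero")
  k <- which.max(cs$amplitudes)  # which.max returns the first (lowest-f) tie
  snr <- cs$amplitudes[k] / mean(cs$amplitudes)
  structure(list(group_id = cs$group_id,
                 frequency = cs$frequencies[k],
                 amplitude = cs$amplitudes[k],
                 snr = snr,
                 significant = snr >= snr_threshold),
            class = "characteristic_peak")
}

#' Consensus spectrum and characteristic peak for a set of raw sequences
#'
#' Convenience wrapper: encodes every sequence, fixes the shared transform
#' length, computes member amplitude spectra and their consensus, and scores
#' the characteristic peak.
#'
#' @param seqs Named character vector of amino-acid strings (names = seq ids).
#' @param group_id Group label.
#' @param table An [eiip_table()].
#' @param snr_threshold Passed to [find_characteristic_frequency()].
#' @return List with \code{consensus} and \code{peak}.
#' @export
group_characteristic_frequency <- function(seqs, group_id = "group",
                                           table = eiip_table(),
                                           snr_threshold = 20) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0(group_id, "_", seq_along(seqs))
  encoded <- Map(encode_sequence, seqs, seq_id = names(seqs),
                 MoreArgs = list(table = table))
  n <- rrm_transform_length(vapply(encoded, function(e) e$length, integer(1)))
  spectra <- lapply(encoded, amplitude_spectrum, n_points = n)
  cs <- cross_spectrum(spectra, group_id = group_id)
  list(consensus = cs,
       peak = find_characteristic_frequency(cs, snr_threshold = snr_threshold))
}

#' Read a FASTA file as a named vector of amino-acid strings
#'
#' Description lines become sequence ids; gaps and whitespace are stripped
#' before EIIP validation.
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta_group <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
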