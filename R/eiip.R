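#' Load the EIIP amino-acid pseudopotential table
#'
#' The electron-ion interaction potential (EIIP) assigns each of the 20
#' canonical amino acids a pseudopotential (Rydberg units) describing the
#' average energy states of its valence electrons. The Resonant Recognition
#' Model maps a protein sequence to a numerical signal through this table.
#' The shipped resource is the standard Veljkovic table used throughout the
#' RRM literature, versioned and checksummed so it cannot silently drift.
#'
#' @param path Path to a two-column tab-separated resource file
#'   (\code{residue}, \code{eiip}) with \code{#} comment headers. Defaults to
#'   the table shipped with the package.
#' @return A named list with \code{entries} (named numeric vector of length
#'   20, names = one-letter residue codes), \code{version_tag}, and
#'   \code{md5} of the resource file.
#' @export
eiip_table <- function(path = system.file("extdata", "eiip_veljkovic.tsv",
                                          package = "rrmlilt")) {
  stopifnot(nzchar(path), file.exists(path))
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  entries <- stats::setNames(raw$eiip, raw$residue)
  hdr <- readLines(path, n = 3L)
  version <- sub(".*version:\\s*", "", grep("version:", hdr, value = TRUE)[1])
  validate_eiip(entries)
  structure(list(entries = entries,
                 version_tag = version,
                 md5 = unname(tools::md5sum(path))),
            class = "eiip_table")
}

# 20 canonical residues, values bounded, Leu/Ile degenerate at the minimum
validate_eiip <- function(entries) {
  canonical <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (!setequal(names(entries), canonical) || length(entries) != 20L)
    stop("EIIP table must contain exactly the 20 canonical residues")
  if (any(entries < 0 | entries > 0.15))
    stop("EIIP values out of range [0, 0.15]")
  if (!isTRUE(all.equal(entries[["L"]], min(entries))) ||
      !isTRUE(all.equal(entries[["I"]], entries[["L"]])))
    stop("Leu and Ile must share the minimal EIIP value")
  invisible(entries)
}

#' Encode a protein sequence as an EIIP numerical signal
#'
#' Each residue is replaced by its EIIP pseudopotential, turning the sequence
#' into the real-valued series whose spectrum the RRM analyses. Matching is
#' case-insensitive; ambiguity codes (B, J, X, Z) and any other non-canonical
#' character are rejected with the offending position, because imputation
#' would change the spectrum.
#'
#' @param seq Amino-acid string (one-letter codes).
#' @param table An [eiip_table()] object.
#' @param seq_id Identifier carried through to downstream spectra.
#' @return An object of class \code{numerical_sequence}: list with
#'   \code{seq_id}, \code{residues}, \code{values}, \code{length}.
#' @export
encode_sequence <- function(seq, table = eiip_table(), seq_id = "seq") {
  stopifnot(inherits(table, "eiip_table"), is.character(seq), length(seq) == 1L)
  seq <- gsub("[-[:space:]]", "", seq)  # strip gaps/whitespace before validation
  if (!nzchar(seq)) stop("empty sequence")
  residues <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!residues %in% names(table$entries))
  if (length(bad) > 0L)
    stop(sprintf("unknown residue '%s' at position %d in '%s'",
                 residues[bad[1]], bad[1], seq_id))
  values <- unname(table$entries[residues])
  structure(list(seq_id = seq_id, residues = paste(residues, collapse = ""),
                 values = values, length = length(values)),
            class = "numerical_sequence")
}
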