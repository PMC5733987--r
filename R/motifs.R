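#' Scan for N-glycosylation sequons
#'
#' Finds every Asn-Xaa-Ser/Thr site with Xaa != Pro, the acceptor pattern
#' for N-linked glycosylation. Overlapping sequons are all reported. The
#' `context` column is the 4-residue window starting at the Asn (clipped at
#' the chain end), mirroring printed site tables such as "27 NQSS".
#'
#' @param seq A `ProteinSequence`.
#' @return Data frame with columns `position` (Asn, reported numbering) and
#'   `context`; zero rows when no sequon exists.
#' @examples
#' find_sequons(protein_sequence("ANQSSA"))
#' @export
find_sequons <- function(seq) {
  stopifnot(inherits(seq, "ProteinSequence"))
  x <- seq_letters(seq)
  l <- length(x)
  hits <- integer(0)
  if (l >= 3L) {
    i <- seq_len(l - 2L)
    ok <- x[i] == "N" & x[i + 1L] != "P" & x[i + 2L] %in% c("S", "T")
    hits <- i[ok]
  }
  data.frame(
    position = seq$offset + hits - 1L,
    context = vapply(hits, function(i)
      substr(seq$residues, i, min(i + 3L, l)), ""),
    stringsAsFactors = FALSE)
}

#' Find the histidine-acid-phosphatase catalytic motif
#'
#' Scans for the conserved RHGXRXP signature (X = any standard residue) and,
#' for each match, the nearest downstream His-Asp dyad whose Asp acts as the
#' proton donor of the catalytic mechanism.
#'
#' @param seq A `ProteinSequence`.
#' @return Data frame with columns `start` (position of the leading Arg) and
#'   `hd_position` (position of the H of the nearest downstream HD dyad, NA
#'   if none).
#' @examples
#' find_catalytic_motif(protein_sequence("ARHGARAPAAAHDA"))
#' @export
find_catalytic_motif <- function(seq) {
  stopifnot(inherits(seq, "ProteinSequence"))
  x <- seq_letters(seq)
  l <- length(x)
  starts <- integer(0)
  if (l >= 7L) {
    i <- seq_len(l - 6L)
    ok <- x[i] == "R" & x[i + 1L] == "H" & x[i + 2L] == "G" &
      x[i + 4L] == "R" & x[i + 6L] == "P"
    starts <- i[ok]
  }
  hd_starts <- which(x[-l] == "H" & x[-1L] == "D")
  hd_for <- vapply(starts, function(s) {
    cand <- hd_starts[hd_starts >= s + 7L]
    if (length(cand)) cand[1] else NA_integer_
  }, integer(1))
  data.frame(
    start = seq$offset + starts - 1L,
    hd_position = seq$offset + hd_for - 1L)
}
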