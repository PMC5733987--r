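# The 20 standard one-letter amino-acid codes, alphabetical.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a validated protein sequence
#'
#' A `ProteinSequence` is a one-letter amino-acid string restricted to the 20
#' standard residues, together with an identifier and a numbering offset.
#' The offset is the reported number of the first residue, so mature chains
#' whose numbering does not start at 1 (or structure-numbered chains) report
#' positions consistently everywhere downstream.
#'
#' @param residues Character scalar over `ACDEFGHIKLMNPQRSTVWY` (may be
#'   empty).
#' @param id Free-text identifier.
#' @param offset Integer; reported number of the first residue (default 1).
#' @param nonstandard How to treat `U` (Sec) and `O` (Pyl): `"reject"`
#'   (default) or `"map"` to Cys/Lys respectively. Any other letter is always
#'   rejected.
#' @return An object of class `ProteinSequence`.
#' @examples
#' protein_sequence("AAG", id = "toy")
#' @export
protein_sequence <- function(residues, id = "", offset = 1L,
                             nonstandard = c("reject", "map")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  residues <- toupper(residues)
  if (nonstandard == "map" && nzchar(residues)) {
    residues <- chartr("UO", "CK", residues)
  }
  bad <- which(!strsplit(residues, "")[[1]] %in% AA_LETTERS)
  if (length(bad)) {
    stop(sprintf(
      "illegal residue letter '%s' at position %d in record '%s'",
      substr(residues, bad[1], bad[1]), bad[1], id))
  }
  structure(list(id = id, residues = residues, offset = as.integer(offset)),
            class = "ProteinSequence")
}

#' @export
length.ProteinSequence <- function(x) nchar(x$residues)

#' @export
print.ProteinSequence <- function(x, ...) {
  cat(sprintf("ProteinSequence '%s': %d aa (numbering starts at %d)\n",
              x$id, length(x), x$offset))
  invisible(x)
}

# Residue letters as a character vector, positions in reported numbering.
seq_letters <- function(seq) strsplit(seq$residues, "")[[1]]
seq_positions <- function(seq) seq$offset + seq_len(length(seq)) - 1L

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that validates every
#' record against the 20-letter standard alphabet. Selenocysteine (`U`) and
#' pyrrolysine (`O`) are rejected by default and can be mapped to Cys/Lys.
#'
#' @param path FASTA file.
#' @param nonstandard `"reject"` (default) or `"map"` (U to C, O to K).
#' @param offset Numbering offset applied to every record.
#' @return List of [protein_sequence()] objects, one per record.
#' @export
read_fasta <- function(path, nonstandard = c("reject", "map"), offset = 1L) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    protein_sequence(as.character(set[[i]]), id = ids[i], offset = offset,
                     nonstandard = nonstandard)
  })
  out
}

#' Write protein sequences to a FASTA file
#'
#' Lines wrapped at 60 columns.
#'
#' @param seqs A `ProteinSequence` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "ProteinSequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Construct an amino-acid composition table
#'
#' A `CompositionTable` carries residue counts over the 20 standard letters
#' and the implied chain length. It stands in for a sequence in all
#' composition-only arithmetic (molecular weight, pI, GRAVY, aliphatic
#' index, charge tallies), which is how the printed composition of a protein
#' can reproduce those quantities without the sequence itself.
#'
#' @param counts Named non-negative integer vector; names must be standard
#'   letters. Missing letters are taken as 0.
#' @return Object of class `CompositionTable` with fields `counts` (named
#'   integer over all 20 letters) and `length`.
#' @examples
#' composition_table(c(A = 2, G = 1))
#' @export
composition_table <- function(counts) {
  if (is.null(names(counts)) && length(counts) > 0)
    stop("counts must be named by residue letter")
  bad <- setdiff(names(counts), AA_LETTERS)
  if (length(bad)) stop("non-standard residue letters: ",
                        paste(bad, collapse = ", "))
  counts <- round(counts)
  if (any(counts < 0)) stop("negative residue counts")
  full <- stats::setNames(integer(20), AA_LETTERS)
  full[names(counts)] <- as.integer(counts)
  structure(list(counts = full, length = sum(full)),
            class = "CompositionTable")
}

#' @export
print.CompositionTable <- function(x, ...) {
  cat(sprintf("CompositionTable: %d residues\n", x$length))
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Amino-acid composition of a sequence
#'
#' @param x A `ProteinSequence` (or a `CompositionTable`, returned as is).
#' @return A [composition_table()].
#' @export
composition <- function(x) {
  if (inherits(x, "CompositionTable")) return(x)
  stopifnot(inherits(x, "ProteinSequence"))
  tab <- table(factor(seq_letters(x), levels = AA_LETTERS))
  composition_table(stats::setNames(as.integer(tab), AA_LETTERS))
}

# Accept either a sequence or a composition where only counts matter.
as_composition <- function(x) composition(x)

#' Mole percent of one residue
#'
#' `100 * count / length`, the "percent" column of a composition table.
#'
#' @param comp A `CompositionTable`.
#' @param residue Standard one-letter code.
#' @return Percent (0-100).
#' @export
mole_percent <- function(comp, residue) {
  comp <- as_composition(comp)
  if (comp$length == 0L) stop("empty composition")
  if (!residue %in% AA_LETTERS) stop("unknown residue letter: ", residue)
  100 * comp$counts[[residue]] / comp$length
}

#' Read a composition fixture (TSV with columns residue, count)
#'
#' @param path TSV file.
#' @return A [composition_table()].
#' @export
read_composition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "count") %in% names(df)))
  composition_table(stats::setNames(df$count, df$residue))
}
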