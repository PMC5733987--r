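#' Kolaskar-Tongaonkar antigenic propensity profile
#'
#' Mean Kolaskar-Tongaonkar propensity over 7-residue windows assigned to
#' window centers, plus the whole-protein mean over all centers (the
#' "average antigenic propensity"). When that mean exceeds 1.0, residues
#' scoring above 1.0 are considered potentially antigenic.
#'
#' @param seq `ProteinSequence` with at least 7 residues.
#' @param tables [load_tables()] output.
#' @param window Window size (the published method uses 7).
#' @return A `ResidueProfile` with an extra `protein_mean` field (class
#'   `PropensityProfile`, inherits `ResidueProfile`).
#' @export
kolaskar_profile <- function(seq, tables, window = 7L) {
  p <- sliding_profile(seq, scale = "kt", window = window, tables = tables)
  p$protein_mean <- mean(p$values)
  class(p) <- c("PropensityProfile", class(p))
  p
}

#' @export
print.PropensityProfile <- function(x, ...) {
  cat(sprintf("Kolaskar-Tongaonkar profile: %d centers, protein mean %.4f\n",
              length(x$values), x$protein_mean))
  invisible(x)
}

#' Extract antigenic determinants from a propensity profile
#'
#' Maximal runs of consecutive window centers whose propensity strictly
#' exceeds the threshold, kept when at least `min_len` long. The threshold
#' is 1.0 when the protein mean is >= 1.0 and the protein mean otherwise
#' (the published decision rule). Note the first and last `(window-1)/2`
#' residues of the chain have no center value and can never belong to a
#' determinant.
#'
#' @param profile A `PropensityProfile` from [kolaskar_profile()].
#' @param min_len Minimum determinant length in residues (default 8, the
#'   common published choice; configurable because source tables differ).
#' @return Data frame with columns `start`, `end` (reported numbering),
#'   `sequence` (center residues across the run), `length`.
#' @export
antigenic_determinants <- function(profile, min_len = 8L) {
  stopifnot(inherits(profile, "PropensityProfile"))
  threshold <- if (profile$protein_mean >= 1.0) 1.0 else profile$protein_mean
  above <- profile$values > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(
    start = profile$positions[starts[keep]],
    end = profile$positions[ends[keep]],
    sequence = vapply(which(keep), function(k)
      paste(profile$residues[starts[k]:ends[k]], collapse = ""), ""),
    length = r$lengths[keep])
}
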