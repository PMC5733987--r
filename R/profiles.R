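#' Sliding-window per-residue profile
#'
#' Arithmetic mean of a per-residue scale over an odd window, assigned to the
#' window's center residue with no edge padding (the ProtScale convention
#' with linear weight 1): a length-L sequence yields `L - window + 1` values
#' at centers `(w-1)/2 + 1 ... L - (w-1)/2` in reported numbering.
#'
#' @param seq A `ProteinSequence` with `length >= window`.
#' @param scale `"kd"` (Kyte-Doolittle hydropathy), `"accessibility"`,
#'   `"kt"`, or a named numeric vector over the 20 letters.
#' @param window Odd window size; 9 is the conventional default for
#'   hydropathy scans.
#' @param tables [load_tables()] output.
#' @return Object of class `ResidueProfile` with fields `scale_name`,
#'   `window`, `positions` (centers, reported numbering), `values`, and
#'   `residues` (center residue letters).
#' @export
sliding_profile <- function(seq, scale = "kd", window = 9L, tables) {
  stopifnot(inherits(seq, "ProteinSequence"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  l <- length(seq)
  if (window > l) stop(sprintf("window (%d) exceeds sequence length (%d)",
                               window, l))
  sc <- resolve_scale(scale, tables)
  x <- sc$values[seq_letters(seq)]
  # centered running mean via cumulative sums
  cs <- c(0, cumsum(x))
  vals <- (cs[(window + 1):(l + 1)] - cs[1:(l - window + 1)]) / window
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(l - half)
  structure(list(scale_name = sc$name, window = window,
                 positions = seq$offset + centers - 1L,
                 values = unname(vals),
                 residues = seq_letters(seq)[centers]),
            class = "ResidueProfile")
}

#' @export
print.ResidueProfile <- function(x, ...) {
  cat(sprintf("ResidueProfile (%s, window %d): %d centers, range %.3f .. %.3f\n",
              x$scale_name, x$window, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Profile extrema with ranked runners-up
#'
#' Returns the minimum and maximum of a profile and the `n` lowest/highest
#' values, as in a printed extrema table. Ties share the extreme score and
#' are all retained, listed in ascending position order.
#'
#' @param p A `ResidueProfile`.
#' @param n How many ranked low/high entries to report (default 3).
#' @param digits Scores are compared after rounding to this many decimals,
#'   so printed-precision ties (e.g. two equal maxima) are preserved.
#' @return List with `min` and `max` (data frames of the tied extreme
#'   entries) and `low`/`high` (the n-ranked tables, columns position,
#'   residue, value).
#' @export
profile_extrema <- function(p, n = 3L, digits = 3L) {
  stopifnot(inherits(p, "ResidueProfile"))
  if (length(p$values) == 0L) stop("empty profile")
  df <- data.frame(position = p$positions, residue = p$residues,
                   value = p$values, stringsAsFactors = FALSE)
  r <- round(df$value, digits)
  low <- df[order(r, df$position), ][seq_len(min(n, nrow(df))), ]
  high <- df[order(-r, df$position), ][seq_len(min(n, nrow(df))), ]
  rownames(low) <- rownames(high) <- NULL
  list(min = df[r == min(r), , drop = FALSE],
       max = df[r == max(r), , drop = FALSE],
       low = low, high = high)
}

#' Write a profile as TSV (position, residue, value)
#'
#' @param p A `ResidueProfile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(p, path) {
  df <- data.frame(position = p$positions, residue = p$residues,
                   value = round(p$values, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
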