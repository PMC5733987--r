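#' Molecular weight from composition
#'
#' Sum of average residue masses plus one water, in daltons. An empty
#' composition therefore returns the mass of water. Divide by 1000 for kDa
#' (the convention of printed reports).
#'
#' @param comp A `CompositionTable` or `ProteinSequence`.
#' @param tables [load_tables()] output.
#' @return Molecular weight in Da.
#' @examples
#' tabs <- load_tables()
#' molecular_weight(composition_table(c(G = 1)), tabs)  # free glycine
#' @export
molecular_weight <- function(comp, tables) {
  comp <- as_composition(comp)
  sum(comp$counts * tables$residue_mass[names(comp$counts)]) +
    tables$water_mass
}

# Net charge at a given pH by Henderson-Hasselbalch sums: one C-terminus,
# one N-terminus with a residue-specific pKa, and the ionizable side chains.
# Vectorized over pH. His is a charge contributor here even though it is
# excluded from the "positively charged residues" tally.
net_charge <- function(comp, nterm_residue, tables, ph) {
  counts <- comp$counts
  pka <- tables$pka
  nt_key <- paste0("Nterm_", nterm_residue)
  nt_pka <- if (nt_key %in% names(pka)) pka[[nt_key]] else
    pka[["Nterm_default"]]
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - ph))
  q <- pos_frac(nt_pka) + neg_frac(pka[["Cterm"]])
  for (r in c("H", "K", "R")) q <- q + counts[[r]] * pos_frac(pka[[paste0("side_", r)]])
  for (r in c("D", "E", "C", "Y")) q <- q + counts[[r]] * neg_frac(pka[[paste0("side_", r)]])
  q
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge is zero, found by
#' bisection on \[0, 14\]. The charge sums one C-terminus (pKa 3.55), one
#' N-terminus with a residue-specific Bjellqvist pKa, the acidic side chains
#' D, E, C, Y and the basic side chains H, K, R -- the ProtParam model, so
#' composition alone (plus the identity of the N-terminal residue)
#' determines the result.
#'
#' @param comp `CompositionTable` or `ProteinSequence` (for a sequence the
#'   N-terminal residue is taken from it when `nterm_residue` is missing).
#' @param nterm_residue One-letter code of the N-terminal residue.
#' @param tables [load_tables()] output.
#' @param tol Bisection stops when `|Q| < tol` (default 1e-4).
#' @return pH of zero net charge.
#' @export
isoelectric_point <- function(comp, nterm_residue = NULL, tables,
                              tol = 1e-4) {
  if (inherits(comp, "ProteinSequence") && is.null(nterm_residue))
    nterm_residue <- substr(comp$residues, 1, 1)
  comp <- as_composition(comp)
  if (comp$length == 0L) stop("empty composition")
  if (is.null(nterm_residue) || !nterm_residue %in% AA_LETTERS)
    stop("nterm_residue must be a standard one-letter code")
  lo <- 0; hi <- 14
  q_lo <- net_charge(comp, nterm_residue, tables, lo)
  if (q_lo < 0) return(lo)  # degenerate: negative even at pH 0
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(comp, nterm_residue, tables, mid)
    if (abs(q) < tol || (hi - lo) < 1e-9) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Charged-residue tallies
#'
#' Negatively charged = Asp + Glu; positively charged = Arg + Lys. His is
#' excluded from the positive tally, matching the printed arithmetic of the
#' source reports (e.g. 19 Arg + 15 Lys = 34 for 3-phytase A).
#'
#' @param comp `CompositionTable` or `ProteinSequence`.
#' @return List with `neg_count`, `neg_pct`, `pos_count`, `pos_pct`.
#' @export
charged_counts <- function(comp) {
  comp <- as_composition(comp)
  if (comp$length == 0L) stop("empty composition")
  neg <- comp$counts[["D"]] + comp$counts[["E"]]
  pos <- comp$counts[["R"]] + comp$counts[["K"]]
  list(neg_count = neg, neg_pct = 100 * neg / comp$length,
       pos_count = pos, pos_pct = 100 * pos / comp$length)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy per residue; negative values indicate a
#' protein that prefers aqueous media, as expected for secreted enzymes.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless GRAVY score.
#' @export
gravy <- function(comp, tables) {
  comp <- as_composition(comp)
  if (comp$length == 0L) stop("empty composition")
  sum(comp$counts * tables$kd_scale[names(comp$counts)]) / comp$length
}

#' Aliphatic index
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in mole percent: the
#' relative volume occupied by aliphatic side chains, a thermostability
#' proxy (Ikai 1980).
#'
#' @inheritParams molecular_weight
#' @return Dimensionless index (0-290 in theory; poly-Ala gives 100).
#' @export
aliphatic_index <- function(comp, tables) {
  comp <- as_composition(comp)
  if (comp$length == 0L) stop("empty composition")
  co <- tables$aliphatic_coeffs
  mole_percent(comp, "A") + co[["a"]] * mole_percent(comp, "V") +
    co[["b"]] * (mole_percent(comp, "I") + mole_percent(comp, "L"))
}

#' Guruprasad instability index
#'
#' `II = (10 / L) * sum DIWV(x_i, x_i+1)` over the L-1 dipeptides of the
#' sequence; values above 40 predict in-vivo instability. Unlike the other
#' Table-style properties this needs the sequence, not just its composition.
#'
#' @param seq A `ProteinSequence` of length >= 2.
#' @param tables [load_tables()] output.
#' @return List with `value` and `stability_label` ("stable"/"unstable").
#' @export
instability_index <- function(seq, tables) {
  stopifnot(inherits(seq, "ProteinSequence"))
  l <- length(seq)
  if (l < 2L) stop("instability index needs at least 2 residues")
  x <- seq_letters(seq)
  total <- sum(tables$diwv[cbind(x[-l], x[-1])])
  value <- 10 / l * total
  list(value = value,
       stability_label = if (value > 40) "unstable" else "stable")
}

#' N-end-rule half-life lookup
#'
#' Estimated half-life as a function of the N-terminal residue, in the three
#' classic contexts (mammalian reticulocytes in vitro, yeast in vivo,
#' E. coli in vivo).
#'
#' @param nterm_residue One-letter code.
#' @param tables [load_tables()] output.
#' @return Named character vector `c(mammalian=, yeast=, ecoli=)`.
#' @export
estimated_half_life <- function(nterm_residue, tables) {
  if (!nterm_residue %in% AA_LETTERS)
    stop("unknown residue letter: ", nterm_residue)
  row <- tables$nend_rule[tables$nend_rule$residue == nterm_residue, ]
  c(mammalian = row$mammalian, yeast = row$yeast, ecoli = row$ecoli)
}

#' Full physicochemical report
#'
#' Computes every composition-derivable property, and the instability index
#' and half-life when a sequence (rather than a bare composition) is given.
#' Values are kept at full precision; the print method and TSV writer round
#' to the conventional printed precision.
#'
#' @param x `ProteinSequence` or `CompositionTable`.
#' @param nterm_residue N-terminal residue; required for a composition,
#'   inferred for a sequence.
#' @param tables [load_tables()] output.
#' @return Object of class `PhysChemReport`.
#' @export
physchem_report <- function(x, nterm_residue = NULL, tables) {
  is_seq <- inherits(x, "ProteinSequence")
  if (is_seq && is.null(nterm_residue))
    nterm_residue <- substr(x$residues, 1, 1)
  comp <- as_composition(x)
  ch <- charged_counts(comp)
  ii <- if (is_seq && length(x) >= 2L) instability_index(x, tables)
  rep <- list(
    length = comp$length,
    mw_da = molecular_weight(comp, tables),
    mw_kda = molecular_weight(comp, tables) / 1000,
    pi = isoelectric_point(comp, nterm_residue, tables),
    neg_count = ch$neg_count, neg_pct = ch$neg_pct,
    pos_count = ch$pos_count, pos_pct = ch$pos_pct,
    gravy = gravy(comp, tables),
    aliphatic_index = aliphatic_index(comp, tables),
    instability_index = if (!is.null(ii)) ii$value else NA_real_,
    stability_label = if (!is.null(ii)) ii$stability_label else NA_character_,
    half_life = estimated_half_life(nterm_residue, tables),
    nterm_residue = nterm_residue)
  class(rep) <- "PhysChemReport"
  rep
}

#' @export
print.PhysChemReport <- function(x, ...) {
  cat(sprintf("Mature protein length            %d\n", x$length))
  cat(sprintf("Molecular Weight (kDa)           %.2f\n", x$mw_kda))
  cat(sprintf("Theoretical Isoelectric Point    %.2f\n", x$pi))
  if (!is.na(x$instability_index))
    cat(sprintf("Instability Index                %.2f (%s)\n",
                x$instability_index,
                if (x$stability_label == "unstable") "Unstable" else "Stable"))
  cat(sprintf("Negatively charged (Asp + Glu)   %d (%.2f%%)\n",
              x$neg_count, x$neg_pct))
  cat(sprintf("Positively charged (Arg + Lys)   %d (%.2f%%)\n",
              x$pos_count, x$pos_pct))
  cat(sprintf("Aliphatic Index                  %.2f\n", x$aliphatic_index))
  cat(sprintf("GRAVY                            %.3f\n", x$gravy))
  cat(sprintf("Estimated half-life (N-term %s)  %s / %s / %s\n",
              x$nterm_residue, x$half_life[["mammalian"]],
              x$half_life[["yeast"]], x$half_life[["ecoli"]]))
  invisible(x)
}
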