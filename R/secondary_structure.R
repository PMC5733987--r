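#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model `E = 27.888 (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol
#' between an amide donor (N, H) and a carbonyl acceptor (C, O). Bonds are
#' conventionally accepted at `E < -0.5` kcal/mol.
#'
#' @param n,h Donor backbone N and amide H coordinates (numeric length-3).
#' @param c_,o Acceptor carbonyl C and O coordinates.
#' @return Energy in kcal/mol.
#' @export
ks_hbond_energy <- function(n, h, c_, o) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  r <- c(ON = d(o, n), CH = d(c_, h), OH = d(o, h), CN = d(c_, n))
  if (any(r < 0.1)) stop("coincident atoms in hydrogen-bond energy")
  27.888 * (1 / r[["ON"]] + 1 / r[["CH"]] - 1 / r[["OH"]] - 1 / r[["CN"]])
}

# Extract per-residue backbone coordinates for one chain, in file order.
# Returns a list of matrices (rows = residues) plus bookkeeping vectors.
chain_backbone <- function(structure, chain) {
  a <- structure$atoms
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (!nrow(a)) stop("chain not in structure: ", chain)
  key <- paste(a$resseq, a$icode, sep = "\r")
  res_keys <- unique(key)
  n_res <- length(res_keys)
  get <- function(name) {
    m <- matrix(NA_real_, n_res, 3)
    sel <- a[a$name == name, , drop = FALSE]
    idx <- match(paste(sel$resseq, sel$icode, sep = "\r"), res_keys)
    m[idx, ] <- cbind(sel$x, sel$y, sel$z)
    m
  }
  first <- !duplicated(key)
  list(resseq = a$resseq[first], resname = a$resname[first],
       N = get("N"), CA = get("CA"), C = get("C"), O = get("O"))
}

#' Assign 3-state secondary structure
#'
#' Simplified Kabsch-Sander assignment: backbone amide H positions are
#' synthesized from the preceding peptide plane (1.01 Angstrom from N,
#' anti-parallel to the preceding C=O), hydrogen bonds are pairs with
#' electrostatic energy below `energy_cutoff`, helices are runs supported by
#' two consecutive i+3/i+4/i+5 turns (3-10 and pi helices folded into H),
#' sheets are residues in parallel or antiparallel bridge patterns, and
#' everything else is coil. Percentages are taken over residues with a
#' complete backbone. Helix takes priority where helix and bridge overlap.
#'
#' @param structure A `PDBStructure`.
#' @param chain Chain id.
#' @param energy_cutoff Hydrogen-bond acceptance energy (default -0.5
#'   kcal/mol).
#' @return List of class `SSAssignment`: `labels` (data frame resseq,
#'   resname, label in H/E/C), `pct_helix`, `pct_sheet`, `pct_other`.
#' @export
assign_ss <- function(structure, chain, energy_cutoff = -0.5) {
  bb <- chain_backbone(structure, chain)
  n_res <- length(bb$resseq)
  complete <- stats::complete.cases(bb$N) & stats::complete.cases(bb$CA) &
    stats::complete.cases(bb$C) & stats::complete.cases(bb$O)
  if (!any(complete)) stop("no residues with complete backbone in chain ",
                           chain)
  # peptide bond intact between i-1 and i when C(i-1)..N(i) < 2.5 A
  linked <- rep(FALSE, n_res)
  if (n_res > 1) {
    dCN <- sqrt(rowSums((bb$C[-n_res, , drop = FALSE] -
                           bb$N[-1, , drop = FALSE])^2))
    linked[-1] <- !is.na(dCN) & dCN < 2.5
  }
  # synthesized amide H: donors are residues with an intact preceding
  # peptide unit and not proline (no amide H)
  H <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)[-1]) {
    if (!linked[i] || bb$resname[i] == "PRO" || !complete[i] ||
        !complete[i - 1]) next
    v <- bb$C[i - 1, ] - bb$O[i - 1, ]
    H[i, ] <- bb$N[i, ] + 1.01 * v / sqrt(sum(v^2))
  }
  donors <- which(!is.na(H[, 1]))
  acceptors <- which(complete)
  # hb[d, a] TRUE when N-H of d donates to C=O of a
  hb <- matrix(FALSE, n_res, n_res)
  if (length(donors) && length(acceptors)) {
    dist2 <- function(P, Q) {
      outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2 +
        outer(P[, 3], Q[, 3], "-")^2
    }
    rON <- sqrt(dist2(bb$O[acceptors, , drop = FALSE],
                      bb$N[donors, , drop = FALSE]))
    rCH <- sqrt(dist2(bb$C[acceptors, , drop = FALSE],
                      H[donors, , drop = FALSE]))
    rOH <- sqrt(dist2(bb$O[acceptors, , drop = FALSE],
                      H[donors, , drop = FALSE]))
    rCN <- sqrt(dist2(bb$C[acceptors, , drop = FALSE],
                      bb$N[donors, , drop = FALSE]))
    e <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    ok <- e < energy_cutoff & rON > 0.1 & rOH > 0.1
    for (k in seq_along(acceptors)) {
      ds <- donors[ok[k, ]]
      ds <- ds[abs(ds - acceptors[k]) >= 2]  # exclude self and i-1/i+1
      hb[ds, acceptors[k]] <- TRUE
    }
  }
  labels <- rep("C", n_res)
  # turns: hb[i + n, i]; two consecutive n-turns make a helix
  for (tn in c(4L, 3L, 5L)) {
    turn <- rep(FALSE, n_res)
    idx <- seq_len(max(0L, n_res - tn))
    turn[idx] <- hb[cbind(idx + tn, idx)]
    for (i in which(turn[-1] & turn[-n_res])) {
      # turns at i and i+1 -> residues i+1 .. i+tn are helical
      span <- (i + 1):min(i + tn, n_res)
      labels[span] <- "H"
    }
  }
  # bridges (parallel / antiparallel), |i - j| >= 3
  hbond <- function(i, j) {
    i >= 1 & j >= 1 & i <= n_res & j <= n_res & hb[cbind(i, j)]
  }
  bridge <- matrix(FALSE, n_res, n_res)
  for (i in seq_len(max(0L, n_res - 1L))[-1]) {
    js <- seq_len(n_res)
    js <- js[js >= 2 & js <= n_res - 1 & abs(js - i) >= 3]
    if (!length(js)) next
    par <- (hbond(rep(i - 1, length(js)), js) &
              hbond(js, rep(i + 1, length(js)))) |
      (hbond(js - 1, rep(i, length(js))) &
         hbond(rep(i, length(js)), js + 1))
    anti <- (hbond(rep(i, length(js)), js) &
               hbond(js, rep(i, length(js)))) |
      (hbond(rep(i - 1, length(js)), js + 1) &
         hbond(js - 1, rep(i + 1, length(js))))
    hitj <- js[par | anti]
    if (length(hitj)) {
      bridge[i, hitj] <- TRUE
      bridge[hitj, i] <- TRUE
    }
  }
  sheet <- rowSums(bridge) > 0
  labels[sheet & labels != "H"] <- "E"
  labels[!complete] <- "C"
  counted <- labels[complete]
  out <- list(
    labels = data.frame(resseq = bb$resseq, resname = bb$resname,
                        label = labels, stringsAsFactors = FALSE),
    pct_helix = 100 * mean(counted == "H"),
    pct_sheet = 100 * mean(counted == "E"),
    pct_other = 100 * mean(counted == "C"))
  class(out) <- "SSAssignment"
  out
}

#' @export
print.SSAssignment <- function(x, ...) {
  cat(sprintf("SSAssignment: %.0f%% helix, %.0f%% sheet, %.0f%% other (%d residues)\n",
              x$pct_helix, x$pct_sheet, x$pct_other, nrow(x$labels)))
  invisible(x)
}
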