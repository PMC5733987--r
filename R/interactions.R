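# Side-chain donor atom names with a synthesizable polar hydrogen, used when
# a structure carries no explicit hydrogens (crystal structures usually do
# not). Backbone amide N atoms (non-Pro) are donors too.
DONOR_SIDECHAIN <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", TRP = "NE1", SER = "OG", THR = "OG1",
  TYR = "OH")

#' Inter-chain interface residues
#'
#' All residue pairs across two chains whose heavy-atom minimum distance is
#' at or below the cutoff - the dimerization-contact detector.
#'
#' @param structure A `PDBStructure`.
#' @param chain_a,chain_b Chain ids (must differ).
#' @param cutoff Contact cutoff in Angstrom (default 4.0).
#' @return Data frame of class `ContactRecords` with columns `residue_a`,
#'   `residue_b` (labels like `Lys_14`), `resseq_a`, `resseq_b`,
#'   `min_distance`; attribute `interface_a`/`interface_b` hold the
#'   deduplicated per-chain residue lists.
#' @export
interface_residues <- function(structure, chain_a, chain_b, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  if (identical(chain_a, chain_b)) stop("chains must differ")
  a <- structure$atoms
  for (ch in c(chain_a, chain_b))
    if (!ch %in% a$chain) stop("chain not in structure: ", ch)
  heavy <- a[a$element != "H" & !a$water, , drop = FALSE]
  at_a <- heavy[heavy$chain == chain_a, , drop = FALSE]
  at_b <- heavy[heavy$chain == chain_b, , drop = FALSE]
  d <- atom_dist(at_a, at_b)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit)) {
    key <- paste(at_a$resseq[hit[, 1]], at_a$icode[hit[, 1]],
                 at_b$resseq[hit[, 2]], at_b$icode[hit[, 2]], sep = "\r")
    # per residue pair, keep the minimum distance
    dmin <- tapply(d[hit], key, min)
    first <- hit[!duplicated(key), , drop = FALSE]
    ukey <- key[!duplicated(key)]
    out <- data.frame(
      residue_a = res_label(at_a$resname[first[, 1]],
                            at_a$resseq[first[, 1]]),
      residue_b = res_label(at_b$resname[first[, 2]],
                            at_b$resseq[first[, 2]]),
      resseq_a = at_a$resseq[first[, 1]],
      resseq_b = at_b$resseq[first[, 2]],
      min_distance = as.numeric(dmin[ukey]),
      stringsAsFactors = FALSE)
    out <- out[order(out$resseq_a, out$resseq_b), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(residue_a = character(0), residue_b = character(0),
                      resseq_a = integer(0), resseq_b = integer(0),
                      min_distance = numeric(0))
  }
  attr(out, "interface_a") <- unique(out$residue_a)
  attr(out, "interface_b") <- unique(out$residue_b)
  class(out) <- c("ContactRecords", class(out))
  out
}

# Donor table for one atom set: polar N/O atoms that either carry an
# explicit hydrogen (within 1.25 A in the same residue) or match the
# name-based synthesizable-H rule. Returns indices into `atoms` plus, where
# available, the coordinates of the explicit hydrogen.
typed_donors <- function(atoms) {
  polar <- atoms$element %in% c("N", "O")
  hyd <- atoms[atoms$element == "H", , drop = FALSE]
  idx <- which(polar)
  has_name_h <- logical(length(idx))
  hx <- matrix(NA_real_, length(idx), 3)
  for (k in seq_along(idx)) {
    at <- atoms[idx[k], ]
    if (nrow(hyd)) {
      same <- hyd[hyd$chain == at$chain & hyd$resseq == at$resseq &
                    hyd$icode == at$icode, , drop = FALSE]
      if (nrow(same)) {
        dd <- sqrt((same$x - at$x)^2 + (same$y - at$y)^2 +
                     (same$z - at$z)^2)
        j <- which(dd < 1.25)
        if (length(j)) {
          j <- j[which.min(dd[j])]
          hx[k, ] <- c(same$x[j], same$y[j], same$z[j])
          has_name_h[k] <- TRUE
          next
        }
      }
    }
    if (at$het) next  # het donors require an explicit hydrogen
    if (at$name == "N" && at$resname != "PRO") has_name_h[k] <- TRUE
    else if (at$resname %in% names(DONOR_SIDECHAIN) &&
             at$name %in% DONOR_SIDECHAIN[[at$resname]])
      has_name_h[k] <- TRUE
  }
  list(idx = idx[has_name_h], h = hx[has_name_h, , drop = FALSE])
}

#' Enumerate hydrogen bonds in a docked pose
#'
#' Donor-acceptor pairs between a receptor and a ligand: donors are N/O
#' atoms with an explicit hydrogen or a synthesizable one (name-based rule
#' for standard residues); acceptors are N/O atoms. A pair is a hydrogen
#' bond when the donor-acceptor distance is within `dist_cutoff`; the
#' D-H...A angle test is applied only when an explicit hydrogen exists.
#' Phosphate oxygens of a ligand are acceptors; P-O-H hydrogens act as
#' donors only when explicit H atoms are present. Output is sorted by
#' distance.
#'
#' @param receptor `PDBStructure` (polymer atoms are used).
#' @param ligand `PDBStructure` or atom data frame of the ligand pose (all
#'   atoms used).
#' @param dist_cutoff Donor-acceptor distance cutoff in Angstrom (default
#'   3.5).
#' @param angle_min Minimum D-H...A angle in degrees when an explicit H is
#'   available (default 120).
#' @return Data frame of class `PoseHBonds`: `receptor_atom`, `ligand_atom`,
#'   `receptor_residue`, `distance`, `angle` (NA without explicit H),
#'   `donor_side` ("receptor" or "ligand").
#' @export
find_pose_hbonds <- function(receptor, ligand, dist_cutoff = 3.5,
                             angle_min = 120) {
  stopifnot(dist_cutoff > 0)
  rat <- if (inherits(receptor, "PDBStructure"))
    receptor$atoms[!receptor$atoms$het, , drop = FALSE] else receptor
  lat <- if (inherits(ligand, "PDBStructure")) ligand$atoms else ligand
  if (!nrow(lat) || !any(lat$element %in% c("N", "O"))) {
    warning("ligand has no N/O atoms; no hydrogen bonds possible")
    return(empty_hbonds())
  }
  rec_d <- typed_donors(rat)
  lig_d <- typed_donors(lat)
  rec_acc <- which(rat$element %in% c("N", "O"))
  lig_acc <- which(lat$element %in% c("N", "O"))
  one_dir <- function(datoms, dinfo, aatoms, aidx, donor_side) {
    if (!length(dinfo$idx) || !length(aidx)) return(empty_hbonds())
    dd <- datoms[dinfo$idx, , drop = FALSE]
    aa <- aatoms[aidx, , drop = FALSE]
    dm <- atom_dist(dd, aa)
    hit <- which(dm <= dist_cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(empty_hbonds())
    ang <- rep(NA_real_, nrow(hit))
    keep <- rep(TRUE, nrow(hit))
    for (k in seq_len(nrow(hit))) {
      hxyz <- dinfo$h[hit[k, 1], ]
      if (!anyNA(hxyz)) {
        dxyz <- unlist(dd[hit[k, 1], c("x", "y", "z")])
        axyz <- unlist(aa[hit[k, 2], c("x", "y", "z")])
        v1 <- dxyz - hxyz
        v2 <- axyz - hxyz
        ang[k] <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        keep[k] <- ang[k] >= angle_min
      }
    }
    hit <- hit[keep, , drop = FALSE]
    ang <- ang[keep]
    if (!nrow(hit)) return(empty_hbonds())
    if (donor_side == "receptor") {
      rec_at <- dd[hit[, 1], ]
      lig_at <- aa[hit[, 2], ]
    } else {
      rec_at <- aa[hit[, 2], ]
      lig_at <- dd[hit[, 1], ]
    }
    data.frame(
      receptor_atom = paste0(res_label(rec_at$resname, rec_at$resseq), ":",
                             rec_at$name),
      ligand_atom = paste0(lig_at$resname, ":", lig_at$name),
      receptor_residue = res_label(rec_at$resname, rec_at$resseq),
      distance = dm[hit],
      angle = ang,
      donor_side = donor_side,
      stringsAsFactors = FALSE)
  }
  out <- rbind(one_dir(rat, rec_d, lat, lig_acc, "receptor"),
               one_dir(lat, lig_d, rat, rec_acc, "ligand"))
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PoseHBonds", class(out))
  out
}

empty_hbonds <- function() {
  data.frame(receptor_atom = character(0), ligand_atom = character(0),
             receptor_residue = character(0), distance = numeric(0),
             angle = numeric(0), donor_side = character(0),
             stringsAsFactors = FALSE)
}

#' Summarize a pose's hydrogen bonds per residue
#'
#' The printed-table convention: total bond count plus the receptor-residue
#' multiset, one entry per bond (a residue donating or accepting twice is
#' listed twice).
#'
#' @param hbonds `PoseHBonds` data frame.
#' @return List with `n_bonds` and `residues` (character, length
#'   `n_bonds`).
#' @export
summarize_pose <- function(hbonds) {
  list(n_bonds = nrow(hbonds), residues = hbonds$receptor_residue)
}
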