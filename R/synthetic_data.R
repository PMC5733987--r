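#' Random sequence with an exact prescribed composition
#'
#' A uniformly random permutation of the residue multiset of a composition,
#' drawn under a fixed seed (the caller's RNG state is untouched). Optionally
#' the first residue can be pinned, e.g. to fix the N-terminal residue the
#' half-life and pI models depend on.
#'
#' @param comp `CompositionTable`.
#' @param seed Integer seed; same composition + seed gives the same
#'   sequence.
#' @param id Identifier for the result.
#' @param first Optional residue letter to place at position 1 (its count
#'   must be positive).
#' @param offset Numbering offset.
#' @return A `ProteinSequence` with `composition()` equal to `comp`.
#' @export
random_sequence <- function(comp, seed = 1L, id = "synthetic", first = NULL,
                            offset = 1L) {
  comp <- as_composition(comp)
  pool <- rep(names(comp$counts), comp$counts)
  if (!is.null(first)) {
    if (comp$counts[[first]] < 1L) stop("composition has no '", first, "'")
    pool <- pool[-match(first, pool)]
  }
  shuffled <- withr::with_seed(seed, sample(pool, length(pool)))
  protein_sequence(paste(c(first, shuffled), collapse = ""), id = id,
                   offset = offset)
}

# ---- toy-structure geometry -------------------------------------------------

# Place atom D given positions a, b, c at the given bond length |c-D|, angle
# b-c-D (degrees) and torsion a-b-c-D (degrees): the standard internal-to-
# Cartesian (NeRF) step.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

atom_row <- function(serial, name, resname, chain, resseq, xyz, element,
                     het = FALSE) {
  data.frame(serial = serial, name = name, altloc = " ", resname = resname,
             chain = chain, resseq = resseq, icode = " ",
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
             element = element, het = het, water = FALSE,
             stringsAsFactors = FALSE)
}

as_structure <- function(atoms, source = "synthetic") {
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, source = source), class = "PDBStructure")
}

# Poly-Ala backbone (N, CA, C, O) with prescribed phi/psi (scalars are
# recycled) and ideal bond geometry; standard bond lengths/angles, omega
# fixed at 180.
build_backbone <- function(n_res, phi, psi, chain = "A") {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  N <- list(c(0, 0, 0))
  CA <- list(c(1.458, 0, 0))
  ang <- 111.2 * pi / 180
  C <- list(CA[[1]] + 1.525 * c(-cos(ang), sin(ang), 0))
  for (i in 2:n_res) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         1.329, 116.2, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          1.458, 121.7, 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.2, phi[i])
  }
  O <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    # carbonyl O in the peptide plane: torsion psi + 180 about N-CA-C
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.8,
                         psi[i] + 180)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    rows[[length(rows) + 1]] <- atom_row(0, "N", "ALA", chain, i, N[[i]], "N")
    rows[[length(rows) + 1]] <- atom_row(0, "CA", "ALA", chain, i, CA[[i]], "C")
    rows[[length(rows) + 1]] <- atom_row(0, "C", "ALA", chain, i, C[[i]], "C")
    rows[[length(rows) + 1]] <- atom_row(0, "O", "ALA", chain, i, O[[i]], "O")
  }
  do.call(rbind, rows)
}

#' Build a toy structure with known geometric ground truth
#'
#' Deterministic fixture generator for every structure-based stage:
#'
#' * `ideal_helix`: poly-Ala backbone at phi = -57, psi = -47 (params:
#'   `n`, default 20) whose geometry guarantees i to i+4 hydrogen bonds.
#' * `lone_strand`: extended poly-Ala at phi = -139, psi = 135 (params:
#'   `n`); no partner strand, so no sheet can be assigned.
#' * `beta_hairpin`: two antiparallel extended strands of `n` residues each
#'   joined by a two-residue type II'-like turn (phi/psi 60,-120 and
#'   -80,0), whose cross-strand hydrogen bonds form real bridge patterns.
#' * `lys_acid_pair`: a Lys whose NZ sits exactly `d` Angstrom from an Asp
#'   OD1 (params: `d`).
#' * `two_chain_contact`: two single-residue chains with one inter-chain
#'   heavy-atom pair at exactly `d` Angstrom (params: `d`).
#' * `hbond_complex`: an Arg NH1 donor with explicit hydrogen plus a
#'   phosphate-bearing het ligand whose acceptor O sits at distance `d` with
#'   D-H...A angle `angle` degrees (params: `d`, `angle` default 180).
#'
#' @param kind Fixture kind (see above).
#' @param params Named list of kind-specific numeric parameters.
#' @param path Optional file path; when given the structure is also written
#'   as PDB.
#' @return A `PDBStructure`.
#' @export
build_toy_structure <- function(kind = c("ideal_helix", "lone_strand",
                                         "beta_hairpin", "lys_acid_pair",
                                         "two_chain_contact",
                                         "hbond_complex"),
                                params = list(), path = NULL) {
  kind <- match.arg(kind)
  p <- function(name, default) {
    v <- if (!is.null(params[[name]])) params[[name]] else default
    if (name %in% c("d") && v <= 0) stop("unphysical parameter d <= 0")
    v
  }
  atoms <- switch(kind,
    ideal_helix = build_backbone(as.integer(p("n", 20)), -57, -47),
    lone_strand = build_backbone(as.integer(p("n", 12)), -139, 135),
    beta_hairpin = {
      n <- as.integer(p("n", 5))
      build_backbone(2L * n + 2L,
                     c(rep(-139, n), 60, -80, rep(-139, n)),
                     c(rep(135, n), -120, 0, rep(135, n)))
    },
    lys_acid_pair = {
      d <- p("d", 5)
      rbind(
        atom_row(0, "N",  "LYS", "A", 1, c(-8, 0, 0), "N"),
        atom_row(0, "CA", "LYS", "A", 1, c(-7, 0, 0), "C"),
        atom_row(0, "C",  "LYS", "A", 1, c(-6, 1, 0), "C"),
        atom_row(0, "O",  "LYS", "A", 1, c(-6, 2, 0), "O"),
        atom_row(0, "NZ", "LYS", "A", 1, c(0, 0, 0), "N"),
        atom_row(0, "N",  "ASP", "A", 2, c(d + 3, 0, 0), "N"),
        atom_row(0, "CA", "ASP", "A", 2, c(d + 2, 0, 0), "C"),
        atom_row(0, "C",  "ASP", "A", 2, c(d + 2, 1, 0), "C"),
        atom_row(0, "O",  "ASP", "A", 2, c(d + 2, 2, 0), "O"),
        atom_row(0, "OD1", "ASP", "A", 2, c(d, 0, 0), "O"))
    },
    two_chain_contact = {
      d <- p("d", 3.5)
      rbind(atom_row(0, "CA", "GLY", "A", 1, c(0, 0, 0), "C"),
            atom_row(0, "CA", "GLY", "B", 1, c(d, 0, 0), "C"))
    },
    hbond_complex = {
      d <- p("d", 3.0)
      theta <- p("angle", 180)
      # donor N at origin, H at distance 1.0 on +x; acceptor placed in the
      # xy-plane so that |N-A| = d and the D-H...A angle equals theta
      ct <- cos(theta * pi / 180)
      r <- ct + sqrt(pmax(0, ct^2 - 1 + d^2))
      axyz <- c(1 - r * ct, r * sin(theta * pi / 180), 0)
      rbind(
        atom_row(0, "CA",  "ARG", "A", 1, c(-3, 0, 0), "C"),
        atom_row(0, "NH1", "ARG", "A", 1, c(0, 0, 0), "N"),
        atom_row(0, "HH11", "ARG", "A", 1, c(1, 0, 0), "H"),
        atom_row(0, "C1",  "IHP", "L", 1, axyz + c(3, 3, 0), "C",
                 het = TRUE),
        atom_row(0, "P1",  "IHP", "L", 1, axyz + c(1.6, 0, 0), "P",
                 het = TRUE),
        atom_row(0, "O1P", "IHP", "L", 1, axyz, "O", het = TRUE))
    })
  st <- as_structure(atoms, source = paste0("synthetic:", kind))
  if (!is.null(path)) write_pdb(st, path)
  st
}

#' Bundled printed-table fixtures
#'
#' Machine-readable transcriptions of the published characterization tables
#' for the two A. niger phytases, verified against a SHA-256 manifest:
#'
#' * `proteins`: per-protein metadata (mature length, N-terminal residue,
#'   signal-peptide length).
#' * `compositions`: named list of `CompositionTable`s (keys `3K4Q`,
#'   `1QFX_A`).
#' * `glycation`: per-lysine nearest acid/base distances (Angstrom; censored
#'   rows store the printed lower bound and `*_censored = TRUE`) plus the
#'   transcribed external-predictor and distance-method calls.
#' * `determinants`: the published antigenic-determinant fragments.
#'
#' The transcription keeps the printed values verbatim; the one arithmetic
#' impossibility in the printed record (a molecular weight inconsistent with
#' its own composition) is annotated in the package vignette rather than
#' patched here.
#'
#' @param data_dir Fixture directory (defaults to the installed copies).
#' @param verify Verify the SHA-256 manifest (default TRUE).
#' @return List with elements `proteins`, `compositions`, `glycation`,
#'   `determinants`.
#' @export
table_fixtures <- function(data_dir = system.file("extdata", "fixtures",
                                                  package = "protchar"),
                           verify = TRUE) {
  files <- c("proteins.tsv", "composition_3K4Q.tsv",
             "composition_1QFX_A.tsv", "table4_glycation.tsv",
             "table5_determinants.tsv")
  if (verify) verify_manifest(data_dir, files)
  proteins <- utils::read.delim(file.path(data_dir, "proteins.tsv"),
                                stringsAsFactors = FALSE)
  comps <- list(
    `3K4Q` = read_composition_tsv(file.path(data_dir,
                                            "composition_3K4Q.tsv")),
    `1QFX_A` = read_composition_tsv(file.path(data_dir,
                                              "composition_1QFX_A.tsv")))
  glyc <- utils::read.delim(file.path(data_dir, "table4_glycation.tsv"),
                            stringsAsFactors = FALSE)
  det <- utils::read.delim(file.path(data_dir, "table5_determinants.tsv"),
                           stringsAsFactors = FALSE)
  list(proteins = proteins, compositions = comps, glycation = glyc,
       determinants = det)
}
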