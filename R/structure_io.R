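# Residue names treated as water when flagging het groups.
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Parse a PDB (or PDBQT) coordinate file
#'
#' Minimal reader for the fixed-column PDB dialect: ATOM/HETATM records are
#' parsed strictly on the coordinate columns (31-54) and tolerantly on
#' trailing fields; only the first MODEL of a multi-model file is kept;
#' alternate locations are resolved to the highest occupancy (ties: altloc
#' 'A', then blank). PDBQT ligand files are accepted read-only (coordinates
#' and element; partial charges ignored).
#'
#' The result holds a flat atom table - the R-idiomatic container - with one
#' row per atom and columns `serial`, `name`, `altloc`, `resname`, `chain`,
#' `resseq`, `icode`, `x`, `y`, `z`, `occupancy`, `element`, `het`, `water`.
#' Author residue numbering is retained verbatim.
#'
#' @param path PDB/PDBQT file.
#' @param model Which MODEL block to keep (default first).
#' @return Object of class `PDBStructure`.
#' @export
parse_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # restrict to the requested MODEL block when MODEL records exist
  model_idx <- grep("^MODEL", lines)
  if (length(model_idx)) {
    endmdl <- grep("^ENDMDL", lines)
    if (length(model_idx) < model) stop("model ", model, " not in file")
    from <- model_idx[model]
    to <- if (length(endmdl) >= model) endmdl[model] else length(lines)
    lines <- lines[from:to]
  }
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  fx <- function(from, to) trimws(substr(lines, from, to))
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v[nzchar(s)])) stop("malformed ", what, " field in ", path)
    v
  }
  x <- num(fx(31, 38), "x-coordinate")
  y <- num(fx(39, 46), "y-coordinate")
  z <- num(fx(47, 54), "z-coordinate")
  if (anyNA(x) || anyNA(y) || anyNA(z) ||
      any(!is.finite(c(x, y, z))))
    stop("missing or non-finite coordinates in ", path)
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1.0
  element <- toupper(fx(77, 78))
  name <- fx(13, 16)
  # derive element from the atom name when the element column is absent or
  # holds a PDBQT atom type
  derive <- !element %in% c("C", "N", "O", "S", "P", "H", "FE", "ZN", "MG",
                            "CA", "NA", "CL", "K", "MN", "CU", "I", "F",
                            "BR")
  element[derive] <- substr(gsub("[^A-Za-z]", "", name[derive]), 1, 1)
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(fx(7, 11))),
    name = name,
    altloc = substr(lines, 17, 17),
    resname = fx(18, 20),
    chain = substr(lines, 22, 22),
    resseq = suppressWarnings(as.integer(fx(23, 26))),
    icode = substr(lines, 27, 27),
    x = x, y = y, z = z,
    occupancy = occ,
    element = toupper(element),
    het = substr(lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
  atoms$water <- atoms$resname %in% WATER_NAMES
  atoms <- resolve_altloc(atoms)
  structure(list(atoms = atoms, source = path), class = "PDBStructure")
}

# Keep one atom per (chain, resseq, icode, resname, name): highest
# occupancy, ties resolved in favor of altloc 'A', then blank, then file
# order.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname,
               atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  pref <- ifelse(atoms$altloc == "A", 0L, ifelse(atoms$altloc == " ", 1L, 2L))
  ord <- order(key, -atoms$occupancy, pref, seq_len(nrow(atoms)))
  first <- !duplicated(key[ord])
  kept <- sort(seq_len(nrow(atoms))[ord][first])
  atoms[kept, , drop = FALSE]
}

#' @export
print.PDBStructure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "PDBStructure: %d atoms, chains [%s], %d polymer + %d het residues\n",
    nrow(a), paste(unique(a$chain), collapse = ","),
    nrow(unique(a[!a$het, c("chain", "resseq", "icode")])),
    nrow(unique(a[a$het, c("chain", "resseq", "icode")]))))
  invisible(x)
}

#' Write a structure back to PDB format
#'
#' Coordinates are written at the standard 3-decimal precision.
#'
#' @param structure A `PDBStructure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  name <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                 sprintf(" %-3s", a$name))
  lines <- sprintf(
    "%s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, a$serial %% 100000L, name, a$altloc, a$resname, a$chain, a$resseq,
    a$icode, a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms by simple predicates
#'
#' Returns all and only matching atoms in file order; every argument left
#' NULL is not filtered on. An empty selection is allowed.
#'
#' @param structure A `PDBStructure`.
#' @param chain,resname,atom_name,resseq Values to keep.
#' @param het TRUE for het-group atoms only, FALSE for polymer only, NA
#'   (default) for both.
#' @return Atom data frame (possibly 0 rows).
#' @export
select_atoms <- function(structure, chain = NULL, resname = NULL,
                         atom_name = NULL, resseq = NULL, het = NA) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(atom_name)) keep <- keep & a$name %in% atom_name
  if (!is.null(resseq)) keep <- keep & a$resseq %in% resseq
  if (!is.na(het)) keep <- keep & a$het == het
  a[keep, , drop = FALSE]
}

# Internal: squared-distance matrix between two atom tables (n x m).
atom_dist <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Internal: residue id label like "Lys_119" from resname/resseq.
res_label <- function(resname, resseq) {
  nice <- paste0(substr(resname, 1, 1), tolower(substr(resname, 2, 3)))
  paste0(nice, "_", resseq)
}
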