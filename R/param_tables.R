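# Aliphatic-index side-chain volume coefficients (Ikai 1980).
ALIPHATIC_A <- 2.9
ALIPHATIC_B <- 3.9

#' Load the numeric constant tables
#'
#' Single authoritative store for every constant the formulas need, read
#' from versioned TSV files with a SHA-256 MANIFEST verified at load:
#'
#' * `residue_mass`: average residue masses (Da) and the mass of water, the
#'   ExPASy/ProtParam set.
#' * `pka`: the Bjellqvist pKa set as used by ProtParam - C-terminus, side
#'   chains D, E, C, Y (acidic) and H, K, R (basic), plus residue-specific
#'   N-terminal values with a default of 7.5.
#' * `kd_scale`: Kyte-Doolittle (1982) hydropathy, spanning -4.5 (Arg) to
#'   4.5 (Ile).
#' * `accessibility_scale`: pluggable solvent-accessibility scale; the
#'   default ships Janin's (1978) molar fraction of accessible residues.
#' * `diwv`: the complete 20 x 20 Guruprasad (1990) dipeptide instability
#'   weight matrix.
#' * `kt_propensity`: Kolaskar-Tongaonkar (1990) antigenic propensities.
#' * `nend_rule`: N-end-rule half-lives (mammalian reticulocyte in vitro,
#'   yeast in vivo, E. coli in vivo) per N-terminal residue.
#'
#' @param data_dir Directory holding the TSV tables and `MANIFEST.sha256`.
#'   Defaults to the copies installed with the package.
#' @param verify Verify SHA-256 checksums against the manifest (default
#'   TRUE).
#' @return A list of class `ParameterTables`.
#' @export
load_tables <- function(data_dir = system.file("extdata", "params",
                                               package = "protchar"),
                        verify = TRUE) {
  files <- c("residue_mass.tsv", "pka.tsv", "kd.tsv",
             "accessibility_janin.tsv", "diwv.tsv", "kt_propensity.tsv",
             "nend_rule.tsv")
  paths <- file.path(data_dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) stop("missing parameter table(s): ",
                            paste(missing, collapse = ", "))
  if (verify) verify_manifest(data_dir, files)

  rm_df <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
  residue_mass <- stats::setNames(rm_df$mass_da, rm_df$residue)
  water_mass <- residue_mass[["H2O"]]
  residue_mass <- residue_mass[names(residue_mass) != "H2O"]

  pka_df <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
  pka <- stats::setNames(pka_df$pka, pka_df$group)

  kd_df <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  kd_scale <- stats::setNames(kd_df$value, kd_df$residue)

  acc_df <- utils::read.delim(paths[4], stringsAsFactors = FALSE)
  accessibility_scale <- stats::setNames(acc_df$value, acc_df$residue)

  diwv_df <- utils::read.delim(paths[5], stringsAsFactors = FALSE)
  diwv <- matrix(NA_real_, 20, 20, dimnames = list(AA_LETTERS, AA_LETTERS))
  diwv[cbind(diwv_df$first, diwv_df$second)] <- diwv_df$weight

  kt_df <- utils::read.delim(paths[6], stringsAsFactors = FALSE)
  kt_propensity <- stats::setNames(kt_df$value, kt_df$residue)

  nend <- utils::read.delim(paths[7], stringsAsFactors = FALSE)

  tables <- structure(list(
    residue_mass = residue_mass, water_mass = water_mass, pka = pka,
    kd_scale = kd_scale, accessibility_scale = accessibility_scale,
    diwv = diwv, kt_propensity = kt_propensity, nend_rule = nend,
    aliphatic_coeffs = c(a = ALIPHATIC_A, b = ALIPHATIC_B)),
    class = "ParameterTables")
  validate_tables(tables)
  tables
}

verify_manifest <- function(data_dir, files) {
  manifest_path <- file.path(data_dir, "MANIFEST.sha256")
  if (!file.exists(manifest_path)) stop("MANIFEST.sha256 not found in ",
                                        data_dir)
  man <- utils::read.delim(manifest_path, header = FALSE,
                           col.names = c("sha256", "file"),
                           stringsAsFactors = FALSE)
  for (f in files) {
    expected <- man$sha256[man$file == f]
    if (length(expected) != 1L) stop("file not listed in MANIFEST: ", f)
    got <- digest::digest(file.path(data_dir, f), algo = "sha256",
                          file = TRUE)
    if (!identical(got, expected))
      stop("checksum mismatch for parameter table ", f)
  }
  invisible(TRUE)
}

validate_tables <- function(t) {
  cover <- function(v, what) {
    if (!all(AA_LETTERS %in% names(v)))
      stop("incomplete alphabet coverage in ", what)
  }
  cover(t$residue_mass, "residue_mass")
  cover(t$kd_scale, "kd_scale")
  cover(t$accessibility_scale, "accessibility_scale")
  cover(t$kt_propensity, "kt_propensity")
  if (any(is.na(t$diwv))) stop("DIWV matrix incomplete (400 pairs required)")
  if (min(t$kd_scale) != -4.5 || max(t$kd_scale) != 4.5)
    stop("Kyte-Doolittle scale must span [-4.5, 4.5]")
  need <- c("Cterm", "Nterm_default", paste0("side_", c("D", "E", "C", "Y",
                                                        "H", "K", "R")))
  if (!all(need %in% names(t$pka)))
    stop("pKa table missing groups: ",
         paste(setdiff(need, names(t$pka)), collapse = ", "))
  if (!all(AA_LETTERS %in% t$nend_rule$residue))
    stop("N-end rule table incomplete")
  invisible(TRUE)
}

#' @export
print.ParameterTables <- function(x, ...) {
  cat("ParameterTables: residue masses, Bjellqvist pKa set,",
      "Kyte-Doolittle scale,\n  accessibility scale, DIWV matrix,",
      "Kolaskar-Tongaonkar propensities, N-end rule\n")
  invisible(x)
}

# Scale lookup used by the profile and report code: either a named scale in
# the tables ("kd", "accessibility", "kt") or a user-supplied named vector.
resolve_scale <- function(scale, tables) {
  if (is.character(scale) && length(scale) == 1L) {
    v <- switch(scale,
                kd = tables$kd_scale,
                accessibility = tables$accessibility_scale,
                kt = tables$kt_propensity,
                stop("unknown scale name: ", scale))
    return(list(name = scale, values = v))
  }
  if (is.numeric(scale) && !is.null(names(scale))) {
    if (!all(AA_LETTERS %in% names(scale)))
      stop("custom scale must cover all 20 residues")
    return(list(name = "custom", values = scale))
  }
  stop("scale must be a scale name or a named numeric vector")
}
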