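# Functional atom sets for the distance rule: the lysine epsilon-amino
# nitrogen versus carboxylate oxygens (acid class) and side-chain nitrogens
# (base class).
ACID_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASE_ATOMS <- list(HIS = c("ND1", "NE2"), ARG = c("NE", "NH1", "NH2"),
                   LYS = "NZ")

#' Per-lysine distance environment
#'
#' For every lysine NZ atom of a chain, the minimum Euclidean distance to
#' the acidic functional atoms (Asp OD1/OD2, Glu OE1/OE2) and to the basic
#' ones (His ND1/NE2, Arg NE/NH1/NH2, NZ of *other* lysines). Distances are
#' atom-level minima in Angstrom - the geometry behind structure-based
#' glycation propensity: nearby charged side chains perturb the epsilon-NH2
#' pKa and catalyze Amadori chemistry.
#'
#' @param structure A `PDBStructure`.
#' @param chain Chain id to analyze.
#' @param include_interchain Also consider candidate atoms on other chains
#'   (default FALSE: the analysis is per chain).
#' @return Data frame of class `LysineEnvironment`: `lysine` (resseq),
#'   `nearest_acid`, `acid_dist`, `nearest_base`, `base_dist` (NA when the
#'   class is absent). Lysines lacking an NZ atom are skipped with a
#'   warning.
#' @export
lysine_environment <- function(structure, chain,
                               include_interchain = FALSE) {
  a <- structure$atoms
  if (!chain %in% a$chain) stop("chain not in structure: ", chain)
  lys <- a[a$chain == chain & a$resname == "LYS" & !a$het, , drop = FALSE]
  lys_res <- unique(lys$resseq)
  nz <- lys[lys$name == "NZ", , drop = FALSE]
  missing_nz <- setdiff(lys_res, nz$resseq)
  if (length(missing_nz))
    warning("lysine(s) without NZ atom skipped: ",
            paste(missing_nz, collapse = ", "))
  cand <- if (include_interchain) a[!a$het, , drop = FALSE] else
    a[a$chain == chain & !a$het, , drop = FALSE]
  pick <- function(sets) {
    keep <- rep(FALSE, nrow(cand))
    for (rn in names(sets)) keep <- keep |
        (cand$resname == rn & cand$name %in% sets[[rn]])
    cand[keep, , drop = FALSE]
  }
  acids <- pick(ACID_ATOMS)
  bases <- pick(BASE_ATOMS)
  env_one <- function(i) {
    p <- nz[i, ]
    near <- function(targets) {
      if (!nrow(targets)) return(c(NA_character_, NA_real_))
      d <- sqrt((targets$x - p$x)^2 + (targets$y - p$y)^2 +
                  (targets$z - p$z)^2)
      k <- which.min(d)
      c(res_label(targets$resname[k], targets$resseq[k]), d[k])
    }
    bt <- bases[!(bases$resname == "LYS" & bases$resseq == p$resseq &
                    bases$chain == p$chain), , drop = FALSE]
    c(near(acids), near(bt))
  }
  res <- t(vapply(seq_len(nrow(nz)), env_one, character(4)))
  out <- data.frame(
    lysine = nz$resseq,
    nearest_acid = res[, 1],
    acid_dist = as.numeric(res[, 2]),
    nearest_base = res[, 3],
    base_dist = as.numeric(res[, 4]),
    stringsAsFactors = FALSE)
  class(out) <- c("LysineEnvironment", class(out))
  out
}

#' Classify lysines as glycable by the distance rule
#'
#' A lysine is called glycable when the minimum of its nearest-acid and
#' nearest-base distances is strictly below the cutoff (default 10 Angstrom;
#' 9.99 is glycable, 10.00 is not). The supporting distance is that minimum.
#'
#' @param envs `LysineEnvironment` data frame (from [lysine_environment()]
#'   or a transcribed fixture with the same columns).
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @return Data frame of class `GlycationCalls`: `lysine`, `glycable`,
#'   `supporting_distance`, `method = "distance"`.
#' @export
classify_glycation <- function(envs, cutoff = 10.0) {
  stopifnot(cutoff > 0)
  d <- pmin(ifelse(is.na(envs$acid_dist), Inf, envs$acid_dist),
            ifelse(is.na(envs$base_dist), Inf, envs$base_dist))
  out <- data.frame(
    lysine = envs$lysine,
    glycable = d < cutoff,
    supporting_distance = ifelse(is.finite(d), d, NA_real_),
    method = rep("distance", length(d)),
    stringsAsFactors = FALSE)
  class(out) <- c("GlycationCalls", class(out))
  out
}

#' Read external per-lysine glycation predictions
#'
#' Two-column TSV (`lysine`, `glycable`), e.g. transcribed calls of a
#' sequence-based predictor consumed as input.
#'
#' @param path TSV file.
#' @return `GlycationCalls` data frame with `method = "external"`.
#' @export
read_glycation_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lysine", "glycable") %in% names(df)))
  out <- data.frame(lysine = df$lysine, glycable = as.logical(df$glycable),
                    supporting_distance = NA_real_, method = "external",
                    stringsAsFactors = FALSE)
  class(out) <- c("GlycationCalls", class(out))
  out
}

#' Agreement statistics between two glycation call sets
#'
#' Both call sets must cover the same lysine universe. Reports the positive
#' counts per method, their overlap, and the two directional fractions:
#' `fraction_b_of_a` = what percent of method-A positives method B also
#' calls, and `fraction_a_with_support` = what percent of method-B positives
#' method A supports.
#'
#' @param calls_a,calls_b `GlycationCalls` data frames (conventionally A =
#'   distance-based, B = external).
#' @return List of class `AgreementStats`: `n_a`, `n_b`, `n_overlap`,
#'   `fraction_b_of_a`, `fraction_a_with_support` (percents).
#' @export
compare_predictions <- function(calls_a, calls_b) {
  if (!setequal(calls_a$lysine, calls_b$lysine) ||
      length(calls_a$lysine) != length(calls_b$lysine))
    stop("call sets cover different lysine universes")
  pos_a <- calls_a$lysine[calls_a$glycable]
  pos_b <- calls_b$lysine[calls_b$glycable]
  ov <- length(intersect(pos_a, pos_b))
  structure(list(
    n_a = length(pos_a), n_b = length(pos_b), n_overlap = ov,
    fraction_b_of_a = if (length(pos_a)) 100 * ov / length(pos_a) else NA_real_,
    fraction_a_with_support = if (length(pos_b)) 100 * ov / length(pos_b)
    else NA_real_),
    class = "AgreementStats")
}

#' @export
print.AgreementStats <- function(x, ...) {
  cat(sprintf(
    "AgreementStats: A %d positives, B %d, overlap %d (B covers %.1f%% of A; %.1f%% of B supported by A)\n",
    x$n_a, x$n_b, x$n_overlap, x$fraction_b_of_a,
    x$fraction_a_with_support))
  invisible(x)
}
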