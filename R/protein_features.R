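# Sequence-derived physicochemical features: average molecular mass and
# the Bjellqvist isoelectric point (Henderson-Hasselbalch charge model
# with the Bjellqvist pK set, zero of net charge found by bisection).

# average (not monoisotopic) residue masses in Da
.AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

#' Bjellqvist pK table
#'
#' The pK set underlying the Bjellqvist isoelectric-point method:
#' side-chain values for D, E, C, Y, H, K, R, the C-terminal carboxyl,
#' and residue-specific N-terminal values (with a generic fallback).
#' The table is immutable at run time; pass a modified copy to
#' [net_charge()] / [isoelectric_point()] to use another scheme.
#'
#' @return List with \code{cterm}, \code{nterm_default}, \code{nterm}
#'   (named residue-specific overrides) and \code{side} (named vector).
#' @export
pk_bjellqvist <- function() {
  list(
    cterm = 3.55,
    nterm_default = 7.50,
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.70),
    side = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00, H = 5.98, K = 10.00, R = 12.00))
}

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da). \code{X}
#' (unknown residue) contributes the unweighted mean of the 20 standard
#' residue masses; in that case the result carries attribute
#' \code{approximate = TRUE}.
#'
#' @param aa_seq Protein sequence (20-letter alphabet plus X).
#' @return Mass in Da.
#' @examples
#' molecular_mass("G")  # 75.07 Da
#' @export
molecular_mass <- function(aa_seq) {
  .check_protein(aa_seq)
  chars <- strsplit(aa_seq, "")[[1]]
  if (any(chars == "*")) stop("sequence contains stop characters", call. = FALSE)
  m <- .AA_MASS[chars]
  nx <- sum(is.na(m))
  m[is.na(m)] <- mean(.AA_MASS)
  out <- sum(m) + .WATER_MASS
  if (nx > 0) attr(out, "approximate") <- TRUE
  out
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch model: each basic group (N-terminus, H, K, R)
#' contributes \eqn{1/(1+10^{pH-pK})}; each acidic group (C-terminus, D,
#' E, C, Y) contributes \eqn{-1/(1+10^{pK-pH})}. Termini are counted
#' once; \code{X} residues carry no charge.
#'
#' @param aa_seq Protein sequence.
#' @param pH pH value(s).
#' @param pk pK table from [pk_bjellqvist()] (or a modified copy).
#' @return Net charge in elementary units (vectorized over \code{pH}).
#' @export
net_charge <- function(aa_seq, pH, pk = pk_bjellqvist()) {
  .check_protein(aa_seq)
  chars <- strsplit(aa_seq, "")[[1]]
  counts <- table(factor(chars, levels = names(.AA_MASS)))
  nt_res <- chars[1L]
  pk_nt <- if (nt_res %in% names(pk$nterm)) pk$nterm[[nt_res]] else pk$nterm_default
  basic_pks <- c(pk_nt, rep(pk$side[["H"]], counts[["H"]]),
                 rep(pk$side[["K"]], counts[["K"]]), rep(pk$side[["R"]], counts[["R"]]))
  acidic_pks <- c(pk$cterm, rep(pk$side[["D"]], counts[["D"]]),
                  rep(pk$side[["E"]], counts[["E"]]), rep(pk$side[["C"]], counts[["C"]]),
                  rep(pk$side[["Y"]], counts[["Y"]]))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - basic_pks))) - sum(1 / (1 + 10^(acidic_pks - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in \eqn{[0, 14]} where [net_charge()] crosses zero. The
#' charge is strictly decreasing in pH, so bisection converges; the
#' iteration stops once the bracketing interval is below \code{tol} pH
#' units AND the residual charge is below 1e-3 elementary units (the
#' second condition matters on flat stretches of the titration curve,
#' the first on steep ones). At most 100 halvings.
#'
#' @param aa_seq Protein sequence.
#' @param pk pK table.
#' @param tol Convergence tolerance on the pH interval (default 1e-3).
#' @return pI in pH units, with attribute \code{charge} = residual net
#'   charge at the returned pH.
#' @export
isoelectric_point <- function(aa_seq, pk = pk_bjellqvist(), tol = 1e-3) {
  lo <- 0; hi <- 14
  q <- NA_real_
  for (it in seq_len(100L)) {
    mid <- (lo + hi) / 2
    q <- net_charge(aa_seq, mid, pk)
    if ((hi - lo) <= tol && abs(q) <= 1e-3) break
    if (q > 0) lo <- mid else hi <- mid
  }
  if (abs(q) > 1e-3) {
    stop("pI bisection did not converge", call. = FALSE)  # unreachable for monotone charge
  }
  structure(mid, charge = q)
}

#' Assemble the per-candidate feature table
#'
#' One row per curated candidate: length, average molecular mass,
#' Bjellqvist pI, Kozak state, assigned group and classification, plus
#' optional pass-through annotation columns (signal peptide,
#' localization, domains) merged from a user-supplied table — these are
#' never computed in-package. When an annotation supplies a signal-
#' peptide cleavage site (column \code{sp_cleavage}, the last residue of
#' the signal peptide), a mature-sequence mass and pI are added.
#'
#' @param curation data.frame from [curate_candidates()].
#' @param orfs ORF table carrying \code{orf_id}, \code{aa_seq},
#'   \code{aa_len}, \code{has_stop}, \code{kozak_state}.
#' @param annotations Optional data.frame with \code{candidate_id} plus
#'   arbitrary annotation columns (pass-through).
#' @param pk pK table for the pI computation.
#' @return data.frame (class \code{vhpo_features}) with deterministic
#'   column order; missing annotations are empty strings.
#' @export
build_feature_table <- function(curation, orfs, annotations = NULL,
                                pk = pk_bjellqvist()) {
  idx <- match(curation$candidate_id, orfs$orf_id)
  if (anyNA(idx)) {
    stop("curation/orf id mismatch: ",
         paste(curation$candidate_id[is.na(idx)], collapse = ","), call. = FALSE)
  }
  if (nrow(curation) == 0L) {
    out <- data.frame(candidate_id = character(), aa_length = integer(),
                      mass_da = numeric(), pI = numeric(), has_stop = logical(),
                      kozak_state = character(), assigned_group = integer(),
                      classification = character(), stringsAsFactors = FALSE)
    class(out) <- c("vhpo_features", class(out))
    return(out)
  }
  aa <- orfs$aa_seq[idx]
  out <- data.frame(
    candidate_id = curation$candidate_id,
    aa_length = orfs$aa_len[idx],
    mass_da = vapply(aa, function(s) as.numeric(molecular_mass(s)), numeric(1)),
    pI = vapply(aa, function(s) as.numeric(isoelectric_point(s, pk = pk)), numeric(1)),
    has_stop = orfs$has_stop[idx],
    kozak_state = orfs$kozak_state[idx],
    assigned_group = curation$assigned_group,
    classification = curation$classification,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    stopifnot("candidate_id" %in% names(annotations))
    if (!all(annotations$candidate_id %in% out$candidate_id)) {
      stop("annotation ids not present among candidates", call. = FALSE)
    }
    ann_cols <- setdiff(names(annotations), "candidate_id")
    m <- match(out$candidate_id, annotations$candidate_id)
    for (cl in ann_cols) {
      v <- annotations[[cl]][m]
      if (is.character(v)) v[is.na(v)] <- ""
      out[[cl]] <- v
    }
    if ("sp_cleavage" %in% names(annotations)) {
      cle <- suppressWarnings(as.integer(annotations$sp_cleavage[m]))
      mature <- ifelse(!is.na(cle) & cle > 0 & cle < out$aa_length,
                       substring(aa, cle + 1L), NA_character_)
      out$mature_mass_da <- ifelse(is.na(mature), NA_real_,
        vapply(mature, function(s) if (is.na(s)) NA_real_ else as.numeric(molecular_mass(s)), numeric(1)))
      out$mature_pI <- ifelse(is.na(mature), NA_real_,
        vapply(mature, function(s) if (is.na(s)) NA_real_ else as.numeric(isoelectric_point(s, pk = pk)), numeric(1)))
    }
  }
  class(out) <- c("vhpo_features", class(out))
  out
}

#' Summarize mass and pI ranges of complete enzymes
#'
#' "Complete" means the ORF ended at an in-frame stop
#' (\code{has_stop = TRUE}); partial 3'-truncated products are excluded
#' from the min/max summaries.
#'
#' @param features Table from [build_feature_table()].
#' @return List with kDa and pI ranges over complete candidates.
#' @export
feature_ranges <- function(features) {
  cmpl <- features[features$has_stop, , drop = FALSE]
  if (!nrow(cmpl)) return(list(mass_kda = c(NA, NA), pI = c(NA, NA), n = 0L))
  list(mass_kda = range(cmpl$mass_da) / 1000, pI = range(cmpl$pI), n = nrow(cmpl))
}
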