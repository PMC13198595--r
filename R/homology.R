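# Group assignment and vanadate-binding-motif curation of vHPO candidates.
#
# The three structural vHPO groups are anchored by five reference enzymes
# (group 1: 1UP8, 5LPC, 5AA6; group 2: 4CIT; group 3: 1IDQ). Candidates
# are assigned to the group of their best-scoring local alignment, the
# three vanadate-binding motifs are mapped through that alignment, and the
# conservation pattern drives the classification. The classification is a
# pure function of the assigned group and the per-site motif states.

.GROUP_OF_PDB <- c("1UP8" = 1L, "5LPC" = 1L, "5AA6" = 1L, "4CIT" = 2L, "1IDQ" = 3L)

#' Load a vHPO reference set (sequences + motif definitions)
#'
#' @param fasta Protein FASTA of the reference enzymes; headers
#'   \code{"<pdb_id> group=<g> organism=<text>"}.
#' @param motifs_tsv TSV with columns \code{pdb_id}, \code{motif_index},
#'   \code{ref_position} (1-based residue index), \code{expected_residue},
#'   \code{role} (\code{vanadate_binding}, \code{catalytic},
#'   \code{covalent_his}).
#' @return An object of class \code{vhpo_refs}: list with \code{seqs}
#'   (data.frame pdb_id, group, organism, aa_seq) and \code{motifs}
#'   (the motif table). Consistency is validated: motif positions lie
#'   within the sequence and carry the expected residue; each reference
#'   has exactly one \code{covalent_his} site, located in motif 3.
#' @export
load_reference_set <- function(fasta, motifs_tsv) {
  ss <- Biostrings::readAAStringSet(fasta)
  headers <- names(ss)
  pdb <- sub("\\s.*$", "", headers)
  grp <- as.integer(sub(".*group=(\\d+).*", "\\1", headers))
  org <- ifelse(grepl("organism=", headers),
                sub(".*organism=([^ ]+).*", "\\1", headers), "unknown")
  seqs <- data.frame(pdb_id = pdb, group = grp, organism = org,
                     aa_seq = unname(as.character(ss)), stringsAsFactors = FALSE)
  motifs <- read.delim(motifs_tsv, stringsAsFactors = FALSE)
  needed <- c("pdb_id", "motif_index", "ref_position", "expected_residue", "role")
  if (!all(needed %in% names(motifs))) {
    stop("motif table must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  for (p in seqs$pdb_id) {
    if (p %in% names(.GROUP_OF_PDB) &&
        seqs$group[seqs$pdb_id == p] != .GROUP_OF_PDB[[p]]) {
      stop(sprintf("reference %s declared in group %d but belongs to group %d",
                   p, seqs$group[seqs$pdb_id == p], .GROUP_OF_PDB[[p]]), call. = FALSE)
    }
    m <- motifs[motifs$pdb_id == p, ]
    s <- seqs$aa_seq[seqs$pdb_id == p]
    if (any(m$ref_position < 1 | m$ref_position > nchar(s))) {
      stop(sprintf("motif position outside reference %s", p), call. = FALSE)
    }
    at <- substring(s, m$ref_position, m$ref_position)
    if (!all(at == m$expected_residue)) {
      stop(sprintf("motif residue mismatch in reference %s", p), call. = FALSE)
    }
    ch <- m[m$role == "covalent_his", ]
    if (nrow(ch) != 1L || ch$motif_index != 3L || ch$expected_residue != "H") {
      stop(sprintf("reference %s must carry exactly one covalent_his site in motif 3", p),
           call. = FALSE)
    }
    if (!setequal(unique(m$motif_index), 1:3)) {
      stop(sprintf("reference %s must define motifs 1..3", p), call. = FALSE)
    }
  }
  structure(list(seqs = seqs, motifs = motifs), class = "vhpo_refs")
}

#' Packaged synthetic reference set
#'
#' Loads the synthetic stand-in reference enzymes shipped with the
#' package (\code{vhpo_refs_synthetic.faa} / \code{vhpo_motifs_synthetic.tsv}).
#' These are constructed sequences that reproduce the group structure and
#' motif layout of the five structurally characterized vHPOs; they are
#' NOT the PDB-derived sequences and are intended for pipeline validation
#' and simulation, not for curating real data (supply your own reference
#' FASTA + motif table for that).
#'
#' @return A \code{vhpo_refs} object.
#' @export
default_reference_set <- function() {
  load_reference_set(
    system.file("extdata", "vhpo_refs_synthetic.faa", package = "vhpotools"),
    system.file("extdata", "vhpo_motifs_synthetic.tsv", package = "vhpotools"))
}

#' @export
print.vhpo_refs <- function(x, ...) {
  cat(sprintf("vHPO reference set: %d sequences (groups %s), %d motif sites\n",
              nrow(x$seqs), paste(sort(unique(x$seqs$group)), collapse = ","),
              nrow(x$motifs)))
  invisible(x)
}

#' Assign a candidate to a vHPO group
#'
#' Aligns the candidate against every reference with [local_align()] and
#' returns the group of the best-scoring reference. Scores below
#' \code{min_score} yield group \code{NA} (no assignment). Score ties are
#' broken by lower group index, then lexicographic PDB id, and recorded.
#'
#' @param aa_seq Candidate protein sequence.
#' @param refs A \code{vhpo_refs} object.
#' @param min_score Raw Smith-Waterman score threshold; the default (73)
#'   was calibrated as the 99th percentile of best scores of
#'   residue-shuffled candidates against the packaged references (see
#'   [calibrate_min_score()]).
#' @param matrix,gap_open,gap_extend Passed to [local_align()].
#' @return List with \code{group} (integer or NA), \code{best_reference}
#'   (pdb id or NA), \code{score}, \code{alignment} (the best
#'   \code{vhpo_alignment}), and \code{tie} (logical).
#' @export
assign_group <- function(aa_seq, refs, min_score = 73,
                         matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(refs, "vhpo_refs"), nrow(refs$seqs) > 0)
  alns <- lapply(refs$seqs$aa_seq, function(t)
    local_align(aa_seq, t, matrix = matrix,
                gap_open = gap_open, gap_extend = gap_extend))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  best_score <- max(scores)
  if (best_score < min_score) {
    return(list(group = NA_integer_, best_reference = NA_character_,
                score = best_score, alignment = NULL, tie = FALSE))
  }
  cand <- which(scores == best_score)
  tie <- length(cand) > 1L
  ord <- order(refs$seqs$group[cand], refs$seqs$pdb_id[cand])
  pick <- cand[ord[1L]]
  list(group = refs$seqs$group[pick], best_reference = refs$seqs$pdb_id[pick],
       score = best_score, alignment = alns[[pick]], tie = tie)
}

#' Map motif sites through an alignment
#'
#' Each reference motif site is looked up among the aligned residue pairs
#' of \code{aln} (candidate = query, reference = target). Sites absent
#' from the aligned pairs are \code{unaligned}; aligned sites are
#' \code{conserved} when the candidate residue equals the expected
#' residue and \code{substituted} otherwise (the observed residue is
#' reported).
#'
#' @param aln A \code{vhpo_alignment} whose target is the reference
#'   carrying \code{motifs}.
#' @param motifs Motif table rows for that reference.
#' @return data.frame: \code{motif_index}, \code{ref_position},
#'   \code{expected_residue}, \code{role}, \code{state}, \code{observed}
#'   (candidate residue or NA), \code{query_pos} (candidate position or NA).
#' @export
map_motif_positions <- function(aln, motifs) {
  stopifnot(inherits(aln, "vhpo_alignment"))
  if (any(motifs$ref_position > nchar(aln$target))) {
    stop("motif position outside reference length", call. = FALSE)
  }
  qchars <- strsplit(aln$query, "")[[1]]
  hit <- match(motifs$ref_position, aln$pairs[, "target_pos"])
  qpos <- ifelse(is.na(hit), NA_integer_, aln$pairs[hit, "query_pos"])
  observed <- ifelse(is.na(qpos), NA_character_, qchars[qpos])
  state <- ifelse(is.na(qpos), "unaligned",
                  ifelse(observed == motifs$expected_residue, "conserved", "substituted"))
  data.frame(motif_index = motifs$motif_index,
             ref_position = motifs$ref_position,
             expected_residue = motifs$expected_residue,
             role = motifs$role, state = state, observed = observed,
             query_pos = qpos, stringsAsFactors = FALSE)
}

#' Classify a candidate from its motif conservation states
#'
#' Table-driven rules, applied in order:
#' \enumerate{
#'   \item no group assignment, or any motif with all of its sites
#'     unaligned \eqn{\rightarrow} \code{rejected};
#'   \item the covalent-histidine site substituted \eqn{\rightarrow}
#'     \code{predicted_inactive} (the enzyme cannot form the covalent
#'     His-vanadate bond);
#'   \item the covalent-histidine site unaligned (motif 3 only partially
#'     covered) \eqn{\rightarrow} \code{rejected} (no evidence of the
#'     catalytic His);
#'   \item fewer than \code{min_conserved_frac} of the
#'     \code{vanadate_binding} sites conserved \eqn{\rightarrow}
#'     \code{rejected};
#'   \item all non-covalent sites conserved \eqn{\rightarrow}
#'     \code{putative_vHPO}; otherwise \code{putative_vHPO_atypical}
#'     (e.g. the recurring His\eqn{\rightarrow}Ser/Thr substitution in
#'     motif 2 of group-2 enzymes).
#' }
#'
#' @param motif_states data.frame from [map_motif_positions()], or NULL.
#' @param assigned_group Integer group or NA.
#' @param min_conserved_frac Minimum fraction of \code{vanadate_binding}
#'   sites conserved for retention (default 0.6).
#' @return One of \code{"putative_vHPO"}, \code{"putative_vHPO_atypical"},
#'   \code{"predicted_inactive"}, \code{"rejected"}.
#' @export
classify_motif_states <- function(motif_states, assigned_group,
                                  min_conserved_frac = 0.6) {
  if (is.na(assigned_group) || is.null(motif_states)) return("rejected")
  by_motif <- split(motif_states$state, motif_states$motif_index)
  if (any(vapply(by_motif, function(s) all(s == "unaligned"), logical(1)))) {
    return("rejected")
  }
  ch <- motif_states[motif_states$role == "covalent_his", , drop = FALSE]
  if (any(ch$state == "substituted")) return("predicted_inactive")
  if (any(ch$state == "unaligned")) return("rejected")
  vb <- motif_states[motif_states$role == "vanadate_binding", , drop = FALSE]
  if (nrow(vb) && mean(vb$state == "conserved") < min_conserved_frac) {
    return("rejected")
  }
  noncov <- motif_states[motif_states$role != "covalent_his", , drop = FALSE]
  if (all(noncov$state == "conserved")) "putative_vHPO" else "putative_vHPO_atypical"
}

#' Curate one candidate ORF
#'
#' Composes [assign_group()], [map_motif_positions()] and
#' [classify_motif_states()] into a curation report.
#'
#' @inheritParams assign_group
#' @param candidate_id Identifier copied into the report.
#' @param min_conserved_frac Passed to [classify_motif_states()].
#' @return Object of class \code{vhpo_curation}: list with
#'   \code{candidate_id}, \code{assigned_group}, \code{best_reference},
#'   \code{score}, \code{identity_pct}, \code{motif_states},
#'   \code{classification}, \code{tie}.
#' @export
curate_candidate <- function(aa_seq, candidate_id = "candidate", refs = default_reference_set(),
                             min_score = 73, min_conserved_frac = 0.6,
                             matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  asg <- assign_group(aa_seq, refs, min_score = min_score, matrix = matrix,
                      gap_open = gap_open, gap_extend = gap_extend)
  motif_states <- NULL
  if (!is.na(asg$group)) {
    motifs <- refs$motifs[refs$motifs$pdb_id == asg$best_reference, , drop = FALSE]
    motif_states <- map_motif_positions(asg$alignment, motifs)
  }
  structure(list(
    candidate_id = candidate_id,
    assigned_group = asg$group,
    best_reference = asg$best_reference,
    score = asg$score,
    identity_pct = if (is.null(asg$alignment)) NA_real_ else asg$alignment$identity_pct,
    motif_states = motif_states,
    classification = classify_motif_states(motif_states, asg$group,
                                           min_conserved_frac = min_conserved_frac),
    tie = asg$tie,
    alignment = asg$alignment), class = "vhpo_curation")
}

#' @export
print.vhpo_curation <- function(x, ...) {
  cat(sprintf("%s: group %s (best ref %s, score %s) -> %s\n",
              x$candidate_id,
              ifelse(is.na(x$assigned_group), "none", x$assigned_group),
              ifelse(is.na(x$best_reference), "-", x$best_reference),
              format(x$score), x$classification))
  if (!is.null(x$motif_states)) {
    sub <- x$motif_states[x$motif_states$state != "conserved", , drop = FALSE]
    if (nrow(sub)) {
      cat("  non-conserved sites:\n")
      for (i in seq_len(nrow(sub))) {
        cat(sprintf("   motif %d %s%d -> %s\n", sub$motif_index[i],
                    sub$expected_residue[i], sub$ref_position[i],
                    ifelse(sub$state[i] == "unaligned", "unaligned", sub$observed[i])))
      }
    }
  }
  invisible(x)
}

#' Curate a table of candidate ORFs
#'
#' @param orfs ORF table (needs \code{orf_id} and \code{aa_seq}).
#' @inheritParams curate_candidate
#' @return data.frame with one row per candidate (id, group, best
#'   reference, score, identity, classification and a compact
#'   substitution summary such as \code{"m2:H310S"}); the full
#'   \code{vhpo_curation} objects are attached as attribute
#'   \code{"reports"}.
#' @export
curate_candidates <- function(orfs, refs = default_reference_set(), min_score = 73,
                              min_conserved_frac = 0.6, matrix = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  reports <- lapply(seq_len(nrow(orfs)), function(i)
    curate_candidate(orfs$aa_seq[i], candidate_id = orfs$orf_id[i], refs = refs,
                     min_score = min_score, min_conserved_frac = min_conserved_frac,
                     matrix = matrix, gap_open = gap_open, gap_extend = gap_extend))
  summarize_sub <- function(r) {
    if (is.null(r$motif_states)) return("")
    s <- r$motif_states[r$motif_states$state == "substituted", , drop = FALSE]
    if (!nrow(s)) return("")
    paste(sprintf("m%d:%s%d%s", s$motif_index, s$expected_residue,
                  s$ref_position, s$observed), collapse = ";")
  }
  out <- data.frame(
    candidate_id = vapply(reports, `[[`, character(1), "candidate_id"),
    assigned_group = vapply(reports, `[[`, integer(1), "assigned_group"),
    best_reference = vapply(reports, `[[`, character(1), "best_reference"),
    score = vapply(reports, `[[`, numeric(1), "score"),
    identity_pct = vapply(reports, `[[`, numeric(1), "identity_pct"),
    classification = vapply(reports, `[[`, character(1), "classification"),
    substitutions = vapply(reports, summarize_sub, character(1)),
    stringsAsFactors = FALSE)
  attr(out, "reports") <- reports
  out
}

#' Calibrate the group-assignment score threshold on a shuffled null
#'
#' Residue-shuffles the reference sequences themselves and records, for
#' each shuffle, the best local-alignment score against the full
#' reference set; the requested quantile (default 0.99) of this null
#' distribution is returned as the recommended \code{min_score}.
#'
#' @param refs A \code{vhpo_refs} object.
#' @param n_shuffle Number of shuffled null sequences (default 100).
#' @param probs Quantile of the null score distribution (default 0.99).
#' @param seed Integer seed for the shuffles.
#' @inheritParams local_align
#' @return Named list: \code{min_score} (the quantile, rounded up) and
#'   \code{null_scores}.
#' @export
calibrate_min_score <- function(refs, n_shuffle = 100, probs = 0.99, seed = 1,
                                matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(refs, "vhpo_refs"))
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(k) {
      src <- refs$seqs$aa_seq[((k - 1L) %% nrow(refs$seqs)) + 1L]
      shuf <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
      max(vapply(refs$seqs$aa_seq, function(t)
        local_align_score(shuf, t, matrix = matrix,
                          gap_open = gap_open, gap_extend = gap_extend),
        numeric(1)))
    }, numeric(1))
  })
  list(min_score = ceiling(unname(quantile(scores, probs))), null_scores = scores)
}

#' Kozak benchmark on a deposited candidate set
#'
#' Runs ORF discovery on a nucleotide FASTA of deposited candidate
#' contigs, keeps the longest ORF per contig (the deposited coding
#' sequence), and counts Kozak-positive starts.
#'
#' @param fasta Nucleotide FASTA path.
#' @param min_aa Minimum ORF length (default 100).
#' @return List with \code{count} (number of Kozak \code{match} starts)
#'   and \code{orfs} (one row per contig).
#' @export
kozak_benchmark <- function(fasta, min_aa = 100L) {
  contigs <- read_contigs(fasta)
  orfs <- discover_orfs(contigs, min_aa = min_aa)
  keep <- do.call(rbind, lapply(split(orfs, orfs$contig_id), function(d)
    d[which.max(d$aa_len), , drop = FALSE]))
  list(count = sum(keep$kozak_state == "match"), orfs = keep)
}

#' Motif-substitution benchmark on a deposited candidate set
#'
#' Curates deposited candidates and tabulates the observed residues at
#' the motif-2 histidine site among group-2 assignments (the recurring
#' His→Ser / His→Thr pattern).
#'
#' @param fasta Nucleotide FASTA of deposited candidate contigs.
#' @param refs Reference set.
#' @param min_aa,min_score Passed through.
#' @return List with \code{his_to_ser}, \code{his_to_thr}, and the full
#'   observed-residue \code{table}.
#' @export
motif_substitution_benchmark <- function(fasta, refs = default_reference_set(),
                                         min_aa = 100L, min_score = 73) {
  contigs <- read_contigs(fasta)
  orfs <- discover_orfs(contigs, min_aa = min_aa)
  orfs <- do.call(rbind, lapply(split(orfs, orfs$contig_id), function(d)
    d[which.max(d$aa_len), , drop = FALSE]))
  cur <- curate_candidates(orfs, refs = refs, min_score = min_score)
  reports <- attr(cur, "reports")
  obs <- unlist(lapply(reports, function(r) {
    if (is.na(r$assigned_group) || r$assigned_group != 2L) return(NULL)
    m2 <- r$motif_states[r$motif_states$motif_index == 2L &
                           r$motif_states$expected_residue == "H", , drop = FALSE]
    m2$observed
  }))
  tab <- table(obs, useNA = "ifany")
  list(his_to_ser = sum(obs == "S", na.rm = TRUE),
       his_to_thr = sum(obs == "T", na.rm = TRUE),
       table = tab)
}

#' Write a curation table as TSV
#'
#' @param curation data.frame from [curate_candidates()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_curation_table <- function(curation, path) {
  write.table(curation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
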