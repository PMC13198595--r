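# Six-frame ORF discovery from assembled transcriptome contigs.
#
# Conventions used throughout:
#  * frames are +1,+2,+3 (forward) and -1,-2,-3 (reverse complement);
#  * ORF coordinates are 0-based half-open on the FORWARD strand and span
#    the coding residues only (the terminating stop codon is excluded, so
#    end - start == 3 * aa_len always holds);
#  * an in-frame codon containing N translates to 'X' and does not
#    terminate the ORF; sequences with > 5% X are flagged.

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE  # standard code, translation table 1
      tab <<- setNames(unname(gc), names(gc))
    }
    tab
  }
})

.revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

.check_contig_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("contig sequence must be a nonempty character scalar", call. = FALSE)
  }
  if (grepl("[^ACGTN]", seq)) {
    stop("contig sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(TRUE)
}

#' Translate one reading frame of a contig
#'
#' Conceptual translation under the standard genetic code (translation
#' table 1). Stop codons are rendered as \code{*}; any codon containing
#' \code{N} is rendered as \code{X}. Negative frames translate the reverse
#' complement. The trailing partial codon, if any, is dropped.
#'
#' @param seq Nucleotide sequence (uppercase, alphabet A/C/G/T/N).
#' @param frame Integer in \code{c(1, 2, 3, -1, -2, -3)}.
#' @return Amino-acid string (possibly empty for very short inputs).
#' @examples
#' translate_frame("ATGAAA", 1)   # "MK"
#' translate_frame("TTTCAT", -1)  # "MK"
#' @export
translate_frame <- function(seq, frame) {
  .check_contig_seq(seq)
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) {
    stop("frame must be one of +1,+2,+3,-1,-2,-3", call. = FALSE)
  }
  s <- if (frame < 0) .revcomp(seq) else seq
  off <- abs(frame) - 1L
  n_codons <- (nchar(s) - off) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- off + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

# Kozak context of a start codon located at 0-based position `cs_start`
# on the coding strand `coding` (7-nt window: -3..-1, ATG, +4).
.kozak_at <- function(coding, cs_start) {
  n <- nchar(coding)
  if (cs_start < 3L || cs_start + 4L > n) {
    return(list(state = "indeterminate", context = ""))
  }
  ctx <- substr(coding, cs_start - 2L, cs_start + 4L)  # 1-based slice of 7 nt
  state <- if (grepl("^[AG][ACGTN]{2}ATGG$", ctx)) "match" else "no_match"
  list(state = state, context = ctx)
}

#' Scan the Kozak consensus at an ORF start
#'
#' Extracts the 7-nt window from position \eqn{-3} to \eqn{+4} around the
#' start codon on the coding strand and tests it against the consensus
#' \code{RxxATGG} (R = purine A/G). With fewer than 3 nt of upstream or
#' 1 nt of downstream context the state is \code{indeterminate}. An
#' \code{N} at a constrained position never matches.
#'
#' @param seq The contig nucleotide sequence the ORF was called on.
#' @param start,end 0-based half-open forward-strand ORF coordinates.
#' @param strand \code{"+"} or \code{"-"}.
#' @return List with \code{state} (\code{match}/\code{no_match}/
#'   \code{indeterminate}) and \code{context} (7-nt string or \code{""}).
#' @export
kozak_scan <- function(seq, start, end, strand = "+") {
  .check_contig_seq(seq)
  n <- nchar(seq)
  if (start < 0L || end > n || start >= end) {
    stop("ORF coordinates fall outside the contig", call. = FALSE)
  }
  if (strand == "+") {
    .kozak_at(seq, start)
  } else {
    .kozak_at(.revcomp(seq), n - end)
  }
}

# ORFs of a single translated frame; internal worker for six_frame_orfs()
.frame_orfs <- function(seq, frame, min_aa, require_met) {
  aa <- translate_frame(seq, frame)
  L <- nchar(seq)
  n_aa <- nchar(aa)
  if (n_aa == 0L) return(NULL)
  aavec <- strsplit(aa, "")[[1]]
  stops <- which(aavec == "*")
  seg_start <- c(1L, stops + 1L)
  seg_end <- c(stops - 1L, n_aa)
  out <- vector("list", length(seg_start))
  off <- abs(frame) - 1L
  for (k in seq_along(seg_start)) {
    s <- seg_start[k]; e <- seg_end[k]
    if (s > e) next
    if (require_met) {
      mets <- which(aavec[s:e] == "M")
      if (!length(mets)) next
      a <- s + mets[1L] - 1L
      n_alt <- length(mets) - 1L
    } else {
      a <- s
      n_alt <- sum(aavec[s:e] == "M")
    }
    len <- e - a + 1L
    if (len < min_aa) next
    has_stop <- e < n_aa && aavec[e + 1L] == "*"
    # coding-strand nt range (0-based half-open) of residues a..e
    cs_start <- off + 3L * (a - 1L)
    cs_end <- off + 3L * e
    if (frame > 0) {
      start <- cs_start; end <- cs_end; strand <- "+"
      coding <- seq
    } else {
      start <- L - cs_end; end <- L - cs_start; strand <- "-"
      coding <- .revcomp(seq)
    }
    aa_seq <- paste(aavec[a:e], collapse = "")
    kz <- .kozak_at(coding, cs_start)
    out[[k]] <- data.frame(
      frame = frame, strand = strand, start = start, end = end,
      aa_len = len, has_stop = has_stop, aa_seq = aa_seq,
      kozak_state = kz$state, kozak_context = kz$context,
      n_alt_starts = n_alt,
      x_flag = mean(strsplit(aa_seq, "")[[1]] == "X") > 0.05,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Six-frame ORF discovery on one contig
#'
#' For every frame, each segment between consecutive in-frame stop codons
#' (and the contig edges) yields at most one ORF: the one beginning at the
#' FIRST ATG of the segment (the longest Met-initiated product) and ending
#' at the next in-frame stop or the contig edge (\code{has_stop = FALSE}
#' in the latter case, the usual 3'-truncated assembly artefact). Only
#' ORFs of at least \code{min_aa} residues are reported; the count
#' includes the initial methionine and excludes the stop. The number of
#' alternative downstream ATG starts per segment is recorded.
#'
#' @param seq Contig nucleotide sequence.
#' @param min_aa Minimum protein length in residues (default 100).
#' @param require_met Require an ATG-initiated ORF (default TRUE); when
#'   FALSE each inter-stop segment is reported from its first residue.
#' @param contig_id,species Identifier columns copied into the result.
#' @return data.frame with one row per ORF: \code{contig_id},
#'   \code{species}, \code{frame}, \code{strand}, \code{start},
#'   \code{end} (0-based half-open, forward strand), \code{aa_len},
#'   \code{has_stop}, \code{aa_seq}, \code{kozak_state},
#'   \code{kozak_context}, \code{n_alt_starts}, \code{x_flag}.
#' @export
six_frame_orfs <- function(seq, min_aa = 100L, require_met = TRUE,
                           contig_id = "contig", species = "unknown") {
  .check_contig_seq(seq)
  if (!is.numeric(min_aa) || min_aa < 1) stop("min_aa must be >= 1", call. = FALSE)
  res <- do.call(rbind, lapply(c(1L, 2L, 3L, -1L, -2L, -3L), .frame_orfs,
                               seq = seq, min_aa = min_aa,
                               require_met = require_met))
  if (is.null(res)) res <- .empty_orf_table()[, -(1:2)]
  res <- cbind(data.frame(contig_id = rep(contig_id, nrow(res)),
                          species = rep(species, nrow(res)),
                          stringsAsFactors = FALSE), res)
  res[order(res$start, res$end, res$frame), , drop = FALSE]
}

.empty_orf_table <- function() {
  data.frame(contig_id = character(), species = character(),
             frame = integer(), strand = character(), start = integer(),
             end = integer(), aa_len = integer(), has_stop = logical(),
             aa_seq = character(), kozak_state = character(),
             kozak_context = character(), n_alt_starts = integer(),
             x_flag = logical(), stringsAsFactors = FALSE)
}

#' Six-frame ORF discovery over a contig table
#'
#' @param contigs data.frame with columns \code{id}, \code{species},
#'   \code{seq} as returned by [read_contigs()].
#' @inheritParams six_frame_orfs
#' @return Combined ORF table (see [six_frame_orfs()]), with a unique
#'   \code{orf_id} column \code{<contig_id>|<frame>|<start>}.
#' @export
discover_orfs <- function(contigs, min_aa = 100L, require_met = TRUE) {
  stopifnot(all(c("id", "species", "seq") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) stop("contig ids must be unique", call. = FALSE)
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    six_frame_orfs(contigs$seq[i], min_aa = min_aa, require_met = require_met,
                   contig_id = contigs$id[i], species = contigs$species[i])
  })
  out <- if (length(rows)) do.call(rbind, rows) else .empty_orf_table()
  if (nrow(out) == 0 && ncol(out) < 13) out <- .empty_orf_table()
  out$orf_id <- sprintf("%s|%+d|%d", out$contig_id, out$frame, out$start)
  rownames(out) <- NULL
  out
}

#' Remove duplicate candidate proteins
#'
#' Within the chosen scope exactly one representative per identical
#' amino-acid sequence is retained: the record with the lexicographically
#' smallest \code{contig_id} (ties broken by smallest \code{start}).
#' Retained rows are returned unchanged, ordered deterministically by
#' species, contig id and start. The operation is idempotent.
#'
#' @param orfs ORF table from [discover_orfs()].
#' @param scope \code{"per_species"} (duplicates removed within each
#'   species only) or \code{"global"}.
#' @return Deduplicated ORF table.
#' @export
dedupe_candidates <- function(orfs, scope = c("per_species", "global")) {
  scope <- match.arg(scope)
  if (nrow(orfs) == 0) return(orfs)
  key <- if (scope == "per_species") paste(orfs$species, orfs$aa_seq, sep = "\r")
         else orfs$aa_seq
  ord <- order(key, orfs$contig_id, orfs$start, orfs$frame)
  o <- orfs[ord, , drop = FALSE]
  keep <- o[!duplicated(key[ord]), , drop = FALSE]
  keep <- keep[order(keep$species, keep$contig_id, keep$start, keep$frame), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Read contigs from a nucleotide multi-FASTA
#'
#' Headers are parsed as \code{"<contig_id> [species=<label>]"}; records
#' without a species tag get species \code{"unknown"}. Sequences are
#' uppercased and validated against the A/C/G/T/N alphabet.
#'
#' @param path FASTA file path.
#' @return data.frame with columns \code{id}, \code{species}, \code{seq}.
#' @export
read_contigs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("\\[species=([^]]+)\\]", headers),
                    sub(".*\\[species=([^]]+)\\].*", "\\1", headers),
                    "unknown")
  seqs <- toupper(as.character(ss))
  for (s in seqs) .check_contig_seq(s)
  if (anyDuplicated(ids)) stop("duplicate contig ids in FASTA", call. = FALSE)
  data.frame(id = ids, species = species, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write ORF proteins to FASTA
#'
#' @param orfs ORF table with \code{orf_id} and \code{aa_seq} columns.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_orf_fasta <- function(orfs, path) {
  aa <- Biostrings::AAStringSet(setNames(orfs$aa_seq, orfs$orf_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
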