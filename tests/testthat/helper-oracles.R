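# Independent oracles used by the property tests. These deliberately do
# NOT share code with the package: the codon table is typed out, the
# alignment oracle enumerates matched-pair sets, the pI oracle is a grid
# scan, and the rank-test oracle enumerates permutations.

# --- translation oracle (hand-typed standard code) ----------------------
.ORACLE_CODE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_translate <- function(seq, frame) {
  s <- if (frame < 0) oracle_revcomp(seq) else seq
  s <- substring(s, abs(frame))
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- .ORACLE_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# --- ORF oracle: test every (frame, ATG) pair independently -------------
# Returns a data.frame keyed like discover_orfs output (frame, start,
# end, aa_seq, has_stop); per (frame, stop segment) the first ATG wins.
oracle_orfs <- function(seq, min_aa = 100) {
  L <- nchar(seq)
  rows <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    aa <- strsplit(oracle_translate(seq, frame), "")[[1]]
    mets <- which(aa == "M")
    seen_segments <- integer()
    for (a in mets) {
      stops_after <- which(aa == "*" & seq_along(aa) > a)
      e <- if (length(stops_after)) min(stops_after) - 1 else length(aa)
      has_stop <- length(stops_after) > 0
      # first ATG per segment: skip if an earlier M shares this segment
      stops_before <- which(aa == "*" & seq_along(aa) < a)
      seg_begin <- if (length(stops_before)) max(stops_before) + 1 else 1
      if (any(aa[seg_begin:a] == "M" & seq(seg_begin, a) < a)) next
      len <- e - a + 1
      if (len < min_aa) next
      off <- abs(frame) - 1
      cs_start <- off + 3 * (a - 1); cs_end <- off + 3 * e
      if (frame > 0) {
        start <- cs_start; end <- cs_end; strand <- "+"
      } else {
        start <- L - cs_end; end <- L - cs_start; strand <- "-"
      }
      rows[[length(rows) + 1]] <- data.frame(
        frame = frame, strand = strand, start = start, end = end,
        aa_len = len, has_stop = has_stop,
        aa_seq = paste(aa[a:e], collapse = ""), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), strand = character(), start = integer(),
               end = integer(), aa_len = integer(), has_stop = logical(),
               aa_seq = character())
  out[order(out$start, out$end, out$frame), , drop = FALSE]
}

random_contig <- function(n, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, n, replace = TRUE), collapse = "")
}

# --- local-alignment oracle: enumerate all matched-pair sets ------------
# Score of an alignment = sum of substitution values over matched pairs
# minus, between consecutive pairs, open+extend*L per nonempty gap run
# (leading/trailing overhangs are free for local alignment). Enumerating
# all strictly increasing pair sets covers every alignment at its
# minimal gap cost, hence yields the optimal local score.
oracle_local_score <- function(q, t, subst, gap_open = 11, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n1 <- length(qc); n2 <- length(tc)
  gapf <- function(d) ifelse(d > 0, gap_open + gap_extend * d, 0)
  best <- 0
  for (k in seq_len(min(n1, n2))) {
    qs <- combn(n1, k); ts <- combn(n2, k)
    match_mat <- matrix(0, ncol(qs), ncol(ts))
    for (r in seq_len(k)) {
      match_mat <- match_mat + subst[qc[qs[r, ]], tc[ts[r, ]], drop = FALSE]
    }
    qcost <- if (k > 1) colSums(gapf(qs[-1, , drop = FALSE] - qs[-k, , drop = FALSE] - 1)) else rep(0, ncol(qs))
    tcost <- if (k > 1) colSums(gapf(ts[-1, , drop = FALSE] - ts[-k, , drop = FALSE] - 1)) else rep(0, ncol(ts))
    best <- max(best, max(match_mat - outer(qcost, tcost, `+`)))
  }
  best
}

random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, TRUE), collapse = "")
}

# --- charge / pI oracles ------------------------------------------------
# term-by-term Henderson-Hasselbalch sheet, vectorized over pH
oracle_charge <- function(aa_seq, pH, pk = vhpotools::pk_bjellqvist()) {
  chars <- strsplit(aa_seq, "")[[1]]
  nt <- chars[1]
  pks_pos <- c(if (nt %in% names(pk$nterm)) pk$nterm[[nt]] else pk$nterm_default,
               unname(pk$side[chars[chars %in% c("H", "K", "R")]]))
  pks_neg <- c(pk$cterm, unname(pk$side[chars[chars %in% c("D", "E", "C", "Y")]]))
  pos <- rowSums(1 / (1 + 10^(outer(pH, pks_pos, `-`))))
  neg <- rowSums(1 / (1 + 10^(outer(-pH, pks_neg, `+`))))
  pos - neg
}

oracle_pi_grid <- function(aa_seq, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  grid[which.min(abs(oracle_charge(aa_seq, grid)))]
}

# --- Mann-Whitney permutation oracle ------------------------------------
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  sets <- combn(n1 + n2, n1)
  us <- apply(sets, 2, function(idx) sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}
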