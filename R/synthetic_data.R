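# Seeded synthetic-data generators with ground truth for every pipeline
# stage: planted-ORF transcriptomes, linear-phase bromination kinetics,
# Cq tables with planted fold changes, and Fv/Fm trajectories with
# planted control-corrected damage. Every generator is a pure function
# of its arguments and seed; repeated calls are identical.

.CODONS_OF <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

.random_nt <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)), collapse = "")
}

# uniform synonymous reverse translation (no codon-usage model)
.reverse_translate <- function(aa_seq, codon2_G = FALSE) {
  chars <- strsplit(aa_seq, "")[[1]]
  cod <- .CODONS_OF()
  codons <- vapply(chars, function(a) sample(cod[[a]], 1L), character(1))
  if (codon2_G && length(codons) >= 2L) {
    gg <- grep("^G", cod[[chars[2L]]], value = TRUE)
    if (length(gg)) codons[2L] <- sample(gg, 1L)
  }
  paste(codons, collapse = "")
}

# mutate `n_mut` positions (excluding `protected`) to different residues
.mutate_protein <- function(chars, n_mut, protected) {
  alphabet <- names(.AA_MASS)
  eligible <- setdiff(seq_along(chars), protected)
  n_mut <- min(n_mut, length(eligible))
  pos <- sample(eligible, n_mut)
  for (p in pos) chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
  chars
}

#' Synthetic transcriptome with planted vHPO ORFs
#'
#' Builds contigs containing vHPO-like ORFs derived from the reference
#' enzymes at a controlled protein identity (motif sites are held fixed
#' except where \code{substitutions} dictates otherwise), reverse-
#' translated with uniform synonymous codons and embedded at random
#' strands and frames in random background sequence. An in-frame stop is
#' placed directly upstream of each planted start so the planted ATG is
#' the first of its segment. A configurable fraction of planted ORFs
#' receives a Kozak-positive start context (when the second residue
#' admits no G-initial codon it is changed to alanine so the +4 G exists);
#' the rest get a pyrimidine at -3. Background ORFs are random proteins
#' unrelated to the references.
#'
#' @param refs \code{vhpo_refs} reference set.
#' @param n_planted,n_background Numbers of planted vHPO and background
#'   ORFs (one per contig).
#' @param identity Target protein identity of planted ORFs to their
#'   source reference, in \eqn{[0.4, 1]} (below 0.4 group assignment is
#'   undefined and the generator refuses).
#' @param substitutions Optional data.frame \code{candidate} (planted
#'   index), \code{ref_position}, \code{residue}: forced residues at
#'   motif sites of that candidate (e.g. the His-to-Asn inactivating
#'   substitution).
#' @param kozak_fraction Fraction of planted ORFs given a Kozak match
#'   context (default 0.3).
#' @param background_len Background contig length in nt (default 1000).
#' @param gc Background GC content (default 0.5).
#' @param seed Integer seed.
#' @return List with \code{contigs} (data.frame id/species/seq) and
#'   \code{truth} (one row per planted entity: id, kind, group,
#'   source_ref, identity, substitutions, kozak, strand, frame, start,
#'   end, aa_seq).
#' @export
make_transcriptome <- function(refs, n_planted = 10, n_background = 10,
                               identity = 0.7, substitutions = NULL,
                               kozak_fraction = 0.3, background_len = 1000,
                               gc = 0.5, seed = 1) {
  stopifnot(inherits(refs, "vhpo_refs"))
  if (identity < 0.4 || identity > 1) {
    stop("planted identity must lie in [0.4, 1]; below 40% group assignment is undefined",
         call. = FALSE)
  }
  with_seed(seed, {
    contigs <- list(); truth <- list()
    n_refs <- nrow(refs$seqs)
    kozak_flags <- if (n_planted > 0) sample(rep(c(TRUE, FALSE),
      times = c(round(kozak_fraction * n_planted),
                n_planted - round(kozak_fraction * n_planted)))) else logical()
    for (i in seq_len(n_planted)) {
      ri <- ((i - 1L) %% n_refs) + 1L
      ref_seq <- refs$seqs$aa_seq[ri]
      pdb <- refs$seqs$pdb_id[ri]
      msites <- refs$motifs[refs$motifs$pdb_id == pdb, ]
      chars <- strsplit(ref_seq, "")[[1]]
      protected <- c(1L, msites$ref_position)
      chars <- .mutate_protein(chars, round((1 - identity) * length(chars)), protected)
      chars[1L] <- "M"
      sub_str <- ""
      if (!is.null(substitutions)) {
        mine <- substitutions[substitutions$candidate == i, , drop = FALSE]
        if (nrow(mine)) {
          for (k in seq_len(nrow(mine))) chars[mine$ref_position[k]] <- mine$residue[k]
          sub_str <- paste(sprintf("%d%s", mine$ref_position, mine$residue), collapse = ";")
        }
      }
      kz <- kozak_flags[i]
      if (kz && !chars[2L] %in% c("A", "G", "V", "D", "E")) chars[2L] <- "A"
      aa <- paste(chars, collapse = "")
      orf_nt <- .reverse_translate(aa, codon2_G = kz)
      ctx <- if (kz) {
        repeat {
          c3 <- paste(c(sample(c("A", "G"), 1), sample(c("A", "C", "G", "T"), 2, TRUE)),
                      collapse = "")
          if (c3 != "ATG") break
        }
        c3
      } else {
        paste(c(sample(c("C", "T"), 1), sample(c("A", "C", "G", "T"), 2, TRUE)),
              collapse = "")
      }
      pad <- .random_nt(sample(0:2, 1), gc)  # varies the reading frame
      flank1 <- .random_nt(3 * sample(10:40, 1), gc)
      flank2 <- .random_nt(3 * sample(10:40, 1), gc)
      coding <- paste0(pad, flank1, "TAA", ctx, orf_nt, "TAA", flank2)
      cs_start <- nchar(pad) + nchar(flank1) + 3L + 3L
      aa_len <- nchar(aa)
      minus <- runif(1) < 0.5
      L <- nchar(coding)
      if (minus) {
        seqc <- .revcomp(coding)
        start <- L - (cs_start + 3L * aa_len); end <- L - cs_start
        strand <- "-"; frame <- -(((cs_start) %% 3L) + 1L)
      } else {
        seqc <- coding
        start <- cs_start; end <- cs_start + 3L * aa_len
        strand <- "+"; frame <- ((cs_start %% 3L) + 1L)
      }
      id <- sprintf("synth_vhpo_%02d", i)
      contigs[[length(contigs) + 1L]] <- data.frame(
        id = id, species = "synthetic", seq = seqc, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, kind = "vHPO", group = refs$seqs$group[ri], source_ref = pdb,
        identity = identity, substitutions = sub_str,
        kozak = ifelse(kz, "match", "no_match"), strand = strand,
        frame = frame, start = start, end = end, aa_seq = aa,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_background)) {
      id <- sprintf("synth_bg_%02d", i)
      if (runif(1) < 0.5) {
        # pure random background contig (usually yields no long ORF)
        seqc <- .random_nt(background_len, gc)
        contigs[[length(contigs) + 1L]] <- data.frame(
          id = id, species = "synthetic", seq = seqc, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, kind = "background", group = NA_integer_, source_ref = NA_character_,
          identity = NA_real_, substitutions = "", kozak = NA_character_,
          strand = NA_character_, frame = NA_integer_, start = NA_integer_,
          end = NA_integer_, aa_seq = NA_character_, stringsAsFactors = FALSE)
      } else {
        # background contig with a planted random (non-vHPO) ORF
        aa <- paste(c("M", sample(names(.AA_MASS), sample(110:180, 1), TRUE)),
                    collapse = "")
        orf_nt <- .reverse_translate(aa)
        flank1 <- .random_nt(3 * sample(10:40, 1), gc)
        flank2 <- .random_nt(3 * sample(10:40, 1), gc)
        seqc <- paste0(flank1, "TAA", .random_nt(3, gc), orf_nt, "TAA", flank2)
        contigs[[length(contigs) + 1L]] <- data.frame(
          id = id, species = "synthetic", seq = seqc, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, kind = "background", group = NA_integer_, source_ref = NA_character_,
          identity = NA_real_, substitutions = "", kozak = NA_character_,
          strand = "+", frame = NA_integer_, start = NA_integer_,
          end = NA_integer_, aa_seq = aa, stringsAsFactors = FALSE)
      }
    }
    list(contigs = do.call(rbind, c(contigs, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Synthetic linear-phase kinetic trace
#'
#' \eqn{A(t) = A_0 + slope \cdot t + N(0, \sigma^2)} on the standard
#' 0-10 min grid at 0.5-min steps (21 points).
#'
#' @param slope True slope in AU/min (default 0.02).
#' @param intercept Baseline absorbance A0 (default 0.1).
#' @param sigma Gaussian noise SD in AU (default 0.002; 0 for noiseless).
#' @param times Time grid in minutes.
#' @param seed Integer seed.
#' @inheritParams kinetic_trace
#' @return A \code{vhpo_trace}.
#' @export
make_kinetic_trace <- function(slope = 0.02, intercept = 0.1, sigma = 0.002,
                               times = seq(0, 10, by = 0.5), seed = 1,
                               sample_id = "synthetic", eps = 37.2,
                               pathlength = 1, volume = 200) {
  stopifnot(sigma >= 0)
  a <- with_seed(seed, intercept + slope * times + rnorm(length(times), 0, sigma))
  kinetic_trace(times, a, sample_id = sample_id, eps = eps,
                pathlength = pathlength, volume = volume)
}

#' Synthetic qPCR Cq dataset with planted fold changes
#'
#' Emulates a stress experiment: treatments x time points x thalli, one
#' reference gene and several target genes. Per biological sample the
#' reference Cq is drawn \eqn{N(ref\_cq\_mean, ref\_cq\_sd^2)}; the
#' target \eqn{\Delta Cq} is \code{baseline_dcq} \eqn{-} the planted
#' \eqn{\log_2} fold change of the stratum plus a thallus-level
#' biological effect \eqn{N(0, \sigma_{bio}^2)} shared across time
#' points (so paired t0/t1 samples share it); technical noise
#' \eqn{N(0, \sigma_{tech}^2)} is added independently to every replicate
#' measurement on the Cq scale.
#'
#' @param genes Target gene names.
#' @param treatments Treatment labels; the first is the control and its
#'   planted fold changes are fixed at 1.
#' @param time_points Time-point labels (first is t0).
#' @param n_thalli Biological replicates per treatment (default 3).
#' @param planted_log2fc Optional data.frame \code{gene},
#'   \code{treatment}, \code{time_point}, \code{log2fc}; omitted strata
#'   default to 0 (fold change 1).
#' @param sigma_bio Biological SD on the dCq scale (cycles, default 0.3).
#' @param sigma_tech Technical SD on the Cq scale (cycles, default 0.1).
#' @param n_tech Technical replicates per measurement (default 2).
#' @param reference_gene Reference gene name (default "EIF5B").
#' @param ref_cq_mean,ref_cq_sd Reference-gene Cq distribution (21, 1).
#' @param baseline_dcq Baseline dCq of every target gene (default 4).
#' @param seed Integer seed.
#' @return List with \code{cq} (long Cq table) and \code{truth}
#'   (planted fold change per gene x treatment x time point).
#' @export
make_qpcr_dataset <- function(genes = c("Sl1_07", "Sl1_29", "Sl1_31", "Sl1_41"),
                              treatments = c("control", "Cu", "H2O2", "elicitor"),
                              time_points = c("t0", "t1", "t2", "t3"),
                              n_thalli = 3, planted_log2fc = NULL,
                              sigma_bio = 0.3, sigma_tech = 0.1, n_tech = 2,
                              reference_gene = "EIF5B", ref_cq_mean = 21,
                              ref_cq_sd = 1, baseline_dcq = 4, seed = 1) {
  stopifnot(length(treatments) >= 1, length(time_points) >= 1, n_thalli >= 1)
  truth <- expand.grid(gene = genes, treatment = treatments,
                       time_point = time_points, stringsAsFactors = FALSE)
  truth$log2fc <- 0
  if (!is.null(planted_log2fc)) {
    for (k in seq_len(nrow(planted_log2fc))) {
      hit <- truth$gene == planted_log2fc$gene[k] &
        truth$treatment == planted_log2fc$treatment[k] &
        truth$time_point == planted_log2fc$time_point[k]
      truth$log2fc[hit] <- planted_log2fc$log2fc[k]
    }
  }
  truth$log2fc[truth$treatment == treatments[1]] <- 0
  truth$fc <- 2^truth$log2fc
  cq <- with_seed(seed, {
    rows <- list()
    for (tr in treatments) for (th in seq_len(n_thalli)) {
      thallus <- sprintf("%s_th%02d", tr, th)
      bio <- rnorm(length(genes), 0, sigma_bio)  # shared across time points
      names(bio) <- genes
      for (tp in time_points) {
        cq_ref <- rnorm(1, ref_cq_mean, ref_cq_sd)
        for (r in seq_len(n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            thallus_id = thallus, treatment = tr, time_point = tp,
            gene = reference_gene, replicate = r,
            cq = cq_ref + rnorm(1, 0, sigma_tech), stringsAsFactors = FALSE)
        }
        for (g in genes) {
          l2 <- truth$log2fc[truth$gene == g & truth$treatment == tr &
                               truth$time_point == tp]
          dcq <- baseline_dcq - l2 + bio[[g]]
          for (r in seq_len(n_tech)) {
            rows[[length(rows) + 1L]] <- data.frame(
              thallus_id = thallus, treatment = tr, time_point = tp,
              gene = g, replicate = r,
              cq = cq_ref + dcq + rnorm(1, 0, sigma_tech), stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  list(cq = cq, truth = truth)
}

#' Synthetic Fv/Fm dataset with planted control-corrected damage
#'
#' Baseline Fv/Fm per thallus is drawn \eqn{N(baseline\_mean,
#' baseline\_sd^2)} (defaults 0.67, 0.03 — the unstressed condition).
#' At each later time point every thallus realizes a percentual
#' reduction drawn \eqn{N(planted, \sigma^2)}, where \code{planted} is 0
#' for the control and for unlisted strata; the planted value is thereby
#' the expected CONTROL-CORRECTED damage. Parameters implying Fv/Fm
#' outside \eqn{[0, 1)} are refused.
#'
#' @param treatments Treatment labels (first = control, planted 0).
#' @param time_points Time points (first = t0).
#' @param n_thalli Thalli per treatment (default 6).
#' @param planted_damage Optional data.frame \code{treatment},
#'   \code{time_point}, \code{damage_pct} (e.g. elicitor t1 = 10.6,
#'   recovered to 0 at t2/t3).
#' @param sigma_damage SD of the realized reduction in percentage
#'   points (default 2.4).
#' @param baseline_mean,baseline_sd Fv/Fm baseline (0.67, 0.03).
#' @param seed Integer seed.
#' @return List with \code{fvfm} (long table) and \code{truth}.
#' @export
make_fvfm_dataset <- function(treatments = c("control", "Cu", "H2O2", "elicitor"),
                              time_points = c("t0", "t1", "t2", "t3"),
                              n_thalli = 6, planted_damage = NULL,
                              sigma_damage = 2.4, baseline_mean = 0.67,
                              baseline_sd = 0.03, seed = 1) {
  if (baseline_mean <= 0 || baseline_mean >= 1) {
    stop("baseline Fv/Fm mean must lie in (0, 1)", call. = FALSE)
  }
  truth <- expand.grid(treatment = treatments, time_point = time_points[-1],
                       stringsAsFactors = FALSE)
  truth$damage_pct <- 0
  if (!is.null(planted_damage)) {
    for (k in seq_len(nrow(planted_damage))) {
      hit <- truth$treatment == planted_damage$treatment[k] &
        truth$time_point == planted_damage$time_point[k]
      truth$damage_pct[hit] <- planted_damage$damage_pct[k]
    }
  }
  truth$damage_pct[truth$treatment == treatments[1]] <- 0
  if (any(truth$damage_pct + 4 * sigma_damage >= 100) ||
      baseline_mean + 4 * baseline_sd >= 1) {
    stop("parameters imply Fv/Fm outside [0, 1)", call. = FALSE)
  }
  fvfm <- with_seed(seed, {
    rows <- list()
    for (tr in treatments) for (th in seq_len(n_thalli)) {
      thallus <- sprintf("%s_th%02d", tr, th)
      base <- min(max(rnorm(1, baseline_mean, baseline_sd), 0.01), 0.95)
      rows[[length(rows) + 1L]] <- data.frame(
        thallus_id = thallus, treatment = tr, time_point = time_points[1],
        fvfm = base, stringsAsFactors = FALSE)
      for (tp in time_points[-1]) {
        d <- truth$damage_pct[truth$treatment == tr & truth$time_point == tp]
        red <- rnorm(1, d, sigma_damage)
        val <- base * (1 - red / 100)
        rows[[length(rows) + 1L]] <- data.frame(
          thallus_id = thallus, treatment = tr, time_point = tp,
          fvfm = min(max(val, 0), 0.9999), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  list(fvfm = fvfm, truth = truth)
}

#' Write a synthetic transcriptome to FASTA (+ truth TSV)
#'
#' @param synth Result of [make_transcriptome()].
#' @param fasta,truth_tsv Output paths.
#' @return Invisibly, the FASTA path.
#' @export
write_transcriptome <- function(synth, fasta, truth_tsv = NULL) {
  headers <- sprintf("%s [species=%s]", synth$contigs$id, synth$contigs$species)
  ss <- Biostrings::DNAStringSet(setNames(synth$contigs$seq, headers))
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(truth_tsv)) {
    write.table(synth$truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}
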