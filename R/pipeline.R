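# End-to-end orchestration: discovery (contigs -> ORFs -> curation ->
# features) and expression (Cq + Fv/Fm -> fold changes, tests, damage).
# Each run writes a self-contained directory of TSVs whose headers carry
# the package version and a hash of the validated configuration, plus a
# serialized copy of the configuration itself.

.DISCOVERY_KEYS <- c("fasta", "out_dir", "refs_fasta", "motifs_tsv", "min_aa",
                     "require_met", "dedupe_scope", "min_score",
                     "min_conserved_frac", "annotations_tsv", "seed")
.EXPRESSION_KEYS <- c("cq_tsv", "fvfm_tsv", "out_dir", "reference_gene",
                      "candidate_reference_genes", "control_group", "t0_label",
                      "schemes", "dunnett_draws", "seed")

.validate_config <- function(config, allowed, required) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("missing configuration key(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the discovery pipeline
#'
#' Executes ORF discovery, deduplication, homology curation and feature
#' assembly on a contig FASTA, writing \code{orfs.tsv},
#' \code{curation.tsv}, \code{features.tsv}, \code{orfs.faa},
#' \code{alignments.txt} and \code{config.yaml} into the run directory.
#' Stage counts are logged to stderr. Configuration is validated before
#' any file is touched; unknown keys are an error.
#'
#' @param config Named list (or path to a YAML file) with keys:
#'   \code{fasta} (input contigs), \code{out_dir}; optional
#'   \code{refs_fasta} + \code{motifs_tsv} (default: packaged synthetic
#'   references), \code{min_aa} (100), \code{require_met} (TRUE),
#'   \code{dedupe_scope} ("per_species"), \code{min_score} (73),
#'   \code{min_conserved_frac} (0.6), \code{annotations_tsv}.
#' @return Invisibly, a list with the ORF, curation and feature tables.
#' @export
run_discovery <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_config(config, .DISCOVERY_KEYS, c("fasta", "out_dir"))
  cfg <- utils::modifyList(list(min_aa = 100L, require_met = TRUE,
                                dedupe_scope = "per_species", min_score = 73,
                                min_conserved_frac = 0.6), config)
  if (!file.exists(cfg$fasta)) stop("input FASTA not found: ", cfg$fasta, call. = FALSE)
  refs <- if (!is.null(cfg$refs_fasta)) {
    load_reference_set(cfg$refs_fasta, cfg$motifs_tsv)
  } else default_reference_set()
  hash <- .config_hash(cfg[setdiff(names(cfg), "out_dir")])  # parameters, not the destination
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  contigs <- read_contigs(cfg$fasta)
  .log_stage("discovery", sprintf("%d contigs read", nrow(contigs)))
  orfs <- discover_orfs(contigs, min_aa = cfg$min_aa, require_met = cfg$require_met)
  .log_stage("discovery", sprintf("%d ORFs >= %d aa", nrow(orfs), cfg$min_aa))
  orfs <- dedupe_candidates(orfs, scope = cfg$dedupe_scope)
  .log_stage("discovery", sprintf("%d ORFs after deduplication", nrow(orfs)))
  if (nrow(orfs) == 0) warning("no ORFs discovered; writing empty tables")

  curation <- curate_candidates(orfs, refs = refs, min_score = cfg$min_score,
                                min_conserved_frac = cfg$min_conserved_frac)
  .log_stage("curation", sprintf(
    "%d putative vHPO, %d atypical, %d predicted inactive, %d rejected",
    sum(curation$classification == "putative_vHPO"),
    sum(curation$classification == "putative_vHPO_atypical"),
    sum(curation$classification == "predicted_inactive"),
    sum(curation$classification == "rejected")))
  ann <- if (!is.null(cfg$annotations_tsv)) read_tsv_table(cfg$annotations_tsv) else NULL
  features <- build_feature_table(curation, orfs, annotations = ann)

  .write_run_table(orfs[, setdiff(names(orfs), "aa_seq")],
                   file.path(cfg$out_dir, "orfs.tsv"), hash)
  .write_run_table(curation, file.path(cfg$out_dir, "curation.tsv"), hash)
  .write_run_table(features, file.path(cfg$out_dir, "features.tsv"), hash)
  if (nrow(orfs)) write_orf_fasta(orfs, file.path(cfg$out_dir, "orfs.faa"))
  reports <- attr(curation, "reports")
  alns <- Filter(Negate(is.null), lapply(reports, `[[`, "alignment"))
  labels <- unlist(lapply(reports, function(r)
    if (!is.null(r$alignment)) sprintf("%s vs %s", r$candidate_id, r$best_reference)))
  if (length(alns)) {
    write_alignment_pairs(alns, file.path(cfg$out_dir, "alignments.txt"), labels)
  }
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  invisible(list(orfs = orfs, curation = curation, features = features,
                 config = cfg, config_hash = hash))
}

#' Run the expression-analysis pipeline
#'
#' Reference-gene evaluation (when >= 2 candidates are given), dCq
#' computation, both fold-change schemes, ANOVA + Dunnett per treatment
#' group and gene (to-control scheme: time points vs t0; to-t0 scheme:
#' treatments vs control), and control-corrected Fv/Fm damage. Writes
#' \code{dcq.tsv}, \code{fc_to_control.tsv}, \code{fc_to_t0.tsv},
#' \code{refgenes.tsv}, \code{tests_*.tsv}, \code{damage.tsv} and
#' \code{config.yaml} into the run directory.
#'
#' @param config Named list or YAML path with keys: \code{cq_tsv},
#'   \code{out_dir}, \code{reference_gene}; optional \code{fvfm_tsv},
#'   \code{candidate_reference_genes}, \code{control_group}
#'   ("control"), \code{t0_label} ("t0"), \code{schemes}
#'   (default both), \code{dunnett_draws} (1e5), \code{seed} (1).
#' @return Invisibly, a list with all computed tables.
#' @export
run_expression <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_config(config, .EXPRESSION_KEYS, c("cq_tsv", "out_dir", "reference_gene"))
  cfg <- utils::modifyList(list(control_group = "control", t0_label = "t0",
                                schemes = c("to_control", "to_t0"),
                                dunnett_draws = 1e5, seed = 1), config)
  if (!file.exists(cfg$cq_tsv)) stop("Cq table not found: ", cfg$cq_tsv, call. = FALSE)
  hash <- .config_hash(cfg[setdiff(names(cfg), "out_dir")])  # parameters, not the destination
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cq <- read_cq_tsv(cfg$cq_tsv)
  if (!cfg$reference_gene %in% cq$gene) {
    stop(sprintf("reference gene '%s' absent from Cq table", cfg$reference_gene),
         call. = FALSE)
  }
  out <- list(config = cfg, config_hash = hash)
  if (!is.null(cfg$candidate_reference_genes) &&
      length(cfg$candidate_reference_genes) >= 2) {
    rg <- evaluate_reference_genes(cq, cfg$candidate_reference_genes)
    out$refgenes <- rg
    .write_run_table(rg$per_gene, file.path(cfg$out_dir, "refgenes.tsv"), hash)
    .log_stage("expression", sprintf("reference gene selected: %s", rg$selected_gene))
  }
  dcq <- compute_dcq(cq, cfg$reference_gene)
  out$dcq <- dcq
  .write_run_table(as.data.frame(dcq), file.path(cfg$out_dir, "dcq.tsv"), hash)

  run_tests <- function(fc, scheme) {
    res <- list()
    for (g in unique(fc$gene)) {
      sub <- fc[fc$gene == g, , drop = FALSE]
      if (scheme == "to_control") {
        # within each treatment, time points vs t0 on the fc scale
        for (tr in setdiff(unique(sub$treatment), character(0))) {
          grp <- split(sub$fc[sub$treatment == tr], sub$time_point[sub$treatment == tr])
          grp <- grp[lengths(grp) >= 2]
          if (length(grp) >= 2 && cfg$t0_label %in% names(grp) &&
              !all(vapply(grp, var, numeric(1)) == 0)) {
            tst <- anova_dunnett(grp, cfg$t0_label, n_draws = cfg$dunnett_draws,
                                 seed = cfg$seed)
            res[[length(res) + 1L]] <- cbind(gene = g, stratum = tr,
                                             tst$comparisons)
          }
        }
      } else {
        # at each time point, treatments vs control on the fc scale
        for (tp in unique(sub$time_point)) {
          grp <- split(sub$fc[sub$time_point == tp], sub$treatment[sub$time_point == tp])
          grp <- grp[lengths(grp) >= 2]
          if (length(grp) >= 2 && cfg$control_group %in% names(grp) &&
              !all(vapply(grp, var, numeric(1)) == 0)) {
            tst <- anova_dunnett(grp, cfg$control_group, n_draws = cfg$dunnett_draws,
                                 seed = cfg$seed)
            res[[length(res) + 1L]] <- cbind(gene = g, stratum = tp,
                                             tst$comparisons)
          }
        }
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }

  if ("to_control" %in% cfg$schemes) {
    fc_ctrl <- fold_change_to_control(dcq, cfg$control_group)
    out$fc_to_control <- fc_ctrl
    .write_run_table(fc_ctrl, file.path(cfg$out_dir, "fc_to_control.tsv"), hash)
    tests <- run_tests(fc_ctrl, "to_control")
    out$tests_to_control <- tests
    if (!is.null(tests)) {
      .write_run_table(tests, file.path(cfg$out_dir, "tests_to_control.tsv"), hash)
    }
    .log_stage("expression", sprintf("%d fold changes (to control)", nrow(fc_ctrl)))
  }
  if ("to_t0" %in% cfg$schemes) {
    fc_t0 <- fold_change_to_t0(dcq, cfg$t0_label)
    out$fc_to_t0 <- fc_t0
    .write_run_table(fc_t0, file.path(cfg$out_dir, "fc_to_t0.tsv"), hash)
    tests <- run_tests(fc_t0, "to_t0")
    out$tests_to_t0 <- tests
    if (!is.null(tests)) {
      .write_run_table(tests, file.path(cfg$out_dir, "tests_to_t0.tsv"), hash)
    }
    .log_stage("expression", sprintf("%d fold changes (to t0)", nrow(fc_t0)))
  }
  if (!is.null(cfg$fvfm_tsv)) {
    fv <- read_fvfm_tsv(cfg$fvfm_tsv)
    dmg <- psii_damage(fv, control_label = cfg$control_group, t0_label = cfg$t0_label)
    out$damage <- dmg
    .write_run_table(dmg, file.path(cfg$out_dir, "damage.tsv"), hash)
    .log_stage("expression", sprintf("%d Fv/Fm damage records", nrow(dmg)))
  }
  yaml::write_yaml(cfg[setdiff(names(cfg), "schemes")],
                   file.path(cfg$out_dir, "config.yaml"))
  invisible(out)
}
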