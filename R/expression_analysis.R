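# RT-qPCR relative expression (2^-ddCq) and Fv/Fm stress analytics.
#
# Cq-scale tables are tagged with class "vhpo_cq_scale"; the statistical
# tests refuse such inputs, enforcing that only 2^-Cq / 2^-dCq / 2^-ddCq
# transformed values are ever evaluated statistically (the exponential
# nature of Cq data makes raw-cycle statistics meaningless).

.tag_cq_scale <- function(df) {
  class(df) <- unique(c("vhpo_cq_scale", class(df)))
  df
}

.assert_transformed <- function(x, what = "values") {
  if (inherits(x, "vhpo_cq_scale")) {
    stop(sprintf(
      "%s are on the Cq/dCq cycle scale; statistical tests accept only 2^- transformed values (fold changes)",
      what), call. = FALSE)
  }
  invisible(TRUE)
}

.check_cq_table <- function(cq) {
  needed <- c("thallus_id", "treatment", "time_point", "gene", "replicate", "cq")
  if (!all(needed %in% names(cq))) {
    stop("Cq table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(cq$cq)) || any(cq$cq <= 0)) stop("Cq values must be positive", call. = FALSE)
  key <- do.call(paste, c(cq[needed[1:5]], sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate (thallus, treatment, time_point, gene, replicate) rows", call. = FALSE)
  invisible(TRUE)
}

# arithmetic mean of technical replicates on the Cq scale
.collapse_tech <- function(cq) {
  agg <- aggregate(cq ~ thallus_id + treatment + time_point + gene, data = cq, FUN = mean)
  agg[order(agg$treatment, agg$time_point, agg$thallus_id, agg$gene), , drop = FALSE]
}

#' Reference-gene-normalized dCq values
#'
#' Technical replicates are averaged arithmetically on the Cq scale,
#' then \eqn{\Delta Cq = Cq_{target} - Cq_{reference}} is computed per
#' biological sample (thallus x treatment x time point) and target gene.
#'
#' @param cq Cq table: \code{thallus_id}, \code{treatment},
#'   \code{time_point}, \code{gene}, \code{replicate}, \code{cq}.
#' @param reference_gene Name of the reference gene (e.g. "EIF5B").
#' @return data.frame (tagged as Cq-scale) with the sample key and
#'   \code{dcq} per target gene.
#' @export
compute_dcq <- function(cq, reference_gene) {
  .check_cq_table(cq)
  if (!reference_gene %in% cq$gene) {
    stop(sprintf("reference gene '%s' absent from Cq table", reference_gene), call. = FALSE)
  }
  m <- .collapse_tech(cq)
  ref <- m[m$gene == reference_gene, c("thallus_id", "treatment", "time_point", "cq")]
  names(ref)[names(ref) == "cq"] <- "cq_ref"
  tgt <- m[m$gene != reference_gene, , drop = FALSE]
  out <- merge(tgt, ref, by = c("thallus_id", "treatment", "time_point"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$cq_ref)) {
    bad <- out[is.na(out$cq_ref), c("thallus_id", "treatment", "time_point")]
    stop("missing reference-gene Cq for sample(s): ",
         paste(unique(do.call(paste, c(bad, sep = "/"))), collapse = ", "), call. = FALSE)
  }
  out$dcq <- out$cq - out$cq_ref
  out <- out[order(out$treatment, out$time_point, out$thallus_id, out$gene),
             c("thallus_id", "treatment", "time_point", "gene", "dcq")]
  rownames(out) <- NULL
  .tag_cq_scale(out)
}

#' Fold changes relative to the control group ("to control" scheme)
#'
#' \eqn{\Delta\Delta Cq} = sample \eqn{\Delta Cq} minus the arithmetic
#' mean \eqn{\Delta Cq} of the control group at the same time point for
#' the same gene; fold change \eqn{= 2^{-\Delta\Delta Cq}}. A fold
#' change of 1 indicates no change relative to the control.
#'
#' @param dcq dCq table from [compute_dcq()].
#' @param control_group Treatment label of the control (default
#'   \code{"control"}).
#' @return data.frame with the sample key, \code{ddcq} and \code{fc};
#'   \code{scheme = "to_control"}.
#' @export
fold_change_to_control <- function(dcq, control_group = "control") {
  stopifnot(all(c("treatment", "time_point", "gene", "dcq") %in% names(dcq)))
  ctrl <- dcq[dcq$treatment == control_group, , drop = FALSE]
  if (!nrow(ctrl)) stop("no control records", call. = FALSE)
  cm <- aggregate(dcq ~ time_point + gene, data = ctrl, FUN = mean)
  names(cm)[names(cm) == "dcq"] <- "dcq_ctrl"
  out <- merge(as.data.frame(dcq), cm, by = c("time_point", "gene"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$dcq_ctrl)) {
    bad <- unique(out[is.na(out$dcq_ctrl), c("time_point", "gene")])
    stop("no control records for stratum(s): ",
         paste(do.call(paste, c(bad, sep = "/")), collapse = ", "), call. = FALSE)
  }
  out$ddcq <- out$dcq - out$dcq_ctrl
  out$fc <- 2^(-out$ddcq)
  out$scheme <- "to_control"
  out <- out[order(out$treatment, out$time_point, out$thallus_id, out$gene),
             c("thallus_id", "treatment", "time_point", "gene", "scheme", "ddcq", "fc")]
  rownames(out) <- NULL
  out
}

#' Fold changes relative to the paired t0 sample ("to t0" scheme)
#'
#' For each thallus, treatment and gene, \eqn{\Delta\Delta Cq} at a later
#' time point is that sample's \eqn{\Delta Cq} minus the \eqn{\Delta Cq}
#' of the SAME thallus at \code{t0}; fold change \eqn{= 2^{-\Delta\Delta Cq}}.
#' This pairing removes inter-individual baseline variability.
#'
#' @param dcq dCq table from [compute_dcq()].
#' @param t0_label Label of the baseline time point (default \code{"t0"}).
#' @return data.frame as in [fold_change_to_control()], with
#'   \code{scheme = "to_t0"} (t0 rows themselves are omitted).
#' @export
fold_change_to_t0 <- function(dcq, t0_label = "t0") {
  stopifnot(all(c("thallus_id", "treatment", "time_point", "gene", "dcq") %in% names(dcq)))
  base <- dcq[dcq$time_point == t0_label, c("thallus_id", "treatment", "gene", "dcq")]
  names(base)[names(base) == "dcq"] <- "dcq_t0"
  later <- dcq[dcq$time_point != t0_label, , drop = FALSE]
  out <- merge(as.data.frame(later), base, by = c("thallus_id", "treatment", "gene"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$dcq_t0)) {
    bad <- unique(out$thallus_id[is.na(out$dcq_t0)])
    stop("missing paired t0 sample for thallus(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out$ddcq <- out$dcq - out$dcq_t0
  out$fc <- 2^(-out$ddcq)
  out$scheme <- "to_t0"
  out <- out[order(out$treatment, out$time_point, out$thallus_id, out$gene),
             c("thallus_id", "treatment", "time_point", "gene", "scheme", "ddcq", "fc")]
  rownames(out) <- NULL
  out
}

#' Summarize fold changes per stratum
#'
#' Reports both the arithmetic mean (the diamond usually plotted) and
#' the geometric mean (the statistically natural summary of ratios).
#'
#' @param fc Fold-change table.
#' @return data.frame per (treatment, time_point, gene): \code{n},
#'   \code{fc_mean}, \code{fc_geomean}.
#' @export
summarize_fold_changes <- function(fc) {
  stopifnot(all(c("treatment", "time_point", "gene", "fc") %in% names(fc)))
  agg <- aggregate(fc ~ treatment + time_point + gene, data = fc,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       geo = exp(mean(log(v)))))
  out <- data.frame(agg[c("treatment", "time_point", "gene")],
                    n = agg$fc[, "n"], fc_mean = agg$fc[, "mean"],
                    fc_geomean = agg$fc[, "geo"])
  out[order(out$gene, out$treatment, out$time_point), , drop = FALSE]
}

#' Evaluate candidate reference genes
#'
#' Computes each candidate gene's Cq range width (max - min over all
#' samples; lower width = more stable expression) and the pairwise
#' Pearson correlation of Cq values over shared samples. The gene with
#' the smallest range width is selected (ties: first in
#' \code{candidate_genes}).
#'
#' @param cq Cq table (see [compute_dcq()]).
#' @param candidate_genes Character vector of >= 2 gene names.
#' @return Object of class \code{vhpo_refgenes}: \code{per_gene}
#'   (cq_min, cq_max, range_width), \code{pairs} (gene pair, Pearson r,
#'   p-value, n shared samples), \code{selected_gene}.
#' @export
evaluate_reference_genes <- function(cq, candidate_genes) {
  .check_cq_table(cq)
  if (length(candidate_genes) < 2L) stop("need at least 2 candidate genes", call. = FALSE)
  m <- .collapse_tech(cq[cq$gene %in% candidate_genes, , drop = FALSE])
  per_gene <- do.call(rbind, lapply(candidate_genes, function(g) {
    v <- m$cq[m$gene == g]
    if (!length(v)) stop(sprintf("gene '%s' absent from Cq table", g), call. = FALSE)
    data.frame(gene = g, cq_min = min(v), cq_max = max(v),
               range_width = max(v) - min(v), stringsAsFactors = FALSE)
  }))
  combos <- combn(candidate_genes, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    a <- m[m$gene == g1, c("thallus_id", "treatment", "time_point", "cq")]
    b <- m[m$gene == g2, c("thallus_id", "treatment", "time_point", "cq")]
    j <- merge(a, b, by = c("thallus_id", "treatment", "time_point"))
    if (nrow(j) < 3L) stop("fewer than 3 shared samples for correlation", call. = FALSE)
    ct <- cor.test(j$cq.x, j$cq.y, method = "pearson")
    data.frame(gene_a = g1, gene_b = g2, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(j), stringsAsFactors = FALSE)
  }))
  sel <- per_gene$gene[which.min(per_gene$range_width)]
  structure(list(per_gene = per_gene, pairs = pairs, selected_gene = sel),
            class = "vhpo_refgenes")
}

#' @export
print.vhpo_refgenes <- function(x, ...) {
  cat("Reference-gene evaluation\n")
  for (i in seq_len(nrow(x$per_gene))) {
    g <- x$per_gene[i, ]
    cat(sprintf("  %s: Cq range %.1f-%.1f (width %.1f)%s\n", g$gene, g$cq_min,
                g$cq_max, g$range_width,
                if (g$gene == x$selected_gene) "  <- selected" else ""))
  }
  for (i in seq_len(nrow(x$pairs))) {
    p <- x$pairs[i, ]
    cat(sprintf("  %s vs %s: Pearson r = %.2f (P = %.2g, n = %d)\n",
                p$gene_a, p$gene_b, p$pearson_r, p$p_value, p$n))
  }
  invisible(x)
}

# ---- statistical tests (transformed-scale only) ------------------------

# max-|t| Monte-Carlo reference sample for a many-to-one (Dunnett) design;
# sizes[1] is the control group. Fully vectorized over draws.
.dunnett_maxt_sample <- function(sizes, n_draws = 1e5, seed = NULL) {
  k <- length(sizes)
  N <- sum(sizes)
  grp <- rep(seq_len(k), sizes)
  with_seed(seed, {
    X <- matrix(rnorm(N * n_draws), nrow = N)
    gm <- rowsum(X, grp) / sizes                   # k x B group means
    ss <- rowsum(X^2, grp) - sizes * gm^2          # within-group SS
    s2 <- colSums(ss) / (N - k)                    # pooled variance per draw
    tt <- abs(gm[-1, , drop = FALSE] - matrix(gm[1, ], k - 1, n_draws, byrow = TRUE)) /
      sqrt(outer(1 / sizes[-1] + 1 / sizes[1], s2))
    apply(tt, 2, max)
  })
}

# observed many-to-one |t| statistics; first element of `groups` is control
.dunnett_obs_t <- function(groups) {
  k <- length(groups)
  sizes <- lengths(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  ss <- vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))
  s2 <- sum(ss) / (N - k)
  list(t = (means[-1] - means[1]) / sqrt(s2 * (1 / sizes[-1] + 1 / sizes[1])),
       s2 = s2, df = N - k)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Classic one-way ANOVA (F test) followed by Dunnett's many-to-one
#' procedure comparing every non-control group against the control.
#' Adjusted p-values are computed against a seeded Monte-Carlo reference
#' distribution of the max-|t| statistic under the null for the same
#' group sizes (default 100 000 draws), which reproduces the Dunnett
#' multivariate-t adjustment without quadrature; decisions are
#' bit-identical under a fixed seed. Inputs must already be on the
#' transformed (2^-ddCq fold-change or Fv/Fm) scale: Cq-scale tables
#' are refused.
#'
#' @param values Named list of numeric vectors (one per group), or a
#'   data.frame with \code{value} and \code{group} columns.
#' @param control_label Name of the control (reference) group.
#' @param n_draws Monte-Carlo draws (>= 1e5 recommended).
#' @param seed Integer seed for the reference distribution.
#' @param alpha Family-wise level for the decisions (default 0.05).
#' @return Object of class \code{vhpo_test}: method, ANOVA F and p,
#'   per-comparison t, raw p (two-sided, pooled-variance df), adjusted
#'   p, decision.
#' @export
anova_dunnett <- function(values, control_label, n_draws = 1e5, seed = 1,
                          alpha = 0.05) {
  .assert_transformed(values, "group values")
  if (is.data.frame(values)) {
    stopifnot(all(c("value", "group") %in% names(values)))
    values <- split(values$value, values$group)
  }
  if (!control_label %in% names(values)) {
    stop(sprintf("control group '%s' not among groups", control_label), call. = FALSE)
  }
  values <- c(values[control_label], values[setdiff(names(values), control_label)])
  if (length(values) < 2L || any(lengths(values) < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  if (all(vapply(values, var, numeric(1)) == 0)) {
    stop("degenerate data: zero within-group variance in every group", call. = FALSE)
  }
  df_long <- data.frame(value = unlist(values),
                        group = factor(rep(names(values), lengths(values)),
                                       levels = names(values)))
  fit <- aov(value ~ group, data = df_long)
  atab <- anova(fit)
  obs <- .dunnett_obs_t(values)
  ref <- .dunnett_maxt_sample(lengths(values), n_draws = n_draws, seed = seed)
  p_adj <- vapply(abs(obs$t), function(tt) mean(ref >= tt), numeric(1))
  p_raw <- 2 * pt(abs(obs$t), df = obs$df, lower.tail = FALSE)
  p_adj <- pmax(p_adj, p_raw)  # adjustment is never anti-conservative
  comp <- data.frame(comparison = paste(names(values)[-1], "-", control_label),
                     estimate = vapply(values[-1], mean, numeric(1)) - mean(values[[1]]),
                     t = obs$t, p_raw = p_raw, p_adjusted = p_adj,
                     significant = p_adj < alpha, stringsAsFactors = FALSE)
  rownames(comp) <- NULL
  structure(list(method = "one-way ANOVA + Dunnett (Monte-Carlo max-|t|)",
                 anova_F = atab[1, "F value"], anova_p = atab[1, "Pr(>F)"],
                 df = obs$df, comparisons = comp, alpha = alpha,
                 n_draws = n_draws, seed = seed), class = "vhpo_test")
}

#' One-sample t tests with Bonferroni-corrected level
#'
#' Runs a one-sample t test against \code{mu} for each value set and
#' compares raw p-values with the Bonferroni-adjusted level
#' \code{family_alpha / m} (reported at 4 decimals; e.g. 0.05/9 ->
#' 0.0056). Zero-variance sets yield an undefined t and a non-decision
#' with a warning.
#'
#' @param samples Named list of numeric vectors (transformed scale, e.g.
#'   control-corrected percentages or fold changes).
#' @param mu Null value (default 0).
#' @param family_alpha Family-wise level (default 0.05).
#' @param m Number of tests in the family (default \code{length(samples)}).
#' @return Object of class \code{vhpo_test} with per-set t, p and
#'   decisions vs \code{alpha_adjusted}.
#' @export
one_sample_t_bonferroni <- function(samples, mu = 0, family_alpha = 0.05,
                                    m = length(samples)) {
  .assert_transformed(samples, "sample values")
  if (!is.list(samples)) samples <- list(samples)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (any(lengths(samples) < 2L)) stop("each set needs n >= 2", call. = FALSE)
  alpha_adj <- round(family_alpha / m, 4)
  rows <- lapply(seq_along(samples), function(i) {
    v <- samples[[i]]
    nm <- if (!is.null(names(samples))) names(samples)[i] else sprintf("set%d", i)
    if (var(v) == 0) {
      warning(sprintf("zero variance in '%s': t undefined, no decision", nm))
      return(data.frame(set = nm, n = length(v), mean = mean(v), t = NA_real_,
                        p_raw = NA_real_, significant = NA, stringsAsFactors = FALSE))
    }
    tt <- t.test(v, mu = mu)
    data.frame(set = nm, n = length(v), mean = mean(v),
               t = unname(tt$statistic), p_raw = tt$p.value,
               significant = tt$p.value < alpha_adj, stringsAsFactors = FALSE)
  })
  structure(list(method = "one-sample t with Bonferroni-corrected level",
                 mu = mu, family_alpha = family_alpha, m = m,
                 alpha_adjusted = alpha_adj,
                 comparisons = do.call(rbind, rows)), class = "vhpo_test")
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The U statistic is
#' computed from ranks; the p-value is exact (null Wilcoxon
#' distribution) when there are no ties and \eqn{n_1 n_2 \le 400}, and a
#' normal approximation with tie and continuity correction otherwise.
#' Used for variability analyses on dCq values (rank-based, so the
#' cycle scale is admissible here).
#'
#' @param a,b Numeric samples (n >= 1 each).
#' @return Object of class \code{vhpo_test} with \code{U} (for sample
#'   \code{a}), \code{p_value} and the method actually used.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n1 * n2 <= 400) {
    # exact two-sided p from the null distribution of U
    lower <- pwilcox(U, n1, n2)
    upper <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
                                ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  structure(list(method = paste("Mann-Whitney U,", method), U = U,
                 n1 = n1, n2 = n2, p_value = p), class = "vhpo_test")
}

#' @export
print.vhpo_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$anova_F)) {
    cat(sprintf("  ANOVA: F = %.3f, p = %.4g\n", x$anova_F, x$anova_p))
  }
  if (!is.null(x$alpha_adjusted)) {
    cat(sprintf("  alpha_adjusted = %.4f (family alpha %.2f, m = %d)\n",
                x$alpha_adjusted, x$family_alpha, x$m))
  }
  if (!is.null(x$U)) cat(sprintf("  U = %g, p = %.4g\n", x$U, x$p_value))
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Distribution diagnostics (warnings only)
#'
#' Shapiro-Wilk normality per group and a pairwise variance-ratio F test;
#' reported for the record and emitted as warnings on failure, never
#' gating any analysis.
#'
#' @param values Named list of numeric vectors.
#' @param alpha Level for the warnings (default 0.05).
#' @return data.frame of per-group Shapiro p and the min pairwise F-test
#'   p, invisibly.
#' @export
check_distribution_assumptions <- function(values, alpha = 0.05) {
  sw <- vapply(values, function(v)
    if (length(v) >= 3 && var(v) > 0) shapiro.test(v)$p.value else NA_real_, numeric(1))
  fp <- NA_real_
  if (length(values) >= 2) {
    combos <- combn(length(values), 2)
    fp <- min(vapply(seq_len(ncol(combos)), function(k) {
      v1 <- values[[combos[1, k]]]; v2 <- values[[combos[2, k]]]
      if (length(v1) >= 2 && length(v2) >= 2 && var(v1) > 0 && var(v2) > 0)
        var.test(v1, v2)$p.value else NA_real_
    }, numeric(1)), na.rm = TRUE)
  }
  if (any(sw < alpha, na.rm = TRUE)) warning("Shapiro-Wilk: non-normality in at least one group")
  if (isTRUE(fp < alpha)) warning("F test: variance heterogeneity between at least one group pair")
  invisible(data.frame(group = names(values), shapiro_p = sw,
                       min_var_test_p = fp, row.names = NULL))
}

# ---- Fv/Fm -------------------------------------------------------------

#' Control-corrected photosystem-II damage from Fv/Fm trajectories
#'
#' For each thallus, the percentual reduction of Fv/Fm from its own t0,
#' \eqn{100 (FvFm_{t0} - FvFm_t)/FvFm_{t0}}, is computed per later time
#' point and corrected by subtracting the mean reduction of the control
#' group at the same time point (difference-in-differences; a ratio
#' alternative is available via \code{method = "ratio"}, which divides
#' by the control mean retention instead).
#'
#' @param fvfm data.frame: \code{thallus_id}, \code{treatment},
#'   \code{time_point}, \code{fvfm} (one row per thallus and time
#'   point; every thallus needs a t0 row with \code{fvfm > 0}).
#' @param control_label Control treatment label (default "control").
#' @param t0_label Baseline time-point label (default "t0").
#' @param method \code{"difference"} (default) or \code{"ratio"}.
#' @return data.frame: thallus_id, treatment, time_point,
#'   \code{reduction_pct}, \code{corrected_reduction_pct}.
#' @export
psii_damage <- function(fvfm, control_label = "control", t0_label = "t0",
                        method = c("difference", "ratio")) {
  method <- match.arg(method)
  stopifnot(all(c("thallus_id", "treatment", "time_point", "fvfm") %in% names(fvfm)))
  if (any(fvfm$fvfm < 0 | fvfm$fvfm >= 1)) {
    stop("Fv/Fm values must lie in [0, 1)", call. = FALSE)
  }
  base <- fvfm[fvfm$time_point == t0_label, c("thallus_id", "treatment", "fvfm")]
  names(base)[3] <- "fvfm_t0"
  if (any(base$fvfm_t0 == 0)) stop("Fv/Fm at t0 is zero for some thallus", call. = FALSE)
  later <- fvfm[fvfm$time_point != t0_label, , drop = FALSE]
  d <- merge(later, base, by = c("thallus_id", "treatment"), sort = FALSE)
  if (nrow(d) < nrow(later)) {
    miss <- setdiff(unique(later$thallus_id), unique(base$thallus_id))
    stop("missing t0 record for thallus(es): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d$reduction_pct <- 100 * (d$fvfm_t0 - d$fvfm) / d$fvfm_t0
  ctrl <- d[d$treatment == control_label, , drop = FALSE]
  cm <- aggregate(reduction_pct ~ time_point, data = ctrl, FUN = mean)
  names(cm)[2] <- "ctrl_reduction"
  d <- merge(d, cm, by = "time_point", all.x = TRUE, sort = FALSE)
  if (anyNA(d$ctrl_reduction)) {
    stop("no control records at time point(s): ",
         paste(unique(d$time_point[is.na(d$ctrl_reduction)]), collapse = ", "), call. = FALSE)
  }
  d$corrected_reduction_pct <- if (method == "difference") {
    d$reduction_pct - d$ctrl_reduction
  } else {
    100 * (1 - (1 - d$reduction_pct / 100) / (1 - d$ctrl_reduction / 100))
  }
  d <- d[order(d$treatment, d$time_point, d$thallus_id),
         c("thallus_id", "treatment", "time_point", "reduction_pct",
           "corrected_reduction_pct")]
  rownames(d) <- NULL
  d
}

#' Read a Cq table TSV
#' @param path TSV with columns thallus_id, treatment, time_point, gene,
#'   replicate, cq (an optional sample_id column is carried along).
#' @return Validated data.frame.
#' @export
read_cq_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .check_cq_table(d)
  d
}

#' Read an Fv/Fm table TSV
#' @param path TSV with columns thallus_id, treatment, time_point, fvfm
#'   (optionally f0).
#' @return data.frame.
#' @export
read_fvfm_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("thallus_id", "treatment", "time_point", "fvfm") %in% names(d)))
  d
}
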