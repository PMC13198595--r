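make_cq_row <- function(thallus, tr, tp, gene, rep_, cq) {
  data.frame(thallus_id = thallus, treatment = tr, time_point = tp,
             gene = gene, replicate = rep_, cq = cq, stringsAsFactors = FALSE)
}

test_that("dCq subtracts the same-sample reference after averaging duplicates", {
  cq <- rbind(make_cq_row("th1", "control", "t0", "EIF5B", 1, 21.0),
              make_cq_row("th1", "control", "t0", "EIF5B", 2, 21.4),
              make_cq_row("th1", "control", "t0", "geneA", 1, 25.0),
              make_cq_row("th1", "control", "t0", "geneA", 2, 25.4),
              make_cq_row("th2", "control", "t0", "EIF5B", 1, 20.0),
              make_cq_row("th2", "control", "t0", "geneA", 1, 20.0))
  d <- compute_dcq(cq, "EIF5B")
  expect_equal(d$dcq[d$thallus_id == "th1"], 4)   # duplicates averaged on Cq
  expect_equal(d$dcq[d$thallus_id == "th2"], 0)
  expect_s3_class(d, "vhpo_cq_scale")
  # missing reference errors with the sample named
  cq_bad <- cq[cq$gene != "EIF5B" | cq$thallus_id != "th2", ]
  expect_error(compute_dcq(cq_bad, "EIF5B"), "th2")
  expect_error(compute_dcq(cq, "NDH"), "NDH")
})

test_that("fold change to control: calibrator mean gives fc 1, powers of two exact", {
  cq <- rbind(make_cq_row("c1", "control", "t1", "EIF5B", 1, 21),
              make_cq_row("c1", "control", "t1", "g", 1, 25),
              make_cq_row("c2", "control", "t1", "EIF5B", 1, 21),
              make_cq_row("c2", "control", "t1", "g", 1, 25),
              make_cq_row("e1", "elicitor", "t1", "EIF5B", 1, 21),
              make_cq_row("e1", "elicitor", "t1", "g", 1, 25),  # same dcq -> fc 1
              make_cq_row("e2", "elicitor", "t1", "EIF5B", 1, 21),
              make_cq_row("e2", "elicitor", "t1", "g", 1, 23))  # ddcq -2 -> fc 4
  fc <- fold_change_to_control(compute_dcq(cq, "EIF5B"))
  expect_equal(fc$fc[fc$thallus_id == "e1"], 1)
  expect_equal(fc$fc[fc$thallus_id == "e2"], 4)
  expect_true(all(fc$fc == 2^(-fc$ddcq)))
  no_ctrl <- cq[cq$treatment != "control", ]
  expect_error(fold_change_to_control(compute_dcq(no_ctrl, "EIF5B")), "control")
})

test_that("fold change to t0 pairs each thallus with itself", {
  cq <- rbind(make_cq_row("e1", "elicitor", "t0", "EIF5B", 1, 21),
              make_cq_row("e1", "elicitor", "t0", "g", 1, 25),
              make_cq_row("e1", "elicitor", "t1", "EIF5B", 1, 22),
              make_cq_row("e1", "elicitor", "t1", "g", 1, 25),  # dcq 3: paired diff -1
              make_cq_row("e2", "elicitor", "t0", "g", 1, 24),
              make_cq_row("e2", "elicitor", "t0", "EIF5B", 1, 20),
              make_cq_row("e2", "elicitor", "t1", "g", 1, 24),
              make_cq_row("e2", "elicitor", "t1", "EIF5B", 1, 20))
  fc <- fold_change_to_t0(compute_dcq(cq, "EIF5B"))
  expect_equal(fc$fc[fc$thallus_id == "e1"], 2)   # ddcq -1
  expect_equal(fc$fc[fc$thallus_id == "e2"], 1)   # unchanged
  # missing pair errors with the thallus named
  cq_bad <- cq[!(cq$thallus_id == "e2" & cq$time_point == "t0"), ]
  expect_error(fold_change_to_t0(compute_dcq(cq_bad, "EIF5B")), "e2")
})

test_that("the two schemes coincide when control means equal each thallus t0 dcq", {
  # constructed fixture: control dcq at every time point == 4 == each t0 dcq
  rows <- list()
  for (th in c("c1", "c2")) for (tp in c("t0", "t1")) {
    rows[[length(rows) + 1]] <- make_cq_row(th, "control", tp, "EIF5B", 1, 21)
    rows[[length(rows) + 1]] <- make_cq_row(th, "control", tp, "g", 1, 25)
  }
  for (th in c("e1", "e2")) {
    rows[[length(rows) + 1]] <- make_cq_row(th, "elicitor", "t0", "EIF5B", 1, 21)
    rows[[length(rows) + 1]] <- make_cq_row(th, "elicitor", "t0", "g", 1, 25)
    rows[[length(rows) + 1]] <- make_cq_row(th, "elicitor", "t1", "EIF5B", 1, 21)
    rows[[length(rows) + 1]] <- make_cq_row(th, "elicitor", "t1", "g", 1,
                                            if (th == "e1") 23 else 24)
  }
  d <- compute_dcq(do.call(rbind, rows), "EIF5B")
  a <- fold_change_to_control(d)
  b <- fold_change_to_t0(d)
  key <- c("thallus_id", "time_point", "gene")
  m <- merge(a[a$time_point == "t1" & a$treatment == "elicitor", c(key, "fc")],
             b[b$treatment == "elicitor", c(key, "fc")], by = key)
  expect_equal(m$fc.x, m$fc.y)
})

test_that("planted fold changes are recovered exactly without noise", {
  pl <- data.frame(gene = "Sl1_07", treatment = "elicitor", time_point = "t1",
                   log2fc = 2)
  q <- make_qpcr_dataset(planted_log2fc = pl, sigma_bio = 0, sigma_tech = 0, seed = 71)
  d <- compute_dcq(q$cq, "EIF5B")
  f0 <- fold_change_to_t0(d)
  hit <- f0$gene == "Sl1_07" & f0$treatment == "elicitor" & f0$time_point == "t1"
  expect_equal(f0$fc[hit], rep(4, sum(hit)))
  expect_true(all(abs(f0$fc[!hit] - 1) < 1e-12))
  fc <- fold_change_to_control(d)
  hitc <- fc$gene == "Sl1_07" & fc$treatment == "elicitor" & fc$time_point == "t1"
  expect_equal(fc$fc[hitc], rep(4, sum(hitc)))
})

test_that("log2 fold change is antisymmetric under swapping sample and calibrator", {
  set.seed(72)
  dcq_s <- runif(10, 2, 8); dcq_c <- runif(10, 2, 8)
  expect_equal(log2(2^(-(dcq_s - dcq_c))), -log2(2^(-(dcq_c - dcq_s))))
})

test_that("reference-gene evaluation picks the narrowest Cq range", {
  # gene A spans 19.4-24.1 (width 4.7), gene B spans 18.2-25.9 (width 7.7)
  set.seed(73)
  n <- 12
  a_cq <- c(19.4, 24.1, runif(n - 2, 19.5, 24.0))
  b_cq <- c(18.2, 25.9, a_cq[3:n] + rnorm(n - 2, 0, 0.8))
  rows <- list()
  for (i in seq_len(n)) {
    th <- sprintf("th%02d", i)
    rows[[length(rows) + 1]] <- make_cq_row(th, "control", "t0", "EIF5B", 1, a_cq[i])
    rows[[length(rows) + 1]] <- make_cq_row(th, "control", "t0", "NDH", 1, b_cq[i])
  }
  rg <- evaluate_reference_genes(do.call(rbind, rows), c("EIF5B", "NDH"))
  expect_equal(rg$selected_gene, "EIF5B")
  expect_equal(rg$per_gene$range_width, c(4.7, 7.7), tolerance = 1e-9)
  expect_true(rg$pairs$pearson_r > 0 && rg$pairs$pearson_r <= 1)
  # identical vectors: r = 1, tie broken by order of candidates
  rows_id <- rows
  for (k in seq_along(rows_id)) if (rows_id[[k]]$gene == "NDH") {
    rows_id[[k]]$cq <- a_cq[(k + 1) %/% 2]
  }
  rg2 <- evaluate_reference_genes(do.call(rbind, rows_id), c("EIF5B", "NDH"))
  expect_equal(rg2$pairs$pearson_r, 1)
  expect_equal(rg2$selected_gene, "EIF5B")
})

test_that("reference-gene correlation recovers a planted r = 0.85", {
  ests <- vapply(1:10, function(s) {
    set.seed(600 + s)
    n <- 100
    x <- rnorm(n)
    y <- 0.85 * x + sqrt(1 - 0.85^2) * rnorm(n)
    rows <- list()
    for (i in seq_len(n)) {
      th <- sprintf("th%03d", i)
      rows[[length(rows) + 1]] <- make_cq_row(th, "control", "t0", "A", 1, 21 + x[i])
      rows[[length(rows) + 1]] <- make_cq_row(th, "control", "t0", "B", 1, 21 + y[i])
    }
    evaluate_reference_genes(do.call(rbind, rows), c("A", "B"))$pairs$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.85), 0.05)
})

test_that("statistical tests refuse Cq-scale inputs at the API boundary", {
  q <- make_qpcr_dataset(seed = 74)
  d <- compute_dcq(q$cq, "EIF5B")
  expect_error(anova_dunnett(d, "control"), "2\\^- transformed")
  expect_error(one_sample_t_bonferroni(d), "2\\^- transformed")
})

test_that("Dunnett adjustment is monotone, reproducible, and matches multcomp", {
  set.seed(75)
  g <- list(control = rnorm(6), a = rnorm(6, 1.2), b = rnorm(6), c = rnorm(6, -0.5))
  t1 <- anova_dunnett(g, "control", n_draws = 1e5, seed = 7)
  t2 <- anova_dunnett(g, "control", n_draws = 1e5, seed = 7)
  expect_identical(t1, t2)                               # bit-identical decisions
  expect_true(all(t1$comparisons$p_adjusted >= t1$comparisons$p_raw))
  # independent oracle: multcomp's multivariate-t Dunnett adjustment
  df_long <- data.frame(value = unlist(g),
                        group = factor(rep(names(g), lengths(g)),
                                       levels = names(g)))
  fit <- stats::aov(value ~ group, data = df_long)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  p_mc <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(unname(t1$comparisons$p_adjusted), unname(as.numeric(p_mc)),
               tolerance = 5e-3)
  # degenerate data error path
  expect_error(anova_dunnett(list(control = c(1, 1), a = c(2, 2)), "control"),
               "degenerate")
})

test_that("one-sample t family reports the Bonferroni-corrected level", {
  set.seed(76)
  s <- lapply(1:9, function(i) rnorm(6))
  names(s) <- paste0("set", 1:9)
  r <- one_sample_t_bonferroni(s, mu = 0, family_alpha = 0.05, m = 9)
  expect_equal(r$alpha_adjusted, 0.0056)
  expect_equal(one_sample_t_bonferroni(s[1:2], m = 1)$alpha_adjusted, 0.05)
  expect_warning(
    rz <- one_sample_t_bonferroni(list(z = c(1, 1, 1)), m = 1), "zero variance")
  expect_true(is.na(rz$comparisons$significant))
})

test_that("Bonferroni family-wise error stays at or below the nominal level", {
  reps <- 4000L
  rejected <- vapply(seq_len(reps), function(k) {
    set.seed(3000 + k)
    fam <- replicate(9, rnorm(3), simplify = FALSE)
    r <- one_sample_t_bonferroni(fam, mu = 0, family_alpha = 0.05, m = 9)
    any(r$comparisons$significant)
  }, logical(1))
  expect_lte(mean(rejected), 0.05 + 0.01)
})

test_that("Mann-Whitney: tie cases, separation, exact p vs permutation oracle", {
  r_id <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r_id$U, 4.5)                      # n1*n2/2
  expect_equal(mann_whitney(1:4, 5:8)$U, 0)      # complete separation
  expect_equal(mann_whitney(5:8, 1:4)$U, 16)
  set.seed(77)
  for (i in 1:15) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- sample(1:100, n1 + n2)                  # distinct -> no ties
    a <- v[1:n1]; b <- v[-(1:n1)]
    got <- mann_whitney(a, b)
    expect_match(got$method, "exact")
    expect_equal(got$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
  }
  # ties force the corrected normal approximation
  big <- mann_whitney(rep(1:10, 3), rep(2:11, 3))
  expect_match(big$method, "tie correction")
})

test_that("PSII damage is control-corrected arithmetic on percent reductions", {
  fv <- rbind(
    data.frame(thallus_id = "c1", treatment = "control", time_point = c("t0", "t1"),
               fvfm = c(0.68, 0.68 * 0.95)),     # control drops 5%
    data.frame(thallus_id = "e1", treatment = "elicitor", time_point = c("t0", "t1"),
               fvfm = c(0.66, 0.66 * 0.80)))     # treated drops 20%
  d <- psii_damage(fv)
  expect_equal(d$reduction_pct[d$thallus_id == "e1"], 20, tolerance = 1e-9)
  expect_equal(d$corrected_reduction_pct[d$thallus_id == "e1"], 15, tolerance = 1e-9)
  expect_equal(d$corrected_reduction_pct[d$thallus_id == "c1"], 0, tolerance = 1e-9)
  # treated trajectory identical to control mean -> corrected 0
  fv2 <- fv; fv2$fvfm[3:4] <- c(0.68, 0.68 * 0.95)
  d2 <- psii_damage(fv2)
  expect_equal(d2$corrected_reduction_pct[d2$thallus_id == "e1"], 0, tolerance = 1e-9)
  # missing t0 and out-of-range values error
  expect_error(psii_damage(fv[-3, ]), "e1")
  fv3 <- fv; fv3$fvfm[1] <- 1.2
  expect_error(psii_damage(fv3), "\\[0, 1\\)")
})

test_that("distribution checks warn but return diagnostics", {
  set.seed(78)
  vals <- list(a = rexp(20), b = rnorm(20, sd = 10))
  expect_warning(diag <- check_distribution_assumptions(vals))
  expect_equal(nrow(diag), 2)
})
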