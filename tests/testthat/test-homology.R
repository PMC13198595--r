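refs <- default_reference_set()

ref_seq <- function(pdb) refs$seqs$aa_seq[refs$seqs$pdb_id == pdb]
ref_motifs <- function(pdb) refs$motifs[refs$motifs$pdb_id == pdb, ]
mutate_site <- function(seq, pos, res) {
  substr(seq, pos, pos) <- res
  seq
}

test_that("reference fixture satisfies its structural invariants", {
  expect_s3_class(refs, "vhpo_refs")
  expect_equal(refs$seqs$group[match(c("1UP8", "5LPC", "5AA6", "4CIT", "1IDQ"),
                                     refs$seqs$pdb_id)], c(1L, 1L, 1L, 2L, 3L))
  ch <- refs$motifs[refs$motifs$role == "covalent_his", ]
  expect_equal(nrow(ch), nrow(refs$seqs))           # exactly one per reference
  expect_true(all(ch$motif_index == 3L))
  expect_true(all(ch$expected_residue == "H"))
})

test_that("group assignment: exact substrings hit their source, shuffles hit nothing", {
  sub <- substr(ref_seq("5AA6"), 101, 250)          # 150-residue exact substring
  asg <- assign_group(sub, refs)
  expect_equal(asg$group, 1L)
  expect_equal(asg$best_reference, "5AA6")
  set.seed(21)
  shuf <- paste(sample(strsplit(ref_seq("1UP8"), "")[[1]]), collapse = "")
  asg2 <- assign_group(shuf, refs)
  expect_true(is.na(asg2$group))
})

test_that("planted candidates at 60% identity recover their group exactly", {
  syn <- make_transcriptome(refs, n_planted = 15, n_background = 0,
                            identity = 0.6, seed = 31)
  for (i in seq_len(nrow(syn$truth))) {
    asg <- assign_group(syn$truth$aa_seq[i], refs)
    expect_equal(asg$group, syn$truth$group[i], info = syn$truth$id[i])
  }
})

test_that("motif mapping reports conserved, substituted and unaligned sites", {
  s <- ref_seq("1UP8")
  mot <- ref_motifs("1UP8")
  ch_pos <- mot$ref_position[mot$role == "covalent_his"]

  st_id <- map_motif_positions(local_align(s, s), mot)
  expect_true(all(st_id$state == "conserved"))

  st_sub <- map_motif_positions(local_align(mutate_site(s, ch_pos, "N"), s), mot)
  expect_equal(st_sub$state[st_sub$ref_position == ch_pos], "substituted")
  expect_equal(st_sub$observed[st_sub$ref_position == ch_pos], "N")
  expect_true(all(st_sub$state[st_sub$ref_position != ch_pos] == "conserved"))

  trunc <- substr(s, 1, min(mot$ref_position[mot$motif_index == 3]) - 40)
  st_tr <- map_motif_positions(local_align(trunc, s), mot)
  expect_true(all(st_tr$state[st_tr$motif_index == 3] == "unaligned"))
  expect_true(all(st_tr$state[st_tr$motif_index != 3] == "conserved"))

  bad <- mot; bad$ref_position[1] <- nchar(s) + 10
  expect_error(map_motif_positions(local_align(s, s), bad), "outside")
})

test_that("classification is a pure table over all state combinations", {
  states <- c("conserved", "substituted", "unaligned")
  # 5-site layout: two vanadate-binding sites in motifs 1 and 2 each
  # would blow up; use 2 vb (motifs 1, 2) + covalent his (motif 3),
  # plus a catalytic site in motif 1 -> 3^4 = 81 combinations
  grid <- expand.grid(vb1 = states, cat1 = states, vb2 = states, ch = states,
                      stringsAsFactors = FALSE)
  expected_rule <- function(vb1, cat1, vb2, ch) {
    # independent restatement of the curation rules
    m1_gone <- vb1 == "unaligned" && cat1 == "unaligned"
    m2_gone <- vb2 == "unaligned"
    m3_gone <- ch == "unaligned"
    if (m1_gone || m2_gone || m3_gone) return("rejected")
    if (ch == "substituted") return("predicted_inactive")
    vb <- c(vb1, vb2)
    if (mean(vb == "conserved") < 0.6) return("rejected")
    if (all(c(vb1, cat1, vb2) == "conserved")) "putative_vHPO" else "putative_vHPO_atypical"
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ms <- data.frame(
      motif_index = c(1L, 1L, 2L, 3L),
      ref_position = c(10L, 14L, 40L, 70L),
      expected_residue = c("R", "K", "H", "H"),
      role = c("vanadate_binding", "catalytic", "vanadate_binding", "covalent_his"),
      state = c(g$vb1, g$cat1, g$vb2, g$ch),
      observed = c("A", "A", "S", "N"), stringsAsFactors = FALSE)
    expect_equal(classify_motif_states(ms, 1L),
                 expected_rule(g$vb1, g$cat1, g$vb2, g$ch),
                 info = paste(unlist(g), collapse = "/"))
  }
  expect_equal(classify_motif_states(NULL, NA_integer_), "rejected")
})

test_that("curation reproduces the canonical patterns", {
  s1 <- ref_seq("1UP8")
  expect_equal(curate_candidate(s1, refs = refs)$classification, "putative_vHPO")

  mot1 <- ref_motifs("1UP8")
  ch_pos <- mot1$ref_position[mot1$role == "covalent_his"]
  inactive <- curate_candidate(mutate_site(s1, ch_pos, "N"), refs = refs)
  expect_equal(inactive$classification, "predicted_inactive")

  # group 2 with the motif-2 His -> Ser substitution, covalent His intact
  s2 <- ref_seq("4CIT")
  mot2 <- ref_motifs("4CIT")
  h2 <- mot2$ref_position[mot2$motif_index == 2 & mot2$expected_residue == "H"]
  atyp <- curate_candidate(mutate_site(s2, h2, "S"), refs = refs)
  expect_equal(atyp$assigned_group, 2L)
  expect_equal(atyp$classification, "putative_vHPO_atypical")
  sub <- atyp$motif_states[atyp$motif_states$state == "substituted", ]
  expect_equal(sub$ref_position, h2)
  expect_equal(sub$observed, "S")
})

test_that("min_score calibration yields a threshold separating noise from homologs", {
  cal <- calibrate_min_score(refs, n_shuffle = 30, seed = 17)
  expect_true(cal$min_score < 100)   # shuffled scores are small
  expect_true(cal$min_score > 20)
  # genuine homologs score far above the calibrated threshold
  syn <- make_transcriptome(refs, n_planted = 2, n_background = 0,
                            identity = 0.6, seed = 18)
  sc <- assign_group(syn$truth$aa_seq[1], refs)$score
  expect_gt(sc, cal$min_score * 3)
})
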