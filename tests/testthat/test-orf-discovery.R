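test_that("frame translation follows the standard code, stops and N-codons included", {
  expect_equal(translate_frame("ATGAAA", 1), "MK")
  expect_equal(translate_frame("TTTCAT", -1), "MK")  # revcomp is ATGAAA
  expect_equal(translate_frame("ATGTAAGGG", 1), "M*G")
  expect_equal(translate_frame("ATGANA", 1), "MX")
  expect_equal(translate_frame("ATGAA", 1), "M")     # partial codon dropped
  expect_error(translate_frame("ATGAAA", 4), "frame")
  expect_error(translate_frame("ATGRAA", 1), "outside")
})

test_that("all six frames agree with an independent codon-table oracle", {
  set.seed(41)
  for (i in 1:50) {
    s <- random_contig(300, with_n = i %% 5 == 0)
    for (f in c(1, 2, 3, -1, -2, -3)) {
      expect_identical(translate_frame(s, f), oracle_translate(s, f))
    }
  }
})

test_that("the 100-residue minimum is enforced at the boundary", {
  body99 <- strrep("GCT", 99)
  orfs <- six_frame_orfs(paste0("ATG", body99, "TAA"), min_aa = 100)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$aa_len, 100L)
  expect_true(orfs$has_stop)
  expect_equal(orfs$aa_seq, paste0("M", strrep("A", 99)))
  # one codon fewer -> below threshold
  short <- six_frame_orfs(paste0("ATG", strrep("GCT", 98), "TAA"), min_aa = 100)
  expect_equal(nrow(short), 0L)
  expect_error(six_frame_orfs("ATGAAA", min_aa = 0), "min_aa")
})

test_that("contigs without any start codon yield no ORFs", {
  expect_equal(nrow(six_frame_orfs(strrep("GCT", 200), min_aa = 10)), 0L)
})

test_that("six-frame discovery matches brute-force (frame, ATG) enumeration", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_contig(1000)
    got <- six_frame_orfs(s, min_aa = 20)
    want <- oracle_orfs(s, min_aa = 20)
    cols <- c("frame", "strand", "start", "end", "aa_len", "has_stop", "aa_seq")
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, cols], want[, cols])
  }
})

test_that("ORFs map onto themselves under reverse complement", {
  set.seed(43)
  for (i in 1:10) {
    s <- random_contig(800)
    rc <- oracle_revcomp(s)
    a <- six_frame_orfs(s, min_aa = 15)
    b <- six_frame_orfs(rc, min_aa = 15)
    expect_equal(nrow(a), nrow(b))
    expect_setequal(a$aa_seq, b$aa_seq)
    L <- nchar(s)
    # mirrored coordinates, swapped strand
    key_a <- sprintf("%s:%d-%d:%s", a$aa_seq, a$start, a$end, a$strand)
    key_b <- sprintf("%s:%d-%d:%s", b$aa_seq, L - b$end, L - b$start,
                     ifelse(b$strand == "+", "-", "+"))
    expect_setequal(key_a, key_b)
  }
})

test_that("Kozak scan classifies contexts and handles missing flank", {
  # A at -3 (purine), G at +4 -> match
  s1 <- paste0("TTTACG", "ATG", "G", strrep("GCT", 30), "TAA")
  o1 <- six_frame_orfs(s1, min_aa = 10)
  expect_equal(o1$kozak_state, "match")
  expect_equal(o1$kozak_context, "ACGATGG")
  # C at -3 -> no match
  s2 <- paste0("TTTCCG", "ATG", "G", strrep("GCT", 30), "TAA")
  expect_equal(six_frame_orfs(s2, min_aa = 10)$kozak_state, "no_match")
  # only 1 nt upstream -> indeterminate
  s3 <- paste0("T", "ATG", strrep("GCT", 30), "TAA")
  o3 <- six_frame_orfs(s3, min_aa = 10)
  expect_equal(o3$kozak_state, "indeterminate")
  expect_equal(o3$kozak_context, "")
  # kozak_scan agrees on explicit coordinates and errors out of range
  kz <- kozak_scan(s1, o1$start, o1$end, "+")
  expect_equal(kz$state, "match")
  expect_error(kozak_scan(s1, 5, nchar(s1) + 3), "outside")
})

test_that("Kozak match count equals a regular-expression oracle on random ORFs", {
  set.seed(44)
  n_match <- 0L; n_oracle <- 0L
  for (i in 1:40) {
    s <- random_contig(700)
    orfs <- six_frame_orfs(s, min_aa = 10)
    if (!nrow(orfs)) next
    n_match <- n_match + sum(orfs$kozak_state == "match")
    n_oracle <- n_oracle + sum(grepl("^[AG]..ATGG$", orfs$kozak_context))
  }
  expect_gt(n_match + n_oracle, 0)
  expect_identical(n_match, n_oracle)
})

test_that("deduplication keeps one representative and is idempotent", {
  base <- six_frame_orfs(paste0("ATG", strrep("GCT", 40), "TAA"), min_aa = 10)
  mk <- function(cid, sp) {
    d <- base; d$contig_id <- cid; d$species <- sp; d
  }
  orfs <- rbind(mk("c2", "spA"), mk("c1", "spA"), mk("c3", "spB"))
  orfs$orf_id <- sprintf("%s|%+d|%d", orfs$contig_id, orfs$frame, orfs$start)
  per_sp <- dedupe_candidates(orfs, "per_species")
  expect_equal(sort(per_sp$contig_id), c("c1", "c3"))   # both species kept
  glob <- dedupe_candidates(orfs, "global")
  expect_equal(glob$contig_id, "c1")                    # smallest contig id wins
  # idempotence and field preservation
  expect_identical(dedupe_candidates(per_sp, "per_species"), per_sp)
  kept <- per_sp[per_sp$contig_id == "c1", ]
  orig <- orfs[orfs$contig_id == "c1", ]
  rownames(kept) <- rownames(orig) <- NULL
  expect_identical(kept, orig)
})

test_that("FASTA round trip preserves ids, species and sequences", {
  refs <- default_reference_set()
  syn <- make_transcriptome(refs, n_planted = 2, n_background = 1, seed = 5)
  fa <- tempfile(fileext = ".fna")
  write_transcriptome(syn, fa)
  back <- read_contigs(fa)
  expect_equal(back$id, syn$contigs$id)
  expect_equal(back$seq, syn$contigs$seq)
  expect_equal(back$species, syn$contigs$species)
})
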