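test_that("seed index counts words per transcript", {
  tx <- new_transcriptome(tibble::tibble(
    transcript_id = "t1", gene_id = "g1", biotype = "mRNA",
    sequence = paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")))
  idx <- build_seed_index(tx, word_size = 7)
  expect_equal(nrow(idx$words), 24)
  expect_error(build_seed_index(tx, word_size = 3), ">= 4")
})

test_that("planted complements are recovered at and only at >= 15 nt", {
  fx <- small_planted_fixture(202, identity_nt = c(15L, 14L))
  tx <- fx$transcriptome
  cand <- tile_candidates(tx[1, ])
  idx <- build_seed_index(tx)
  hits <- find_hits_all(cand, idx)
  off <- hits[!hits$target_id %in% fx$on_target_ids, ]
  plants <- fx$manifest$plants
  # the 15-nt plant (decoy 1) is hit; the 14-nt plant (decoy 2) is not
  expect_true(all(off$target_id == plants$decoy_id[1]))
  expect_true(nrow(off) >= 1)
  expect_true(all(off$matched_nt >= 15))
  # recovered span matches the manifest ground truth
  expect_true(all(off$target_start >= plants$decoy_start[1] - 1 &
                    off$target_end <= plants$decoy_start[1] +
                      plants$identity_nt[1] + 1))
})

test_that("retained hits equal full Smith-Waterman brute force", {
  for (seed in c(301, 302, 303)) {
    fx <- small_planted_fixture(seed, identity_nt = c(17L, 15L))
    tx <- fx$transcriptome
    cand <- tile_candidates(tx[1, ])
    idx <- build_seed_index(tx)
    hits <- find_hits_all(cand, idx)
    brute <- oracle_brute_hits(cand, tx)
    expect_setequal(hit_key(hits), hit_key(brute))
  }
})

test_that("site maps cluster overlapping spans by single linkage", {
  hits <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    target_id = "T",
    probe_start = 0L, probe_end = 20L,
    target_start = c(10L, 25L, 60L),
    target_end = c(30L, 45L, 80L),
    matched_nt = 20L, score = 20L,
    probe_aln = "ACGT", target_aln = "ACGT")
  tx <- new_transcriptome(tibble::tibble(
    transcript_id = c("T", "U"), gene_id = c("gT", "gU"),
    biotype = "mRNA", sequence = strrep("ACGT", 30)))
  sm <- build_site_map(hits, tx)
  # [10,30) and [25,45) overlap -> one site spanning [10,45); [60,80) apart
  expect_equal(nrow(sm$sites), 2)
  expect_equal(sm$sites$start, c(10L, 60L))
  expect_equal(sm$sites$end, c(45L, 80L))
  cfg1 <- sm$configs[sm$configs$site_id == sm$sites$site_id[1], ]
  expect_setequal(cfg1$probe_id, c("p1", "p2"))
  # hits partition into sites
  expect_equal(nrow(sm$configs), nrow(hits))
  # adjacent-but-not-overlapping spans stay separate
  hits2 <- hits
  hits2$target_start <- c(10L, 30L, 60L)
  hits2$target_end <- c(30L, 50L, 80L)
  expect_equal(nrow(build_site_map(hits2, tx)$sites), 3)
  # targets without hits report zero sites
  expect_equal(sm$n_sites$n_sites[sm$n_sites$target_id == "U"], 0L)
})

test_that("rRNA-binding probes are flagged from the site map", {
  fx <- small_planted_fixture(404)
  tx <- fx$transcriptome
  # plant an exact window of the target into the rRNA decoy by hand
  r <- which(tx$biotype == "rRNA")
  win <- substr(tx$sequence[1], 31, 50)
  seq <- tx$sequence[r]
  substr(seq, 21, 40) <- win
  tx$sequence[r] <- seq
  cand <- tile_candidates(tx[1, ])
  idx <- build_seed_index(tx)
  hits <- find_hits_all(cand, idx)
  sm <- build_site_map(hits, tx)
  flagged <- flag_rRNA_probes(sm, tx)
  expect_true("TARGET_iso1_p30" %in% flagged)
  # flagged probes are exactly those with an rRNA hit
  rrna_hits <- unique(hits$probe_id[hits$target_id ==
                                      tx$transcript_id[r]])
  expect_setequal(flagged, rrna_hits)
  # empty site map flags nothing
  sm0 <- build_site_map(hits[0, ], tx)
  expect_length(flag_rRNA_probes(sm0, tx), 0)
})

test_that("self-alignments find hairpin stems and honour K", {
  # ACGT repeats are self-complementary: stems must exist
  p <- list(probe_id = "p", sequence = "ACGTACGTACGTACGTACGT")
  cfg <- self_alignments(p)
  expect_gt(nrow(cfg), 0)
  # brute-force scan oracle: all complementary substring pairs >= 3 bp
  s <- strsplit(p$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  found <- FALSE
  n <- length(s)
  for (i in 1:(n - 2)) for (j in n:(i + 2)) {
    len <- 0
    while (i + len <= n && j - len >= 1 && (j - len) - (i + len) > 3 &&
           s[i + len] == comp[[s[j - len]]]) len <- len + 1
    if (len >= 3) found <- TRUE
  }
  expect_true(found)
  # stems are genuinely self-complementary
  for (k in seq_len(nrow(cfg))) {
    stem <- cfg$probe_aln[k]
    i <- cfg$i_start[k]; j <- cfg$j_end[k]; L <- cfg$stem_length[k]
    partner <- substr(p$sequence, j - L + 2, j + 1)
    expect_equal(revcomp(stem), partner)
  }
  # homopolymer cannot pair with itself
  expect_equal(nrow(self_alignments(list(probe_id = "a",
                                         sequence = strrep("A", 20)))), 0)
  # K = 1 truncates to the top configuration
  one <- self_alignments(p, k_max = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$stem_length, max(cfg$stem_length))
})

test_that("cross-alignments cover both orientations and are symmetric", {
  a <- list(probe_id = "a", sequence = "ATCGGATCCGTTAGCAATGC")
  b <- list(probe_id = "b", sequence = revcomp(a$sequence))
  cfg <- cross_alignments(a, b)
  anti <- cfg[cfg$orientation == "antiparallel", ]
  # full-length perfect duplex in the antiparallel orientation
  expect_equal(anti$matched_nt, 20L)
  expect_equal(anti$probe_aln, anti$partner_aln)
  # homopolymer pair: no stable configuration
  expect_equal(nrow(cross_alignments(
    list(probe_id = "x", sequence = strrep("A", 20)),
    list(probe_id = "y", sequence = strrep("A", 20)))), 0)
  # symmetry of matched counts
  set.seed(5)
  for (k in 1:10) {
    s1 <- list(probe_id = "i", sequence = paste(
      sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
    s2 <- list(probe_id = "j", sequence = paste(
      sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
    c12 <- cross_alignments(s1, s2)
    c21 <- cross_alignments(s2, s1)
    expect_equal(sort(c12$matched_nt), sort(c21$matched_nt))
  }
})
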