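ranked_row <- function(probe_id, start, sequence, dg_on, n_off = 0,
                       dg_off = 0, dg_self = 0, target_id = "T") {
  tibble::tibble(probe_id = probe_id, target_id = target_id, start = start,
                 length = nchar(sequence), sequence = sequence,
                 n_offtargets = n_off, dg_off_sum = dg_off, dg_on = dg_on,
                 dg_self = dg_self, cross_accrued = 0,
                 energy_gap = dg_on - (dg_off + dg_self))
}

test_that("prioritization rank orders by off-targets, gap, then start", {
  cand <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"), target_id = "T",
    start = c(40, 0, 20, 60), length = 20,
    sequence = strrep("A", 20))
  sm <- list(sites = tibble::tibble(), configs = tibble::tibble())
  kds <- make_kds(site = tibble::tibble(
    probe_id = c("a", "b", "c", "d", "d"),
    target_id = c("T", "T", "T", "off", "T"),
    site_id = c("s1", "s2", "s3", "o1", "s4"),
    kd = 1e-9, dg_min = c(-25, -20, -20, -10, -25)))
  r <- rank_candidates(cand, sm, kds, on_target_ids = "T")
  # d has an off-target -> last despite the strong on-target energy
  expect_equal(r$probe_id[4], "d")
  # a (-25) precedes b and c (-20); b precedes c on start tie-break
  expect_equal(r$probe_id, c("a", "b", "c", "d"))
  # expression weighting multiplies off-target counts by expression
  expr <- tibble::tibble(transcript_id = "off", expression = 7)
  rw <- rank_candidates(cand, sm, kds, "T", expression = expr,
                        weight_by_expression = TRUE)
  expect_equal(rw$n_offtargets[rw$probe_id == "d"], 7)
})

test_that("fully overlapping candidates yield a single selection", {
  seqs <- vapply(0:5, function(s) strrep("ACGTA", 4), character(1))
  pool <- dplyr::bind_rows(lapply(0:5, function(s)
    ranked_row(paste0("p", s), s, seqs[s + 1], dg_on = -20 - s)))
  sel <- select_probes(pool, max_probes = 10, min_spacing = 3)
  expect_equal(nrow(sel$selected), 1)
  expect_equal(sel$selected$probe_id, "p5")  # strongest gap
  expect_equal(sort(unique(sel$excluded$reason)), "overlap")
})

test_that("zero-off-target probes are exhausted before off-target probes", {
  pool <- dplyr::bind_rows(
    ranked_row("dirty", 0, "ATCGGATCCGTTAGCAATGC", dg_on = -40,
               n_off = 1, dg_off = -12),
    ranked_row("clean1", 50, "TTGCACTGAAGCACTTAGGC", dg_on = -18),
    ranked_row("clean2", 100, "TGCAAGGCTTAACCGGATTA", dg_on = -17))
  sel <- select_probes(pool, max_probes = 3)
  expect_equal(sel$selected$probe_id, c("clean1", "clean2", "dirty"))
  expect_equal(sel$selected$phase,
               c("no_offtarget", "no_offtarget", "with_offtarget"))
  # the cap is respected and recorded
  sel2 <- select_probes(pool, max_probes = 2)
  expect_equal(nrow(sel2$selected), 2)
  expect_true("dirty" %in%
                sel2$excluded$probe_id[sel2$excluded$reason == "cap"])
  expect_error(select_probes(pool, max_probes = 0), ">= 1")
})

test_that("cross-dimer accrual re-ranks a reverse-complement pair", {
  a_seq <- "ATCGGATCCGTTAGCAATGC"
  pool <- dplyr::bind_rows(
    ranked_row("A", 0, a_seq, dg_on = -30),
    ranked_row("B", 100, revcomp(a_seq), dg_on = -25),
    ranked_row("C", 200, "TGGATTACAGGCATGAGCCA", dg_on = -24.5))
  # before any selection B outranks C
  expect_lt(pool$energy_gap[pool$probe_id == "B"],
            pool$energy_gap[pool$probe_id == "C"])
  sel <- select_probes(pool, max_probes = 3)
  # after A is taken, B's perfect cross-dimer with A demotes it below C
  expect_equal(sel$selected$probe_id, c("A", "C", "B"))
  expect_lt(sel$selected$cross_accrued[sel$selected$probe_id == "B"], -15)
})

test_that("selection is deterministic and respects spacing end-to-end", {
  d <- arf4_design()
  sel <- d$selection$selected
  expect_gte(nrow(sel), 20)
  by_start <- sel[order(sel$start), ]
  gaps <- by_start$start[-1] - (by_start$start[-nrow(by_start)] +
                                  by_start$length[-nrow(by_start)])
  expect_true(all(gaps >= d$selection$min_spacing))
  # no rRNA-flagged probe selected
  expect_length(intersect(sel$probe_id, d$rrna_flagged), 0)
  # phase dominance on the full run
  phases <- sel$phase[order(sel$order)]
  if (any(phases == "with_offtarget")) {
    expect_lt(max(which(phases == "no_offtarget")),
              min(which(phases == "with_offtarget")))
  }
  # identical inputs yield byte-identical selections
  sel2 <- select_probes(d$ranked, max_probes = d$config$max_probes,
                        min_spacing = d$config$min_spacing,
                        rrna_flagged = d$rrna_flagged)
  expect_identical(sel2$selected, d$selection$selected)
})

test_that("removing a planted homology frees zero-off-target probes", {
  with_plant <- small_planted_fixture(606, identity_nt = c(18L, 17L))
  spec_clean <- fixture_spec(seed = 606, target_length = 120, n_decoys = 4,
                             decoy_length = c(80, 160),
                             include_rRNA_decoy = TRUE, plants = NULL)
  without_plant <- generate_fixture(spec_clean, dir = tempfile())
  n_clean_selected <- function(fx) {
    tx <- fx$transcriptome
    cand <- tile_candidates(tx[1, ])
    idx <- build_seed_index(tx)
    sm <- build_site_map(find_hits_all(cand, idx), tx)
    kds <- build_dissociation_constants(sm, NULL, NULL)
    ranked <- rank_candidates(cand, sm, kds, fx$on_target_ids)
    sel <- select_probes(ranked, max_probes = 10)
    sum(sel$selected$n_offtargets == 0)
  }
  expect_gte(n_clean_selected(without_plant),
             n_clean_selected(with_plant))
})

test_that("refinement flags planted promiscuous probes and keeps clean sets", {
  fx <- small_planted_fixture(707, identity_nt = c(20L, 20L))
  tx <- fx$transcriptome
  plants <- fx$manifest$plants
  tseq <- tx$sequence[1]
  # two clean probes + one spanning the planted window
  clean1 <- revcomp(substr(tseq, 86, 105))
  clean2 <- revcomp(substr(tseq, 36, 55))
  dirty <- revcomp(substr(tseq, plants$window_start[1] + 1,
                          plants$window_start[1] + 20))
  probes <- c(good1 = clean1, good2 = clean2, bad = dirty)
  ref <- refine_probe_set(probes, tx, fx$target_id, remove_k = 1)
  expect_equal(ref$problem_probes$probe_id[1], "bad")
  expect_equal(ref$removed, "bad")
  expect_setequal(ref$kept, c("good1", "good2"))
  # a clean set suggests no removals
  ref2 <- refine_probe_set(probes[1:2], tx, fx$target_id, remove_k = 2)
  expect_length(ref2$removed, 0)
  # unlocatable sequences are reported and skipped
  expect_warning(
    ref3 <- refine_probe_set(c(probes, odd = strrep("ACGT", 5)), tx,
                             fx$target_id),
    "not locatable")
  expect_equal(ref3$skipped, "odd")
  expect_error(refine_probe_set(character(0), tx, fx$target_id), "empty")
})
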