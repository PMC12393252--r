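# Probe secondary-structure alignments: self-hybridization (hairpin stems)
# and probe-probe cross-dimerization. Configurations are enumerated
# exhaustively over ungapped pairings; a configuration's aligned pair is
# written so that identical characters mark paired bases, matching the
# convention of the hit table.

comp_chr <- function(x) chartr("ACGTN", "TGCAN", x)

#' Self-hybridization configurations of a probe
#'
#' Enumerates every ungapped antiparallel stem the probe can form with
#' itself: base `i` pairs with base `j > i` when complementary, and maximal
#' runs of at least `min_run` consecutive pairs along an anti-diagonal form
#' one configuration. A minimum hairpin loop of 3 nt separates the paired
#' strands. The top `k_max` configurations by stem length are retained.
#'
#' @param probe One-row data frame or list with `probe_id` and `sequence`.
#' @param k_max Maximum number of configurations kept (default 5).
#' @param min_run Minimum consecutive paired bases per stem (default 3).
#' @return Tibble of configurations: `probe_id`, `i_start`, `j_end` (0-based
#'   positions of the stem's outermost pair), `stem_length`, `probe_aln`,
#'   `partner_aln` (equal strings: a perfect stem duplex).
#' @export
self_alignments <- function(probe, k_max = 5, min_run = 3) {
  if (is.data.frame(probe)) probe <- as.list(probe[1, ])
  stems <- .self_scan_cpp(probe$sequence, min_run, 3L)
  if (!nrow(stems)) {
    return(tibble(probe_id = character(), i_start = integer(),
                  j_end = integer(), stem_length = integer(),
                  probe_aln = character(), partner_aln = character()))
  }
  o <- order(-stems$stem_length, stems$i_start)
  stems <- stems[head(o, k_max), , drop = FALSE]
  top <- substr(rep(probe$sequence, nrow(stems)),
                stems$i_start + 1, stems$i_start + stems$stem_length)
  tibble(probe_id = probe$probe_id,
         i_start = stems$i_start, j_end = stems$j_end,
         stem_length = stems$stem_length,
         probe_aln = top, partner_aln = top)
}

#' Cross-dimerization configurations of two probes
#'
#' Returns at most two configurations: the best antiparallel pairing
#' (5'->3' against 3'->5') and the best parallel pairing (5'->3' against
#' 5'->3'), each being the relative offset whose complementary runs pair the
#' most bases. Runs shorter than 2 bp carry no stacking energy and are
#' ignored when scoring. Energetics are symmetric in the two probes.
#'
#' @param probe_i,probe_j One-row data frames or lists with `probe_id` and
#'   `sequence`.
#' @return Tibble of configurations: `probe_i`, `probe_j`, `orientation`
#'   (`antiparallel`/`parallel`), `matched_nt`, `probe_aln`, `partner_aln`.
#'   Probes with no complementary run of >= 2 bp in an orientation
#'   contribute no row for it (no stable interaction).
#' @export
cross_alignments <- function(probe_i, probe_j) {
  if (is.data.frame(probe_i)) probe_i <- as.list(probe_i[1, ])
  if (is.data.frame(probe_j)) probe_j <- as.list(probe_j[1, ])
  out <- list()
  for (orient in c("antiparallel", "parallel")) {
    cfg <- best_dimer_config(probe_i$sequence, probe_j$sequence, orient)
    if (is.null(cfg)) next
    out[[length(out) + 1]] <- tibble(
      probe_i = probe_i$probe_id, probe_j = probe_j$probe_id,
      orientation = orient, matched_nt = cfg$matched,
      probe_aln = cfg$a, partner_aln = cfg$b)
  }
  if (!length(out)) {
    return(tibble(probe_i = character(), probe_j = character(),
                  orientation = character(), matched_nt = integer(),
                  probe_aln = character(), partner_aln = character()))
  }
  bind_rows(out)
}

# Best ungapped pairing of a against b in the given orientation: the
# relative offset maximizing the number of bases lying in complementary
# runs >= 2 bp. Returns the aligned pair over the overlap (identical chars
# = paired), or NULL when no offset pairs a 2-bp run.
best_dimer_config <- function(a, b, orientation) {
  res <- .dimer_scan_cpp(a, b, orientation == "antiparallel")
  if (res$matched == 0) return(NULL)
  list(a = res$a, b = res$b, matched = res$matched)
}

# Best cross-dimer hybridization free energy (kcal/mol) between each probe in
# `seqs` and `seq`; +Inf (no interaction) where no stable configuration
# exists. Used by the selection loop's re-ranking step.
cross_dg_best <- function(seqs, seq, conditions) {
  vapply(seqs, function(s) {
    dgs <- numeric(0)
    for (orient in c("antiparallel", "parallel")) {
      cfg <- best_dimer_config(s, seq, orient)
      if (is.null(cfg)) next
      e <- nn_duplex_energy(cfg$a, cfg$b, conditions)
      if (e$stable) dgs <- c(dgs, e$dg)
    }
    if (length(dgs)) min(dgs) else Inf
  }, numeric(1), USE.NAMES = FALSE)
}
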