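#' Prioritization rank of candidate probes
#'
#' Orders candidates lexicographically by (i) number of off-target binding
#' sites — optionally weighted by target expression — ascending, then (ii)
#' the energy gap `dG_on - (sum of off-target dG + self-hybridization dG +
#' accrued cross-dimer dG)` ascending (a more negative on-target energy and
#' weaker competing interactions rank better), then (iii) target start
#' coordinate ascending as a deterministic tie-break.
#'
#' @param candidates Candidate tibble from [tile_candidates()].
#' @param site_map A `fish_site_map` built from all candidates' hits.
#' @param kds A `fish_kd` covering the candidates (site + self entries).
#' @param on_target_ids Transcript ids counted as on-target.
#' @param expression Optional tibble `transcript_id`, `expression` used when
#'   `weight_by_expression = TRUE`.
#' @param weight_by_expression Count off-target sites weighted by target
#'   expression instead of plainly (default `FALSE`, the equal-expression
#'   assumption).
#' @return Candidate tibble with `n_offtargets`, `dg_on`, `dg_off_sum`,
#'   `dg_self`, `cross_accrued`, `energy_gap`, sorted by rank.
#' @export
rank_candidates <- function(candidates, site_map, kds, on_target_ids,
                            expression = NULL,
                            weight_by_expression = FALSE) {
  site <- kds$site
  off <- site %>% filter(!.data$target_id %in% on_target_ids)
  if (weight_by_expression) {
    if (is.null(expression)) {
      abort("expression table required for expression-weighted ranking")
    }
    expr <- setNames(expression$expression, expression$transcript_id)
    off_counts <- off %>%
      mutate(w = unname(expr[.data$target_id]),
             w = if_else(is.na(.data$w), 0, .data$w)) %>%
      group_by(.data$probe_id) %>%
      summarise(n_offtargets = sum(.data$w), .groups = "drop")
  } else {
    off_counts <- off %>%
      group_by(.data$probe_id) %>%
      summarise(n_offtargets = dplyr::n(), .groups = "drop")
  }
  off_dg <- off %>%
    group_by(.data$probe_id) %>%
    summarise(dg_off_sum = sum(.data$dg_min), .groups = "drop")
  on_dg <- site %>%
    filter(.data$target_id %in% on_target_ids) %>%
    group_by(.data$probe_id) %>%
    summarise(dg_on = min(.data$dg_min), .groups = "drop")
  self_dg <- kds$self %>% select("probe_id", dg_self = "dg_min")
  candidates %>%
    left_join(off_counts, by = "probe_id") %>%
    left_join(off_dg, by = "probe_id") %>%
    left_join(on_dg, by = "probe_id") %>%
    left_join(self_dg, by = "probe_id") %>%
    mutate(
      n_offtargets = if_else(is.na(.data$n_offtargets), 0,
                             as.numeric(.data$n_offtargets)),
      dg_off_sum = if_else(is.na(.data$dg_off_sum), 0, .data$dg_off_sum),
      dg_on = if_else(is.na(.data$dg_on), 0, .data$dg_on),
      dg_self = if_else(is.na(.data$dg_self), 0, .data$dg_self),
      cross_accrued = 0,
      energy_gap = .data$dg_on -
        (.data$dg_off_sum + .data$dg_self + .data$cross_accrued)
    ) %>%
    arrange(.data$n_offtargets, .data$energy_gap, .data$start)
}

#' Greedy prioritization-rank probe selection
#'
#' Assembles the final probe set in two phases: first over candidates with
#' no off-targets, then over the rest. Each phase repeats a three-step
#' cycle: (i) take the top-ranked remaining candidate; (ii) permanently drop
#' every remaining candidate that violates the minimum spacing against any
#' selected probe; (iii) add each remaining candidate's best cross-dimer
#' hybridization energy against the newly selected probe to its accrued
#' secondary-structure term and re-rank. Selection stops at the probe cap or
#' when no candidates remain.
#'
#' @param ranked Ranked candidate tibble from [rank_candidates()], with
#'   rRNA-binding probes already removed.
#' @param max_probes Maximum number of probes to select (>= 1).
#' @param min_spacing Minimum gap in nt between adjacent selected probes on
#'   the target (default 3).
#' @param conditions A [thermo_conditions()] used for cross-dimer energies.
#' @param rrna_flagged Probe ids excluded upstream as rRNA-binding (recorded
#'   in the exclusion table).
#' @return A `fish_selection`: `selected` (candidate rows with `phase` and
#'   selection `order`), `excluded` (`probe_id`, `reason`), `max_probes`,
#'   `min_spacing`.
#' @export
select_probes <- function(ranked, max_probes, min_spacing = 3,
                          conditions = thermo_conditions(),
                          rrna_flagged = character(0)) {
  if (max_probes < 1) abort("max_probes must be >= 1")
  pool <- ranked %>% filter(!.data$probe_id %in% rrna_flagged)
  excluded <- tibble(probe_id = rrna_flagged,
                     reason = rep("rRNA", length(rrna_flagged)))
  selected <- pool[0, ]
  run_phase <- function(phase_pool, phase_label, selected, excluded) {
    while (nrow(phase_pool) > 0 && nrow(selected) < max_probes) {
      phase_pool <- phase_pool %>%
        arrange(.data$n_offtargets, .data$energy_gap, .data$start)
      pick <- phase_pool[1, ]
      pick$phase <- phase_label
      pick$order <- nrow(selected) + 1L
      selected <- bind_rows(selected, pick)
      phase_pool <- phase_pool[-1, ]
      if (nrow(phase_pool)) {
        conflict <- spacing_conflict(phase_pool, pick, min_spacing)
        if (any(conflict)) {
          excluded <- bind_rows(
            excluded,
            tibble(probe_id = phase_pool$probe_id[conflict],
                   reason = "overlap"))
          phase_pool <- phase_pool[!conflict, ]
        }
      }
      if (nrow(phase_pool)) {
        dg_cross <- cross_dg_best(phase_pool$sequence, pick$sequence,
                                  conditions)
        add <- if_else(is.finite(dg_cross), dg_cross, 0)
        phase_pool$cross_accrued <- phase_pool$cross_accrued + add
        phase_pool$energy_gap <- phase_pool$dg_on -
          (phase_pool$dg_off_sum + phase_pool$dg_self +
             phase_pool$cross_accrued)
      }
    }
    list(pool = phase_pool, selected = selected, excluded = excluded)
  }
  clean <- pool %>% filter(.data$n_offtargets == 0)
  dirty <- pool %>% filter(.data$n_offtargets > 0)
  ph1 <- run_phase(clean, "no_offtarget", selected, excluded)
  selected <- ph1$selected; excluded <- ph1$excluded
  # overlap removals apply across phases: drop phase-2 candidates that
  # conflict with phase-1 selections before ranking them
  if (nrow(selected) && nrow(dirty)) {
    for (k in seq_len(nrow(selected))) {
      conflict <- spacing_conflict(dirty, selected[k, ], min_spacing)
      if (any(conflict)) {
        excluded <- bind_rows(
          excluded, tibble(probe_id = dirty$probe_id[conflict],
                           reason = "overlap"))
        dirty <- dirty[!conflict, ]
      }
    }
    # phase-1 selections also accrue cross-dimer terms onto phase-2 pool
    for (k in seq_len(nrow(selected))) {
      if (!nrow(dirty)) break
      dg_cross <- cross_dg_best(dirty$sequence, selected$sequence[k],
                                conditions)
      add <- if_else(is.finite(dg_cross), dg_cross, 0)
      dirty$cross_accrued <- dirty$cross_accrued + add
    }
    if (nrow(dirty)) {
      dirty$energy_gap <- dirty$dg_on -
        (dirty$dg_off_sum + dirty$dg_self + dirty$cross_accrued)
    }
  }
  ph2 <- run_phase(dirty, "with_offtarget", selected, excluded)
  selected <- ph2$selected; excluded <- ph2$excluded
  if (nrow(ph2$pool)) {
    excluded <- bind_rows(excluded,
                          tibble(probe_id = ph2$pool$probe_id,
                                 reason = "cap"))
  }
  structure(list(selected = selected, excluded = excluded,
                 max_probes = max_probes, min_spacing = min_spacing),
            class = "fish_selection")
}

# TRUE where a candidate violates min_spacing against the picked probe
# (half-open coordinates on the shared target).
spacing_conflict <- function(pool, pick, min_spacing) {
  same <- pool$target_id == pick$target_id
  c_end <- pool$start + pool$length
  p_end <- pick$start + pick$length
  same & !(pool$start >= p_end + min_spacing |
             c_end + min_spacing <= pick$start)
}

#' @export
print.fish_selection <- function(x, ...) {
  cat("<fish_selection>", nrow(x$selected), "probes selected (cap",
      x$max_probes, ", spacing >=", x$min_spacing, "nt);",
      nrow(x$excluded), "candidates excluded\n")
  invisible(x)
}

#' Evaluate and refine an existing probe set
#'
#' Locates the supplied probe sequences on the target transcript (exact
#' antisense match), evaluates the set as-is through the homology,
#' thermodynamic, equilibrium and statistics stages without re-tiling, ranks
#' probes by their contribution to off-target signal, and optionally removes
#' the worst `remove_k` probes whose expected off-target binding exceeds
#' `removal_threshold`.
#'
#' @param sequences Named character vector of probe sequences (5'->3'), or
#'   unnamed (ids are generated).
#' @param transcriptome A `fish_transcriptome`.
#' @param target_id Target transcript the probes were designed against.
#' @param config A [design_config()]; on-target ids default to `target_id`.
#' @param remove_k Maximum number of probes to remove (default 0:
#'   report-only).
#' @param removal_threshold Expected off-target bindings per cell above
#'   which a probe becomes a removal candidate (default 0).
#' @return List with `probes` (located probes), `skipped` (sequences not
#'   locatable on the target), `evaluation` (a `fish_evaluation`),
#'   `problem_probes` (rankings), `kept`, `removed`.
#' @export
refine_probe_set <- function(sequences, transcriptome, target_id,
                             config = design_config(),
                             remove_k = 0, removal_threshold = 0) {
  if (length(sequences) == 0) abort("empty probe set")
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("probe_", seq_along(sequences))
  }
  tseq <- transcript_sequence(transcriptome, target_id)
  window <- revcomp(unname(sequences))
  pos <- vapply(window, function(w) {
    regexpr(w, tseq, fixed = TRUE)[[1]]
  }, integer(1), USE.NAMES = FALSE)
  skipped <- names(sequences)[pos < 0]
  if (length(skipped)) {
    warn(paste0("probe(s) not locatable on ", target_id, ": ",
                paste(skipped, collapse = ", ")))
  }
  keep <- pos > 0
  if (!any(keep)) abort("no probe could be located on the target")
  probes <- tibble(
    probe_id = names(sequences)[keep],
    target_id = target_id,
    start = pos[keep] - 1L,
    length = nchar(sequences[keep]),
    sequence = unname(sequences[keep])
  )
  on_targets <- config$on_targets %||% target_id
  evaluation <- evaluate_probe_set(probes, transcriptome, config,
                                   on_target_ids = on_targets)
  problems <- evaluation$reports[[1]]
  ranking <- identify_problem_probes(
    evaluation$state,
    evaluation$expression[[evaluation$modes[1]]],
    on_targets, kds = evaluation$kds)
  candidates <- ranking$probe_id[ranking$expected_offtarget >
                                   removal_threshold]
  removed <- head(candidates, remove_k)
  list(probes = probes, skipped = skipped, evaluation = evaluation,
       problem_probes = ranking,
       kept = setdiff(probes$probe_id, removed), removed = removed)
}
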