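#' Design run configuration
#'
#' Collects every tunable of a design or evaluation run with the standard
#' defaults: 20-nt probes, 3-nt minimum spacing, alignments retained at
#' >= 15 matched nt, word size 7, 37 C, 300 mM Na+, 5 nM per probe, 10 um
#' cell radius, and the equal-transcript-expression assumption.
#'
#' @param fasta,annotation,expression Input paths (expression optional).
#' @param expression_level `"transcript"` or `"gene"` (gene-level tables are
#'   imputed to transcripts by isoform count).
#' @param target_id Transcript to tile.
#' @param on_targets Transcripts counted as on-target (default: all isoforms
#'   of the target's gene when an annotation is loaded, else the target).
#' @param probe_length,min_spacing,max_probes Tiling and selection settings.
#' @param temperature_C,sodium_M Hybridization conditions.
#' @param probe_conc_nM Total concentration per probe (nM).
#' @param cell_radius_um Cell radius (um) for copies-to-molar conversion.
#' @param expression_mode One or more of `"equal"`, `"mean_average"`,
#'   `"cell_line"`; the first is used for design-time reporting.
#' @param cell_line Context id for `"cell_line"` mode.
#' @param min_match,word_size Homology-search settings.
#' @param weight_by_expression Weight off-target counts by expression during
#'   ranking (default FALSE).
#' @param seed Integer seed recorded with the run.
#' @param tol,max_iter,damping Equilibrium solver settings.
#' @return A `fish_config` list.
#' @export
design_config <- function(fasta = NULL, annotation = NULL,
                          expression = NULL,
                          expression_level = "transcript",
                          target_id = NULL, on_targets = NULL,
                          probe_length = 20, min_spacing = 3,
                          max_probes = 48,
                          temperature_C = 37, sodium_M = 0.3,
                          probe_conc_nM = 5, cell_radius_um = 10,
                          expression_mode = "equal", cell_line = NULL,
                          min_match = 15, word_size = 7,
                          weight_by_expression = FALSE, seed = 1,
                          tol = 1e-12, max_iter = 10000, damping = 0.5) {
  structure(as.list(environment()), class = "fish_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys match the arguments of
#'   [design_config()].
#' @return A `fish_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(design_config)))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(design_config, vals)
}

resolve_inputs <- function(config) {
  if (is.null(config$fasta)) abort("config$fasta is required")
  if (!file.exists(config$fasta)) {
    abort(paste0("FASTA file not found: ", config$fasta))
  }
  tx <- load_transcriptome(config$fasta, config$annotation)
  expr_tbl <- NULL
  if (!is.null(config$expression)) {
    expr_tbl <- read_expression(config$expression,
                                level = config$expression_level)
    expr_tbl <- tmm_normalize(expr_tbl, level = config$expression_level)
    if (identical(config$expression_level, "gene")) {
      expr_tbl <- impute_isoform_expression(expr_tbl, tx)
    }
  }
  if (is.null(config$target_id)) abort("config$target_id is required")
  if (!config$target_id %in% tx$transcript_id) {
    abort(paste0("target ", config$target_id, " not in transcriptome"))
  }
  on_targets <- config$on_targets
  if (is.null(on_targets)) {
    gene <- tx$gene_id[tx$transcript_id == config$target_id]
    on_targets <- tx$transcript_id[tx$gene_id == gene]
  }
  list(transcriptome = tx, expression = expr_tbl, on_targets = on_targets)
}

mode_expression <- function(mode, expr_tbl, tx, cell_line = NULL) {
  expression_vector(expr_tbl, mode = mode, transcriptome = tx,
                    cell_line = cell_line)
}

#' Evaluate a probe set at equilibrium
#'
#' Runs the evaluation stages for a fixed probe set (no re-tiling): homology
#' search, binding-site map, self/cross-dimer enumeration, dissociation
#' constants, the coupled equilibrium solve and specificity statistics,
#' once per requested expression mode.
#'
#' @param probes Tibble with `probe_id`, `target_id`, `start`, `length`,
#'   `sequence` (selection order is preserved in reports).
#' @param transcriptome A `fish_transcriptome`.
#' @param config A [design_config()].
#' @param on_target_ids On-target transcript ids.
#' @param expr_tbl Normalised transcript-level expression tibble (required
#'   for non-equal modes).
#' @param index Optional prebuilt [build_seed_index()] for the
#'   transcriptome.
#' @return A `fish_evaluation`: `results` (per mode: `state`, `report`,
#'   `expression`), `kds`, `site_map`, `hits`, `probes`, `modes`,
#'   `on_target_ids`, `config`.
#' @export
evaluate_probe_set <- function(probes, transcriptome, config = design_config(),
                               on_target_ids, expr_tbl = NULL,
                               index = NULL) {
  if (nrow(probes) == 0) abort("empty probe set")
  conditions <- thermo_conditions(config$temperature_C, config$sodium_M)
  cell <- cell_model(config$cell_radius_um)
  if (is.null(index)) {
    index <- build_seed_index(transcriptome, word_size = config$word_size)
  }
  hits <- find_hits_all(probes, index, min_match = config$min_match)
  site_map <- build_site_map(hits, transcriptome)
  selfs <- bind_rows(lapply(seq_len(nrow(probes)), function(i) {
    self_alignments(probes[i, ])
  }))
  crosses <- list()
  n <- nrow(probes)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      crosses[[length(crosses) + 1]] <- cross_alignments(probes[i, ],
                                                         probes[j, ])
    }
  }
  crosses <- if (length(crosses)) bind_rows(crosses) else NULL
  kds <- build_dissociation_constants(site_map, selfs, crosses, conditions)
  probe_total <- setNames(rep(config$probe_conc_nM * 1e-9, n),
                          probes$probe_id)
  modes <- config$expression_mode
  results <- list()
  for (mode in modes) {
    expr <- mode_expression(mode, expr_tbl, transcriptome,
                            cell_line = config$cell_line)
    site_tot <- site_map$sites %>%
      left_join(expr, by = c(target_id = "transcript_id")) %>%
      mutate(total_M = site_total_concentration(.data$expression, cell)) %>%
      select("target_id", "site_id", "total_M")
    state <- solve_equilibrium(
      kds, probe_total, site_tot,
      control = list(tol = config$tol, max_iter = config$max_iter,
                     damping = config$damping))
    report <- specificity_report(state, expr, on_target_ids, mode = mode,
                                 probe_order = probes$probe_id, kds = kds)
    results[[mode]] <- list(state = state, report = report,
                            expression = expr)
  }
  structure(list(results = results, kds = kds, site_map = site_map,
                 hits = hits, probes = probes, modes = modes,
                 on_target_ids = on_target_ids, config = config,
                 state = results[[1]]$state,
                 reports = lapply(results, `[[`, "report"),
                 expression = lapply(results, `[[`, "expression")),
            class = "fish_evaluation")
}

#' Design a probe set end-to-end
#'
#' Full pipeline: load inputs, tile candidates, enumerate on/off-target
#' hybridization sites for every candidate, flag rRNA binders, compute
#' thermodynamics, rank by prioritization rank, select greedily with
#' spacing and cross-dimer updates, then evaluate the selected set at
#' equilibrium.
#'
#' @param config A [design_config()] (or path to a YAML config).
#' @return A `fish_design`: `selection`, `evaluation`, `candidates`,
#'   `ranked`, `rrna_flagged`, `metrics`, `config`, `transcriptome`.
#' @export
run_design <- function(config) {
  if (is.character(config)) config <- load_config(config)
  inputs <- resolve_inputs(config)
  tx <- inputs$transcriptome
  conditions <- thermo_conditions(config$temperature_C, config$sodium_M)
  target <- tx[tx$transcript_id == config$target_id, ]
  candidates <- tile_candidates(target, probe_length = config$probe_length)
  index <- build_seed_index(tx, word_size = config$word_size)
  hits <- find_hits_all(candidates, index, min_match = config$min_match)
  site_map <- build_site_map(hits, tx)
  rrna_flagged <- flag_rRNA_probes(site_map, tx)
  selfs <- bind_rows(lapply(seq_len(nrow(candidates)), function(i) {
    self_alignments(candidates[i, ])
  }))
  kds_rank <- build_dissociation_constants(site_map, selfs, NULL, conditions)
  rank_expr <- NULL
  if (config$weight_by_expression) {
    rank_expr <- mode_expression(config$expression_mode[1],
                                 inputs$expression, tx,
                                 cell_line = config$cell_line)
  }
  ranked <- rank_candidates(candidates, site_map, kds_rank,
                            inputs$on_targets,
                            expression = rank_expr,
                            weight_by_expression = config$weight_by_expression)
  selection <- select_probes(ranked, max_probes = config$max_probes,
                             min_spacing = config$min_spacing,
                             conditions = conditions,
                             rrna_flagged = rrna_flagged)
  probes <- selection$selected %>%
    select("probe_id", "target_id", "start", "length", "sequence")
  evaluation <- evaluate_probe_set(probes, tx, config,
                                   on_target_ids = inputs$on_targets,
                                   expr_tbl = inputs$expression,
                                   index = index)
  metrics <- design_metrics(evaluation, selection,
                            target_length = target$length)
  structure(list(selection = selection, evaluation = evaluation,
                 candidates = candidates, ranked = ranked,
                 rrna_flagged = rrna_flagged, metrics = metrics,
                 config = config, transcriptome = tx,
                 on_targets = inputs$on_targets),
            class = "fish_design")
}

#' Summary metrics of an evaluated probe set
#'
#' @param evaluation A `fish_evaluation`.
#' @param selection Optional `fish_selection` (adds coverage/exclusions).
#' @param target_length Target length in nt (for coverage).
#' @param mode Expression mode to report (default: the evaluation's first).
#' @return Named list of scalar metrics.
#' @export
design_metrics <- function(evaluation, selection = NULL,
                           target_length = NULL, mode = NULL) {
  mode <- mode %||% evaluation$modes[1]
  rep <- evaluation$results[[mode]]$report
  n_vals_on <- seq_along(rep$n_on) - 1
  n_vals_off <- seq_along(rep$n_off) - 1
  on_total <- sum(rep$n_on)
  out <- list(
    n_probes = nrow(evaluation$probes),
    mode = mode,
    mean_probes_bound_per_on_target =
      if (on_total > 0) sum(n_vals_on * rep$n_on) / on_total else NA_real_,
    total_offtarget_bindings = sum(n_vals_off * rep$n_off),
    specificity_load = rep$specificity_load,
    off_on_ratio = rep$off_on_ratio,
    equilibrium_residual = evaluation$results[[mode]]$state$residual,
    equilibrium_iterations = evaluation$results[[mode]]$state$iterations
  )
  if (!is.null(target_length)) {
    out$coverage_pct <- 100 * sum(evaluation$probes$length) / target_length
  }
  if (!is.null(selection)) {
    out$n_excluded_rrna <- sum(selection$excluded$reason == "rRNA")
    out$n_zero_offtarget <-
      sum(selection$selected$n_offtargets == 0)
  }
  out
}

#' Evaluate an existing probe FASTA against a transcriptome
#'
#' Locates each probe on the configured target by exact antisense match and
#' evaluates the set under each requested expression mode. Evaluating a
#' design's own exported probes reproduces the design-time metrics exactly.
#'
#' @param config A [design_config()] or YAML path.
#' @param probe_fasta FASTA of probe sequences (ids preserved; file order =
#'   selection order).
#' @return A `fish_evaluation` with a `metrics` field per mode.
#' @export
run_evaluate <- function(config, probe_fasta) {
  if (is.character(config)) config <- load_config(config)
  inputs <- resolve_inputs(config)
  tx <- inputs$transcriptome
  seqs <- Biostrings::readBStringSet(probe_fasta)
  if (length(seqs) == 0) abort("empty probe FASTA")
  sequences <- setNames(toupper(as.character(seqs)),
                        sub("\\s.*$", "", names(seqs)))
  tseq <- transcript_sequence(tx, config$target_id)
  pos <- vapply(revcomp(unname(sequences)), function(w) {
    regexpr(w, tseq, fixed = TRUE)[[1]]
  }, integer(1), USE.NAMES = FALSE)
  if (any(pos < 0)) {
    abort(paste0("probe(s) not locatable on target: ",
                 paste(names(sequences)[pos < 0], collapse = ", ")))
  }
  probes <- tibble(probe_id = names(sequences),
                   target_id = config$target_id,
                   start = pos - 1L,
                   length = nchar(unname(sequences)),
                   sequence = unname(sequences))
  evaluation <- evaluate_probe_set(probes, tx, config,
                                   on_target_ids = inputs$on_targets,
                                   expr_tbl = inputs$expression)
  evaluation$metrics <- lapply(evaluation$modes, function(m) {
    design_metrics(evaluation, mode = m)
  })
  names(evaluation$metrics) <- evaluation$modes
  evaluation
}

#' Sweep hybridization conditions for a probe set
#'
#' Re-evaluates a probe set over a grid of temperatures, sodium
#' concentrations and/or probe concentrations, returning one row of summary
#' metrics per condition.
#'
#' @param config A [design_config()] or YAML path.
#' @param probes Probe tibble (as in [evaluate_probe_set()]).
#' @param sweep Named list of condition vectors; any of `temperature_C`,
#'   `sodium_M`, `probe_conc_nM`.
#' @return Tibble with the condition columns plus
#'   `mean_probes_bound_per_on_target`, `total_offtarget_bindings`,
#'   `specificity_load`.
#' @export
run_simulation <- function(config, probes, sweep) {
  if (is.character(config)) config <- load_config(config)
  inputs <- resolve_inputs(config)
  allowed <- c("temperature_C", "sodium_M", "probe_conc_nM")
  bad <- setdiff(names(sweep), allowed)
  if (length(bad)) {
    abort(paste0("unsupported sweep variable(s): ", paste(bad, collapse = ", ")))
  }
  grid <- expand.grid(sweep, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cfg <- config
    for (v in names(grid)) cfg[[v]] <- grid[k, v]
    ev <- evaluate_probe_set(probes, inputs$transcriptome, cfg,
                             on_target_ids = inputs$on_targets,
                             expr_tbl = inputs$expression)
    m <- design_metrics(ev)
    bind_cols(as_tibble(grid[k, , drop = FALSE]),
              tibble(mean_probes_bound_per_on_target =
                       m$mean_probes_bound_per_on_target,
                     total_offtarget_bindings = m$total_offtarget_bindings,
                     specificity_load = m$specificity_load))
  })
  bind_rows(rows)
}

#' @export
print.fish_design <- function(x, ...) {
  m <- x$metrics
  cat("<fish_design>", m$n_probes, "probes on", x$config$target_id, "\n",
      " mean probes bound per on-target molecule:",
      format(m$mean_probes_bound_per_on_target, digits = 4), "\n",
      " total off-target bindings/cell:",
      format(m$total_offtarget_bindings, digits = 4), "\n",
      " specificity load:", format(m$specificity_load, digits = 4), "\n")
  invisible(x)
}

#' @export
print.fish_evaluation <- function(x, ...) {
  cat("<fish_evaluation>", nrow(x$probes), "probes under mode(s):",
      paste(x$modes, collapse = ", "), "\n")
  invisible(x)
}
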