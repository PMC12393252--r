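#' Per-site bound probability at equilibrium
#'
#' The probability that a target site is occupied by any probe:
#' `p(j,s) = X / (X + 1)` with `X = sum_i C_i,free / Kd(i,j,s)`.
#'
#' @param state A converged `fish_equilibrium`.
#' @param kds A `fish_kd` (defaults to the one stored on the state).
#' @return Tibble `target_id`, `site_id`, `p`.
#' @export
site_bound_probability <- function(state, kds = state$kds) {
  x <- setNames(state$probe$free_M, state$probe$probe_id)
  st <- kds$site %>% filter(.data$probe_id %in% names(x))
  occ <- st %>%
    mutate(term = unname(x[.data$probe_id]) / .data$kd) %>%
    group_by(.data$target_id, .data$site_id) %>%
    summarise(X = sum(.data$term), .groups = "drop")
  state$site %>%
    select("target_id", "site_id") %>%
    left_join(occ, by = c("target_id", "site_id")) %>%
    mutate(X = if_else(is.na(.data$X), 0, .data$X),
           p = .data$X / (.data$X + 1)) %>%
    select("target_id", "site_id", "p")
}

#' Poisson-Binomial bound-count distribution
#'
#' Distribution of the number of occupied sites on one target, given
#' independent per-site bound probabilities. Computed by iterative
#' convolution — the numerically stable expansion of the Poisson-Binomial
#' probability-generating function product.
#'
#' @param p Numeric vector of per-site bound probabilities in `[0, 1]`.
#' @return Numeric vector of length `length(p) + 1`: `P(n bound)` for
#'   `n = 0..N`.
#' @export
bound_count_distribution <- function(p) {
  if (any(p < 0 | p > 1)) abort("site probabilities must lie in [0, 1]")
  pmf <- 1
  for (ps in p) {
    pmf <- c(pmf * (1 - ps), 0) + c(0, pmf * ps)
  }
  pmf
}

#' On- and off-target bound-count spectra
#'
#' Expression-weighted molecule counts per cell with `n` probes bound:
#' `Non(n) = sum_{j in on} Expression_j P(n | j)` and likewise `Noff(n)`
#' over off-targets, with expression in RNA copies per cell (under the
#' equal-expression mode every target counts one copy, so the spectra are
#' per-copy rates).
#'
#' @param pmfs Named list, target id -> bound-count pmf (vectors may have
#'   different lengths; they are zero-padded to a common support).
#' @param expression Tibble `transcript_id`, `expression` (copies per cell)
#'   as returned by [expression_vector()].
#' @param on_target_ids Character vector of designated on-target transcripts
#'   (multiple isoforms may be listed).
#' @return List with `n_on`, `n_off` (numeric vectors over `n = 0..Nmax`)
#'   and `n_max`.
#' @export
on_off_counts <- function(pmfs, expression, on_target_ids) {
  unknown <- setdiff(on_target_ids, expression$transcript_id)
  if (length(unknown)) {
    abort(paste0("unknown on-target id(s): ", paste(unknown, collapse = ", ")))
  }
  n_max <- max(c(0L, lengths(pmfs) - 1L))
  expr <- setNames(expression$expression, expression$transcript_id)
  n_on <- numeric(n_max + 1)
  n_off <- numeric(n_max + 1)
  for (j in names(pmfs)) {
    v <- pmfs[[j]]
    v <- c(v, rep(0, n_max + 1 - length(v)))
    w <- expr[[j]]
    if (is.null(w) || is.na(w)) w <- 0
    if (j %in% on_target_ids) n_on <- n_on + w * v else n_off <- n_off + w * v
  }
  list(n_on = n_on, n_off = n_off, n_max = n_max)
}

#' Probe-set specificity load
#'
#' Total probes bound to off-targets divided by the mean number of probes
#' bound per on-target molecule:
#' `load = (sum_n n Noff(n)) / (sum_n n Non(n) / sum_n Non(n))`.
#'
#' @param n_on,n_off Spectra from [on_off_counts()] (index 1 is `n = 0`).
#' @return Scalar load (>= 0).
#' @export
specificity_load <- function(n_on, n_off) {
  n_vals_on <- seq_along(n_on) - 1
  n_vals_off <- seq_along(n_off) - 1
  on_bindings <- sum(n_vals_on * n_on)
  if (on_bindings <= 0) abort("zero on-target binding: specificity load undefined")
  mean_on <- on_bindings / sum(n_on)
  sum(n_vals_off * n_off) / mean_on
}

#' Per-probe off-target binding and accumulation curve
#'
#' Attributes each off-target site's expected occupancy (copies per cell)
#' to probes in proportion to their term `C_i,free / Kd(i,j,s)` in the
#' site-bound probability, then accumulates over the probe set in selection
#' order.
#'
#' @param state A converged `fish_equilibrium`.
#' @param expression Tibble `transcript_id`, `expression`.
#' @param on_target_ids Designated on-target transcript ids.
#' @param probe_order Probe ids in selection order (defaults to the state's
#'   probe order).
#' @param kds A `fish_kd`.
#' @return Tibble `probe_id`, `expected_offtarget` (expected off-target
#'   bound molecules per cell attributable to the probe), `cumulative`;
#'   attribute `off_on_ratio` holds total off- over on-target expected
#'   bindings.
#' @export
offtarget_accumulation <- function(state, expression, on_target_ids,
                                   probe_order = NULL, kds = state$kds) {
  probe_order <- probe_order %||% state$probe$probe_id
  shares <- probe_site_occupancy(state, expression, kds)
  off <- shares %>% filter(!.data$target_id %in% on_target_ids)
  on <- shares %>% filter(.data$target_id %in% on_target_ids)
  per_probe <- off %>%
    group_by(.data$probe_id) %>%
    summarise(expected_offtarget = sum(.data$expected), .groups = "drop")
  out <- tibble(probe_id = probe_order) %>%
    left_join(per_probe, by = "probe_id") %>%
    mutate(expected_offtarget = if_else(is.na(.data$expected_offtarget), 0,
                                        .data$expected_offtarget),
           cumulative = cumsum(.data$expected_offtarget))
  on_total <- sum(on$expected)
  attr(out, "off_on_ratio") <-
    if (on_total > 0) sum(off$expected) / on_total else NA_real_
  out
}

# Expected bound molecules per cell, per (probe, site): the probe's share of
# Eq-14-style site occupancy, scaled by the target's expression.
probe_site_occupancy <- function(state, expression, kds = state$kds) {
  x <- setNames(state$probe$free_M, state$probe$probe_id)
  expr <- setNames(expression$expression, expression$transcript_id)
  st <- kds$site %>% filter(.data$probe_id %in% names(x))
  st %>%
    mutate(term = unname(x[.data$probe_id]) / .data$kd) %>%
    group_by(.data$target_id, .data$site_id) %>%
    mutate(share = .data$term / (sum(.data$term) + 1)) %>%
    ungroup() %>%
    mutate(w = unname(expr[.data$target_id]),
           w = if_else(is.na(.data$w), 0, .data$w),
           expected = .data$w * .data$share) %>%
    select("probe_id", "target_id", "site_id", "expected")
}

#' Rank probes by their contribution to off-target signal
#'
#' Two rankings: by per-probe expected off-target bindings, and by the
#' leave-one-out reduction in the number of off-targets carrying two or more
#' bound probes (`sum_{n>=2} Noff(n)`), recomputed from the same free
#' concentrations with the probe's site terms removed.
#'
#' @inheritParams offtarget_accumulation
#' @return Tibble `probe_id`, `expected_offtarget`, `rank_total`,
#'   `loo_multi_reduction`, `rank_multi`, sorted by `rank_total`.
#' @export
identify_problem_probes <- function(state, expression, on_target_ids,
                                    kds = state$kds) {
  x <- setNames(state$probe$free_M, state$probe$probe_id)
  probes <- state$probe$probe_id
  acc <- offtarget_accumulation(state, expression, on_target_ids,
                                probe_order = probes, kds = kds)
  off_sites <- kds$site %>%
    filter(!.data$target_id %in% on_target_ids,
           .data$probe_id %in% probes) %>%
    mutate(term = unname(x[.data$probe_id]) / .data$kd)
  expr <- setNames(expression$expression, expression$transcript_id)
  multi_off <- function(drop_probe = NULL) {
    st <- off_sites
    if (!is.null(drop_probe)) st <- st[st$probe_id != drop_probe, ]
    if (!nrow(st)) return(0)
    ps <- st %>%
      group_by(.data$target_id, .data$site_id) %>%
      summarise(X = sum(.data$term), .groups = "drop") %>%
      mutate(p = .data$X / (.data$X + 1))
    total <- 0
    for (j in unique(ps$target_id)) {
      pmf <- bound_count_distribution(ps$p[ps$target_id == j])
      w <- expr[[j]]; if (is.null(w) || is.na(w)) w <- 0
      if (length(pmf) >= 3) total <- total + w * sum(pmf[-(1:2)])
    }
    total
  }
  base_multi <- multi_off()
  loo <- vapply(probes, function(p) base_multi - multi_off(p), numeric(1))
  acc %>%
    mutate(loo_multi_reduction = unname(loo[.data$probe_id])) %>%
    mutate(rank_total = rank(-.data$expected_offtarget, ties.method = "first"),
           rank_multi = rank(-.data$loo_multi_reduction,
                             ties.method = "first")) %>%
    arrange(.data$rank_total) %>%
    select("probe_id", "expected_offtarget", "rank_total",
           "loo_multi_reduction", "rank_multi")
}

#' Spot signal-to-noise ratio
#'
#' `SNR = (mu_signal - mu_background) / sigma_background`.
#'
#' @param mu_signal Maximum spot intensity.
#' @param mu_background Mean local background intensity.
#' @param sigma_background Background standard deviation (> 0).
#' @return SNR (vectorised).
#' @export
snr <- function(mu_signal, mu_background, sigma_background) {
  if (any(sigma_background <= 0)) abort("sigma_background must be > 0")
  (mu_signal - mu_background) / sigma_background
}

#' Specificity report for an evaluated probe set
#'
#' Bundles per-site bound probabilities, per-target Poisson-Binomial
#' bound-count distributions, on/off-target spectra, specificity load and
#' per-probe off-target attribution into one result object.
#'
#' @param state A converged `fish_equilibrium`.
#' @param expression Tibble `transcript_id`, `expression`.
#' @param on_target_ids Designated on-target transcript ids.
#' @param mode Label of the expression mode used (for reporting).
#' @param probe_order Probe ids in selection order.
#' @param kds A `fish_kd`.
#' @return A `fish_specificity` object with fields `site_p`, `pmfs`,
#'   `n_on`, `n_off`, `specificity_load`, `expected_off_per_probe`,
#'   `accumulation`, `off_on_ratio`, `mode`.
#' @export
specificity_report <- function(state, expression, on_target_ids,
                               mode = "equal", probe_order = NULL,
                               kds = state$kds) {
  site_p <- site_bound_probability(state, kds)
  pmfs <- lapply(split(site_p$p, site_p$target_id), bound_count_distribution)
  counts <- on_off_counts(pmfs, expression, on_target_ids)
  load <- tryCatch(specificity_load(counts$n_on, counts$n_off),
                   error = function(e) NA_real_)
  acc <- offtarget_accumulation(state, expression, on_target_ids,
                                probe_order = probe_order, kds = kds)
  structure(list(
    site_p = site_p, pmfs = pmfs,
    n_on = counts$n_on, n_off = counts$n_off,
    specificity_load = load,
    expected_off_per_probe = mean(acc$expected_offtarget),
    accumulation = acc,
    off_on_ratio = attr(acc, "off_on_ratio"),
    mode = mode, on_target_ids = on_target_ids),
    class = "fish_specificity")
}

#' @export
print.fish_specificity <- function(x, ...) {
  n_off_total <- sum((seq_along(x$n_off) - 1) * x$n_off)
  cat("<fish_specificity> mode:", x$mode, "\n",
      " expected off-target bindings/cell:", format(n_off_total, digits = 4),
      "\n  specificity load:", format(x$specificity_load, digits = 4), "\n")
  invisible(x)
}
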