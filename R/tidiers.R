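# broom-style tidiers for the result objects.

#' Tidy an equilibrium state
#'
#' One row per species with its concentration: free probes, self-dimers,
#' cross-dimers, free sites and bound probe-site complexes.
#'
#' @param x A `fish_equilibrium`.
#' @param ... Unused.
#' @return Tibble `species`, `id`, `conc_M`.
#' @export
tidy.fish_equilibrium <- function(x, ...) {
  bind_rows(
    tibble(species = "probe_free", id = x$probe$probe_id,
           conc_M = x$probe$free_M),
    tibble(species = "probe_self", id = x$probe$probe_id,
           conc_M = x$probe$self_M),
    tibble(species = "cross_dimer",
           id = paste(x$cross$probe_i, x$cross$probe_j, sep = ":"),
           conc_M = x$cross$conc_M),
    tibble(species = "site_free",
           id = paste(x$site$target_id, x$site$site_id, sep = ":"),
           conc_M = x$site$free_M),
    tibble(species = "bound",
           id = paste(x$bound$probe_id, x$bound$target_id, x$bound$site_id,
                      sep = ":"),
           conc_M = x$bound$conc_M))
}

#' @rdname tidy.fish_equilibrium
#' @export
glance.fish_equilibrium <- function(x, ...) {
  tibble(n_probes = nrow(x$probe), n_sites = nrow(x$site),
         residual = x$residual, iterations = x$iterations,
         converged = x$converged, method = x$method)
}

#' Tidy a specificity report
#'
#' @param x A `fish_specificity`.
#' @param ... Unused.
#' @return Tibble `n`, `n_on`, `n_off`: expected molecules per cell with
#'   `n` probes bound.
#' @export
tidy.fish_specificity <- function(x, ...) {
  tibble(n = seq_along(x$n_on) - 1, n_on = x$n_on, n_off = x$n_off)
}

#' @rdname tidy.fish_specificity
#' @export
glance.fish_specificity <- function(x, ...) {
  n_vals <- seq_along(x$n_off) - 1
  tibble(mode = x$mode,
         specificity_load = x$specificity_load,
         total_offtarget_bindings = sum(n_vals * x$n_off),
         expected_off_per_probe = x$expected_off_per_probe,
         off_on_ratio = x$off_on_ratio)
}

#' Tidy a selection result
#'
#' @param x A `fish_selection`.
#' @param ... Unused.
#' @return The selected-probe tibble with rank fields.
#' @export
tidy.fish_selection <- function(x, ...) {
  as_tibble(x$selected)
}

#' @rdname tidy.fish_selection
#' @export
glance.fish_selection <- function(x, ...) {
  tibble(n_selected = nrow(x$selected),
         n_excluded = nrow(x$excluded),
         max_probes = x$max_probes, min_spacing = x$min_spacing)
}

#' Tidy a design result
#'
#' @param x A `fish_design`.
#' @param ... Unused.
#' @return The selected-probe tibble.
#' @export
tidy.fish_design <- function(x, ...) tidy(x$selection)

#' @rdname tidy.fish_design
#' @export
glance.fish_design <- function(x, ...) {
  as_tibble(x$metrics[vapply(x$metrics, is.numeric, logical(1))])
}
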