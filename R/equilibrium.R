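#' Cell geometry model
#'
#' @param radius_um Cell radius in micrometres (default 10, approximating a
#'   Jurkat cell).
#' @return List with `radius_um` and `volume_L` (sphere volume in litres).
#' @export
cell_model <- function(radius_um = 10) {
  if (radius_um <= 0) abort("cell radius must be positive")
  list(radius_um = radius_um,
       volume_L = (4 / 3) * pi * radius_um^3 * 1e-15)
}

#' Parity coefficient of a cross-dimer reaction
#'
#' Stoichiometric factor of a probe in a cross-dimerization reaction: 2 when
#' a probe dimerizes with another copy of itself, 1 between distinct probes.
#'
#' @param i,j Probe indices or ids.
#' @return 1 or 2 (vectorised).
#' @export
parity <- function(i, j) ifelse(i == j, 2, 1)

#' Convert per-cell RNA copies to molar concentration
#'
#' Expression (nTPM, treated as RNA copies per cell) divided by the cell
#' volume and Avogadro's number.
#'
#' @param ntpm Non-negative expression value(s), copies per cell.
#' @param cell A [cell_model()].
#' @return Concentration(s) in molar.
#' @export
site_total_concentration <- function(ntpm, cell = cell_model()) {
  if (any(ntpm < 0)) abort("nTPM must be non-negative")
  ntpm / (cell$volume_L * .AVOGADRO)
}

#' Solve the coupled probe-target binding equilibrium
#'
#' Solves the steady-state mass-action system coupling probe-target site
#' binding, probe self-hybridization and probe cross-dimerization. Free
#' probe concentrations follow the recursion
#' `C_free = C_total / (1 + 1/Kd_self + sum_j alpha_ij C_j,free / Kd_cross
#'  + sum_{j,s} C_T(j,s),free / Kd_site)`,
#' with free site concentrations eliminated through
#' `C_T,free = C_T,total / (1 + sum_i C_i,free / Kd_site)`.
#' The solver is a damped fixed-point (Picard) iteration started at
#' `free = total`; if it has not converged after `newton_after` iterations a
#' damped Newton iteration with a finite-difference Jacobian takes over.
#' Converged free concentrations are back-substituted into the mass-action
#' relations to recover self-dimer, cross-dimer and bound-complex
#' concentrations.
#'
#' @param kds A `fish_kd` from [build_dissociation_constants()].
#' @param probe_total_M Named numeric vector of total probe concentrations
#'   (molar); names are probe ids.
#' @param site_total_M Tibble with `target_id`, `site_id`, `total_M`.
#' @param control List of solver settings: `tol` (relative fixed-point
#'   tolerance, default 1e-12), `max_iter` (default 10000), `damping`
#'   (default 0.5), `newton_after` (default 1000).
#' @return A `fish_equilibrium` object: tibbles `probe` (`probe_id`,
#'   `total_M`, `free_M`, `self_M`), `cross` (`probe_i`, `probe_j`,
#'   `conc_M`), `site` (`target_id`, `site_id`, `total_M`, `free_M`),
#'   `bound` (`probe_id`, `target_id`, `site_id`, `conc_M`), and fields
#'   `residual`, `iterations`, `converged`, `method`.
#' @export
solve_equilibrium <- function(kds, probe_total_M, site_total_M,
                              control = list()) {
  ctl <- utils::modifyList(
    list(tol = 1e-12, max_iter = 10000, damping = 0.5, newton_after = 1000),
    control)
  probes <- names(probe_total_M)
  if (is.null(probes)) abort("probe_total_M must be a named vector")
  if (any(probe_total_M < 0)) abort("probe totals must be >= 0")
  if (any(site_total_M$total_M < 0)) abort("site totals must be >= 0")
  np <- length(probes)
  sites <- site_total_M
  ns <- nrow(sites)
  skey <- paste(sites$target_id, sites$site_id)
  # sparse site triplets
  st <- kds$site %>% filter(.data$probe_id %in% probes)
  st_p <- match(st$probe_id, probes)
  st_s <- match(paste(st$target_id, st$site_id), skey)
  keep <- !is.na(st_s)
  st <- st[keep, ]; st_p <- st_p[keep]; st_s <- st_s[keep]
  if (any(st$kd <= 0)) abort("all Kd must be > 0")
  st_ka <- 1 / st$kd
  # self terms
  ka_self <- rep(0, np)
  if (nrow(kds$self)) {
    m <- match(kds$self$probe_id, probes)
    ok <- !is.na(m)
    ka_self[m[ok]] <- 1 / kds$self$kd[ok]
  }
  # cross pairs expanded to both directions, alpha applied
  cr <- kds$cross %>%
    filter(.data$probe_i %in% probes, .data$probe_j %in% probes)
  if (nrow(cr)) {
    ci <- match(cr$probe_i, probes); cj <- match(cr$probe_j, probes)
    hetero <- ci != cj
    cross_i <- c(ci, cj[hetero])
    cross_j <- c(cj, ci[hetero])
    cross_ka <- c(1 / cr$kd, (1 / cr$kd)[hetero])
    cross_alpha <- parity(cross_i, cross_j)
  } else {
    cross_i <- integer(0); cross_j <- integer(0)
    cross_ka <- numeric(0); cross_alpha <- numeric(0)
  }
  total <- unname(probe_total_M)
  s_tot <- sites$total_M

  site_free_of <- function(x) {
    occ <- rep(0, ns)
    if (length(st_ka)) {
      tmp <- rowsum(x[st_p] * st_ka, st_s)
      occ[as.integer(rownames(tmp))] <- tmp[, 1]
    }
    s_tot / (1 + occ)
  }
  denom_of <- function(x, sfree) {
    d <- 1 + ka_self
    if (length(cross_ka)) {
      add <- rowsum(cross_alpha * x[cross_j] * cross_ka, cross_i)
      d[as.integer(rownames(add))] <- d[as.integer(rownames(add))] + add[, 1]
    }
    if (length(st_ka)) {
      add <- rowsum(sfree[st_s] * st_ka, st_p)
      d[as.integer(rownames(add))] <- d[as.integer(rownames(add))] + add[, 1]
    }
    d
  }
  fp_map <- function(x) total / denom_of(x, site_free_of(x))

  x <- total
  it <- 0L; res <- Inf; method <- "picard"
  scale_ref <- max(total, 1e-300)
  while (it < ctl$max_iter) {
    it <- it + 1L
    x_new <- fp_map(x)
    res <- max(abs(x_new - x) / scale_ref)
    x <- (1 - ctl$damping) * x + ctl$damping * x_new
    if (res <= ctl$tol) break
    if (it == ctl$newton_after && res > ctl$tol) {
      method <- "picard+newton"
      x <- newton_refine(x, fp_map, total, ctl)
      res <- max(abs(fp_map(x) - x) / scale_ref)
      if (res <= ctl$tol) break
    }
  }
  if (res > ctl$tol) {
    abort(sprintf(
      "equilibrium solver did not converge: residual %.3e after %d iterations",
      res, it))
  }
  sfree <- site_free_of(x)
  # back-substitution (mass action)
  self_M <- x * ka_self
  if (length(cross_ka) && nrow(cr)) {
    ci <- match(cr$probe_i, probes); cj <- match(cr$probe_j, probes)
    cross_tbl <- tibble(probe_i = cr$probe_i, probe_j = cr$probe_j,
                        conc_M = x[ci] * x[cj] / cr$kd)
  } else {
    cross_tbl <- tibble(probe_i = character(), probe_j = character(),
                        conc_M = numeric())
  }
  bound_tbl <- tibble(
    probe_id = st$probe_id, target_id = st$target_id, site_id = st$site_id,
    conc_M = sfree[st_s] * x[st_p] * st_ka)
  structure(list(
    probe = tibble(probe_id = probes, total_M = total, free_M = x,
                   self_M = self_M),
    cross = cross_tbl,
    site = tibble(target_id = sites$target_id, site_id = sites$site_id,
                  total_M = s_tot, free_M = sfree),
    bound = bound_tbl,
    residual = res, iterations = it,
    converged = TRUE, method = method,
    kds = kds),
    class = "fish_equilibrium")
}

# Damped Newton on F(x) = x - fp_map(x) with finite-difference Jacobian;
# keeps iterates positive by step halving.
newton_refine <- function(x, fp_map, total, ctl, steps = 50) {
  n <- length(x)
  scale_ref <- max(total, 1e-300)
  for (k in seq_len(steps)) {
    fx <- x - fp_map(x)
    if (max(abs(fx)) / scale_ref <= ctl$tol) return(x)
    J <- matrix(0, n, n)
    h <- pmax(abs(x) * 1e-7, 1e-16 * scale_ref)
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- xp[j] + h[j]
      J[, j] <- ((xp - fp_map(xp)) - fx) / h[j]
    }
    step <- tryCatch(solve(J, fx), error = function(e) fx)
    lambda <- 1
    repeat {
      x_try <- x - lambda * step
      if (all(x_try > 0) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- pmax(x_try, 0)
  }
  x
}

#' Complete an equilibrium state with complex concentrations
#'
#' Back-substitutes converged free concentrations into the mass-action
#' relations: `C_self = C_free / Kd_self`, `C_cross(i,j) = C_i,free *
#' C_j,free / Kd_cross`, `C_bound(i,j,s) = C_T,free * C_i,free / Kd_site`.
#' [solve_equilibrium()] already returns a completed state; this function
#' recomputes the complex tables from the state's free concentrations.
#'
#' @param state A `fish_equilibrium`.
#' @param kds A `fish_kd` (defaults to the one stored on the state).
#' @return The state with `probe$self_M`, `cross` and `bound` recomputed.
#' @export
complex_concentrations <- function(state, kds = state$kds) {
  probes <- state$probe$probe_id
  x <- setNames(state$probe$free_M, probes)
  ka_self <- setNames(rep(0, length(probes)), probes)
  if (nrow(kds$self)) {
    ok <- kds$self$probe_id %in% probes
    ka_self[kds$self$probe_id[ok]] <- 1 / kds$self$kd[ok]
  }
  state$probe$self_M <- unname(x * ka_self)
  cr <- kds$cross %>%
    filter(.data$probe_i %in% probes, .data$probe_j %in% probes)
  state$cross <- tibble(probe_i = cr$probe_i, probe_j = cr$probe_j,
                        conc_M = x[cr$probe_i] * x[cr$probe_j] / cr$kd)
  sfree <- setNames(state$site$free_M,
                    paste(state$site$target_id, state$site$site_id))
  st <- kds$site %>% filter(.data$probe_id %in% probes,
                            paste(.data$target_id, .data$site_id) %in%
                              names(sfree))
  state$bound <- tibble(
    probe_id = st$probe_id, target_id = st$target_id, site_id = st$site_id,
    conc_M = unname(sfree[paste(st$target_id, st$site_id)]) *
      unname(x[st$probe_id]) / st$kd)
  state
}

#' @export
print.fish_equilibrium <- function(x, ...) {
  cat("<fish_equilibrium>", nrow(x$probe), "probes,", nrow(x$site),
      "sites; residual", format(x$residual, digits = 3), "after",
      x$iterations, "iterations (", x$method, ")\n")
  invisible(x)
}
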