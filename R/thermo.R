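#' Hybridization conditions
#'
#' @param temperature_C Hybridization temperature in Celsius (default 37).
#' @param sodium_M Monovalent sodium concentration in molar (default 0.3).
#' @return A `fish_conditions` list with `temperature_K`, `sodium_M` and the
#'   gas constant `R` in kcal/(mol K).
#' @export
thermo_conditions <- function(temperature_C = 37, sodium_M = 0.3) {
  if (sodium_M <= 0) abort("sodium_M must be > 0")
  tK <- temperature_C + 273.15
  if (tK <= 0) abort("temperature must be above absolute zero")
  structure(list(temperature_K = tK, sodium_M = sodium_M, R = .GAS_CONSTANT),
            class = "fish_conditions")
}

.nn_cache <- new.env(parent = emptyenv())

#' Unified DNA/DNA nearest-neighbor parameter table
#'
#' @return Data frame with columns `term`, `dh` (kcal/mol), `ds`
#'   (cal/(mol K)); stack rows are keyed by the 5'->3' dinucleotide of one
#'   strand, plus `initiation` and `terminal_at` rows.
#' @export
nn_parameters <- function() {
  if (is.null(.nn_cache$tab)) {
    path <- system.file("extdata", "nn_unified_dna.csv",
                        package = "fishprobes")
    .nn_cache$tab <- utils::read.csv(path, comment.char = "#",
                                     stringsAsFactors = FALSE)
    .nn_cache$dh <- setNames(.nn_cache$tab$dh, .nn_cache$tab$term)
    .nn_cache$ds <- setNames(.nn_cache$tab$ds, .nn_cache$tab$term)
  }
  .nn_cache$tab
}

nn_lookup <- function() {
  nn_parameters()
  list(dh = .nn_cache$dh, ds = .nn_cache$ds)
}

#' Nearest-neighbor duplex energy of an aligned pair
#'
#' Splits a gapped pairwise alignment at mismatches and gaps into perfectly
#' matched segments. Segments of at least 2 bp contribute the sum of their
#' unified nearest-neighbor stack enthalpies/entropies; one duplex-initiation
#' term is applied per duplex, plus a terminal A.T penalty for each duplex
#' end closing on an A.T pair. The entropy receives the sodium correction
#' `dS + 0.368 * n_stacks * ln[Na+]`, and the free energy is evaluated at
#' the condition temperature as `dG = dH - T * dS / 1000`.
#'
#' The aligned pair follows the hit-table convention: two equal-length gapped
#' strings in which identical characters mark paired bases (probe versus
#' target-complement). An alignment with no matched segment of >= 2 bp has
#' no stable duplex (`stable = FALSE`, infinite `dg`).
#'
#' @param aln_a,aln_b The two gapped alignment strings.
#' @param conditions A [thermo_conditions()] object.
#' @return List with `dh` (kcal/mol), `ds` (cal/(mol K), salt-corrected),
#'   `dg` (kcal/mol at temperature), `n_stacks`, `stable`.
#' @export
nn_duplex_energy <- function(aln_a, aln_b, conditions = thermo_conditions()) {
  if (nchar(aln_a) != nchar(aln_b)) {
    abort("aligned strands must have equal length")
  }
  a <- strsplit(aln_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln_b, "", fixed = TRUE)[[1]]
  matched <- a == b & a != "-" & a != "N"
  r <- rle(matched)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- which(r$values & r$lengths >= 2)
  if (!length(seg)) {
    return(list(dh = NA_real_, ds = NA_real_, dg = Inf, n_stacks = 0L,
                stable = FALSE))
  }
  lk <- nn_lookup()
  dh <- 0; ds <- 0; n_stacks <- 0L
  for (k in seg) {
    run <- a[starts[k]:ends[k]]
    stacks <- paste0(run[-length(run)], run[-1])
    dh <- dh + sum(lk$dh[stacks])
    ds <- ds + sum(lk$ds[stacks])
    n_stacks <- n_stacks + length(stacks)
  }
  dh <- dh + lk$dh[["initiation"]]
  ds <- ds + lk$ds[["initiation"]]
  first_base <- a[starts[seg[1]]]
  last_base <- a[ends[seg[length(seg)]]]
  n_term_at <- sum(c(first_base, last_base) %in% c("A", "T"))
  dh <- dh + n_term_at * lk$dh[["terminal_at"]]
  ds <- ds + n_term_at * lk$ds[["terminal_at"]]
  ds <- ds + 0.368 * n_stacks * log(conditions$sodium_M)
  dg <- dh - conditions$temperature_K * ds / 1000
  list(dh = unname(dh), ds = unname(ds), dg = unname(dg),
       n_stacks = n_stacks, stable = TRUE)
}

# Vectorised duplex energies for a table of aligned pairs.
nn_energy_batch <- function(aln_a, aln_b, conditions) {
  res <- purrr::map2(aln_a, aln_b, nn_duplex_energy, conditions = conditions)
  tibble(dh = map_dbl(res, "dh"), ds = map_dbl(res, "ds"),
         dg = map_dbl(res, "dg"), stable = purrr::map_lgl(res, "stable"))
}

#' Dissociation constant from configuration free energies
#'
#' All binding configurations of a pair contribute to a single bound-state
#' partition function `Ka = sum_l exp(-dG_l / RT)`; the dissociation constant
#' is its reciprocal — molar for bimolecular reactions (1 M standard state),
#' dimensionless for unimolecular self-hybridization. No configurations
#' means no stable interaction (`Kd = Inf`).
#'
#' @param dg Numeric vector of configuration hybridization free energies
#'   (kcal/mol); may be empty.
#' @param molecularity `"uni"` or `"bi"` (affects units only).
#' @param conditions A [thermo_conditions()] object.
#' @return Scalar Kd.
#' @export
kd_from_configs <- function(dg, molecularity = c("bi", "uni"),
                            conditions = thermo_conditions()) {
  molecularity <- match.arg(molecularity)
  if (any(is.nan(dg) | is.na(dg))) {
    abort("non-finite configuration free energy")
  }
  dg <- dg[dg < Inf]  # +Inf marks "no stable duplex": no contribution
  if (!length(dg)) return(Inf)
  ka <- sum(exp(-dg / (conditions$R * conditions$temperature_K)))
  1 / ka
}

#' Assemble dissociation constants for a design run
#'
#' Aggregates configuration energies into per-interaction dissociation
#' constants: `kd_site` over all of a probe's alignments within one binding
#' site, `kd_self` over its hairpin stems, and `kd_cross` over both
#' cross-dimer orientations of each probe pair.
#'
#' @param site_map A `fish_site_map` whose configs cover the probes.
#' @param self_configs Tibble from [self_alignments()] rows (all probes).
#' @param cross_configs Tibble from [cross_alignments()] rows (all pairs),
#'   or `NULL` for none.
#' @param conditions A [thermo_conditions()] object.
#' @return A `fish_kd` list with tibbles `site` (`probe_id`, `target_id`,
#'   `site_id`, `kd`, `dg_min`), `self` (`probe_id`, `kd`, `dg_min`) and
#'   `cross` (`probe_i`, `probe_j`, `kd`, `dg_min`; stored once per unordered
#'   pair), plus the conditions. Absent entries mean no stable interaction.
#' @export
build_dissociation_constants <- function(site_map, self_configs = NULL,
                                         cross_configs = NULL,
                                         conditions = thermo_conditions()) {
  RT <- conditions$R * conditions$temperature_K
  cfg <- site_map$configs
  if (nrow(cfg)) {
    en <- nn_energy_batch(cfg$probe_aln, cfg$target_aln, conditions)
    site <- bind_cols(cfg[, c("probe_id", "target_id", "site_id")], en) %>%
      filter(.data$stable) %>%
      group_by(.data$probe_id, .data$target_id, .data$site_id) %>%
      summarise(kd = 1 / sum(exp(-.data$dg / RT)), dg_min = min(.data$dg),
                .groups = "drop")
  } else {
    site <- tibble(probe_id = character(), target_id = character(),
                   site_id = character(), kd = numeric(),
                   dg_min = numeric())
  }
  if (!is.null(self_configs) && nrow(self_configs)) {
    en <- nn_energy_batch(self_configs$probe_aln, self_configs$partner_aln,
                          conditions)
    self <- bind_cols(self_configs["probe_id"], en) %>%
      filter(.data$stable) %>%
      group_by(.data$probe_id) %>%
      summarise(kd = 1 / sum(exp(-.data$dg / RT)), dg_min = min(.data$dg),
                .groups = "drop")
  } else {
    self <- tibble(probe_id = character(), kd = numeric(),
                   dg_min = numeric())
  }
  if (!is.null(cross_configs) && nrow(cross_configs)) {
    en <- nn_energy_batch(cross_configs$probe_aln,
                          cross_configs$partner_aln, conditions)
    cross <- bind_cols(cross_configs[, c("probe_i", "probe_j")], en) %>%
      filter(.data$stable) %>%
      mutate(a = pmin(.data$probe_i, .data$probe_j),
             b = pmax(.data$probe_i, .data$probe_j)) %>%
      group_by(probe_i = .data$a, probe_j = .data$b) %>%
      summarise(kd = 1 / sum(exp(-.data$dg / RT)), dg_min = min(.data$dg),
                .groups = "drop")
  } else {
    cross <- tibble(probe_i = character(), probe_j = character(),
                    kd = numeric(), dg_min = numeric())
  }
  structure(list(site = site, self = self, cross = cross,
                 conditions = conditions),
            class = "fish_kd")
}

#' @export
print.fish_kd <- function(x, ...) {
  cat("<fish_kd>", nrow(x$site), "probe-site,", nrow(x$self), "self,",
      nrow(x$cross), "cross interactions at",
      sprintf("%.2f K / %.2g M Na+\n", x$conditions$temperature_K,
              x$conditions$sodium_M))
  invisible(x)
}
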