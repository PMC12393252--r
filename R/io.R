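# Exporters. Human-readable tables use 1-based closed coordinates; BED is
# 0-based half-open, with the transcript id as the chromosome.

#' Write design artifacts to a run directory
#'
#' Writes the probe table (TSV, 1-based closed coordinates), probe FASTA,
#' BED of on-target placements, a JSON design report and the resolved
#' configuration YAML.
#'
#' @param design A `fish_design` from [run_design()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel <- design$selection$selected
  paths <- list(
    probes_tsv = file.path(dir, "probes.tsv"),
    probes_fasta = file.path(dir, "probes.fa"),
    probes_bed = file.path(dir, "probes.bed"),
    report_json = file.path(dir, "design_report.json"),
    config_yaml = file.path(dir, "config.yaml"))
  tab <- sel %>%
    mutate(start_1based = .data$start + 1L,
           end_1based = .data$start + .data$length) %>%
    select("probe_id", target = "target_id", start = "start_1based",
           end = "end_1based", "sequence", "phase", "n_offtargets",
           dG_on = "dg_on", "energy_gap")
  utils::write.table(tab, paths$probes_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste0(">", sel$probe_id, "\n", sel$sequence),
             paths$probes_fasta)
  bed <- sel %>%
    mutate(end = .data$start + .data$length) %>%
    select("target_id", "start", "end", "probe_id")
  utils::write.table(bed, paths$probes_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  report <- c(design$metrics, list(
    on_targets = design$on_targets,
    excluded = as.list(table(design$selection$excluded$reason)),
    probe_conc_nM = design$config$probe_conc_nM,
    temperature_C = design$config$temperature_C,
    sodium_M = design$config$sodium_M))
  jsonlite::write_json(report, paths$report_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg <- design$config
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, paths$config_yaml)
  invisible(paths)
}

#' Export hits as TSV
#'
#' @param hits Hit tibble from [find_hits_all()].
#' @param path Output TSV path (1-based closed coordinates).
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  out <- hits %>%
    mutate(target_start = .data$target_start + 1L,
           probe_start = .data$probe_start + 1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a binding-site map as BED
#'
#' @param site_map A `fish_site_map`.
#' @param path Output BED path (chrom = transcript id, 0-based half-open).
#' @return Invisibly, `path`.
#' @export
write_site_bed <- function(site_map, path) {
  bed <- site_map$sites %>%
    select("target_id", "start", "end", "site_id")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export candidate probes as FASTA
#'
#' @param candidates Candidate tibble.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_probe_fasta <- function(candidates, path) {
  writeLines(paste0(">", candidates$probe_id, "\n", candidates$sequence),
             path)
  invisible(path)
}
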