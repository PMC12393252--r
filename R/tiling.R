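#' Reverse complement of DNA sequences
#'
#' Vectorised over input; accepts the DNA alphabet plus `N`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAC") # "GTT"
revcomp <- function(seq) {
  if (any(grepl("[^ACGTNacgtn]", seq))) {
    abort("revcomp(): sequences must be over the {A,C,G,T,N} alphabet")
  }
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Tile a target transcript with candidate probes
#'
#' Enumerates every antisense oligo of the chosen length along the target,
#' one candidate per start offset (0-based). Windows containing `N` are
#' skipped. No GC or melting-temperature pre-filter is applied: ranking and
#' selection operate on the full candidate pool, and the minimum-spacing
#' constraint is enforced at selection time so that overlapping candidates
#' all remain available to the global ranking.
#'
#' @param target Either a `fish_transcriptome` row subset with one record or
#'   a list/one-row data frame with `transcript_id` and `sequence`.
#' @param probe_length Probe length in nt (default 20).
#' @return Tibble of candidates: `probe_id`, `target_id`, `start` (0-based),
#'   `length`, `sequence` (the probe, 5'->3', reverse complement of the
#'   target window).
#' @export
tile_candidates <- function(target, probe_length = 20) {
  if (is.data.frame(target)) {
    if (nrow(target) != 1) abort("tile_candidates() expects a single target")
    target <- as.list(target[1, ])
  }
  seq <- chartr("U", "T", toupper(target$sequence))
  id <- target$transcript_id
  if (probe_length < 10) abort("probe_length must be >= 10")
  L <- nchar(seq)
  if (L < probe_length) {
    abort(paste0("target ", id, " (", L, " nt) is shorter than probe_length"))
  }
  starts <- 0:(L - probe_length)
  windows <- substring(seq, starts + 1, starts + probe_length)
  has_n <- grepl("N", windows, fixed = TRUE)
  if (any(has_n)) {
    inform(paste0("skipped ", sum(has_n), " window(s) containing N on ", id))
  }
  starts <- starts[!has_n]
  windows <- windows[!has_n]
  tibble(
    probe_id = paste0(id, "_p", starts),
    target_id = id,
    start = starts,
    length = probe_length,
    sequence = revcomp(windows)
  )
}
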