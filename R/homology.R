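#' Build an exact k-mer seed index over a transcriptome
#'
#' Indexes every `word_size`-mer of each transcript in the hybridization-
#' relevant orientation: a probe hybridizes where the transcript carries the
#' reverse complement of the probe, so matching the reverse complement of a
#' probe against the sense transcript is equivalent to matching the probe
#' against the reverse complement of the transcript. Seeds anchor the
#' gapped extension performed by [find_hits()].
#'
#' @param transcriptome A `fish_transcriptome`.
#' @param word_size Seed word size (default 7, BLAST-style).
#' @return A `fish_seed_index` (environment-backed hash of k-mer ->
#'   positions, plus a `words` tibble with one row per indexed word).
#' @export
build_seed_index <- function(transcriptome, word_size = 7) {
  if (word_size < 4) abort("word_size must be >= 4")
  words <- purrr::map2(
    transcriptome$transcript_id, transcriptome$sequence,
    function(id, seq) {
      L <- nchar(seq)
      if (L < word_size) return(NULL)
      pos <- 0:(L - word_size)
      tibble(kmer = substring(seq, pos + 1, pos + word_size),
             target_id = id, pos = pos)
    }
  )
  words <- bind_rows(words)
  words <- words[!grepl("N", words$kmer, fixed = TRUE), ]
  ht <- new.env(parent = emptyenv(), size = max(16L, nrow(words)))
  split_idx <- split(seq_len(nrow(words)), words$kmer)
  tid <- words$target_id
  pos <- words$pos
  for (k in names(split_idx)) {
    i <- split_idx[[k]]
    assign(k, list(target_id = tid[i], pos = pos[i]), envir = ht)
  }
  structure(
    list(hash = ht, word_size = word_size, words = words,
         seq = setNames(transcriptome$sequence,
                        transcriptome$transcript_id)),
    class = "fish_seed_index")
}

#' @export
print.fish_seed_index <- function(x, ...) {
  cat("<fish_seed_index> word size", x$word_size, "-",
      nrow(x$words), "indexed words over", length(x$seq), "transcripts\n")
  invisible(x)
}

#' Find hybridization sites of a probe across the transcriptome
#'
#' Seed-and-extend local alignment of the probe's binding-site sequence (its
#' reverse complement) against each transcript, with BLAST-style scoring
#' (reward +1, mismatch -3, affine gaps open 5 / extend 2, no low-complexity
#' filtering). Alignments with fewer than `min_match` identical aligned base
#' pairs are discarded: shorter duplexes are unlikely to affect hybridization
#' at working conditions. The probe's own source window is always recovered
#' as the on-target hit.
#'
#' @param probe One-row data frame or list with `probe_id` and `sequence`.
#' @param index A `fish_seed_index` from [build_seed_index()].
#' @param min_match Minimum number of matched (identical aligned) nucleotides
#'   for a hit to be retained (default 15).
#' @return Tibble of hits: `probe_id`, `target_id`, `probe_start`,
#'   `probe_end`, `target_start`, `target_end` (0-based half-open;
#'   target coordinates on the sense transcript), `matched_nt`, `score`,
#'   `probe_aln`, `target_aln`. The aligned pair is written probe 5'->3'
#'   against the complement of the target read in the same direction, so
#'   identical characters mark paired bases.
#' @export
find_hits <- function(probe, index, min_match = 15) {
  if (is.data.frame(probe)) probe <- as.list(probe[1, ])
  q <- revcomp(probe$sequence)
  n <- nchar(q)
  w <- index$word_size
  if (n < w) return(empty_hits())
  qpos <- 0:(n - w)
  kmers <- substring(q, qpos + 1, qpos + w)
  found <- mget(kmers, envir = index$hash, ifnotfound = list(NULL))
  rows <- list()
  seed_tid <- character(0); seed_diag <- integer(0)
  for (k in seq_along(found)) {
    hit <- found[[k]]
    if (is.null(hit)) next
    seed_tid <- c(seed_tid, hit$target_id)
    seed_diag <- c(seed_diag, hit$pos - qpos[k])
  }
  if (!length(seed_tid)) return(empty_hits())
  key <- paste(seed_tid, seed_diag)
  first <- !duplicated(key)
  seed_tid <- seed_tid[first]; seed_diag <- seed_diag[first]
  o <- order(seed_tid, seed_diag)
  seed_tid <- seed_tid[o]; seed_diag <- seed_diag[o]
  acc <- list(tid = character(0), ts = integer(0), te = integer(0),
              ps = integer(0), pe = integer(0), m = integer(0),
              sc = integer(0), qa = character(0), sa = character(0))
  for (tid in unique(seed_tid)) {
    diags <- seed_diag[seed_tid == tid]
    # cluster nearby diagonals: one gapped alignment can span several
    clusters <- split(diags, cumsum(c(1, diff(diags) > 5)))
    tseq <- index$seq[[tid]]
    L <- nchar(tseq)
    for (cl in clusters) {
      win_start <- max(0, min(cl) - 6)
      win_end <- min(L, max(cl) + n + 6)
      window <- substr(tseq, win_start + 1, win_end)
      a <- .sw_align_cpp(q, window)
      if (a$score <= 0 || a$matched_nt < min_match) next
      k <- length(acc$tid) + 1L
      acc$tid[k] <- tid
      acc$ts[k] <- win_start + a$s_start
      acc$te[k] <- win_start + a$s_end
      acc$ps[k] <- n - a$q_end
      acc$pe[k] <- n - a$q_start
      acc$m[k] <- a$matched_nt
      acc$sc[k] <- a$score
      acc$qa[k] <- a$q_aln
      acc$sa[k] <- a$s_aln
    }
  }
  if (!length(acc$tid)) return(empty_hits())
  # dedupe identical (target, span): keep the max-score alignment
  o <- order(acc$tid, acc$ts, -acc$sc)
  dup <- duplicated(paste(acc$tid, acc$ts, acc$te)[o])
  keep <- o[!dup]
  tibble(
    probe_id = probe$probe_id,
    target_id = acc$tid[keep],
    probe_start = acc$ps[keep],
    probe_end = acc$pe[keep],
    target_start = acc$ts[keep],
    target_end = acc$te[keep],
    matched_nt = acc$m[keep],
    score = acc$sc[keep],
    probe_aln = revcomp_gapped(acc$qa[keep]),
    target_aln = revcomp_gapped(acc$sa[keep])
  )
}

#' Find hits for every candidate probe
#'
#' @param candidates Candidate tibble from [tile_candidates()].
#' @inheritParams find_hits
#' @return Combined hit tibble (see [find_hits()]).
#' @export
find_hits_all <- function(candidates, index, min_match = 15) {
  res <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    res[[i]] <- find_hits(candidates[i, ], index, min_match = min_match)
  }
  bind_rows(res)
}

empty_hits <- function() {
  tibble(probe_id = character(), target_id = character(),
         probe_start = integer(), probe_end = integer(),
         target_start = integer(), target_end = integer(),
         matched_nt = integer(), score = integer(),
         probe_aln = character(), target_aln = character())
}

# reverse a gapped alignment string and complement its bases
revcomp_gapped <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Build a non-overlapping binding-site map from retained hits
#'
#' Per target, hit spans are clustered by single-linkage on interval overlap;
#' each cluster becomes one site whose span is the union of its members, and
#' every member alignment becomes one binding configuration of that site.
#'
#' @param hits Hit tibble from [find_hits_all()].
#' @param transcriptome A `fish_transcriptome` (supplies the target universe
#'   for `n_sites`).
#' @return A `fish_site_map`: list with `sites` (target_id, site_id, start,
#'   end), `configs` (hits annotated with `site_id`) and `n_sites`
#'   (target_id, n_sites; targets without hits have 0).
#' @export
build_site_map <- function(hits, transcriptome) {
  if (nrow(hits) == 0) {
    sites <- tibble(target_id = character(), site_id = character(),
                    start = integer(), end = integer())
    configs <- dplyr::mutate(empty_hits(), site_id = character())
  } else {
    pieces <- lapply(split(hits, hits$target_id), function(h) {
      ir <- IRanges::IRanges(start = h$target_start + 1, end = h$target_end)
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      ov <- IRanges::findOverlaps(ir, red, select = "first")
      site_ids <- paste0(h$target_id[1], "_s", seq_along(red))
      sites <- tibble(target_id = h$target_id[1],
                      site_id = site_ids,
                      start = IRanges::start(red) - 1L,
                      end = IRanges::end(red))
      h$site_id <- site_ids[ov]
      list(sites = sites, configs = h)
    })
    sites <- bind_rows(lapply(pieces, `[[`, "sites"))
    configs <- bind_rows(lapply(pieces, `[[`, "configs"))
  }
  n_sites <- sites %>% dplyr::count(.data$target_id, name = "n_sites")
  n_sites <- tibble(target_id = transcriptome$transcript_id) %>%
    left_join(n_sites, by = "target_id") %>%
    mutate(n_sites = if_else(is.na(.data$n_sites), 0L, as.integer(.data$n_sites)))
  structure(list(sites = sites, configs = configs, n_sites = n_sites),
            class = "fish_site_map")
}

#' @export
print.fish_site_map <- function(x, ...) {
  cat("<fish_site_map>", nrow(x$sites), "sites,",
      nrow(x$configs), "configurations over",
      sum(x$n_sites$n_sites > 0), "targets\n")
  invisible(x)
}

#' Probes with retained hits on ribosomal RNA
#'
#' rRNA is identified from the annotation biotype; any probe with at least
#' one retained hit on an rRNA transcript is flagged (such probes are removed
#' before selection, since rRNA's abundance makes even weak binding costly).
#'
#' @param site_map A `fish_site_map`.
#' @param transcriptome A `fish_transcriptome`.
#' @return Character vector of flagged probe ids (possibly empty).
#' @export
flag_rRNA_probes <- function(site_map, transcriptome) {
  rrna <- transcriptome$transcript_id[transcriptome$biotype == "rRNA"]
  unique(site_map$configs$probe_id[site_map$configs$target_id %in% rrna])
}
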