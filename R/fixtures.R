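# Deterministic synthetic transcriptomes with planted homologies, so every
# stage is testable without reference downloads. Plants are sense copies of
# target windows (the sequence a decoy must carry for a probe, which is the
# reverse complement of its window, to hybridize there).

#' Specify a synthetic fixture
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @param target_length Length of the primary target transcript (nt).
#' @param n_isoforms Number of isoforms of the target gene (isoform 2..k are
#'   3' subsequences of the primary isoform).
#' @param isoform_fraction Fraction of the target shared by each extra
#'   isoform.
#' @param n_decoys Number of random decoy transcripts.
#' @param decoy_length Length range `c(lo, hi)` for decoys.
#' @param include_rRNA_decoy Add one rRNA-biotype decoy.
#' @param plants Data frame of planted homologies with columns
#'   `window_start` (0-based on the target), `window_length`, `identity_nt`
#'   (length of the exact copy, `<= window_length`), `decoy` (decoy number,
#'   or `"rRNA"` for the rRNA decoy). `NULL` for none.
#' @param gc GC fraction of random sequence (default 0.5).
#' @param expression_meanlog,expression_sdlog Log-normal TPM parameters.
#' @param contexts Context (cell line) names for the expression table.
#' @return A `fish_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, target_length = 300, n_isoforms = 1,
                         isoform_fraction = 0.75, n_decoys = 5,
                         decoy_length = c(150, 300),
                         include_rRNA_decoy = FALSE, plants = NULL,
                         gc = 0.5, expression_meanlog = log(50),
                         expression_sdlog = 1,
                         contexts = c("cell_line_1", "cell_line_2",
                                      "cell_line_3")) {
  if (!is.null(plants)) {
    plants <- as_tibble(plants)
    if (any(plants$identity_nt > plants$window_length)) {
      abort("planted identity_nt cannot exceed the window length")
    }
    if (any(plants$window_start + plants$window_length > target_length)) {
      abort("planted window extends beyond the target")
    }
  }
  structure(list(seed = seed, target_length = target_length,
                 n_isoforms = n_isoforms,
                 isoform_fraction = isoform_fraction,
                 n_decoys = n_decoys, decoy_length = decoy_length,
                 include_rRNA_decoy = include_rRNA_decoy, plants = plants,
                 gc = gc, expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog, contexts = contexts),
            class = "fish_fixture_spec")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

#' Generate a synthetic fixture on disk
#'
#' Writes a FASTA transcriptome, a TSV annotation, a TSV TPM expression
#' matrix and a JSON ground-truth manifest. Planted homologies are exact
#' sense copies of target sub-windows of length `identity_nt`; the 5 nt
#' flanking each plant are forced to mismatch the target continuation so a
#' plant below the retention threshold cannot be extended past it by chance.
#' Decoys are re-rolled until they share no 12-mer with the target outside
#' planted regions, keeping the manifest exact at fixture scale.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (fasta, annotation, expression, manifest),
#'   `transcriptome` (loaded `fish_transcriptome`), `manifest` (list with
#'   the planted-site ground truth), `target_id` and `on_target_ids`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  scan_k <- 12L
  # target: re-roll until its own k-mers are unique (no internal repeats)
  for (try in 1:50) {
    target <- random_dna(spec$target_length, spec$gc)
    if (!anyDuplicated(kmer_set(target, scan_k))) break
    if (try == 50) abort("could not generate a repeat-free target")
  }
  target_kmers <- kmer_set(target, scan_k)
  target_id <- "TARGET_iso1"
  records <- tibble(transcript_id = target_id, gene_id = "GENE_TARGET",
                    biotype = "mRNA", sequence = target)
  if (spec$n_isoforms > 1) {
    for (k in 2:spec$n_isoforms) {
      len <- round(spec$isoform_fraction * spec$target_length)
      iso <- substr(target, spec$target_length - len + 1,
                    spec$target_length)
      records <- bind_rows(records, tibble(
        transcript_id = paste0("TARGET_iso", k), gene_id = "GENE_TARGET",
        biotype = "mRNA", sequence = iso))
    }
  }

  plants <- spec$plants
  plant_rows <- list()
  decoy_ids <- paste0("DECOY_", seq_len(spec$n_decoys))
  all_decoy_ids <- decoy_ids
  if (spec$include_rRNA_decoy) all_decoy_ids <- c(decoy_ids, "DECOY_rRNA")
  for (d_idx in seq_along(all_decoy_ids)) {
    did <- all_decoy_ids[d_idx]
    is_rrna <- identical(did, "DECOY_rRNA")
    dlen <- round(stats::runif(1, spec$decoy_length[1], spec$decoy_length[2]))
    my_plants <- NULL
    if (!is.null(plants)) {
      sel <- if (is_rrna) plants$decoy == "rRNA" else
        plants$decoy == as.character(d_idx)
      if (any(sel)) my_plants <- plants[sel, ]
    }
    for (try in 1:50) {
      seq_chr <- strsplit(random_dna(dlen, spec$gc), "", fixed = TRUE)[[1]]
      plant_mask <- rep(FALSE, dlen)
      rows <- list()
      ok <- TRUE
      if (!is.null(my_plants)) {
        # space plants evenly along the decoy
        n_pl <- nrow(my_plants)
        slot <- floor(dlen / n_pl)
        for (p in seq_len(n_pl)) {
          idlen <- my_plants$identity_nt[p]
          wstart <- my_plants$window_start[p]
          pos <- (p - 1) * slot + max(6, floor((slot - idlen) / 2))
          if (pos + idlen + 5 > dlen) { ok <- FALSE; break }
          copy <- substr(target, wstart + 1, wstart + idlen)
          seq_chr[(pos + 1):(pos + idlen)] <-
            strsplit(copy, "", fixed = TRUE)[[1]]
          plant_mask[max(1, pos - scan_k + 2):
                       min(dlen, pos + idlen + scan_k - 1)] <- TRUE
          # anti-extension flanks: mismatch the target continuation
          tchr <- strsplit(target, "", fixed = TRUE)[[1]]
          for (f in 1:5) {
            tl <- wstart - f; dl <- pos - f
            if (tl >= 0 && dl >= 0) {
              seq_chr[dl + 1] <- mismatch_base(tchr[tl + 1])
            }
            tr <- wstart + idlen - 1 + f; dr <- pos + idlen - 1 + f
            if (tr < spec$target_length && dr < dlen) {
              seq_chr[dr + 1] <- mismatch_base(tchr[tr + 1])
            }
          }
          rows[[p]] <- tibble(
            decoy_id = did, decoy_start = pos,
            identity_nt = idlen, target_id = target_id,
            window_start = wstart,
            window_length = my_plants$window_length[p])
        }
      }
      if (!ok) next
      dseq <- paste(seq_chr, collapse = "")
      # scan for accidental homologies to the target outside plants
      dk <- kmer_set(dseq, scan_k)
      hit <- which(dk %in% target_kmers)
      spurious <- hit[!plant_mask[hit]]
      if (!length(spurious)) {
        records <- bind_rows(records, tibble(
          transcript_id = did,
          gene_id = paste0("GENE_", did),
          biotype = if (is_rrna) "rRNA" else
            sample(c("mRNA", "lncRNA"), 1, prob = c(0.8, 0.2)),
          sequence = dseq))
        plant_rows <- c(plant_rows, rows)
        break
      }
      if (try == 50) abort(paste0("could not de-collide decoy ", did))
    }
  }

  tx <- new_transcriptome(records,
                          isoform_counts = c(GENE_TARGET = spec$n_isoforms))
  # expression: log-normal TPM per transcript and context; rRNA abundant
  n_tx <- nrow(records)
  tpm <- matrix(stats::rlnorm(n_tx * length(spec$contexts),
                              spec$expression_meanlog,
                              spec$expression_sdlog),
                nrow = n_tx, dimnames = list(records$transcript_id,
                                             spec$contexts))
  tpm[records$biotype == "rRNA", ] <- tpm[records$biotype == "rRNA", ] * 50

  paths <- list(
    fasta = file.path(dir, "transcripts.fa"),
    annotation = file.path(dir, "annotation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeLines(paste0(">", records$transcript_id, "\n", records$sequence),
             paths$fasta)
  ann <- records %>%
    select("transcript_id", "gene_id", "biotype") %>%
    mutate(isoform_count = if_else(.data$gene_id == "GENE_TARGET",
                                   spec$n_isoforms, 1L))
  utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr_df <- data.frame(id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(expr_df, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    seed = spec$seed,
    target_id = target_id,
    on_target_ids = records$transcript_id[records$gene_id == "GENE_TARGET"],
    decoy_ids = all_decoy_ids,
    plants = if (length(plant_rows)) bind_rows(plant_rows) else
      tibble(decoy_id = character(), decoy_start = integer(),
             identity_nt = integer(), target_id = character(),
             window_start = integer(), window_length = integer()))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  list(paths = paths, transcriptome = tx, manifest = manifest,
       target_id = target_id,
       on_target_ids = manifest$on_target_ids)
}

mismatch_base <- function(b) {
  alt <- setdiff(c("A", "C", "G", "T"), b)
  sample(alt, 1)
}

#' A hard-gene benchmark fixture specification
#'
#' A miniature of the benchmark gene-selection criteria used for probe
#' design validation: one ~1.5 kb target with two isoforms (fewer than five),
#' thirty random decoys plus one rRNA decoy, and eight planted off-target
#' homologies of 15-20 nt — including one on the rRNA decoy — with
#' log-normal expression across three cell-line contexts.
#'
#' @param seed Integer seed (default 424).
#' @return A `fish_fixture_spec`.
#' @export
arf4_like_scenario <- function(seed = 424) {
  plants <- tibble(
    window_start = c(80, 260, 440, 620, 800, 980, 1160, 1340),
    window_length = 20L,
    identity_nt = c(20L, 18L, 16L, 15L, 17L, 19L, 15L, 16L),
    decoy = c("1", "4", "7", "11", "15", "19", "23", "rRNA"))
  fixture_spec(
    seed = seed, target_length = 1500, n_isoforms = 2,
    isoform_fraction = 0.7, n_decoys = 30, decoy_length = c(400, 800),
    include_rRNA_decoy = TRUE, plants = plants,
    expression_meanlog = log(60), expression_sdlog = 1)
}
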