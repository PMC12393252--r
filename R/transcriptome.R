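#' Load a transcriptome from FASTA plus annotation
#'
#' Reads a multi-record FASTA of transcript sequences and an annotation that
#' maps every transcript id to a gene id and biotype, returning a tidy
#' transcriptome table consumed by all downstream stages. RNA alphabets are
#' normalised to DNA (`U` is stored as `T`); record order follows the FASTA.
#'
#' The annotation may be either a 4-column TSV with header
#' `transcript_id, gene_id, biotype, isoform_count`, or a GTF/GFF3 file whose
#' transcript features carry `transcript_id`, `gene_id` and
#' `transcript_biotype` (or `gene_biotype`) attributes. Transcript ids present
#' in the FASTA but missing from the annotation are kept with
#' `gene_id = transcript_id` and `biotype = "other"`.
#'
#' @param fasta_path Path to a (wrapped or unwrapped) multi-record FASTA file.
#' @param annotation_path Path to a TSV or GTF/GFF3 annotation file.
#' @return A tibble of class `fish_transcriptome` with columns
#'   `transcript_id`, `gene_id`, `biotype` (one of `mRNA`, `lncRNA`, `rRNA`,
#'   `other`), `sequence` and `length`, and an `isoform_counts` attribute
#'   (named integer vector, gene id -> maximum isoform count).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "ACGUACGUACGU", ">t2", "GGGCCCAAATTT"), fa)
#' ann <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\tgene_id\tbiotype\tisoform_count",
#'              "t1\tg1\tmRNA\t2", "t2\tg2\trRNA\t1"), ann)
#' load_transcriptome(fa, ann)
load_transcriptome <- function(fasta_path, annotation_path) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) abort("empty FASTA: no transcript records found")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate transcript ids in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sequences <- toupper(chartr("u", "t", as.character(seqs)))
  sequences <- chartr("U", "T", sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    abort(paste0("non-IUPAC characters in transcript(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  ann <- read_annotation(annotation_path)
  tbl <- tibble(transcript_id = ids, sequence = unname(sequences)) %>%
    left_join(ann$map, by = "transcript_id") %>%
    mutate(
      gene_id = if_else(is.na(.data$gene_id), .data$transcript_id,
                        .data$gene_id),
      biotype = if_else(is.na(.data$biotype), "other", .data$biotype),
      length = nchar(.data$sequence)
    ) %>%
    select("transcript_id", "gene_id", "biotype", "sequence", "length")
  new_transcriptome(tbl, isoform_counts = ann$isoform_counts)
}

#' Construct a transcriptome from an in-memory table
#'
#' @param records Data frame with columns `transcript_id`, `gene_id`,
#'   `biotype`, `sequence`.
#' @param isoform_counts Optional named integer vector (gene id -> maximum
#'   isoform count). Genes not named default to the number of loaded records.
#' @return A `fish_transcriptome` tibble.
#' @export
new_transcriptome <- function(records, isoform_counts = NULL) {
  tbl <- as_tibble(records)
  required <- c("transcript_id", "gene_id", "biotype", "sequence")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("transcriptome is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tbl) == 0) abort("transcriptome has no records")
  if (anyDuplicated(tbl$transcript_id)) abort("duplicate transcript ids")
  if (any(!nzchar(tbl$sequence))) abort("empty transcript sequence")
  tbl$sequence <- chartr("U", "T", toupper(tbl$sequence))
  tbl$biotype <- normalise_biotype(tbl$biotype)
  tbl$length <- nchar(tbl$sequence)
  loaded <- table(tbl$gene_id)
  counts <- setNames(as.integer(loaded), names(loaded))
  if (!is.null(isoform_counts)) {
    ic <- setNames(as.integer(isoform_counts), names(isoform_counts))
    common <- intersect(names(ic), names(counts))
    counts[common] <- pmax(counts[common], ic[common])
    counts <- c(counts, ic[setdiff(names(ic), names(counts))])
  }
  structure(tbl, isoform_counts = counts,
            class = c("fish_transcriptome", class(tbl)))
}

#' Isoform counts of a transcriptome
#' @param transcriptome A `fish_transcriptome`.
#' @return Named integer vector, gene id -> isoform count.
#' @export
isoform_counts <- function(transcriptome) {
  attr(transcriptome, "isoform_counts")
}

normalise_biotype <- function(x) {
  x <- tolower(as.character(x))
  dplyr::case_when(
    grepl("rrna", x) ~ "rRNA",
    x %in% c("mrna", "protein_coding", "protein-coding", "coding") ~ "mRNA",
    grepl("lnc", x) ~ "lncRNA",
    TRUE ~ "other"
  )
}

read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (grepl("\\.(gtf|gff3?|gff)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF/GFF annotation requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    md <- as.data.frame(gr)
    if (!"transcript_id" %in% names(md)) {
      abort("GTF/GFF annotation lacks a transcript_id attribute")
    }
    bio <- md$transcript_biotype %||% md$gene_biotype %||%
      rep("other", nrow(md))
    map <- tibble(
      transcript_id = md$transcript_id,
      gene_id = md$gene_id %||% md$transcript_id,
      biotype = normalise_biotype(bio)
    ) %>%
      filter(!is.na(.data$transcript_id)) %>%
      distinct(.data$transcript_id, .keep_all = TRUE)
    counts <- map %>% dplyr::count(.data$gene_id)
    ic <- setNames(as.integer(counts$n), counts$gene_id)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    required <- c("transcript_id", "gene_id", "biotype")
    if (!all(required %in% names(tab))) {
      abort(paste0("TSV annotation must have columns ",
                   paste(required, collapse = ", ")))
    }
    map <- as_tibble(tab[, required])
    map$biotype <- normalise_biotype(map$biotype)
    if ("isoform_count" %in% names(tab)) {
      per_gene <- tapply(as.integer(tab$isoform_count), tab$gene_id, max)
      ic <- setNames(as.integer(per_gene), names(per_gene))
    } else {
      counts <- map %>% dplyr::count(.data$gene_id)
      ic <- setNames(as.integer(counts$n), counts$gene_id)
    }
  }
  list(map = map, isoform_counts = ic)
}

transcript_sequence <- function(transcriptome, transcript_id) {
  i <- match(transcript_id, transcriptome$transcript_id)
  if (any(is.na(i))) {
    abort(paste0("unknown transcript id(s): ",
                 paste(transcript_id[is.na(i)], collapse = ", ")))
  }
  transcriptome$sequence[i]
}
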