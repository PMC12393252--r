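#' TMM scaling factors for an expression matrix
#'
#' Computes trimmed-mean-of-M-values scaling factors across expression
#' contexts (cell lines). The reference context is the one whose
#' upper-quartile of library-size-scaled values lies closest to the mean
#' upper-quartile; for each other context the factor is `2^m`, where `m` is
#' the doubly trimmed (30% on M-values, 5% on A-values, from each tail) mean
#' of the per-gene log2 ratios against the reference, computed over genes
#' positive in both contexts.
#'
#' @param tpm Wide table: a data frame whose first column is the feature id
#'   and remaining columns are per-context TPM values, or a numeric matrix
#'   with rownames.
#' @return Named numeric vector of per-context scaling factors (reference
#'   context has factor 1).
#' @export
tmm_factors <- function(tpm) {
  m <- as_expression_matrix(tpm)
  if (ncol(m) < 1) abort("expression table has no contexts")
  if (any(m < 0)) abort("negative TPM values are not allowed")
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    abort(paste0("context(s) with all-zero expression: ",
                 paste(colnames(m)[zero], collapse = ", ")))
  }
  if (ncol(m) == 1) return(setNames(1, colnames(m)))
  scaled <- sweep(m, 2, lib, "/")
  uq <- apply(scaled, 2, function(x) quantile(x, 0.75, names = FALSE))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    if (k == ref) return(1)
    2^trimmed_mean_m(scaled[, k], scaled[, ref])
  }, numeric(1))
  setNames(f, colnames(m))
}

# Doubly trimmed mean of M-values of obs vs ref (both already library-size
# scaled); logratio_trim/abs_trim follow the published TMM defaults.
trimmed_mean_m <- function(obs, ref, logratio_trim = 0.3, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(0)
  M <- log2(obs[keep] / ref[keep])
  A <- 0.5 * log2(obs[keep] * ref[keep])
  lo_m <- quantile(M, logratio_trim, names = FALSE)
  hi_m <- quantile(M, 1 - logratio_trim, names = FALSE)
  lo_a <- quantile(A, abs_trim, names = FALSE)
  hi_a <- quantile(A, 1 - abs_trim, names = FALSE)
  sel <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
  if (!any(sel)) return(mean(M))
  mean(M[sel])
}

#' TMM-normalise an expression matrix to nTPM
#'
#' Applies [tmm_factors()] to a TPM table and rescales each context so it
#' sums to one million, yielding normalised TPM (nTPM).
#'
#' @inheritParams tmm_factors
#' @param level Either `"transcript"` or `"gene"`; recorded on the result.
#' @return A tibble with an `id` column and one nTPM column per context;
#'   attribute `level` records the feature level.
#' @export
tmm_normalize <- function(tpm, level = c("transcript", "gene")) {
  level <- match.arg(level)
  m <- as_expression_matrix(tpm)
  f <- tmm_factors(tpm)
  norm <- sweep(m, 2, f, "*")
  norm <- sweep(norm, 2, colSums(norm), "/") * 1e6
  out <- as_tibble(as.data.frame(norm), rownames = "id")
  attr(out, "level") <- level
  out
}

#' Impute transcript-level expression from gene-level nTPM
#'
#' Each transcript of gene `g` receives `nTPM(g) / isoform_count(g)`, where
#' the isoform count is the maximum annotated number of isoforms for the gene
#' (see [isoform_counts()]).
#'
#' @param gene_table Gene-level expression tibble (id column = gene ids) as
#'   returned by [tmm_normalize()] with `level = "gene"`.
#' @param transcriptome A `fish_transcriptome`.
#' @return Transcript-level expression tibble covering every transcript of
#'   the genes present in `gene_table`, attribute `level = "transcript"`.
#' @export
impute_isoform_expression <- function(gene_table, transcriptome) {
  lvl <- attr(gene_table, "level") %||% "gene"
  if (!identical(lvl, "gene")) {
    abort("impute_isoform_expression() expects a gene-level table")
  }
  ic <- isoform_counts(transcriptome)
  genes <- gene_table$id
  missing_ic <- setdiff(genes, names(ic))
  if (length(missing_ic)) {
    abort(paste0("gene(s) absent from isoform counts: ",
                 paste(missing_ic, collapse = ", ")))
  }
  tx <- transcriptome %>%
    as_tibble() %>%
    select("transcript_id", "gene_id") %>%
    filter(.data$gene_id %in% genes)
  contexts <- setdiff(names(gene_table), "id")
  gm <- as.matrix(gene_table[, contexts, drop = FALSE])
  rownames(gm) <- gene_table$id
  per_iso <- gm[tx$gene_id, , drop = FALSE] / ic[tx$gene_id]
  out <- as_tibble(as.data.frame(per_iso, row.names = NULL))
  out <- bind_cols(tibble(id = tx$transcript_id), out)
  attr(out, "level") <- "transcript"
  out
}

#' Resolve an expression vector under an expression mode
#'
#' Produces the per-transcript expression used for off-target weighting:
#' `"equal"` assigns 1 to every transcript (the conventional equal-expression
#' assumption), `"mean_average"` averages nTPM across contexts, and
#' `"cell_line"` selects a single context's column. Transcripts present in
#' the transcriptome but absent from the table receive 0 with a warning
#' (absent means not expressed).
#'
#' @param table Transcript-level expression tibble (ignored for `"equal"`;
#'   may be `NULL` in that case).
#' @param mode One of `"equal"`, `"mean_average"`, `"cell_line"`.
#' @param transcriptome A `fish_transcriptome`.
#' @param cell_line Context id, required when `mode = "cell_line"`.
#' @return Tibble with columns `transcript_id`, `expression`.
#' @export
expression_vector <- function(table, mode = c("equal", "mean_average",
                                              "cell_line"),
                              transcriptome, cell_line = NULL) {
  mode <- match.arg(mode)
  ids <- transcriptome$transcript_id
  if (mode == "equal") {
    return(tibble(transcript_id = ids, expression = 1))
  }
  if (is.null(table)) abort("an expression table is required for this mode")
  lvl <- attr(table, "level") %||% "transcript"
  if (!identical(lvl, "transcript")) {
    abort("expression_vector() needs a transcript-level table; see impute_isoform_expression()")
  }
  contexts <- setdiff(names(table), "id")
  if (mode == "cell_line") {
    if (is.null(cell_line)) abort("cell_line must be given for mode 'cell_line'")
    if (!cell_line %in% contexts) {
      abort(paste0("unknown cell line '", cell_line, "'; available: ",
                   paste(contexts, collapse = ", ")))
    }
    vals <- setNames(table[[cell_line]], table$id)
  } else {
    vals <- rowMeans(as.matrix(table[, contexts, drop = FALSE]))
    names(vals) <- table$id
  }
  out <- unname(vals[ids])
  if (anyNA(out)) {
    warn(paste0(sum(is.na(out)),
                " transcript(s) missing from expression table; set to 0"))
    out[is.na(out)] <- 0
  }
  tibble(transcript_id = ids, expression = out)
}

as_expression_matrix <- function(tpm) {
  if (is.matrix(tpm)) {
    if (is.null(rownames(tpm))) abort("expression matrix needs rownames")
    return(tpm)
  }
  df <- as.data.frame(tpm)
  id_col <- if ("id" %in% names(df)) "id" else names(df)[1]
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  storage.mode(m) <- "double"
  m
}

#' Read a TSV expression matrix
#'
#' @param path TSV file: first column feature ids, remaining columns contexts,
#'   header row required.
#' @param level `"transcript"` or `"gene"`.
#' @return Wide expression tibble with `id` column and `level` attribute.
#' @export
read_expression <- function(path, level = c("transcript", "gene")) {
  level <- match.arg(level)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(tab)[1] <- "id"
  out <- as_tibble(tab)
  attr(out, "level") <- level
  out
}
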