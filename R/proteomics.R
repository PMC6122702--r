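#' Construct / validate a ProteomicsTable
#'
#' Summarised label-free proteomics comparison of two cell lines: one row
#' per protein with the encoding gene symbol, the number of unique
#' peptides, the linear mean fold (first cell line over second, > 0) and
#' the FDR-adjusted ANOVA P value. `direction` is derived from the fold
#' when absent and validated against it otherwise.
#'
#' @param df data.frame with columns `gene`, `unique_peptides`,
#'   `mean_fold`, `adj_p` (and optionally `direction`).
#' @param cell_lines labels of the two compared cell lines (fold =
#'   first / second).
#' @return a validated `ProteomicsTable` data.frame with a `direction`
#'   column in `<first>_higher` / `<second>_higher`.
#' @export
proteomics_table <- function(df, cell_lines = c("HLE", "HUH7")) {
  need <- c("gene", "unique_peptides", "mean_fold", "adj_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$gene <- normalize_symbols(df$gene)
  df$unique_peptides <- as.integer(df$unique_peptides)
  if (any(df$unique_peptides < 0)) stop("unique_peptides must be >= 0")
  if (any(!is.finite(df$mean_fold) | df$mean_fold <= 0))
    stop("mean_fold must be finite and > 0")
  if (any(df$adj_p < 0 | df$adj_p > 1)) stop("adj_p must be in [0, 1]")
  derived <- ifelse(df$mean_fold >= 1, paste0(cell_lines[1], "_higher"),
                    paste0(cell_lines[2], "_higher"))
  if (!is.null(df$direction)) {
    bad <- df$direction != derived & df$mean_fold != 1
    if (any(bad))
      stop("direction inconsistent with mean_fold for: ",
           paste(df$gene[bad], collapse = ", "))
  }
  df$direction <- derived
  out <- df[, c("gene", "unique_peptides", "mean_fold", "adj_p", "direction")]
  class(out) <- c("ProteomicsTable", "data.frame")
  attr(out, "cell_lines") <- cell_lines
  out
}

#' Read a proteomics results TSV
#'
#' Expects columns `gene`, `unique_peptides`, `mean_fold`, `adj_p`
#' (supplementary-table column semantics for a two-cell-line comparison).
#'
#' @param path TSV path.
#' @param cell_lines labels of the two compared cell lines.
#' @return a `ProteomicsTable`.
#' @export
read_proteomics_table <- function(path, cell_lines = c("HLE", "HUH7")) {
  proteomics_table(read_tsv_plain(path), cell_lines = cell_lines)
}

#' Filter proteins by peptide support and significance
#'
#' Keeps proteins with at least `min_peptides` unique peptides and
#' FDR-adjusted P below `alpha`. Idempotent.
#'
#' @param table a `ProteomicsTable`.
#' @param min_peptides minimum unique peptides (default 2).
#' @param alpha adjusted-P threshold (default 0.05).
#' @return filtered `ProteomicsTable`.
#' @export
filter_significant_proteins <- function(table, min_peptides = 2L, alpha = 0.05) {
  out <- table[table$unique_peptides >= min_peptides & table$adj_p < alpha, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top fold-difference proteins per direction
#'
#' Per direction, proteins whose linear fold (or its reciprocal for the
#' second cell line) exceeds `min_fold` are ranked by descending fold and
#' the top `n` returned.
#'
#' @param table a (typically pre-filtered) `ProteomicsTable`.
#' @param n list length per direction (default 20).
#' @param min_fold linear fold threshold, applied in either direction
#'   (default 2).
#' @return named list of two data.frames (one per direction label), each
#'   with a `fold_over_other` column on the linear scale.
#' @export
top_fold_proteins <- function(table, n = 20L, min_fold = 2) {
  cl <- attr(table, "cell_lines") %||% c("A", "B")
  dirs <- paste0(cl, "_higher")
  out <- lapply(seq_along(dirs), function(i) {
    fold <- if (i == 1) table$mean_fold else 1 / table$mean_fold
    d <- table[table$direction == dirs[i] & fold > min_fold, , drop = FALSE]
    d$fold_over_other <- if (i == 1) d$mean_fold else 1 / d$mean_fold
    d <- d[order(-d$fold_over_other, d$gene), , drop = FALSE]
    rownames(d) <- NULL
    utils::head(d, n)
  })
  stats::setNames(out, dirs)
}

#' Score gene-protein agreement for mimicry assignments
#'
#' For each gene shared between the mimicry assignments and the proteomics
#' table, the protein fold agrees when the sign of its log equals the
#' agreed transcript delta sign. The returned table carries the fraction of
#' shared, sign-defined genes that agree as attribute `agreement_fraction`.
#'
#' @param assignments output of [assign_hmg_mimicry()].
#' @param table a `ProteomicsTable`.
#' @return data.frame `gene`, `delta_sign`, `protein_log2_fold`,
#'   `agreement` (`agrees`/`disagrees`/`absent`), with attribute
#'   `agreement_fraction`.
#' @export
gene_protein_agreement <- function(assignments, table) {
  i <- match(assignments$gene, table$gene)
  lf <- log2(table$mean_fold[i])
  agreement <- rep("absent", nrow(assignments))
  has <- !is.na(lf) & assignments$delta_sign != 0L & sign_int(lf) != 0L
  agreement[has] <- ifelse(sign_int(lf[has]) == assignments$delta_sign[has],
                           "agrees", "disagrees")
  out <- data.frame(gene = assignments$gene,
                    delta_sign = assignments$delta_sign,
                    protein_log2_fold = lf,
                    agreement = agreement,
                    stringsAsFactors = FALSE, row.names = NULL)
  denom <- sum(agreement != "absent")
  attr(out, "agreement_fraction") <-
    if (denom) sum(agreement == "agrees") / denom else NA_real_
  out
}
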