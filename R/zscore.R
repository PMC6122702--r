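#' z-score of expression fold within one dataset
#'
#' Standardises log2 fold changes across the dataset's significant genes
#' (p < `alpha`): `z_g = (logFC_g - mean(logFC)) / sd(logFC)` with the
#' sample standard deviation (n - 1). If all logFCs are equal, every z is
#' 0 by convention.
#'
#' @param table a `DiffExprTable`.
#' @param gene_subset optional gene set; when given, the standardisation is
#'   computed over the significant genes within the subset.
#' @param alpha significance threshold selecting the genes (default 0.05).
#' @return named numeric vector of z scores.
#' @export
zscore_fold <- function(table, gene_subset = NULL, alpha = 0.05) {
  rows <- table$p < alpha & is.finite(table$logFC)
  if (!is.null(gene_subset)) rows <- rows & table$gene %in% gene_subset
  lfc <- stats::setNames(table$logFC[rows], table$gene[rows])
  if (length(lfc) < 2)
    stop("need at least 2 significant genes with a logFC to z-score")
  s <- stats::sd(lfc)
  if (s == 0) return(stats::setNames(rep(0, length(lfc)), names(lfc)))
  (lfc - mean(lfc)) / s
}

#' Rank genes by their average z score across tumour datasets
#'
#' For each gene the average z is taken over the datasets where the gene has
#' a z score (i.e. was significant there); genes absent everywhere get
#' `NA` and sort last. Rows are ordered by descending average z (ties by
#' symbol); `rank` is a dense ordering of the distinct average-z values.
#'
#' @param profiles named list (dataset id -> named z vector from
#'   [zscore_fold()]).
#' @param genes genes to report; default: union of all profiled genes.
#' @return data.frame with `gene`, one `z_<dataset>` column per dataset,
#'   `avg_z`, `n_datasets`, `rank`.
#' @export
average_z_rank <- function(profiles, genes = NULL) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  genes <- genes %||% sort(unique(unlist(lapply(profiles, names))))
  if (!length(genes)) stop("no genes to rank")
  zmat <- vapply(profiles, function(p) unname(p[genes]), numeric(length(genes)))
  zmat <- matrix(zmat, nrow = length(genes),
                 dimnames = list(genes, names(profiles)))
  n_ds <- rowSums(!is.na(zmat))
  avg <- ifelse(n_ds > 0, rowMeans(zmat, na.rm = TRUE), NA_real_)
  out <- data.frame(gene = genes, zmat, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-1] <- paste0("z_", names(profiles))
  out$avg_z <- unname(avg)
  out$n_datasets <- unname(n_ds)
  out <- out[order(-xtfrm(out$avg_z), out$gene, na.last = TRUE), , drop = FALSE]
  uniq <- unique(out$avg_z[!is.na(out$avg_z)])
  out$rank <- match(out$avg_z, uniq)
  rownames(out) <- NULL
  out
}

#' Classify consensus genes as concordant or discordant with tumours
#'
#' For each consensus gene, the tumour direction is the majority logFC sign
#' among the tumour datasets where the gene is significant (p < `alpha`);
#' an exact sign tie or no significant dataset gives direction `none`. The
#' call is `concordant` when cell-line and tumour directions agree,
#' `discordant` when they oppose, and `unclassified` when the tumour
#' direction is `none` — a partition of the consensus genes.
#'
#' @param consensus a `ConsensusGeneSet`, or a list of them (e.g. the up
#'   and the down set) classified jointly.
#' @param tumour_tables list of tumour `DiffExprTable`s (contrast oriented
#'   tumour minus non-tumour).
#' @param alpha per-dataset significance threshold (default 0.05).
#' @return data.frame with `gene`, `cellline_direction`, `tumour_direction`,
#'   `call`, `n_tumour_sig`.
#' @export
classify_concordance <- function(consensus, tumour_tables, alpha = 0.05) {
  sets <- if (inherits(consensus, "ConsensusGeneSet")) list(consensus) else consensus
  stopifnot(all(vapply(sets, inherits, TRUE, "ConsensusGeneSet")))
  genes <- unlist(lapply(sets, function(s)
    stats::setNames(rep(s$direction, length(s$members)), names(s$members))))
  if (!length(genes)) stop("consensus set is empty")
  if (anyDuplicated(names(genes)))
    stop("a gene appears in more than one consensus set")
  sgn <- sapply(tumour_tables, function(t) {
    i <- match(names(genes), t$gene)
    s <- sign_int(t$logFC[i])
    s[is.na(i) | t$p[i] >= alpha] <- NA_integer_
    s
  })
  sgn <- matrix(sgn, nrow = length(genes))
  n_pos <- rowSums(sgn == 1L, na.rm = TRUE)
  n_neg <- rowSums(sgn == -1L, na.rm = TRUE)
  tumour_dir <- ifelse(n_pos > n_neg, "up",
                       ifelse(n_neg > n_pos, "down", "none"))
  cl_dir <- unname(genes)
  call <- ifelse(tumour_dir == "none", "unclassified",
                 ifelse(tumour_dir == cl_dir, "concordant", "discordant"))
  out <- data.frame(gene = names(genes), cellline_direction = cl_dir,
                    tumour_direction = tumour_dir, call = call,
                    n_tumour_sig = n_pos + n_neg,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene), , drop = FALSE]
}
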