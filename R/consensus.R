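#' Consensus gene selection across datasets
#'
#' A gene enters the consensus set for a direction when it is significant
#' (p < `alpha`) with that logFC sign in at least `k_min` datasets. Genes
#' that meet the criterion in *both* directions (via different datasets)
#' are excluded from both sets, as are genes flagged `ambiguous` by probe
#' collapsing; exclusions are reported with a message.
#'
#' @param tables list of `DiffExprTable`s sharing the contrast orientation.
#' @param direction `"up"` or `"down"`.
#' @param k_min minimum number of supporting datasets (default 2).
#' @param alpha per-dataset significance threshold (default 0.05).
#' @return a `ConsensusGeneSet`: list with `direction`, `k_min`, `alpha`,
#'   and `members`, a named list mapping each gene to the character vector
#'   of supporting dataset ids (sorted by gene symbol).
#' @export
consensus_select <- function(tables, direction = c("up", "down"),
                             k_min = 2L, alpha = 0.05) {
  direction <- match.arg(direction)
  if (k_min > length(tables))
    stop(sprintf("k_min (%d) exceeds the number of datasets (%d)",
                 k_min, length(tables)))
  ids <- dataset_ids(tables)
  sup <- support_by_direction(tables, ids, alpha)
  up_ok <- names(which(vapply(sup$up, length, 1L) >= k_min))
  dn_ok <- names(which(vapply(sup$down, length, 1L) >= k_min))
  both <- intersect(up_ok, dn_ok)
  if (length(both))
    message("excluded from both consensus directions (conflicting evidence): ",
            paste(both, collapse = ", "))
  keep <- sort(setdiff(if (direction == "up") up_ok else dn_ok, both))
  members <- sup[[direction]][keep]
  structure(list(direction = direction, k_min = as.integer(k_min),
                 alpha = alpha, members = members),
            class = "ConsensusGeneSet")
}

dataset_ids <- function(tables) {
  ids <- vapply(seq_along(tables), function(i) {
    attr(tables[[i]], "dataset_id") %||% names(tables)[i] %||% paste0("dataset", i)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset ids across tables")
  ids
}

# per-direction support: gene -> character vector of dataset ids where the
# gene is significant with that sign (ambiguous genes contribute nothing)
support_by_direction <- function(tables, ids, alpha) {
  up <- list(); down <- list()
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    amb <- if (!is.null(t$ambiguous)) t$ambiguous else FALSE
    sig <- t$p < alpha & !amb
    for (g in t$gene[sig & t$logFC > 0]) up[[g]] <- c(up[[g]], ids[i])
    for (g in t$gene[sig & t$logFC < 0]) down[[g]] <- c(down[[g]], ids[i])
  }
  list(up = up, down = down)
}

#' @export
print.ConsensusGeneSet <- function(x, ...) {
  cat(sprintf("ConsensusGeneSet: %d genes %sregulated in >= %d datasets (p < %g)\n",
              length(x$members), x$direction, x$k_min, x$alpha))
  invisible(x)
}

#' @export
as.data.frame.ConsensusGeneSet <- function(x, ...) {
  data.frame(gene = names(x$members),
             direction = x$direction,
             n_support = vapply(x$members, length, 1L),
             supporters = vapply(x$members, paste, "", collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Core genes shared by every dataset's top-n list
#'
#' Per table, the `n` genes with the stated logFC sign ranked by ascending
#' adjusted P (ties: larger |logFC|, then symbol order) are taken; the
#' result is their intersection across all tables, restricted to genes with
#' adjusted P below `alpha_adj` in every table, ordered by mean per-table
#' rank (ties by symbol).
#'
#' @param tables list of `DiffExprTable`s.
#' @param direction `"up"` or `"down"`.
#' @param n list length per table (default 100).
#' @param alpha_adj adjusted-P ceiling applied in every table (default 1e-4).
#' @return character vector of core genes, ordered by mean rank.
#' @export
top_core_genes <- function(tables, direction = c("up", "down"),
                           n = 100L, alpha_adj = 1e-4) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  per_table <- lapply(tables, function(t) {
    rows <- if (direction == "up") t$logFC > 0 else t$logFC < 0
    t <- t[rows, , drop = FALSE]
    t <- t[order(t$adj_p, -abs(t$logFC), t$gene), , drop = FALSE]
    t$rank <- seq_len(nrow(t))
    utils::head(t, n)
  })
  core <- Reduce(intersect, lapply(per_table, function(t) t$gene))
  if (!length(core)) return(character())
  ok <- vapply(core, function(g) {
    all(vapply(per_table, function(t) t$adj_p[match(g, t$gene)] < alpha_adj, TRUE))
  }, TRUE)
  core <- core[ok]
  if (!length(core)) return(character())
  mean_rank <- vapply(core, function(g) {
    mean(vapply(per_table, function(t) t$rank[match(g, t$gene)], 1L))
  }, 1)
  core[order(mean_rank, core)]
}
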