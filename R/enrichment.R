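#' Hypergeometric / EASE gene-set over-representation
#'
#' For each term the overlap `k` between the query and the term's members
#' (both intersected with the universe) is scored with the upper-tail
#' hypergeometric probability `P[X >= k]` for a draw of size `n` (the
#' query) from a universe of `N` genes containing `K` term members. Mode
#' `"ease"` applies the DAVID EASE correction: the tail is computed at
#' `max(k - 1, 0)`, a conservative penalty for single-gene overlaps.
#' Benjamini-Hochberg FDR is computed within each category (pathway, MF,
#' CC, BP separately), matching per-chart FDR reporting.
#'
#' Query genes outside the universe are dropped with a message.
#'
#' @param query character vector of gene symbols.
#' @param collection a `GeneSetCollection`.
#' @param universe character vector of background gene symbols (typically
#'   all genes measured in the contributing datasets).
#' @param mode `"ease"` (default) or `"standard"`.
#' @return data.frame of `EnrichmentRow`s: `term_id`, `name`, `category`,
#'   `k`, `K`, `n`, `N`, `p`, `fdr`, ordered by ascending `p` (ties:
#'   larger `k`, then term id).
#' @export
hypergeom_enrich <- function(query, collection, universe,
                             mode = c("ease", "standard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "GeneSetCollection"))
  universe <- unique(normalize_symbols(universe))
  universe <- universe[nzchar(universe)]
  query <- unique(normalize_symbols(query))
  query <- query[nzchar(query)]
  if (!length(universe)) stop("universe is empty")
  if (!length(query)) stop("query is empty")
  outside <- setdiff(query, universe)
  if (length(outside))
    message(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (!length(query)) stop("no query gene is in the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    s <- collection$sets[[term]]
    members <- intersect(s$genes, universe)
    K <- length(members)
    k <- length(intersect(query, members))
    keff <- if (mode == "ease") max(k - 1L, 0L) else k
    p <- stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, name = s$name, category = s$category,
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::ave(out$p, out$category, FUN = bh_adjust)
  out <- out[order(out$p, -out$k, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top enriched terms per category
#'
#' Applies the reporting thresholds (P and per-chart FDR ceilings) and
#' keeps the `n_pathway` best pathways plus the `n_go` best terms in each
#' GO category (MF, CC, BP), ranked by ascending P (ties: larger overlap,
#' then term id).
#'
#' @param rows output of [hypergeom_enrich()].
#' @param p_max P-value ceiling (default 1e-4).
#' @param fdr_max FDR ceiling (default 0.25).
#' @param n_pathway pathways to keep (default 10).
#' @param n_go terms per GO category to keep (default 5).
#' @return filtered, ordered data.frame (possibly empty).
#' @export
select_top_terms <- function(rows, p_max = 1e-4, fdr_max = 0.25,
                             n_pathway = 10L, n_go = 5L) {
  keep <- rows[rows$p < p_max & rows$fdr < fdr_max, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  keep <- keep[order(keep$p, -keep$k, keep$term_id), , drop = FALSE]
  pieces <- lapply(split(keep, keep$category), function(d) {
    utils::head(d, if (d$category[1] == "pathway") n_pathway else n_go)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$p, -out$k, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
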