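#' Estimate empirical-Bayes variance-shrinkage hyperparameters
#'
#' Fits a scaled inverse-chi-square prior to per-probe sample variances by
#' moment matching on the log scale (digamma/trigamma matching), the
#' standard empirical-Bayes scheme for microarray variance moderation.
#' Under the model s2_g ~ s0^2 * F(d, d0), `log(s2)` has finite moments for
#' every d0 > 0, so the fit is stable even for heavy-tailed variance
#' distributions where raw-scale moments diverge.
#'
#' @param sample_variances per-probe sample variances (length >= 10).
#' @param d residual degrees of freedom of each variance (scalar).
#' @return a `ShrinkageParams` list with `d0` (prior df, possibly `Inf`)
#'   and `s0_sq` (prior variance).
#' @export
estimate_shrinkage <- function(sample_variances, d) {
  v <- sample_variances[is.finite(sample_variances)]
  if (length(v) < 10) stop("need at least 10 probe variances to estimate shrinkage")
  if (d < 1) stop("residual df must be >= 1")
  if (all(v == v[1]))
    return(structure(list(d0 = Inf, s0_sq = v[1]), class = "ShrinkageParams"))
  # zero variances carry no log-scale information; offset by smallest positive
  if (any(v <= 0)) v[v <= 0] <- min(v[v > 0]) * 1e-4
  z <- log(v)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- mean((e - ebar)^2) * n / (n - 1) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    # variances no more dispersed than chi-square: infinite prior df, and
    # E[s2] = s0^2 exactly, so the arithmetic mean is the moment estimate
    d0 <- Inf
    s0_sq <- mean(v)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  if (!is.finite(s0_sq) || s0_sq <= 0) {
    warning("degenerate variance distribution; falling back to d0 = 0")
    return(structure(list(d0 = 0, s0_sq = mean(v)), class = "ShrinkageParams"))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ShrinkageParams")
}

# Newton solve of trigamma(y) = x for y > 0 (x > 0). Monotone decreasing
# target; iterate on 1/y-ish scale for stability at small x.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Per-probe moderated t-test between two sample groups
#'
#' The GEO2R-equivalent differential-expression engine: per probe, the log2
#' fold change is the difference of group means (first contrast group minus
#' second), the pooled residual variance is shrunk towards an
#' empirical-Bayes prior, posterior variance
#' `s2_tilde = (d0*s0^2 + d*s2) / (d0 + d)` with `d = nA + nB - 2`, and
#' `t = logFC / (s_tilde * sqrt(1/nA + 1/nB))` is referred to a t
#' distribution on `d0 + d` degrees of freedom. P values are two-sided;
#' `adj_p` is Benjamini-Hochberg over all retained probes.
#'
#' Probes with fewer than 2 finite values in either group are dropped (a
#' message reports how many). With `shrinkage = "estimate"` the prior is
#' fitted with [estimate_shrinkage()]; `d0 = 0` reproduces the ordinary
#' pooled two-sample t, `d0 = Inf` the fully shrunk limit.
#'
#' @param dataset an [expression_dataset()].
#' @param contrast character of length 2: `c(A, B)`, logFC = mean(A) - mean(B).
#' @param shrinkage `"estimate"` or a `ShrinkageParams`-like list with
#'   `d0` and `s0_sq`.
#' @param engine `"moderated"` (default) or `"welch"` for a plain Welch t
#'   sensitivity analysis (no shrinkage, Welch-Satterthwaite df).
#' @return data.frame with columns `probe_id`, `gene`, `logFC`, `t`, `p`,
#'   `adj_p`, plus attribute `shrinkage`.
#' @export
moderated_t_test <- function(dataset, contrast, shrinkage = "estimate",
                             engine = c("moderated", "welch")) {
  stopifnot(inherits(dataset, "ExpressionDataset"), length(contrast) == 2)
  engine <- match.arg(engine)
  groups <- dataset$sample_groups
  a_cols <- names(groups)[groups == contrast[1]]
  b_cols <- names(groups)[groups == contrast[2]]
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop(sprintf("each contrast group needs >= 2 samples (got %d '%s', %d '%s')",
                 length(a_cols), contrast[1], length(b_cols), contrast[2]))
  A <- dataset$values[, a_cols, drop = FALSE]
  B <- dataset$values[, b_cols, drop = FALSE]
  nA <- rowSums(is.finite(A)); nB <- rowSums(is.finite(B))
  keep <- nA >= 2 & nB >= 2
  if (!all(keep))
    message(sum(!keep), " probe(s) dropped: fewer than 2 finite values in a group")
  if (!any(keep)) stop("no probe has >= 2 usable samples per group")
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  nA <- nA[keep]; nB <- nB[keep]
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  logfc <- mA - mB
  ssA <- rowSums((A - mA)^2, na.rm = TRUE)
  ssB <- rowSums((B - mB)^2, na.rm = TRUE)

  if (engine == "welch") {
    vA <- ssA / (nA - 1); vB <- ssB / (nB - 1)
    se2 <- vA / nA + vB / nB
    tt <- ifelse(se2 > 0, logfc / sqrt(se2), ifelse(logfc == 0, 0, sign(logfc) * Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)), nA + nB - 2)
    pp <- ifelse(is.finite(tt), 2 * stats::pt(-abs(tt), df), ifelse(tt == 0, 1, 0))
    shr <- list(d0 = NA_real_, s0_sq = NA_real_)
  } else {
    d <- nA + nB - 2
    s2 <- (ssA + ssB) / d
    if (identical(shrinkage, "estimate")) {
      shr <- tryCatch(estimate_shrinkage(s2, d = stats::median(d)),
                      error = function(e) {
                        warning("shrinkage estimation failed (", conditionMessage(e),
                                "); falling back to d0 = 0")
                        list(d0 = 0, s0_sq = mean(s2))
                      })
    } else shr <- shrinkage
    d0 <- shr$d0; s0 <- shr$s0_sq
    s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else (d0 * s0 + d * s2) / (d0 + d)
    se <- sqrt(s2_post * (1 / nA + 1 / nB))
    tt <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
    df <- d0 + d
    pp <- ifelse(is.finite(tt), 2 * stats::pt(-abs(tt), df), ifelse(tt == 0, 1, 0))
  }
  out <- data.frame(probe_id = rownames(A),
                    gene = unname(dataset$probe_to_gene[rownames(A)]),
                    logFC = unname(logfc), t = unname(tt), p = unname(pp),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$adj_p <- bh_adjust(out$p)
  attr(out, "shrinkage") <- shr
  attr(out, "dataset_id") <- dataset$dataset_id
  attr(out, "contrast") <- contrast
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1 (thin validated
#' wrapper over `p.adjust`).
#'
#' @param p vector of P values in `[0, 1]`.
#' @return adjusted P values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Collapse probe-level statistics to one row per gene
#'
#' Probes with an empty gene symbol are dropped. Per symbol the row with the
#' smallest P is kept (ties: larger |logFC|, then lexicographically smallest
#' probe id), `n_probes` records how many probes were collapsed. Genes whose
#' significant probes (p < `alpha`) disagree in logFC sign are flagged
#' `ambiguous` and are excluded from downstream consensus selection.
#'
#' @param probe_table output of [moderated_t_test()].
#' @param probe_to_gene optional named map overriding the table's `gene`
#'   column.
#' @param alpha significance level used for the sign-disagreement flag.
#' @return a `DiffExprTable`: data.frame with `gene`, `logFC`, `t`, `p`,
#'   `adj_p`, `n_probes`, `ambiguous`, carrying `dataset_id` and `contrast`
#'   attributes.
#' @export
collapse_probes <- function(probe_table, probe_to_gene = NULL, alpha = 0.05) {
  stopifnot(all(c("probe_id", "logFC", "p") %in% names(probe_table)))
  tab <- probe_table
  if (!is.null(probe_to_gene))
    tab$gene <- unname(normalize_symbols(probe_to_gene[tab$probe_id]))
  tab <- tab[!is.na(tab$gene) & nzchar(tab$gene), , drop = FALSE]
  if (!nrow(tab)) {
    out <- data.frame(gene = character(), logFC = numeric(), t = numeric(),
                      p = numeric(), adj_p = numeric(), n_probes = integer(),
                      ambiguous = logical(), probe_id = character())
  } else {
    ord <- order(tab$gene, tab$p, -abs(tab$logFC), tab$probe_id)
    tab <- tab[ord, , drop = FALSE]
    first <- !duplicated(tab$gene)
    n_probes <- as.integer(table(tab$gene)[tab$gene[first]])
    sig <- tab[tab$p < alpha, , drop = FALSE]
    amb_genes <- unique(sig$gene[ave(sign(sig$logFC), sig$gene,
                                     FUN = function(s) length(unique(s[s != 0]))) > 1])
    out <- data.frame(gene = tab$gene[first], logFC = tab$logFC[first],
                      t = tab$t[first], p = tab$p[first], adj_p = tab$adj_p[first],
                      n_probes = n_probes,
                      ambiguous = tab$gene[first] %in% amb_genes,
                      probe_id = tab$probe_id[first],
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$p, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dataset_id") <- attr(probe_table, "dataset_id")
  attr(out, "contrast") <- attr(probe_table, "contrast")
  class(out) <- c("DiffExprTable", "data.frame")
  out
}

#' Full per-dataset differential expression
#'
#' Convenience wrapper: [moderated_t_test()] then [collapse_probes()].
#'
#' @inheritParams moderated_t_test
#' @param alpha significance level for the probe sign-disagreement flag.
#' @return a `DiffExprTable`.
#' @export
diff_expr <- function(dataset, contrast, shrinkage = "estimate",
                      engine = c("moderated", "welch"), alpha = 0.05) {
  collapse_probes(moderated_t_test(dataset, contrast, shrinkage, engine),
                  alpha = alpha)
}

#' Read a GEO2R-style differential-expression export
#'
#' Auto-detects the GEO2R TSV dialect by header (columns `ID`,
#' `adj.P.Val`, `P.Value`, `t`, `logFC`, `Gene.symbol`) and collapses it to
#' a `DiffExprTable`; plain tables with columns `gene`, `logFC`, `p`
#' (optionally `t`, `adj_p`, `n_probes`, `ambiguous`) are passed through.
#'
#' @param path TSV path.
#' @param dataset_id identifier stored on the table.
#' @param alpha significance level for the sign-disagreement flag.
#' @return a `DiffExprTable`.
#' @export
read_diffexpr_table <- function(path, dataset_id = NULL, alpha = 0.05) {
  dataset_id <- dataset_id %||% sub("[._].*$", "", basename(path))
  df <- read_tsv_plain(path)
  if (all(c("ID", "P.Value", "logFC") %in% names(df))) {
    tab <- data.frame(probe_id = as.character(df$ID),
                      gene = normalize_symbols(df[["Gene.symbol"]] %||% ""),
                      logFC = as.numeric(df$logFC),
                      t = as.numeric(df[["t"]] %||% NA),
                      p = as.numeric(df$P.Value),
                      adj_p = as.numeric(df[["adj.P.Val"]] %||% bh_adjust(df$P.Value)),
                      stringsAsFactors = FALSE)
    attr(tab, "dataset_id") <- dataset_id
    return(collapse_probes(tab, alpha = alpha))
  }
  if (!all(c("gene", "logFC", "p") %in% names(df)))
    stop("unrecognised differential-expression table dialect in ", path)
  df$gene <- normalize_symbols(df$gene)
  if (is.null(df$adj_p)) df$adj_p <- bh_adjust(df$p)
  if (is.null(df$t)) df$t <- NA_real_
  if (is.null(df$n_probes)) df$n_probes <- 1L
  if (is.null(df$ambiguous)) df$ambiguous <- FALSE
  df$ambiguous <- as.logical(df$ambiguous)
  out <- df[, c("gene", "logFC", "t", "p", "adj_p", "n_probes", "ambiguous")]
  attr(out, "dataset_id") <- dataset_id
  class(out) <- c("DiffExprTable", "data.frame")
  out
}

#' Write a DiffExprTable to TSV
#'
#' @param x a `DiffExprTable`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_diffexpr_table <- function(x, path) {
  write_tsv_stable(as.data.frame(x)[, c("gene", "logFC", "t", "p", "adj_p",
                                        "n_probes", "ambiguous")], path)
}
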