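# Small builders shared across test files.

# Minimal two-group expression dataset from a probe x sample matrix.
make_dataset <- function(values, genes = NULL, groups = NULL, id = "DS1") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(groups))
    groups <- rep(c("a", "b"), length.out = ncol(values))
  expression_dataset(id, values,
                     stats::setNames(genes, rownames(values)),
                     stats::setNames(groups, colnames(values)))
}

# DiffExprTable straight from per-gene vectors (bypasses probe level).
make_de_table <- function(gene, logFC, p, adj_p = NULL, id = "DS1",
                          ambiguous = FALSE) {
  out <- data.frame(gene = gene, logFC = logFC, t = logFC, p = p,
                    adj_p = adj_p %||% p.adjust(p, "BH"),
                    n_probes = 1L,
                    ambiguous = rep(ambiguous, length.out = length(gene)),
                    stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- id
  class(out) <- c("DiffExprTable", "data.frame")
  out
}

# Random two-group dataset on the log2 scale.
random_dataset <- function(n_probes = 20, n_per_group = 4, sd = 1, id = "RND") {
  x <- matrix(rnorm(n_probes * 2 * n_per_group, 8, sd), nrow = n_probes)
  make_dataset(x, groups = rep(c("a", "b"), each = n_per_group), id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
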