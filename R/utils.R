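#' Normalise gene symbols
#'
#' Uppercases and trims symbols so matching across platforms is
#' case-insensitive. Idempotent. An optional two-column alias table
#' (columns `alias`, `symbol`) is applied after uppercasing.
#'
#' @param x character vector of gene symbols (may contain `""` for
#'   unannotated probes; empty strings are preserved).
#' @param alias optional data.frame with columns `alias` and `symbol`.
#' @return character vector of the same length.
#' @export
normalize_symbols <- function(x, alias = NULL) {
  out <- toupper(trimws(as.character(x)))
  out[is.na(out)] <- ""
  if (!is.null(alias)) {
    stopifnot(all(c("alias", "symbol") %in% names(alias)))
    key <- toupper(trimws(alias$alias))
    val <- toupper(trimws(alias$symbol))
    hit <- match(out, key)
    out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  out
}

# Fixed-format number serialisation: 6 significant digits, plain decimal
# or scientific as needed, so TSV outputs are diff-able and bit-stable.
fmt_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

# Stable TSV writer: no quotes, no row names, "." decimal regardless of
# locale, numeric columns serialised with fmt_num.
write_tsv_stable <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sign() that returns exactly -1, 0, +1 as integer
sign_int <- function(x) as.integer(sign(x))
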