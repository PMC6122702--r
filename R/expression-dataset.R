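#' Construct an ExpressionDataset
#'
#' Container for one accession's log2 expression matrix together with its
#' probe-to-gene annotation and sample group labels. This is the unit on
#' which per-dataset differential expression is computed.
#'
#' @param dataset_id accession-style identifier (e.g. `"GSE57083"`).
#' @param values numeric matrix of log2 intensities, probes in rows
#'   (rownames = probe ids), samples in columns (colnames = sample ids).
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol; probes absent from the map get an empty symbol. Symbols are
#'   normalised with [normalize_symbols()].
#' @param sample_groups named character vector mapping every sample id to a
#'   group label; at least two distinct labels are required.
#' @param platform_id optional platform identifier.
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(dataset_id, values, probe_to_gene,
                               sample_groups, platform_id = "") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (!is.numeric(values)) stop("expression values must be numeric")
  missing_grp <- setdiff(colnames(values), names(sample_groups))
  if (length(missing_grp))
    stop("sample(s) without a group label: ", paste(missing_grp, collapse = ", "))
  sample_groups <- sample_groups[colnames(values)]
  if (length(unique(sample_groups)) < 2)
    stop("need at least two distinct group labels")
  p2g <- stats::setNames(rep("", nrow(values)), rownames(values))
  if (length(probe_to_gene)) {
    known <- intersect(names(probe_to_gene), rownames(values))
    p2g[known] <- normalize_symbols(probe_to_gene[known])
  }
  structure(
    list(dataset_id = dataset_id, platform_id = platform_id,
         values = values, probe_to_gene = p2g, sample_groups = sample_groups),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset", x$dataset_id,
      sprintf("(%d probes x %d samples; groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$sample_groups), collapse = " / ")))
  invisible(x)
}

#' Read an ExpressionDataset from TSV files
#'
#' The matrix file is a TSV with probe ids in the first column and sample
#' ids in the header; the groups file is a two-column TSV (`sample`,
#' `group`); the annotation file a two-column TSV (`probe`, `symbol`).
#' Probes with no annotation entry get an empty symbol.
#'
#' @param matrix_path,groups_path,annot_path file paths.
#' @param dataset_id,platform_id identifiers stored on the object; the
#'   default uses the matrix file name.
#' @param log2_transform `"auto"` applies `log2(x + 1)` when the matrix
#'   maximum exceeds 50 (mirroring GEO2R auto-detection); `"on"` always
#'   applies it; `"off"` never does.
#' @return an [expression_dataset()].
#' @export
read_expression_dataset <- function(matrix_path, groups_path, annot_path,
                                    dataset_id = NULL, platform_id = "",
                                    log2_transform = c("auto", "off", "on")) {
  log2_transform <- match.arg(log2_transform)
  dataset_id <- dataset_id %||% sub("[._].*$", "", basename(matrix_path))
  raw <- utils::read.delim(matrix_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("matrix file needs a probe column plus >=1 sample")
  probes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals), dimnames(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "", "NaN")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row %d (probe %s), column '%s'",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1], probes[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  rownames(num) <- probes
  if (log2_transform == "on" ||
      (log2_transform == "auto" && max(num, na.rm = TRUE) > 50))
    num <- log2(num + 1)

  grp <- read_tsv_plain(groups_path)
  if (ncol(grp) < 2) stop("groups file needs two columns (sample, group)")
  groups <- stats::setNames(as.character(grp[[2]]), as.character(grp[[1]]))

  ann <- read_tsv_plain(annot_path)
  if (ncol(ann) < 2) stop("annotation file needs two columns (probe, symbol)")
  p2g <- stats::setNames(as.character(ann[[2]]), as.character(ann[[1]]))

  expression_dataset(dataset_id, num, p2g, groups, platform_id = platform_id)
}

#' Write an ExpressionDataset to TSV files
#'
#' Inverse of [read_expression_dataset()]; values are serialised with 6
#' significant digits.
#'
#' @param x an `ExpressionDataset`.
#' @param matrix_path,groups_path,annot_path output paths.
#' @return invisibly, the matrix path.
#' @export
write_expression_dataset <- function(x, matrix_path, groups_path, annot_path) {
  stopifnot(inherits(x, "ExpressionDataset"))
  df <- data.frame(ID = rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_stable(df, matrix_path)
  write_tsv_stable(data.frame(sample = names(x$sample_groups),
                              group = unname(x$sample_groups)), groups_path)
  write_tsv_stable(data.frame(probe = names(x$probe_to_gene),
                              symbol = unname(x$probe_to_gene)), annot_path)
  invisible(matrix_path)
}

#' Convert a GEO series-matrix file to the TSV matrix + groups form
#'
#' Thin converter for `*_series_matrix.txt`: metadata lines starting with
#' `!` are skipped (sample titles are taken from `!Sample_title` when
#' present and written alongside), and the table between
#' `!series_matrix_table_begin`/`_end` becomes the probe x sample TSV.
#'
#' @param path series-matrix file.
#' @param matrix_out output TSV path for the expression table.
#' @param titles_out optional output TSV path for (sample, title) pairs.
#' @return invisibly, `matrix_out`.
#' @export
convert_series_matrix <- function(path, matrix_out, titles_out = NULL) {
  lines <- readLines(path, warn = FALSE)
  titles <- grep("^!Sample_title", lines, value = TRUE)
  tab <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(tab)) stop("no expression table found in ", path)
  writeLines(gsub('"', "", tab), matrix_out)
  if (!is.null(titles_out) && length(titles)) {
    fields <- strsplit(gsub('"', "", titles[1]), "\t")[[1]][-1]
    header <- strsplit(gsub('"', "", tab[1]), "\t")[[1]][-1]
    n <- min(length(fields), length(header))
    write_tsv_stable(data.frame(sample = header[seq_len(n)],
                                title = fields[seq_len(n)]), titles_out)
  }
  invisible(matrix_out)
}
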