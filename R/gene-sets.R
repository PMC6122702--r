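#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `term<TAB>description<TAB>member1<TAB>member2...`. Member symbols are
#' uppercased; empty member lists are rejected.
#'
#' @param path GMT file path.
#' @param category category assigned to every set in this file, one of
#'   `"pathway"`, `"MF"`, `"CC"`, `"BP"`, or a named character vector /
#'   two-column data.frame (`term`, `category`) giving a per-term sidecar
#'   mapping.
#' @return a `GeneSetCollection`: a list with element `sets`, a named list
#'   of `list(name, category, genes)`.
#' @export
read_gmt <- function(path, category = "pathway") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields (term, description, >=1 member)", i))
    sets[[f[1]]] <- list(name = f[2], category = NA_character_,
                         genes = unique(normalize_symbols(f[-(1:2)])))
  }
  if (is.data.frame(category))
    category <- stats::setNames(as.character(category[[2]]), as.character(category[[1]]))
  for (term in names(sets)) {
    sets[[term]]$category <- if (length(category) == 1L && is.null(names(category)))
      category else unname(category[term] %||% NA_character_)
    if (is.na(sets[[term]]$category))
      sets[[term]]$category <- "pathway"
  }
  gene_set_collection(sets)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of `list(name, category, genes)`; categories must
#'   be in `pathway`, `MF`, `CC`, `BP`; no empty member lists.
#' @return a `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a non-empty named list")
  for (term in names(sets)) {
    s <- sets[[term]]
    if (!length(s$genes)) stop("empty member list for set ", term)
    if (!s$category %in% c("pathway", "MF", "CC", "BP"))
      stop("unknown category '", s$category, "' for set ", term)
    sets[[term]]$genes <- unique(normalize_symbols(s$genes))
  }
  structure(list(sets = sets), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection with", length(x$sets), "sets\n")
  invisible(x)
}

#' Write a GeneSetCollection to GMT
#'
#' @param x a `GeneSetCollection`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "GeneSetCollection"))
  lines <- vapply(names(x$sets), function(term) {
    s <- x$sets[[term]]
    paste(c(term, s$name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a curated gene list (e.g. tumour-derived metabolic genes)
#'
#' Accepts either one symbol per line or a CSV with a symbol column
#' (named `symbol`, `gene`, or the first column). Symbols are uppercased
#' and deduplicated.
#'
#' @param path file path.
#' @param direction `"up"` or `"down"`: the direction of regulation in the
#'   tumours this list encodes.
#' @param source free-text provenance.
#' @return an `HMGList`: list with `direction`, `genes`, `source`.
#' @export
read_hmg_list <- function(path, direction = c("up", "down"), source = basename(path)) {
  direction <- match.arg(direction)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene list file: ", path)
  if (grepl(",", lines[1])) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    col <- intersect(c("symbol", "gene", "Symbol", "Gene"), names(df))
    genes <- if (length(col)) df[[col[1]]] else df[[1]]
  } else {
    genes <- lines
    if (normalize_symbols(genes[1]) %in% c("SYMBOL", "GENE")) genes <- genes[-1]
  }
  hmg_list(genes, direction, source)
}

#' Construct an HMGList
#'
#' @param genes character vector of symbols.
#' @param direction `"up"` or `"down"`.
#' @param source free-text provenance.
#' @return an `HMGList`.
#' @export
hmg_list <- function(genes, direction = c("up", "down"), source = "") {
  direction <- match.arg(direction)
  genes <- unique(normalize_symbols(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene list is empty after normalisation")
  structure(list(direction = direction, genes = genes, source = source),
            class = "HMGList")
}

#' Check that up and down gene lists are disjoint
#'
#' @param up,down `HMGList` objects with directions `"up"` and `"down"`.
#' @return invisibly `TRUE`; error listing shared symbols otherwise.
#' @export
validate_hmg_pair <- function(up, down) {
  stopifnot(inherits(up, "HMGList"), inherits(down, "HMGList"))
  if (up$direction != "up" || down$direction != "down")
    stop("expected an up-list and a down-list, in that order")
  shared <- intersect(up$genes, down$genes)
  if (length(shared))
    stop("symbol(s) present in both up and down lists: ",
         paste(shared, collapse = ", "))
  invisible(TRUE)
}
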