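#' Assign tumour-altered metabolic genes to the cell line that mimics them
#'
#' For two representative cell lines (by default HLE, poorly
#' differentiated, and HUH7, well differentiated) and two independent
#' expression datasets, the per-gene difference `HLE - HUH7` is computed in
#' each dataset. A gene from the up-list is assigned to HLE when the delta
#' is positive in both datasets (HLE reproduces the tumour's upregulation),
#' and to HUH7 when negative in both; down-list genes symmetrically
#' (negative deltas in both -> HLE). Disagreeing or zero deltas give
#' `ambiguous`. Genes absent from either dataset are excluded (a message
#' reports how many).
#'
#' Protein evidence, when supplied, is recorded as `protein_support`
#' (`agrees` / `disagrees` / `absent`, comparing the sign of the log
#' protein fold to the agreed transcript delta sign); with
#' `protein_veto = TRUE`, assignments whose protein evidence disagrees are
#' demoted to `ambiguous`.
#'
#' @param hmg_up,hmg_down `HMGList` objects (directions `"up"`, `"down"`).
#' @param deltas named list of exactly two named numeric vectors of log2
#'   differences (first cell line minus second), one per dataset.
#' @param protein optional `ProteomicsTable` ([proteomics_table()]), folds
#'   oriented first-cell-line / second-cell-line.
#' @param cell_lines labels of the two cell lines; the first is the one a
#'   direction-matching delta assigns.
#' @param protein_veto demote protein-contradicted assignments to ambiguous.
#' @return data.frame with `gene`, `hmg_direction`, one `delta_<dataset>`
#'   sign column per dataset, `delta_sign` (agreed sign or 0),
#'   `assigned_to`, `protein_support`.
#' @export
assign_hmg_mimicry <- function(hmg_up, hmg_down, deltas, protein = NULL,
                               cell_lines = c("HLE", "HUH7"),
                               protein_veto = FALSE) {
  validate_hmg_pair(hmg_up, hmg_down)
  if (length(deltas) != 2)
    stop("exactly two delta datasets are required, got ", length(deltas))
  if (is.null(names(deltas))) names(deltas) <- paste0("dataset", 1:2)
  genes <- c(stats::setNames(rep("up", length(hmg_up$genes)), hmg_up$genes),
             stats::setNames(rep("down", length(hmg_down$genes)), hmg_down$genes))
  present <- names(genes) %in% names(deltas[[1]]) &
    names(genes) %in% names(deltas[[2]])
  if (any(!present))
    message(sum(!present), " gene(s) absent from at least one delta dataset; excluded")
  genes <- genes[present]
  if (!length(genes)) stop("no curated gene is present in both delta datasets")
  s1 <- sign_int(deltas[[1]][names(genes)])
  s2 <- sign_int(deltas[[2]][names(genes)])
  agreed <- ifelse(s1 == s2 & s1 != 0L, s1, 0L)
  dir_sign <- ifelse(unname(genes) == "up", 1L, -1L)
  assigned <- ifelse(agreed == 0L, "ambiguous",
                     ifelse(agreed == dir_sign, cell_lines[1], cell_lines[2]))

  support <- rep("absent", length(genes))
  if (!is.null(protein)) {
    i <- match(names(genes), protein$gene)
    pf <- sign_int(log(protein$mean_fold[i]))
    has <- !is.na(pf) & agreed != 0L
    support[has] <- ifelse(pf[has] == agreed[has], "agrees", "disagrees")
    support[!is.na(pf) & agreed == 0L] <- "absent"
    if (protein_veto) assigned[support == "disagrees"] <- "ambiguous"
  }
  out <- data.frame(gene = names(genes), hmg_direction = unname(genes),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[[paste0("delta_", names(deltas)[1])]] <- unname(s1)
  out[[paste0("delta_", names(deltas)[2])]] <- unname(s2)
  out$delta_sign <- unname(agreed)
  out$assigned_to <- unname(assigned)
  out$protein_support <- support
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate mimicry assignments by metabolic process
#'
#' Counts assigned genes per (process, cell line, direction); genes without
#' a process mapping are counted under `"Others"`. Ambiguous assignments
#' are not counted.
#'
#' @param assignments output of [assign_hmg_mimicry()].
#' @param process_map named character vector (gene -> process) or a
#'   two-column data.frame (gene, process).
#' @return data.frame with `process`, `cell_line`, `direction`, `count`,
#'   all observed combinations included (zero rows omitted).
#' @export
aggregate_by_process <- function(assignments, process_map) {
  if (is.data.frame(process_map))
    process_map <- stats::setNames(as.character(process_map[[2]]),
                                   normalize_symbols(process_map[[1]]))
  a <- assignments[assignments$assigned_to != "ambiguous", , drop = FALSE]
  if (!nrow(a))
    return(data.frame(process = character(), cell_line = character(),
                      direction = character(), count = integer()))
  proc <- process_map[a$gene]
  proc[is.na(proc)] <- "Others"
  out <- as.data.frame(table(process = proc, cell_line = a$assigned_to,
                             direction = a$hmg_direction),
                       stringsAsFactors = FALSE)
  names(out)[4] <- "count"
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(out$process, out$cell_line, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
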