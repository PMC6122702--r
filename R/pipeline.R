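pipeline_defaults <- function() {
  list(alpha = 0.05, k_min = 2L, alpha_adj = 1e-4, top_n = 100L,
       p_max = 1e-4, fdr_max = 0.25, min_peptides = 2L, min_fold = 2,
       enrich_mode = "ease", protein_veto = FALSE, engine = "moderated",
       seed = 1L, stages = c("diffexpr", "consensus", "zrank", "concordance",
                             "mimicry", "enrichment", "proteomics"))
}

known_config_keys <- function() {
  c("datasets", "hmg_up", "hmg_down", "gmt", "gmt_categories", "proteomics",
    "process_map", "deltas", "out_dir", names(pipeline_defaults()))
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML path or a list. Unknown keys are rejected (typo safety),
#' thresholds are range-checked, referenced paths must exist, and defaults
#' are filled in: `alpha = 0.05`, `k_min = 2`, `alpha_adj = 1e-4`,
#' `top_n = 100`, `p_max = 1e-4`, `fdr_max = 0.25`, `min_peptides = 2`,
#' `min_fold = 2`, EASE enrichment, moderated-t engine.
#'
#' The `datasets` entry is a list of records with fields `id`, `role`
#' (`cellline` or `tumour`), `matrix`, `groups`, `annot` (or `geo2r` for a
#' precomputed export), and optional `contrast` (two group labels, first
#' minus second; defaults to `poorly_diff` vs `well_diff` for cell lines
#' and `tumour` vs `non_tumour` for tumours).
#'
#' @param config YAML file path or config list.
#' @return validated `PipelineConfig` list with defaults applied.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), known_config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    stop("config must list at least one dataset")
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  for (nm in c("alpha", "alpha_adj", "p_max", "fdr_max")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop(nm, " must be in (0, 1], got ", v)
  }
  if (cfg$min_fold < 1) stop("min_fold must be >= 1")
  if (cfg$min_peptides < 0) stop("min_peptides must be >= 0")
  if (cfg$top_n < 1) stop("top_n must be >= 1")
  if (!cfg$enrich_mode %in% c("ease", "standard"))
    stop("enrich_mode must be 'ease' or 'standard'")
  if (!cfg$engine %in% c("moderated", "welch"))
    stop("engine must be 'moderated' or 'welch'")
  bad_stage <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad_stage)) stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  roles <- vapply(cfg$datasets, function(d) d$role %||% stop("dataset without role"), "")
  if (!all(roles %in% c("cellline", "tumour")))
    stop("dataset role must be 'cellline' or 'tumour'")
  n_cl <- sum(roles == "cellline")
  if (cfg$k_min < 1 || cfg$k_min > n_cl)
    stop(sprintf("k_min (%d) must be between 1 and the number of cell-line datasets (%d)",
                 cfg$k_min, n_cl))
  for (d in cfg$datasets) {
    if (is.null(d$id)) stop("every dataset needs an id")
    paths <- unlist(d[intersect(names(d), c("matrix", "groups", "annot", "geo2r"))])
    if (!length(paths)) stop("dataset ", d$id, " has no input paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("dataset ", d$id, ": missing input file(s): ",
           paste(missing, collapse = ", "))
  }
  for (nm in c("hmg_up", "hmg_down", "gmt", "proteomics", "process_map",
               "gmt_categories")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop(nm, " file not found: ", cfg[[nm]])
  }
  if (!is.null(cfg$deltas)) {
    if (length(cfg$deltas) != 2) stop("deltas must list exactly two tables")
    for (pth in unlist(cfg$deltas))
      if (!file.exists(pth)) stop("delta table not found: ", pth)
  }
  structure(cfg, class = "PipelineConfig")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

default_contrast <- function(role) {
  if (role == "cellline") c("poorly_diff", "well_diff") else c("tumour", "non_tumour")
}

#' Run the full cross-dataset concordance pipeline
#'
#' Executes, in order and as requested via `config$stages`: per-dataset
#' differential expression; consensus selection across cell-line datasets
#' (both directions); z-score-of-fold ranking across tumour datasets;
#' concordance calling; metabolic-gene mimicry assignment (when `deltas`
#' and the curated lists are configured); gene-set enrichment of the
#' consensus sets (when `gmt` is configured); proteomics overlay (when
#' `proteomics` is configured). Every stage writes its TSV under
#' `out_dir`, a `manifest.json` records the config hash, seed and package
#' version, and `summary.tsv` the headline counts. Per-stage gene counts
#' are logged to stderr so silent filtering is auditable.
#'
#' @param config a `PipelineConfig`, config list, or YAML path.
#' @return invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "PipelineConfig")) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, paste0(...))
  set.seed(cfg$seed)
  res <- list(out_dir = cfg$out_dir)
  summary_rows <- list()
  note <- function(key, value)
    summary_rows[[length(summary_rows) + 1]] <<- data.frame(key = key, value = value)
  run_stage <- function(stage) stage %in% cfg$stages

  roles <- vapply(cfg$datasets, function(d) d$role, "")
  ids <- vapply(cfg$datasets, function(d) d$id, "")

  ## diffexpr -----------------------------------------------------------
  tables <- list()
  if (run_stage("diffexpr")) {
    for (d in cfg$datasets) {
      tab <- tryCatch({
        if (!is.null(d$geo2r)) {
          read_diffexpr_table(d$geo2r, dataset_id = d$id, alpha = cfg$alpha)
        } else {
          ds <- read_expression_dataset(d$matrix, d$groups, d$annot,
                                        dataset_id = d$id)
          diff_expr(ds, d$contrast %||% default_contrast(d$role),
                    engine = cfg$engine, alpha = cfg$alpha)
        }
      }, error = function(e)
        stop("stage diffexpr failed on dataset ", d$id, ": ",
             conditionMessage(e), call. = FALSE))
      stage_log("diffexpr", d$id, ": ", nrow(tab), " genes (",
                sum(tab$ambiguous), " ambiguous)")
      write_diffexpr_table(tab, out("diffexpr_", d$id, ".tsv"))
      tables[[d$id]] <- tab
    }
    res$tables <- tables
  }
  cl_tables <- tables[ids[roles == "cellline"]]
  tm_tables <- tables[ids[roles == "tumour"]]

  ## consensus ----------------------------------------------------------
  if (run_stage("consensus") && length(cl_tables)) {
    res$consensus_up <- consensus_select(cl_tables, "up", cfg$k_min, cfg$alpha)
    res$consensus_down <- consensus_select(cl_tables, "down", cfg$k_min, cfg$alpha)
    stage_log("consensus", length(res$consensus_up$members), " up / ",
              length(res$consensus_down$members), " down genes in >= ",
              cfg$k_min, " datasets")
    write_tsv_stable(rbind(as.data.frame(res$consensus_up),
                           as.data.frame(res$consensus_down)),
                     out("consensus.tsv"))
    note("consensus_up", length(res$consensus_up$members))
    note("consensus_down", length(res$consensus_down$members))
    core_up <- top_core_genes(cl_tables, "up", cfg$top_n, cfg$alpha_adj)
    core_dn <- top_core_genes(cl_tables, "down", cfg$top_n, cfg$alpha_adj)
    write_tsv_stable(data.frame(
      gene = c(core_up, core_dn),
      direction = rep(c("up", "down"), c(length(core_up), length(core_dn)))),
      out("core_genes.tsv"))
    note("core_up", length(core_up)); note("core_down", length(core_dn))
    res$core_up <- core_up; res$core_down <- core_dn
  }

  ## z-score ranking across tumour datasets -----------------------------
  if (run_stage("zrank") && length(tm_tables)) {
    profiles <- lapply(tm_tables, zscore_fold, alpha = cfg$alpha)
    consensus_genes <- c(names(res$consensus_up$members %||% NULL),
                         names(res$consensus_down$members %||% NULL))
    res$zrank <- average_z_rank(profiles,
                                genes = if (length(consensus_genes))
                                  sort(consensus_genes) else NULL)
    stage_log("zrank", nrow(res$zrank), " genes ranked over ",
              length(profiles), " tumour datasets")
    write_tsv_stable(res$zrank, out("zrank.tsv"))
  }

  ## concordance --------------------------------------------------------
  if (run_stage("concordance") && length(tm_tables) &&
      !is.null(res$consensus_up)) {
    res$concordance <- classify_concordance(
      list(res$consensus_up, res$consensus_down), tm_tables, alpha = cfg$alpha)
    tally <- table(res$concordance$call)
    stage_log("concordance", paste(names(tally), tally, collapse = ", "))
    write_tsv_stable(res$concordance, out("concordance.tsv"))
    for (k in c("concordant", "discordant", "unclassified"))
      note(paste0("concordance_", k), sum(res$concordance$call == k))
  }

  ## mimicry ------------------------------------------------------------
  if (run_stage("mimicry") && !is.null(cfg$deltas) &&
      !is.null(cfg$hmg_up) && !is.null(cfg$hmg_down)) {
    hmg_up <- read_hmg_list(cfg$hmg_up, "up")
    hmg_dn <- read_hmg_list(cfg$hmg_down, "down")
    deltas <- lapply(cfg$deltas, function(pth) {
      df <- read_tsv_plain(pth)
      stats::setNames(as.numeric(df[[2]]), normalize_symbols(df[[1]]))
    })
    if (is.null(names(deltas)) || !all(nzchar(names(deltas))))
      names(deltas) <- paste0("delta", seq_along(deltas))
    prot <- if (!is.null(cfg$proteomics))
      filter_significant_proteins(read_proteomics_table(cfg$proteomics),
                                  cfg$min_peptides, cfg$alpha) else NULL
    res$mimicry <- assign_hmg_mimicry(hmg_up, hmg_dn, deltas, protein = prot,
                                      protein_veto = cfg$protein_veto)
    tally <- table(res$mimicry$assigned_to)
    stage_log("mimicry", paste(names(tally), tally, collapse = ", "))
    write_tsv_stable(res$mimicry, out("mimicry.tsv"))
    for (k in names(tally)) note(paste0("mimicry_", k), as.integer(tally[k]))
    if (!is.null(cfg$process_map)) {
      pm <- read_tsv_plain(cfg$process_map)
      res$process_counts <- aggregate_by_process(res$mimicry, pm)
      write_tsv_stable(res$process_counts, out("process_counts.tsv"))
    }
  }

  ## enrichment ---------------------------------------------------------
  if (run_stage("enrichment") && !is.null(cfg$gmt) && length(tables)) {
    cats <- if (!is.null(cfg$gmt_categories))
      read_tsv_plain(cfg$gmt_categories) else "pathway"
    collection <- read_gmt(cfg$gmt, category = cats)
    universe <- Reduce(intersect, lapply(tables, function(t) t$gene))
    stage_log("enrichment", "universe of ", length(universe),
              " genes measured in every dataset")
    for (dir in c("up", "down")) {
      set <- res[[paste0("consensus_", dir)]]
      if (is.null(set) || !length(set$members)) next
      enr <- hypergeom_enrich(names(set$members), collection, universe,
                              mode = cfg$enrich_mode)
      write_tsv_stable(enr, out("enrichment_", dir, ".tsv"))
      top <- select_top_terms(enr, cfg$p_max, cfg$fdr_max)
      write_tsv_stable(top, out("enrichment_top_", dir, ".tsv"))
      res[[paste0("enrichment_", dir)]] <- enr
      note(paste0("enriched_terms_", dir, "_reported"), nrow(top))
    }
  }

  ## proteomics overlay -------------------------------------------------
  if (run_stage("proteomics") && !is.null(cfg$proteomics)) {
    prot <- read_proteomics_table(cfg$proteomics)
    filt <- filter_significant_proteins(prot, cfg$min_peptides, cfg$alpha)
    stage_log("proteomics", nrow(filt), " of ", nrow(prot),
              " proteins pass peptide/significance filters")
    write_tsv_stable(filt, out("proteomics_filtered.tsv"))
    tops <- top_fold_proteins(filt, n = 20L, min_fold = cfg$min_fold)
    for (nm in names(tops))
      write_tsv_stable(tops[[nm]], out("proteomics_top_", nm, ".tsv"))
    if (!is.null(res$mimicry)) {
      agr <- gene_protein_agreement(res$mimicry, filt)
      write_tsv_stable(agr, out("gene_protein_agreement.tsv"))
      note("gene_protein_agreement_fraction",
           round(attr(agr, "agreement_fraction"), 6))
      res$agreement <- agr
    }
    res$proteomics_filtered <- filt
  }

  ## manifest + summary -------------------------------------------------
  cfg_file <- out("config_used.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  # hash the analytic configuration only: the output location must not
  # change the recorded identity of a run
  hash_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(hash_file), add = TRUE)
  cfg_for_hash <- unclass(cfg)
  cfg_for_hash$out_dir <- NULL
  yaml::write_yaml(cfg_for_hash, hash_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(hash_file)),
    seed = cfg$seed,
    stages_run = intersect(pipeline_defaults()$stages, cfg$stages),
    package_version = as.character(utils::packageVersion("mimicmap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (length(summary_rows))
    write_tsv_stable(do.call(rbind, summary_rows), out("summary.tsv"))
  invisible(res)
}
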