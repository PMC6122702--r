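#' Configuration for the synthetic study generator
#'
#' Defaults emulate the structure of the multi-dataset cell-line vs tumour
#' microarray comparison the pipeline targets: three cell-line and four
#' tumour two-group contrasts, log2-scale intensities with planted group
#' effects, probe multiplicity, cross-platform gene dropout, curated
#' up/down metabolic-gene lists, a planted enriched gene set, and a
#' proteomics table correlated with the transcript deltas.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_celline_datasets,n_tumour_datasets dataset counts (3 and 4).
#' @param samples_per_group samples per contrast group per dataset (10).
#' @param effect_size_log2 planted shift delta on the log2 scale (1.5).
#' @param noise_sd per-sample noise SD sigma (0.5; the default delta is 3*sigma).
#' @param fraction_up,fraction_down fraction of genes planted as up/down in
#'   the poorly differentiated cell lines (0.1 each).
#' @param fraction_concordant fraction of planted genes whose tumour
#'   direction matches the cell-line direction (0.8).
#' @param probe_multiplicity probabilities of a gene having 1, 2, or 3
#'   probes on a platform (0.5, 0.3, 0.2).
#' @param platform_dropout_prob probability a gene is absent from a given
#'   dataset's platform (0.05).
#' @param n_gene_sets number of random gene sets (50).
#' @param planted_enriched_terms number of sets built to overlap the
#'   planted up-genes heavily (1).
#' @param gene_set_size inclusive size range of random sets (20..50).
#' @param delta_noise_sd SD of the noise on the two per-gene cell-line
#'   difference tables (0.25).
#' @param proteomics_noise_sd SD of the noise linking protein log2 folds to
#'   the planted transcript delta (0.25).
#' @param seed RNG seed; the same seed reproduces every output byte.
#' @return a validated `GeneratorConfig` list.
#' @export
generator_config <- function(n_genes = 2000L,
                             n_celline_datasets = 3L,
                             n_tumour_datasets = 4L,
                             samples_per_group = 10L,
                             effect_size_log2 = 1.5,
                             noise_sd = 0.5,
                             fraction_up = 0.1,
                             fraction_down = 0.1,
                             fraction_concordant = 0.8,
                             probe_multiplicity = c(0.5, 0.3, 0.2),
                             platform_dropout_prob = 0.05,
                             n_gene_sets = 50L,
                             planted_enriched_terms = 1L,
                             gene_set_size = c(20L, 50L),
                             delta_noise_sd = 0.25,
                             proteomics_noise_sd = 0.25,
                             seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_celline_datasets = as.integer(n_celline_datasets),
              n_tumour_datasets = as.integer(n_tumour_datasets),
              samples_per_group = as.integer(samples_per_group),
              effect_size_log2 = effect_size_log2, noise_sd = noise_sd,
              fraction_up = fraction_up, fraction_down = fraction_down,
              fraction_concordant = fraction_concordant,
              probe_multiplicity = probe_multiplicity,
              platform_dropout_prob = platform_dropout_prob,
              n_gene_sets = as.integer(n_gene_sets),
              planted_enriched_terms = as.integer(planted_enriched_terms),
              gene_set_size = as.integer(gene_set_size),
              delta_noise_sd = delta_noise_sd,
              proteomics_noise_sd = proteomics_noise_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "GeneratorConfig")
}

validate_generator_config <- function(cfg) {
  frac <- c(cfg$fraction_up, cfg$fraction_down, cfg$fraction_concordant,
            cfg$platform_dropout_prob)
  if (any(frac < 0 | frac > 1)) stop("fractions must be in [0, 1]")
  if (cfg$fraction_up + cfg$fraction_down > 1)
    stop("fraction_up + fraction_down must be <= 1")
  if (cfg$effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
  if (cfg$noise_sd <= 0 || cfg$delta_noise_sd <= 0 || cfg$proteomics_noise_sd <= 0)
    stop("noise SDs must be > 0")
  if (length(cfg$probe_multiplicity) != 3 ||
      abs(sum(cfg$probe_multiplicity) - 1) > 1e-8 ||
      any(cfg$probe_multiplicity < 0))
    stop("probe_multiplicity must be 3 probabilities summing to 1")
  if (cfg$n_genes < 10) stop("n_genes must be >= 10")
  if (cfg$n_celline_datasets < 1) stop("need >= 1 cell-line dataset")
  if (cfg$n_tumour_datasets < 0) stop("n_tumour_datasets must be >= 0")
  if (cfg$samples_per_group < 2) stop("need >= 2 samples per group")
  if (length(cfg$gene_set_size) != 2 || cfg$gene_set_size[1] > cfg$gene_set_size[2] ||
      cfg$gene_set_size[1] < 2)
    stop("gene_set_size must be an increasing pair >= 2")
  invisible(TRUE)
}

#' Generate a synthetic multi-dataset study with planted truth
#'
#' See [generator_config()] for the generative model. All randomness is
#' driven by `config$seed`; the same config yields byte-identical outputs
#' when written with [write_synthetic_study()].
#'
#' @param config a `GeneratorConfig`.
#' @return a `SyntheticStudy` list: `datasets` (named list of
#'   [expression_dataset()]s), `celline_ids`, `tumour_ids`, `hmg_up`,
#'   `hmg_down`, `gene_sets`, `deltas` (two named vectors, first cell line
#'   minus second), `proteomics`, `process_map`, `truth`, `config`.
#' @export
generate_synthetic_study <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  delta <- config$effect_size_log2

  cl_dir <- sample(c("up", "down", "none"), n, replace = TRUE,
                   prob = c(config$fraction_up, config$fraction_down,
                            1 - config$fraction_up - config$fraction_down))
  concordant <- stats::runif(n) < config$fraction_concordant
  tumour_dir <- ifelse(cl_dir == "none", "none",
                       ifelse(concordant, cl_dir,
                              ifelse(cl_dir == "up", "down", "up")))
  conc_label <- ifelse(cl_dir == "none", "none",
                       ifelse(concordant, "concordant", "discordant"))

  # curated tumour-derived metabolic gene lists = the planted tumour-altered genes
  hmg_up_genes <- genes[tumour_dir == "up"]
  hmg_dn_genes <- genes[tumour_dir == "down"]
  is_hmg <- tumour_dir != "none"

  # mimicry truth: down-regulated metabolic genes lean towards the poorly
  # differentiated line, up-regulated ones towards the well differentiated
  mimic <- rep("none", n)
  mimic[is_hmg] <- ifelse(
    stats::runif(sum(is_hmg)) < ifelse(tumour_dir[is_hmg] == "down", 0.7, 0.35),
    "HLE", "HUH7")

  processes <- c("fatty acid metabolism", "urea cycle", "amino acid metabolism",
                 "glycolysis", "TCA cycle", "pentose phosphate pathway",
                 "molecule transport", "glycan metabolism")
  process <- rep(NA_character_, n)
  process[is_hmg] <- sample(c(processes, NA), sum(is_hmg), replace = TRUE,
                            prob = c(rep(0.115, 8), 0.08))
  process_map <- stats::setNames(process[is_hmg & !is.na(process)],
                                 genes[is_hmg & !is.na(process)])

  dir_sign <- function(d) c(up = 1, down = -1, none = 0)[d]
  celline_ids <- paste0("SYNCL", seq_len(config$n_celline_datasets))
  tumour_ids <- if (config$n_tumour_datasets > 0)
    paste0("SYNTM", seq_len(config$n_tumour_datasets)) else character()
  groups_for <- function(role) {
    if (role == "cellline") c("poorly_diff", "well_diff") else c("tumour", "non_tumour")
  }
  make_dataset <- function(id, role, eff_dir) {
    present <- stats::runif(n) >= config$platform_dropout_prob
    mult <- sample(1:3, n, replace = TRUE, prob = config$probe_multiplicity)
    gene_idx <- rep(which(present), mult[present])
    probe_id <- paste0(genes[gene_idx], "_p",
                       sequence(mult[present]))
    mu <- stats::rnorm(n, 8, 2)
    offset <- stats::rnorm(length(gene_idx), 0, 0.3)
    spg <- config$samples_per_group
    grp <- groups_for(role)
    samples <- paste0(id, "_S", sprintf("%02d", seq_len(2 * spg)))
    group_lab <- stats::setNames(rep(grp, each = spg), samples)
    eff <- delta * dir_sign(eff_dir[gene_idx])
    base <- mu[gene_idx] + offset
    vals <- matrix(stats::rnorm(length(gene_idx) * 2 * spg, 0, config$noise_sd),
                   nrow = length(gene_idx))
    vals <- vals + base
    vals[, seq_len(spg)] <- vals[, seq_len(spg)] + eff
    dimnames(vals) <- list(probe_id, samples)
    expression_dataset(id, vals, stats::setNames(genes[gene_idx], probe_id),
                       group_lab, platform_id = paste0("SYNPL_", role))
  }
  datasets <- list()
  for (id in celline_ids) datasets[[id]] <- make_dataset(id, "cellline", cl_dir)
  for (id in tumour_ids) datasets[[id]] <- make_dataset(id, "tumour", tumour_dir)
  realized <- lapply(datasets, function(d)
    sort(unique(d$probe_to_gene[nzchar(d$probe_to_gene)])))

  # two independent HLE - HUH7 difference tables
  mimic_sign <- ifelse(mimic == "none", 0,
                       ifelse(mimic == "HLE", 1, -1) * dir_sign(tumour_dir))
  deltas <- lapply(1:2, function(i) {
    d <- mimic_sign * delta + stats::rnorm(n, 0, config$delta_noise_sd)
    stats::setNames(d, genes)
  })
  names(deltas) <- c("SYNDELTA1", "SYNDELTA2")

  # proteomics correlated with the planted transcript delta
  prot_lf <- mimic_sign * delta + stats::rnorm(n, 0, config$proteomics_noise_sd)
  prot_sig <- stats::runif(n) < 0.9
  prot_p <- ifelse(prot_sig, stats::runif(n, 0, 0.049), stats::runif(n, 0.05, 1))
  proteomics <- proteomics_table(data.frame(
    gene = genes,
    unique_peptides = 1L + stats::rpois(n, 3),
    mean_fold = 2^prot_lf,
    adj_p = prot_p,
    stringsAsFactors = FALSE))

  # gene sets: random background sets plus planted enriched term(s)
  sets <- list()
  cats <- c("pathway", "MF", "CC", "BP")
  for (i in seq_len(config$n_gene_sets)) {
    size <- sample(seq(config$gene_set_size[1], config$gene_set_size[2]), 1)
    sets[[sprintf("RND%03d", i)]] <-
      list(name = sprintf("random set %d", i),
           category = cats[(i - 1L) %% 4L + 1L],
           genes = sample(genes, size))
  }
  up_planted <- genes[cl_dir == "up"]
  planted_terms <- character()
  for (i in seq_len(config$planted_enriched_terms)) {
    core <- sample(up_planted, min(40L, length(up_planted)))
    pad <- sample(setdiff(genes, core), max(0L, 50L - length(core)))
    term <- sprintf("PLANTED%02d", i)
    sets[[term]] <- list(name = sprintf("planted enriched term %d", i),
                         category = "pathway", genes = c(core, pad))
    planted_terms <- c(planted_terms, term)
  }

  truth <- list(
    genes = data.frame(gene = genes, cellline_direction = cl_dir,
                       tumour_direction = tumour_dir, concordance = conc_label,
                       hmg = ifelse(is_hmg, tumour_dir, "none"),
                       mimic = mimic,
                       process = ifelse(is.na(process), "", process),
                       stringsAsFactors = FALSE),
    realized = realized,
    planted_terms = planted_terms,
    instance_id = paste0("syn-", config$seed))

  structure(list(datasets = datasets, celline_ids = celline_ids,
                 tumour_ids = tumour_ids,
                 hmg_up = if (length(hmg_up_genes))
                   hmg_list(hmg_up_genes, "up", "synthetic planted truth"),
                 hmg_down = if (length(hmg_dn_genes))
                   hmg_list(hmg_dn_genes, "down", "synthetic planted truth"),
                 gene_sets = gene_set_collection(sets),
                 deltas = deltas, proteomics = proteomics,
                 process_map = process_map, truth = truth, config = config),
            class = "SyntheticStudy")
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits, under `dir`: per-dataset `<id>_matrix.tsv`, `<id>_groups.tsv`,
#' `<id>_annot.tsv`; `hmg_up.txt` / `hmg_down.txt`; `gene_sets.gmt` plus
#' `gene_set_categories.tsv`; `delta_<id>.tsv`; `proteomics.tsv`;
#' `process_map.tsv`; `truth_genes.tsv`; `generator_config.yaml`.
#'
#' @param study a `SyntheticStudy`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "SyntheticStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  for (id in names(study$datasets))
    write_expression_dataset(study$datasets[[id]], p(id, "_matrix.tsv"),
                             p(id, "_groups.tsv"), p(id, "_annot.tsv"))
  if (!is.null(study$hmg_up)) writeLines(study$hmg_up$genes, p("hmg_up.txt"))
  if (!is.null(study$hmg_down)) writeLines(study$hmg_down$genes, p("hmg_down.txt"))
  write_gmt(study$gene_sets, p("gene_sets.gmt"))
  write_tsv_stable(data.frame(
    term = names(study$gene_sets$sets),
    category = vapply(study$gene_sets$sets, function(s) s$category, "")),
    p("gene_set_categories.tsv"))
  for (id in names(study$deltas))
    write_tsv_stable(data.frame(gene = names(study$deltas[[id]]),
                                delta = unname(study$deltas[[id]])),
                     p("delta_", id, ".tsv"))
  write_tsv_stable(study$proteomics, p("proteomics.tsv"))
  write_tsv_stable(data.frame(gene = names(study$process_map),
                              process = unname(study$process_map)),
                   p("process_map.tsv"))
  write_tsv_stable(study$truth$genes, p("truth_genes.tsv"))
  yaml::write_yaml(unclass(study$config), p("generator_config.yaml"))
  invisible(dir)
}

#' Score pipeline outputs against planted truth
#'
#' Computes recovery metrics for the stages present in `results`:
#' * consensus: sensitivity = planted cell-line DEGs recovered in the
#'   matching direction's consensus set; specificity = unplanted genes kept
#'   out of both sets;
#' * concordance: sensitivity = planted concordant genes called
#'   `concordant`; specificity = planted discordant genes called
#'   `discordant` (a missing or unclassified gene counts as a miss);
#' * mimicry: sensitivity = curated genes assigned to their true cell
#'   line; specificity = fraction of non-ambiguous assignments that are
#'   correct;
#' * enrichment: whether every planted term ranks first in its category.
#'
#' @param truth the `truth` element of a [generate_synthetic_study()]
#'   result.
#' @param results list with any of: `consensus_up` / `consensus_down`
#'   (`ConsensusGeneSet` or character vector), `concordance` (data.frame
#'   `gene`, `call`), `mimicry` (data.frame `gene`, `assigned_to`),
#'   `enrichment` (data.frame from [hypergeom_enrich()]), and optionally
#'   `instance_id` (validated against the truth's).
#' @return data.frame with `metric`, `value`, `n` (denominator).
#' @export
score_recovery <- function(truth, results) {
  if (!is.null(results$instance_id) &&
      !identical(results$instance_id, truth$instance_id))
    stop("results instance id (", results$instance_id,
         ") does not match truth (", truth$instance_id, ")")
  tg <- truth$genes
  rows <- list()
  add <- function(metric, value, n)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value,
                                            n = n, stringsAsFactors = FALSE)
  members_of <- function(x) {
    if (is.null(x)) character()
    else if (inherits(x, "ConsensusGeneSet")) names(x$members)
    else as.character(x)
  }
  if (!is.null(results$consensus_up) || !is.null(results$consensus_down)) {
    up <- members_of(results$consensus_up)
    dn <- members_of(results$consensus_down)
    planted <- tg$cellline_direction != "none"
    hit <- (tg$cellline_direction == "up" & tg$gene %in% up) |
      (tg$cellline_direction == "down" & tg$gene %in% dn)
    add("consensus_sensitivity", mean(hit[planted]), sum(planted))
    add("consensus_specificity",
        mean(!tg$gene[!planted] %in% c(up, dn)), sum(!planted))
  }
  if (!is.null(results$concordance)) {
    cc <- results$concordance
    call_of <- cc$call[match(tg$gene, cc$gene)]
    conc <- tg$concordance == "concordant"
    disc <- tg$concordance == "discordant"
    add("concordance_sensitivity",
        mean(!is.na(call_of[conc]) & call_of[conc] == "concordant"), sum(conc))
    add("concordance_specificity",
        mean(!is.na(call_of[disc]) & call_of[disc] == "discordant"), sum(disc))
  }
  if (!is.null(results$mimicry)) {
    mm <- results$mimicry
    truth_hmg <- tg$mimic != "none"
    assigned <- mm$assigned_to[match(tg$gene, mm$gene)]
    add("mimicry_sensitivity",
        mean(!is.na(assigned[truth_hmg]) &
               assigned[truth_hmg] == tg$mimic[truth_hmg]), sum(truth_hmg))
    ok <- !is.na(assigned) & assigned %in% c("HLE", "HUH7")
    add("mimicry_specificity",
        if (any(ok)) mean(assigned[ok] == tg$mimic[ok]) else NA_real_, sum(ok))
  }
  if (!is.null(results$enrichment)) {
    enr <- results$enrichment
    first <- vapply(truth$planted_terms, function(term) {
      cat_rows <- enr[enr$category == enr$category[enr$term_id == term][1], ]
      cat_rows$term_id[which.min(cat_rows$p)] == term
    }, TRUE)
    add("enrichment_planted_first", mean(first), length(first))
  }
  do.call(rbind, rows)
}
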