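#' Default pipeline configuration
#'
#' A nested list understood by [run_all()]: `seed`; either `simulate`
#' (passed to [simulation_config()]) or `input` (paths `matrix`,
#' `metadata`); `out_dir`; `analysis` (passed to [analysis_config()]);
#' `qc` (`corr_threshold`, `remove_outliers`); `uc_filter` (enabled);
#' `classifier` (`ntree`).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return Configuration list.
#' @export
default_pipeline_config <- function(out_dir = "crohnsig_run", seed = 1L) {
  list(seed = as.integer(seed),
       out_dir = out_dir,
       simulate = list(),          # empty list = simulate with defaults
       input = NULL,
       analysis = list(),
       qc = list(corr_threshold = 0.7, remove_outliers = TRUE),
       uc_filter = list(enabled = TRUE),
       classifier = list(ntree = 500))
}

#' Read a pipeline configuration from YAML or JSON
#' @param path File ending in .yaml/.yml or .json.
#' @return Configuration list merged over [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("config must be .yaml/.yml or .json")
  cfg <- default_pipeline_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  if (!is.null(cfg$input)) cfg$simulate <- NULL
  cfg
}

stage_record <- function(manifest, name, outputs, counts = list()) {
  manifest$stages[[name]] <- list(
    outputs = as.list(outputs),
    checksums = as.list(unname(tools::md5sum(unlist(outputs)))),
    counts = counts)
  manifest
}

#' Run the full pipeline: QC, filtering, DEG calling, specificity, patterns,
#' UC filtration, feature selection, and random-forest discrimination
#'
#' Stages communicate via files under `config$out_dir`; the returned
#' manifest records every stage's outputs with md5 checksums and the gene
#' counts of the filtering funnel (DEG >= CI-surviving >= class-assigned >=
#' UC-retained >= selected), which is non-increasing by construction.
#' Idempotent given identical config and seed.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML/JSON config file.
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_all <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acfg <- do.call(analysis_config,
                  c(config$analysis, list(seed = config$seed)))
  manifest <- list(config = config, seed = config$seed, stages = list())
  stage <- "input"
  finish <- function(manifest) {
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE, null = "null")
    manifest
  }
  on_fail <- function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    finish(manifest)
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    # --- input / simulate ---
    if (!is.null(config$input)) {
      m <- read_matrix(config$input$matrix)
      meta <- read_metadata(config$input$metadata)
      manifest <- stage_record(manifest, "input",
                               list(matrix = config$input$matrix,
                                    metadata = config$input$metadata),
                               list(n_genes = nrow(m), n_samples = ncol(m)))
    } else {
      stage <- "simulate"
      scfg <- do.call(simulation_config,
                      c(config$simulate, list(seed = config$seed)))
      cohort <- generate_cohort(scfg)
      paths <- write_cohort(cohort, file.path(out_dir, "cohort"))
      m <- cohort$matrix; meta <- cohort$metadata
      manifest <- stage_record(manifest, "simulate", as.list(paths),
                               list(n_genes = nrow(m), n_samples = ncol(m)))
    }

    # --- qc ---
    stage <- "qc"
    qc <- detect_outliers(m, meta, config$qc$corr_threshold)
    qp <- file.path(out_dir, "qc_report.json")
    write_qc_report(qc, qp)
    if (isTRUE(config$qc$remove_outliers) && length(qc$outlier_sample_ids)) {
      keep <- setdiff(colnames(m), qc$outlier_sample_ids)
      m <- m[, keep, drop = FALSE]
      class(m) <- c("expr_matrix", class(m))
      meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
    }
    manifest <- stage_record(manifest, "qc", list(report = qp),
                             list(n_outliers = length(qc$outlier_sample_ids)))

    # --- low-expression filter ---
    stage <- "filter"
    m <- filter_low_expression(m, acfg$min_expression)
    fp <- file.path(out_dir, "filtered_matrix.tsv")
    write_matrix(m, fp)
    manifest <- stage_record(manifest, "filter", list(matrix = fp),
                             list(n_genes_retained = nrow(m)))

    # --- four pairwise comparisons ---
    stage <- "deg"
    tables <- build_comparison_set(m, meta, acfg)
    dpaths <- list(); dcounts <- list()
    for (nm in names(tables)) {
      p <- file.path(out_dir, paste0("deg_", nm, ".tsv"))
      write_comparison(tables[[nm]], p)
      dpaths[[nm]] <- p
      dcounts[[paste0("n_deg_", nm)]] <- sum(tables[[nm]]$is_deg)
      dcounts[[paste0("n_ci_", nm)]] <- sum(pass_flag(tables[[nm]]))
    }
    manifest <- stage_record(manifest, "deg", dpaths, dcounts)

    # --- specificity ---
    stage <- "specificity"
    assignment <- classify_tissue_specific(tables, acfg)
    spaths <- write_gene_classes(assignment, file.path(out_dir, "specificity"))
    cls <- table(factor(assignment$gene_class,
                        c("CCG", "ICG", "CD_common", "none")))
    manifest <- stage_record(manifest, "specificity", as.list(spaths),
                             list(n_ccg = unname(cls[["CCG"]]),
                                  n_icg = unname(cls[["ICG"]]),
                                  n_cd_common = unname(cls[["CD_common"]])))

    # --- patterns ---
    stage <- "patterns"
    pats <- assign_patterns(m, meta, assignment, tables, acfg)
    pp <- file.path(out_dir, "pattern_assignments.tsv")
    utils::write.table(pats, pp, sep = "\t", quote = FALSE, row.names = FALSE)
    pcp <- file.path(out_dir, "pattern_counts.tsv")
    utils::write.table(data.frame(tissue = rownames(pattern_counts(pats)),
                                  pattern_counts(pats)),
                       pcp, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- stage_record(manifest, "patterns",
                             list(assignments = pp, counts = pcp),
                             list(n_classified =
                                    sum(pats$pattern %in% LETTERS[1:6])))

    # --- UC filtration ---
    ccg <- assignment$gene_id[assignment$gene_class == "CCG"]
    icg <- assignment$gene_id[assignment$gene_class == "ICG"]
    candidates <- c(ccg, icg)
    if (isTRUE(config$uc_filter$enabled)) {
      stage <- "uc_filter"
      if (!"UC" %in% meta$group) stop("UC group absent but uc_filter enabled")
      uc <- uc_signature(m, meta, acfg)
      ucres <- filter_uc(ccg, icg, uc,
                         assignment$gene_id[assignment$gene_class == "CD_common"])
      upaths <- write_uc_filtration(ucres, file.path(out_dir, "uc_filter"))
      candidates <- c(ucres$retained_ccg, ucres$retained_icg)
      manifest <- stage_record(manifest, "uc_filter", as.list(upaths),
                               list(n_uc_degs = length(ucres$uc_degs),
                                    n_retained_ccg = length(ucres$retained_ccg),
                                    n_retained_icg = length(ucres$retained_icg)))
    }

    # --- feature selection ---
    stage <- "select"
    if (!length(candidates)) stop("no candidate genes survive the funnel")
    sel <- select_features(m, candidates, meta, acfg)
    ep <- file.path(out_dir, "gene_evaluations.tsv")
    utils::write.table(sel$evaluations, ep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gp <- file.path(out_dir, "selected_genes.txt")
    writeLines(sel$selected, gp)
    manifest <- stage_record(manifest, "select",
                             list(evaluations = ep, selected = gp),
                             list(n_candidates = length(candidates),
                                  n_selected = length(sel$selected)))

    # --- classify + evaluate ---
    stage <- "classify"
    if (!length(sel$selected)) stop("no genes selected for the discriminator")
    cd <- meta[meta$group %in% c("CCD", "ICD"), , drop = FALSE]
    sp <- stratified_split(cd, acfg$split_fraction, seed = acfg$seed)
    model <- train_discriminator(m, sel$selected, sp$train, meta,
                                 seed = acfg$seed,
                                 ntree = config$classifier$ntree)
    mp <- file.path(out_dir, "model.rds")
    saveRDS(list(format_version = 1L, model = model), mp)
    manifest <- stage_record(manifest, "classify", list(model = mp),
                             list(n_genes = length(sel$selected),
                                  n_train = length(sp$train)))

    stage <- "evaluate"
    labels <- meta$group[match(sp$test, meta$sample_id)]
    report <- evaluate_discriminator(model, m, sp$test, labels)
    rp <- file.path(out_dir, "classifier_report.json")
    write_classifier_report(report, rp)
    manifest <- stage_record(manifest, "evaluate", list(report = rp),
                             list(accuracy = report$accuracy,
                                  auc = report$auc, ppv = report$ppv,
                                  npv = report$npv, n_test = length(sp$test)))

    finish(manifest)
  }, error = on_fail)
}
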