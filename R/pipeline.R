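## End-to-end orchestration: a declarative config (YAML), staged execution
## with stderr logging, and reproducible on-disk outputs with a manifest.

#' Build a pipeline configuration
#'
#' Exactly one of `input_dir` (a fixture bundle directory, see
#' [read_fixture_bundle()]) or `sim` (a list of [sim_design()] arguments)
#' must be supplied. All defaults can be inspected with
#' [write_default_config()].
#'
#' @param input_dir fixture bundle directory, or `NULL` to simulate.
#' @param sim list of [sim_design()] arguments, or `NULL` to read inputs.
#' @param out_dir output directory.
#' @param normalization [normalize_counts()] method used for differential
#'   expression.
#' @param alpha significance threshold for hit calling, in (0, 1).
#' @param de_regions regions analysed for differential expression.
#' @param case_group case group label.
#' @param control_groups the two control group labels (vehicle first).
#' @param qc named list overriding [segment_qc_thresholds()] arguments.
#' @param selection named list overriding [selection_rule()] arguments.
#' @param seed integer seed for every stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL, out_dir = "spothits_out",
                            normalization = "median", alpha = 0.05,
                            de_regions = c("SN", "VTA", "CP"),
                            case_group = "GqCNO",
                            control_groups = c("GqVeh", "CNOalone"),
                            qc = list(), selection = list(),
                            seed = 1L, log_level = "info") {
  if (is.null(input_dir) == is.null(sim))
    stop("exactly one of `input_dir` or `sim` must be given", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, length(control_groups) == 2)
  structure(list(input_dir = input_dir, sim = sim, out_dir = out_dir,
                 normalization = normalization, alpha = alpha,
                 de_regions = de_regions, case_group = case_group,
                 control_groups = control_groups, qc = qc,
                 selection = selection, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Write a config file populated with all defaults
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
write_default_config <- function(path) {
  cfg <- pipeline_config(sim = list(seed = 1))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

log_stage <- function(config, stage, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf("[spothits:%s] %s", stage, paste0(...)))
}

run_stage <- function(config, stage, expr) {
  log_stage(config, stage, "start")
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

## deterministic JSON writer for result objects
write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Stages, in order: load-or-simulate inputs, segment QC, disc selection,
#' normalization (with the selection diagnostic on per-section pseudobulk),
#' per-region dual-control differential expression, hit calling, PCA,
#' activity-score comparison, and mouse-to-human congruence. Writes
#' per-region DE TSVs, ranked hit lists (one symbol per line), a
#' normalization report, a congruence result, a QC report, PCA coordinates
#' and a run manifest (config hash, seed, output checksums). Rerunning with
#' the same config reproduces all files byte-identically.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "de"), showWarnings = FALSE)
  dir.create(file.path(out, "hits"), showWarnings = FALSE)

  ## inputs
  data <- run_stage(config, "input", {
    if (!is.null(config$sim)) {
      args <- config$sim
      if (is.null(args$seed)) args$seed <- config$seed
      if (!is.null(args$planted_effects))
        args$planted_effects <- as.data.frame(args$planted_effects)
      if (!is.null(args$n_per_group))
        args$n_per_group <- unlist(args$n_per_group)
      sim <- simulate_dataset(do.call(sim_design, args))
      list(se = sim$se, activity = sim$activity, human = sim$human,
           segment_qc = sim$segment_qc, truth = sim$truth)
    } else {
      se <- read_fixture_bundle(config$input_dir)
      extras <- S4Vectors::metadata(se)
      list(se = se, activity = extras$activity,
           human = extras$human_directions, segment_qc = extras$segment_qc,
           truth = NULL)
    }
  })
  se <- data$se
  counts <- SummarizedExperiment::assay(se, "counts")
  negp <- SummarizedExperiment::rowData(se)$is_negative_probe
  meta <- as.data.frame(SummarizedExperiment::colData(se))

  ## segment QC (GeoMx-style table, when present)
  qc_report <- run_stage(config, "qc", {
    if (is.null(data$segment_qc)) NULL else {
      thr <- do.call(segment_qc_thresholds, config$qc)
      rep <- qc_filter_segments(data$segment_qc, thr)
      utils::write.csv(rep, file.path(out, "qc_report.csv"),
                       row.names = FALSE, quote = FALSE)
      rep
    }
  })

  ## disc selection
  assignment <- run_stage(config, "select", {
    rule <- do.call(selection_rule, config$selection)
    a <- select_discs(se, rule = rule)
    utils::write.csv(a, file.path(out, "selection.csv"), row.names = FALSE,
                     quote = FALSE)
    a
  })

  ## normalization + diagnostic on per-section pseudobulk
  normd <- run_stage(config, "normalize", {
    norm <- normalize_counts(counts, config$normalization,
                             negative_probes = negp)
    pseudobulk <- sapply(split(seq_len(ncol(counts)), meta$section_id),
                         function(ix) rowSums(counts[, ix, drop = FALSE]))
    diag <- normalization_diagnostic(pseudobulk,
                                     negative_probes = negp)
    write_json_out(list(used_method = config$normalization,
                        chosen_by_diagnostic = diag$chosen,
                        report = diag$report),
                   file.path(out, "normalization_report.json"))
    list(mat = norm[!negp, , drop = FALSE], diagnostic = diag)
  })

  ## per-region dual-control DE + hits
  de <- list(); hits <- list()
  run_stage(config, "de", {
    for (rg in config$de_regions) {
      cmp <- lapply(config$control_groups, function(ctrl)
        compare_groups(normd$mat, assignment, rg, config$case_group, ctrl))
      names(cmp) <- config$control_groups
      for (ctrl in config$control_groups) {
        export_volcano(cmp[[ctrl]],
                       file.path(out, "de",
                                 sprintf("%s_%s_vs_%s.tsv", rg,
                                         config$case_group, ctrl)))
      }
      de[[rg]] <- cmp
      h <- call_hits(cmp[[1]], cmp[[2]], alpha = config$alpha)
      hits[[rg]] <- h
      utils::write.table(h, file.path(out, "hits",
                                      sprintf("%s_hits.tsv", rg)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(h$gene[order(h$rank_by_fcs)],
                 file.path(out, "hits", sprintf("%s_ranked_genes.txt", rg)))
    }
  })

  ## PCA on median-normalized aggregates of the midbrain DA regions
  pca <- run_stage(config, "pca", {
    med <- normalize_counts(counts, "median", negative_probes = negp)
    emb <- pca_embed(med[!negp, , drop = FALSE], assignment,
                     regions = intersect(c("SN", "VTA"),
                                         assignment$region_label))
    utils::write.csv(cbind(emb,
                           var_explained_pc1 = attr(emb, "var_explained")[1],
                           var_explained_pc2 = attr(emb, "var_explained")[2]),
                     file.path(out, "pca_coordinates.csv"),
                     row.names = FALSE, quote = FALSE)
    emb
  })

  ## activity scores over the expanded DA regions
  activity <- run_stage(config, "activity", {
    if (is.null(data$activity)) NULL else {
      expanded <- unique(c(expand_region(assignment, "SN"),
                           expand_region(assignment, "VTA")))
      act <- normalize_activity(data$activity)
      act <- act[act$barcode %in% expanded, ]
      case <- act$normalized_score[act$group == config$case_group]
      ctrl <- act$normalized_score[act$group != config$case_group]
      ks <- compare_activity(case, ctrl)
      res <- list(n_case = length(case), n_ctrl = length(ctrl),
                  ks_statistic = ks$statistic, p_value = ks$p_value)
      write_json_out(res, file.path(out, "activity.json"))
      res
    }
  })

  ## mouse-to-human congruence on the SN hit set (all DE regions pooled if
  ## SN yields nothing)
  congruence <- run_stage(config, "congruence", {
    if (is.null(data$human) || !nrow(data$human)) NULL else {
      mouse_hits <- if (!is.null(hits$SN) && nrow(hits$SN)) hits$SN
                    else do.call(rbind, lapply(hits, as.data.frame))
      cg <- congruence_test(mouse_hits, data$human)
      write_json_out(list(counts = as.vector(cg$counts),
                          chi_square = cg$chi_square, p_value = cg$p_value,
                          n_mapped = cg$n_mapped,
                          untestable = cg$untestable),
                     file.path(out, "congruence.json"))
      cg
    }
  })

  ## manifest: config hash, seed, checksums of every output file
  manifest <- run_stage(config, "manifest", {
    cfg_path <- file.path(out, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
    man <- list(package_version = as.character(utils::packageVersion("spothits")),
                seed = config$seed,
                config_md5 = unname(tools::md5sum(cfg_path)),
                files = lapply(stats::setNames(files, files), function(f)
                  unname(tools::md5sum(file.path(out, f)))))
    write_json_out(man, file.path(out, "manifest.json"))
    man
  })
  log_stage(config, "done", "outputs in ", out)

  invisible(list(se = se, qc = qc_report, assignment = assignment,
                 normalization = normd$diagnostic, de = de, hits = hits,
                 pca = pca, activity = activity, congruence = congruence,
                 manifest = manifest, truth = data$truth))
}
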