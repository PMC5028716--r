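#' Study configuration
#'
#' Bundles every knob of an end-to-end run: exactly one cohort source
#' (a manifest CSV of image paths, or synthetic generator parameters with
#' a seed), optional isotropic resampling, the feature manifest, the
#' selection parameters, and the statistics options.
#'
#' @param cohort either `list(type = "manifest", path = <csv>)` or
#'   `list(type = "synthetic", n_mutant =, n_wt =, seed =, ...)` with
#'   further arguments forwarded to [generate_cohort()].
#' @param target_spacing optional isotropic spacing (mm) to resample every
#'   scan to before extraction; `NULL` skips resampling (the synthetic
#'   grids are already isotropic).
#' @param manifest a [feature_manifest()].
#' @param selection list: `k`, `corr_threshold`, `method`.
#' @param stats_opts list: `icc_model`, `p_method`.
#' @param out_dir directory for report CSVs, or `NULL` for in-memory only.
#' @return A `study_config` list.
#' @export
study_config <- function(cohort, target_spacing = NULL,
                         manifest = default_manifest(),
                         selection = list(k = 15, corr_threshold = 0.95,
                                          method = "spearman"),
                         stats_opts = list(icc_model = "oneway", p_method = "auto"),
                         out_dir = NULL) {
  if (is.null(cohort$type) || !cohort$type %in% c("manifest", "synthetic"))
    stop("cohort source must have type 'manifest' or 'synthetic'", call. = FALSE)
  if (cohort$type == "manifest" && !file.exists(cohort$path))
    stop("cohort manifest not found: ", cohort$path, call. = FALSE)
  structure(list(cohort = cohort, target_spacing = target_spacing,
                 manifest = manifest, selection = selection,
                 stats_opts = stats_opts, out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors the [study_config()] arguments; a `manifest` entry may
#' be a path to a feature-manifest YAML (relative paths resolve against the
#' config file's directory), otherwise the default manifest is used.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  man <- if (is.null(y$manifest)) default_manifest() else {
    mp <- if (grepl("^(/|[A-Za-z]:)", y$manifest)) y$manifest else file.path(base, y$manifest)
    read_manifest(mp)
  }
  if (identical(y$cohort$type, "manifest") && !grepl("^(/|[A-Za-z]:)", y$cohort$path))
    y$cohort$path <- file.path(base, y$cohort$path)
  args <- list(cohort = y$cohort, manifest = man)
  for (f in c("target_spacing", "selection", "stats_opts", "out_dir"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(study_config, args)
}

config_hash <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL  # the output location is not part of the run identity
  js <- jsonlite::toJSON(rapply(config, unclass, how = "replace"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  writeLines(as.character(js), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

load_study_cohort <- function(config) {
  src <- config$cohort
  if (src$type == "manifest") return(read_cohort(src$path))
  args <- src[setdiff(names(src), "type")]
  do.call(generate_cohort, args)
}

#' Run the full delta-radiomics study
#'
#' Generates or loads the cohort, optionally resamples to isotropic
#' resolution, extracts the pre- and post-treatment feature tables, forms
#' the delta table, runs variance/correlation feature selection on the
#' delta values, evaluates the selected panel's per-feature ROC AUC at
#' all three time points, and computes the delta-table correlation matrix
#' of the selected panel. Deterministic given the configuration (and its
#' seed); when `out_dir` is set the reports are written as CSV plus a JSON
#' run manifest carrying the seed, config hash and package version.
#'
#' @param config a [study_config()].
#' @return List: `tables` (pre/post/delta [feature_table()]s), `selection`,
#'   `auc` (data frame over timepoints), `correlation`, `run_info`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- with_stage("cohort", load_study_cohort(config))
  if (!is.null(config$target_spacing)) {
    cohort <- with_stage("resample", lapply(cohort, function(s) {
      pre <- resample_isotropic(s$pre$image, s$pre$mask, config$target_spacing)
      post <- resample_isotropic(s$post$image, s$post$mask, config$target_spacing)
      subject_study(s$subject_id, s$label, pre, post)
    }))
  }
  pre <- with_stage("extract_pre",
                    cohort_feature_table(cohort, config$manifest, "pre"))
  post <- with_stage("extract_post",
                     cohort_feature_table(cohort, config$manifest, "post"))
  delta <- with_stage("delta", delta_table(pre, post))
  sel <- with_stage("selection", select_features(
    delta, k = config$selection$k, corr_threshold = config$selection$corr_threshold,
    method = config$selection$method))
  aucs <- with_stage("auc", do.call(rbind, lapply(
    list(pre = pre, post = post, delta = delta), function(tab)
      auc_report(tab, features = sel$selected,
                 p_method = config$stats_opts$p_method))))
  rownames(aucs) <- NULL
  cm <- with_stage("correlation",
                   correlation_matrix(delta[, c("subject_id", "label", sel$selected)],
                                      method = config$selection$method))
  run_info <- list(seed = config$cohort$seed %||% NA,
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("deltarad")),
                   n_subjects = length(cohort),
                   n_features = length(manifest_feature_names(config$manifest)),
                   n_selected = length(sel$selected))
  res <- list(tables = list(pre = pre, post = post, delta = delta),
              selection = sel, auc = aucs, correlation = cm,
              run_info = run_info)
  if (!is.null(config$out_dir)) with_stage("report", write_study_reports(res, config$out_dir))
  res
}

write_study_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wr(as.data.frame(res$tables$pre), "features_pre.csv")
  wr(as.data.frame(res$tables$post), "features_post.csv")
  wr(as.data.frame(res$tables$delta), "features_delta.csv")
  wr(res$selection$report, "selection_report.csv")
  wr(res$auc, "auc_report.csv")
  cm <- as.data.frame(res$correlation)
  cm <- cbind(feature = rownames(res$correlation), cm)
  wr(cm, "correlation_matrix.csv")
  jsonlite::write_json(res$run_info, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the test--retest stability analysis
#'
#' Extracts every manifest feature from both scans of each test--retest
#' pair and reports the per-feature intraclass correlation coefficient,
#' sorted descending, plus a mean +/- sd summary.
#'
#' @param pairs list of pairs from [generate_test_retest()], or a
#'   `study_config` whose synthetic cohort parameters are reused to
#'   generate them.
#' @param manifest a [feature_manifest()].
#' @param icc_model forwarded to [icc()].
#' @param out_dir optional report directory.
#' @return List: `report` (feature, icc, model, n_pairs; sorted by
#'   descending ICC), `summary` (mean, sd over reported features).
#' @export
run_stability <- function(pairs, manifest = default_manifest(),
                          icc_model = "oneway", out_dir = NULL) {
  if (length(pairs) < 2)
    stop("sample-size error: need at least 2 test-retest pairs", call. = FALSE)
  f1 <- with_stage("extract_test", do.call(rbind, lapply(pairs, function(p)
    extract_features(p$scan1$image, p$scan1$mask, manifest))))
  f2 <- with_stage("extract_retest", do.call(rbind, lapply(pairs, function(p)
    extract_features(p$scan2$image, p$scan2$mask, manifest))))
  rep <- with_stage("icc", do.call(rbind, lapply(colnames(f1), function(f) {
    r <- icc(f1[, f], f2[, f], model = icc_model)
    data.frame(feature = f, icc = r$icc, model = r$model,
               n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  })))
  rep <- rep[order(-rep$icc, rep$feature), ]
  rownames(rep) <- NULL
  out <- list(report = rep,
              summary = c(mean = mean(rep$icc), sd = stats::sd(rep$icc)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rep, file.path(out_dir, "icc_report.csv"), row.names = FALSE)
  }
  out
}
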