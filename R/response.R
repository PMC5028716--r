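#' Build a feature table
#'
#' A feature table is a data frame with identifier columns `subject_id`
#' and `label` followed by one numeric column per feature, plus a
#' `timepoint` attribute (`"pre"`, `"post"` or `"delta"`).
#'
#' @param features numeric matrix or data frame (subjects x features) with
#'   column names.
#' @param subject_id character vector of subject ids.
#' @param label integer 0/1 vector.
#' @param timepoint one of `"pre"`, `"post"`, `"delta"`.
#' @return A `feature_table` data frame.
#' @export
feature_table <- function(features, subject_id, label,
                          timepoint = c("pre", "post", "delta")) {
  timepoint <- match.arg(timepoint)
  features <- as.data.frame(features, check.names = FALSE)
  if (is.null(names(features)) || anyDuplicated(names(features)))
    stop("feature columns must have unique names", call. = FALSE)
  if (!all(label %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (anyNA(features)) stop("feature table has missing cells", call. = FALSE)
  tab <- cbind(data.frame(subject_id = as.character(subject_id),
                          label = as.integer(label), stringsAsFactors = FALSE),
               features)
  attr(tab, "timepoint") <- timepoint
  class(tab) <- c("feature_table", "data.frame")
  tab
}

feature_columns <- function(tab) setdiff(names(tab), c("subject_id", "label"))

#' Extract features for a whole cohort
#'
#' @param cohort list of [subject_study()] objects.
#' @param manifest a [feature_manifest()].
#' @param timepoint `"pre"` or `"post"`: which scan of each study to use.
#' @return A [feature_table()].
#' @export
cohort_feature_table <- function(cohort, manifest = default_manifest(),
                                 timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  rows <- lapply(cohort, function(s) {
    scan <- s[[timepoint]]
    extract_features(scan$image, scan$mask, manifest)
  })
  feature_table(do.call(rbind, rows),
                subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
                label = vapply(cohort, `[[`, integer(1), "label"),
                timepoint = timepoint)
}

#' Delta (pre minus post) feature table
#'
#' Aligns the two tables by `subject_id` and returns the cell-wise
#' difference, pre-treatment minus post-treatment.
#'
#' @param pre,post [feature_table()]s with identical subjects and feature
#'   columns.
#' @return A [feature_table()] tagged `"delta"`.
#' @export
delta_table <- function(pre, post) {
  if (!setequal(pre$subject_id, post$subject_id) ||
      anyDuplicated(pre$subject_id) || anyDuplicated(post$subject_id))
    stop("alignment error: subject ids differ between pre and post tables",
         call. = FALSE)
  if (!identical(feature_columns(pre), feature_columns(post)))
    stop("alignment error: feature columns differ between pre and post tables",
         call. = FALSE)
  post <- post[match(pre$subject_id, post$subject_id), ]
  if (!identical(pre$label, post$label))
    stop("alignment error: labels disagree between pre and post tables",
         call. = FALSE)
  fc <- feature_columns(pre)
  feature_table(as.data.frame(pre[, fc, drop = FALSE]) -
                  as.data.frame(post[, fc, drop = FALSE]),
                pre$subject_id, pre$label, timepoint = "delta")
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the absolute mean. Declared
#' undefined (`NA`, excluded from variance ranking) when the mean is
#' numerically zero (`|mean| < 1e-12`).
#'
#' @param x numeric vector, length >= 2.
#' @return Scalar CV, or `NA_real_` when undefined.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (abs(m) < 1e-12) return(NA_real_)
  stats::sd(x) / abs(m)
}

#' Variance-then-correlation feature selection
#'
#' Implements the two-stage screen used on the delta table: (1) rank the
#' candidate features (the `always_include` volumetric features are kept
#' out of the ranking pool) by coefficient of variation and keep the top
#' `k`; (2) while any retained pair has `|rho| > corr_threshold`
#' (Spearman by default), remove from the worst-offending pair the feature
#' with the larger mean absolute correlation to the remaining candidates
#' (ties broken by lower CV, then by name); (3) append the
#' `always_include` features. The result is deterministic and invariant
#' to the input column order.
#'
#' @param delta a [feature_table()] (normally the delta table).
#' @param k number of most-variant features to shortlist (default 15).
#' @param corr_threshold pairwise pruning threshold (default 0.95).
#' @param method correlation statistic, `"spearman"` (default) or
#'   `"pearson"`.
#' @param always_include features appended for comparison regardless of
#'   rank (default `Volume`, `Max_Diameter`).
#' @return List with `selected` (ordered names) and `report` (per-feature
#'   data frame: cv, rank, pruned_by, selected).
#' @export
select_features <- function(delta, k = 15, corr_threshold = 0.95,
                            method = c("spearman", "pearson"),
                            always_include = c("Volume", "Max_Diameter")) {
  method <- match.arg(method)
  if (k < 1) stop("parameter error: k must be >= 1", call. = FALSE)
  fc <- sort(feature_columns(delta))
  pool <- setdiff(fc, always_include)
  cv <- vapply(pool, function(f) coefficient_of_variation(delta[[f]]), numeric(1))
  ranked <- pool[order(-cv, pool, na.last = TRUE)]
  ranked <- ranked[!is.na(cv[ranked])]
  shortlist <- utils::head(ranked, k)
  pruned_by <- stats::setNames(character(length(fc)), fc)
  keep <- shortlist
  if (length(keep) > 1) {
    cm <- abs(stats::cor(as.matrix(delta[, keep, drop = FALSE]), method = method))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    while (length(keep) > 1 && max(cm) > corr_threshold) {
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- colnames(cm)[worst]
      mean_abs <- rowMeans(cm[pair, , drop = FALSE])
      drop <- pair[order(-mean_abs, cv[pair], pair)][1]
      survivor <- setdiff(pair, drop)
      pruned_by[drop] <- survivor
      keep <- setdiff(keep, drop)
      cm <- cm[keep, keep, drop = FALSE]
    }
  }
  selected <- c(keep[order(match(keep, ranked))], intersect(always_include, fc))
  report <- data.frame(
    feature = fc,
    cv = vapply(fc, function(f) {
      v <- coefficient_of_variation(delta[[f]]); if (is.na(v)) NA_real_ else v
    }, numeric(1)),
    rank = match(fc, ranked),
    pruned_by = pruned_by[fc],
    selected = fc %in% selected,
    stringsAsFactors = FALSE, row.names = NULL)
  list(selected = selected, report = report)
}
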