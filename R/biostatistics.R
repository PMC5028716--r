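#' ROC AUC with Mann--Whitney significance
#'
#' The AUC is computed through the Mann--Whitney U identity
#' `AUC = U / (n_pos * n_neg)` with ties counted 1/2, taking label 1
#' (mutant) as the positive class. The two-sided p-value comes from the
#' Mann--Whitney U test: exact enumeration when `n_pos * n_neg <= 400`
#' and the data are tie-free, the tie-corrected normal approximation (with
#' continuity correction) otherwise; the method may also be forced.
#'
#' @param values numeric per-subject feature values.
#' @param labels 0/1 vector, same length.
#' @param p_method `"auto"` (default), `"exact"` or `"normal"`.
#' @return An `auc_result` list: `auc`, `p_two_sided`, `direction`
#'   (+1 when mutants run higher), `n_pos`, `n_neg`, `p_method`.
#' @export
roc_auc <- function(values, labels, p_method = c("auto", "exact", "normal")) {
  p_method <- match.arg(p_method)
  if (length(values) != length(labels)) stop("length mismatch", call. = FALSE)
  if (anyNA(values) || anyNA(labels)) stop("missing values", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos < 1 || n_neg < 1)
    stop("class error: both classes must be present", call. = FALSE)
  r <- rank(values)
  U <- sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2
  auc <- U / (n_pos * n_neg)
  ties <- anyDuplicated(values) > 0
  use_exact <- switch(p_method,
                      auto = n_pos * n_neg <= 400 && !ties,
                      exact = TRUE,
                      normal = FALSE)
  if (length(unique(values)) == 1L) {
    p <- 1  # fully tied data carry no ordering information
  } else {
    p <- suppressWarnings(stats::wilcox.test(
      values[labels == 1], values[labels == 0],
      exact = use_exact, correct = TRUE)$p.value)
  }
  structure(list(auc = auc, p_two_sided = min(p, 1),
                 direction = sign(auc - 0.5), n_pos = n_pos, n_neg = n_neg,
                 p_method = if (use_exact) "exact" else "normal"),
            class = "auc_result")
}

#' Inter-feature correlation matrix
#'
#' @param table a [feature_table()] (needs >= 3 subjects).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Symmetric matrix with unit diagonal; correlations that are
#'   undefined because a column is constant are reported as 0 and the
#'   offending features listed in the `constant_features` attribute (with
#'   a warning).
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  fc <- feature_columns(table)
  m <- as.matrix(table[, fc, drop = FALSE])
  if (nrow(m) < 3) stop("need at least 3 subjects", call. = FALSE)
  const <- fc[apply(m, 2, function(x) stats::sd(x) == 0)]
  cm <- suppressWarnings(stats::cor(m, method = method))
  if (length(const)) {
    warning("constant feature column(s) reported with correlation 0: ",
            paste(const, collapse = ", "))
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 1
  attr(cm, "constant_features") <- const
  cm
}

#' Test--retest intraclass correlation coefficient
#'
#' Default estimator is the one-way random-effects single-measurement
#' ICC(1,1) `= (MSB - MSW) / (MSB + MSW)` for two replicates, the
#' standard choice for same-protocol repeat scans. Two-way estimators
#' ICC(2,1) (random raters, absolute agreement) and ICC(3,1) (fixed
#' raters, consistency) are available; the estimator used is recorded in
#' the result.
#'
#' @param test,retest numeric per-subject values, paired by position
#'   (length >= 2).
#' @param model `"oneway"` (default), `"twoway_random"` or
#'   `"twoway_fixed"`.
#' @return An `icc_result` list: `icc`, `n_pairs`, `model`.
#' @export
icc <- function(test, retest, model = c("oneway", "twoway_random", "twoway_fixed")) {
  model <- match.arg(model)
  if (length(test) != length(retest))
    stop("pairing error: test and retest lengths differ", call. = FALSE)
  n <- length(test)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(test) || anyNA(retest)) stop("missing values", call. = FALSE)
  y <- cbind(test, retest)
  k <- 2
  subj_means <- rowMeans(y)
  grand <- mean(y)
  MSB <- k * sum((subj_means - grand)^2) / (n - 1)
  MSW <- sum((y - subj_means)^2) / n            # df = n(k-1) = n
  col_means <- colMeans(y)
  SSC <- n * sum((col_means - grand)^2)         # df = k-1 = 1
  SSE <- sum((y - outer(subj_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  val <- switch(model,
    oneway = if (MSB + MSW > 0) (MSB - MSW) / (MSB + MSW) else 0,
    twoway_random = {
      den <- MSB + (k - 1) * MSE + k / n * (MSC - MSE)
      if (den > 0) (MSB - MSE) / den else 0
    },
    twoway_fixed = {
      den <- MSB + (k - 1) * MSE
      if (den > 0) (MSB - MSE) / den else 0
    })
  lab <- switch(model, oneway = "ICC(1,1)", twoway_random = "ICC(2,1)",
                twoway_fixed = "ICC(3,1)")
  structure(list(icc = val, n_pairs = n, model = lab), class = "icc_result")
}

#' Per-feature AUC report for a feature table
#'
#' @param table a [feature_table()].
#' @param features feature names to evaluate (default: all).
#' @param p_method forwarded to [roc_auc()].
#' @return Data frame: feature, timepoint, auc, p, direction, n_pos,
#'   n_neg, plus a supplementary Benjamini--Hochberg `p_adj_bh` column
#'   (the primary screen itself applies no multiplicity correction).
#' @export
auc_report <- function(table, features = feature_columns(table),
                       p_method = "auto") {
  rows <- lapply(features, function(f) {
    r <- roc_auc(table[[f]], table$label, p_method = p_method)
    data.frame(feature = f, timepoint = attr(table, "timepoint") %||% NA_character_,
               auc = r$auc, p = r$p_two_sided, direction = r$direction,
               n_pos = r$n_pos, n_neg = r$n_neg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
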