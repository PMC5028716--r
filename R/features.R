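#' The default radiomic feature manifest
#'
#' A feature manifest is a declarative catalogue of which features to
#' extract, as a list of class entries with parameter grids. The default
#' manifest expands to exactly 183 features:
#' 12 size/shape (`Volume`, `Max_Diameter`, `Boundary_Radius_Std`,
#' `Shape_SI1..SI9`), 6 sigmoid margin (offset/slope/amplitude means at
#' line half-lengths 3 and 5 mm), 14 Laws energies, 16 Gabor energies
#' (orientations 0/45/90/135 degrees x wavelengths 3/5/7/9 px), and
#' 135 co-occurrence features (15 statistics x distances 1/2/4 x
#' aggregations mean/std/range).
#'
#' @return A `feature_manifest` list.
#' @export
default_manifest <- function() {
  feature_manifest(list(
    list(class = "size"),
    list(class = "shape_index", smoothing_sigma = 1.5),
    list(class = "sigmoid", half_lengths = c(3, 5), step_mm = 0.5,
         max_lines = 100, smoothing_sigma = 1.5),
    list(class = "laws", ids = 1:14),
    list(class = "gabor", orientations = c(0, 45, 90, 135),
         wavelengths = c(3, 5, 7, 9), bandwidth = 1),
    list(class = "glcm", statistics = glcm_statistic_names(),
         distances = c(1, 2, 4), aggregations = c("mean", "std", "range"),
         n_levels = 32)))
}

#' Construct a feature manifest
#'
#' @param entries list of entries, each a list with a `class` element
#'   (`"size"`, `"shape_index"`, `"sigmoid"`, `"laws"`, `"gabor"`,
#'   `"glcm"`) and class-specific parameters; see [default_manifest()].
#' @return A `feature_manifest` whose expansion ([manifest_feature_names()])
#'   is checked to be duplicate-free.
#' @export
feature_manifest <- function(entries) {
  m <- structure(list(entries = entries), class = "feature_manifest")
  nms <- manifest_feature_names(m)
  if (anyDuplicated(nms))
    stop("manifest expands to duplicate feature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  m
}

#' Expand a manifest into its ordered feature-name list
#'
#' @param manifest a [feature_manifest()].
#' @return Character vector of feature names, in extraction order.
#' @export
manifest_feature_names <- function(manifest = default_manifest()) {
  unlist(lapply(manifest$entries, function(e) {
    switch(e$class,
      size = c("Volume", "Max_Diameter", "Boundary_Radius_Std"),
      shape_index = paste0("Shape_SI", 1:9),
      sigmoid = as.vector(t(outer(
        c("Sigmoid-Offset-Mean-d", "Sigmoid-Slope-Mean-d", "Sigmoid-Amplitude-Mean-d"),
        e$half_lengths, function(a, b) paste0(a, b)))),
      laws = paste0("Laws_Energy-", e$ids),
      gabor = as.vector(vapply(e$wavelengths, function(w)
        sprintf("Gabor_Energy-dir%g-w%g", e$orientations, w),
        character(length(e$orientations)))),
      glcm = as.vector(vapply(e$distances, function(d)
        as.vector(vapply(e$statistics, function(s)
          sprintf("GLCM_%s-%s-d%d", s, e$aggregations, d),
          character(length(e$aggregations)))),
        character(length(e$statistics) * length(e$aggregations)))),
      stop("unknown manifest class '", e$class, "'", call. = FALSE))
  }))
}

#' Extract all manifest features from one lesion
#'
#' Evaluates every manifest entry on the image/mask pair. The output is a
#' named numeric vector whose names and order are exactly the manifest
#' expansion; every value is finite (degenerate cases resolve to the
#' documented fallbacks inside the individual extractors). Any extractor
#' failure aborts with the feature class named in the message.
#'
#' @inheritParams laws_energy
#' @param manifest a [feature_manifest()] (default [default_manifest()]).
#' @return Named numeric feature vector.
#' @export
extract_features <- function(volume, mask, manifest = default_manifest()) {
  validate_pair(volume, mask)
  out <- numeric(0)
  for (e in manifest$entries) {
    vals <- tryCatch(extract_entry(volume, mask, e), error = function(err)
      stop("feature extraction failed in class '", e$class, "': ",
           conditionMessage(err), call. = FALSE))
    out <- c(out, vals)
  }
  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

extract_entry <- function(volume, mask, e) {
  switch(e$class,
    size = c(Volume = tumor_volume(mask),
             Max_Diameter = max_diameter(mask),
             Boundary_Radius_Std = boundary_radius_std(mask)),
    shape_index = shape_index_features(mask, e$smoothing_sigma %||% 1.5),
    sigmoid = {
      v <- unlist(lapply(e$half_lengths, function(h) {
        f <- sigmoid_margin_features(volume, mask, sigmoid_config(
          half_length_mm = h, step_mm = e$step_mm %||% 0.5,
          max_lines = e$max_lines %||% 100,
          smoothing_sigma = e$smoothing_sigma %||% 1.5))
        attributes(f) <- list(names = names(f))
        f
      }))
      # manifest order groups by statistic then half-length
      nms <- as.vector(t(outer(
        c("Sigmoid-Offset-Mean-d", "Sigmoid-Slope-Mean-d", "Sigmoid-Amplitude-Mean-d"),
        e$half_lengths, function(a, b) paste0(a, b))))
      v[nms]
    },
    laws = {
      if (!all(e$ids %in% 1:14))
        stop("filter ids must be in 1..14", call. = FALSE)
      en <- laws_energy_all(volume, mask)
      stats::setNames(en[e$ids], paste0("Laws_Energy-", e$ids))
    },
    gabor = {
      grid <- expand.grid(orientation = e$orientations, wavelength = e$wavelengths)
      plist <- lapply(seq_len(nrow(grid)), function(i)
        gabor_params(grid$orientation[i], grid$wavelength[i], e$bandwidth %||% 1))
      stats::setNames(gabor_energy_all(volume, mask, plist),
                      sprintf("Gabor_Energy-dir%g-w%g", grid$orientation, grid$wavelength))
    },
    glcm = glcm_features_all(volume, mask, e$statistics, e$distances,
                             e$aggregations,
                             glcm_config(n_levels = e$n_levels %||% 32)),
    stop("unknown manifest class '", e$class, "'", call. = FALSE))
}

#' Read / write a feature manifest as YAML
#'
#' @param path YAML file path.
#' @return `read_manifest` returns a [feature_manifest()];
#'   `write_manifest` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  feature_manifest(yaml::read_yaml(path))
}

#' @rdname read_manifest
#' @param manifest a [feature_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest$entries, path)
  invisible(path)
}
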