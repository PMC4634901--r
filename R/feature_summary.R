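# Per-timepoint feature summaries (heatmap matrices) and per-node color
# values for trajectory / lineage-tree color-coding.

#' Per-timepoint feature means
#'
#' Averages each selected feature over all objects at each timepoint — a
#' population-level fingerprint of the movie, useful both for QC (an
#' out-of-focus frame shows up as a stripe) and for reading population
#' trends. Timepoints present in the image table but with no objects give
#' missing cells (never interpolated — a hole is exactly what the display
#' must reveal).
#'
#' @param ds a `tracking_dataset`.
#' @param features character subset of `ds$feature_names`
#'   (default: all features).
#' @param by_group if `TRUE`, average per imaging group and include a
#'   `group_index` column; default pools all groups.
#' @return object of class `heatmap_matrix`: a tibble with `timepoint`
#'   (one row per distinct timepoint in the image table) and one column
#'   per feature; attribute `normalized` is `FALSE`.
#' @export
timepoint_feature_matrix <- function(ds, features = NULL, by_group = FALSE) {
  features <- features %||% ds$feature_names
  unknown <- setdiff(features, ds$feature_names)
  if (length(unknown)) {
    abort_param(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")))
  }

  obj <- ds$objects %>%
    dplyr::left_join(ds$images[c("image_index", "group_index", "timepoint")],
                     by = "image_index")
  keys <- if (by_group) c("group_index", "timepoint") else "timepoint"
  means <- obj %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(features), mean),
                     .groups = "drop")

  grid <- if (by_group) {
    dplyr::distinct(ds$images, .data$group_index, .data$timepoint)
  } else {
    dplyr::distinct(ds$images["timepoint"])
  }
  out <- grid %>%
    dplyr::left_join(means, by = keys) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))

  structure(out, class = c("heatmap_matrix", class(out)),
            normalized = FALSE, feature_names = features)
}

#' Feature columns of a heatmap matrix, in display order
#' @param m a `heatmap_matrix`.
#' @return character vector of feature names.
#' @export
heatmap_features <- function(m) attr(m, "feature_names")

#' Is a heatmap matrix normalized?
#' @param m a `heatmap_matrix`.
#' @return logical.
#' @export
is_normalized <- function(m) isTRUE(attr(m, "normalized"))

#' Min-max normalize a heatmap matrix per feature
#'
#' Each feature column is mapped through `(v - min) / (max - min)` over
#' its finite cells, so every non-constant column spans exactly \[0, 1\].
#' Zero-range (constant) columns map to 0 — a constant carries no signal.
#' Missing cells stay missing. The operation is idempotent.
#'
#' @param m a `heatmap_matrix`.
#' @return the normalized `heatmap_matrix` (attribute `normalized = TRUE`).
#' @export
minmax_normalize <- function(m) {
  feats <- heatmap_features(m)
  for (f in feats) {
    v <- m[[f]]
    fin <- is.finite(v)
    if (!any(fin)) next
    lo <- min(v[fin]); hi <- max(v[fin])
    m[[f]] <- if (hi > lo) (v - lo) / (hi - lo) else ifelse(fin, 0, v)
  }
  attr(m, "normalized") <- TRUE
  m
}

#' Map a per-node feature to colors in \[0, 1\]
#'
#' Computes the color value of every graph node for a selected feature,
#' for color-coding trajectories and lineage trees. Scaling is either
#' global min-max or percentile-based (robust to heavy tails; values
#' outside the percentile window are clipped to 0/1). Nodes with missing
#' feature values are excluded from the scale and flagged for neutral
#' rendering.
#'
#' @param g a `lineage_graph`.
#' @param feature feature name (must be a node feature column).
#' @param scale `"global"` (min-max) or `"percentile"`.
#' @param p_lo,p_hi percentile window (percent) when `scale = "percentile"`.
#' @return object of class `feature_colormap`: tibble with `node_id`,
#'   `value` (in \[0,1\], `NA` when missing) and `missing`; attributes
#'   `feature` and `scale` (the (min, max) used).
#' @export
feature_colormap <- function(g, feature, scale = c("global", "percentile"),
                             p_lo = 2, p_hi = 98) {
  scale <- match.arg(scale)
  if (!feature %in% names(g$nodes)) {
    abort_param(sprintf("feature '%s' not present on graph nodes", feature))
  }
  v <- g$nodes[[feature]]
  fin <- is.finite(v)
  if (!any(fin)) abort_param(sprintf("feature '%s' is missing on every node", feature))

  lims <- if (scale == "global") {
    range(v[fin])
  } else {
    stats::quantile(v[fin], c(p_lo, p_hi) / 100, type = 7, names = FALSE)
  }
  span <- lims[2] - lims[1]
  val <- if (span > 0) pmin(pmax((v - lims[1]) / span, 0), 1) else
    ifelse(fin, 0, NA_real_)
  val[!fin] <- NA_real_

  structure(tibble::tibble(node_id = g$nodes$node_id, value = val,
                           missing = !fin),
            class = c("feature_colormap", "tbl_df", "tbl", "data.frame"),
            feature = feature, scale = lims)
}

#' Write a heatmap matrix as CSV
#'
#' @param m a `heatmap_matrix`.
#' @param path output CSV (timepoints x features).
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(m, path) {
  readr::write_csv(tibble::as_tibble(m), path, progress = FALSE)
  invisible(path)
}

#' Export a colormap as JSON
#'
#' @param cm a `feature_colormap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_colormap_json <- function(cm, path) {
  write_json_stable(list(
    schema = "trackqc-colormap", version = "1.0",
    feature = attr(cm, "feature"),
    scale = list(min = attr(cm, "scale")[[1]], max = attr(cm, "scale")[[2]]),
    nodes = cm$node_id, values = cm$value), path)
}
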