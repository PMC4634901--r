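# Internal helpers shared across modules.

#' Compose node identifiers from table keys
#'
#' A node of the lineage graph is one object observation, keyed by
#' `(image_index, object_index)`. The string form `"<image>_<object>"` is
#' used as the graph vertex name and in all reports.
#'
#' @param image_index,object_index integer vectors of equal length.
#' @return character vector of node ids.
#' @export
node_id <- function(image_index, object_index) {
  paste0(as.integer(image_index), "_", as.integer(object_index))
}

# Inverse of node_id(): a tibble with image_index / object_index columns.
split_node_id <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  tibble::tibble(
    node_id = ids,
    image_index = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
    object_index = vapply(parts, function(p) as.integer(p[[2]]), integer(1))
  )
}

# Deterministic node ordering used everywhere: (timepoint, image, object).
order_nodes <- function(nodes) {
  nodes[order(nodes$timepoint, nodes$image_index, nodes$object_index), ,
        drop = FALSE]
}

# Logging ----------------------------------------------------------------

# Violations and recoverable oddities are logged to stderr at WARNING.
# Silence with options(trackqc.verbose = FALSE) (tests do).
tq_log <- function(level, msg) {
  if (isTRUE(getOption("trackqc.verbose", TRUE))) {
    message(sprintf("%s [trackqc] %s", level, msg))
  }
  invisible(NULL)
}

# Errors -----------------------------------------------------------------

abort_schema <- function(msg) abort(msg, class = "trackqc_schema_error")
abort_integrity <- function(msg) abort(msg, class = "trackqc_integrity_error")
abort_param <- function(msg) abort(msg, class = "trackqc_parameter_error")
abort_io <- function(msg) abort(msg, class = "trackqc_io_error")

# JSON -------------------------------------------------------------------

# All JSON emitted by the package goes through this writer so that output
# is byte-identical for identical inputs (fixed key order is the caller's
# responsibility; jsonlite preserves list order).
write_json_stable <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          null = "null", na = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# Sidecar manifest written next to every rendered figure.
manifest_path <- function(out) paste0(out, ".manifest.json")

write_manifest <- function(out, manifest) {
  write_json_stable(manifest, manifest_path(out))
  invisible(manifest)
}

#' Read the manifest sidecar of a rendered figure
#'
#' Every renderer writes `<out>.manifest.json` describing what was drawn
#' (glyph/segment/patch counts, color ranges), so downstream checks never
#' have to parse pixels.
#'
#' @param out path that was passed to the renderer.
#' @return a named list.
#' @export
read_manifest <- function(out) read_json_file(manifest_path(out))
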