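# Graph-topology quality control: loop / crossing / singleton detection,
# track-length statistics, and singleton pruning.
#
# Rationale: cells divide (one-to-many) and may transiently touch
# (many-to-one), but a split whose branches re-merge ("loop") or a merge
# that later re-splits ("crossing") is unlikely in normal biology and
# usually marks a transient mis-segmentation; a track spanning only a few
# frames ("singleton") is usually a spurious detection.

node_key <- function(g) stats::setNames(seq_len(nrow(g$nodes)), g$nodes$node_id)
node_tp <- function(g) stats::setNames(g$nodes$timepoint, g$nodes$node_id)

# Number of internally vertex-disjoint directed paths u -> m, by max-flow
# on the node-split network (each vertex v other than u, m becomes
# v_in -> v_out with capacity 1). Also returns a decomposition into that
# many vertex-disjoint paths.
disjoint_paths <- function(g, u, m, want_paths = FALSE) {
  ids <- g$nodes$node_id
  vin <- paste0(ids, "+i")
  vout <- paste0(ids, "+o")
  internal <- data.frame(from = vin, to = vout,
                         capacity = ifelse(ids %in% c(u, m), 1000, 1))
  ee <- data.frame(from = paste0(g$edges$parent, "+o"),
                   to = paste0(g$edges$child, "+i"),
                   capacity = 1000)
  net <- rbind(internal, ee)
  sg <- igraph::graph_from_data_frame(net, directed = TRUE)
  fl <- igraph::max_flow(sg, source = paste0(u, "+o"),
                         target = paste0(m, "+i"), capacity = net$capacity)
  k <- as.integer(round(fl$value))
  if (!want_paths || k == 0) return(list(k = k, paths = NULL))

  # decompose the (0/1 off the endpoints) flow into k paths
  el <- igraph::as_edgelist(sg)
  flow <- round(fl$flow)
  pos <- flow > 0
  rem <- data.frame(from = el[pos, 1], to = el[pos, 2], f = flow[pos],
                    stringsAsFactors = FALSE)
  src <- paste0(u, "+o"); tgt <- paste0(m, "+i")
  paths <- vector("list", k)
  for (p in seq_len(k)) {
    cur <- src
    walk <- character(0)
    while (cur != tgt) {
      i <- which(rem$from == cur & rem$f > 0)[1]
      nxt <- rem$to[i]
      rem$f[i] <- rem$f[i] - 1
      walk <- c(walk, nxt)
      cur <- nxt
    }
    verts <- unique(sub("\\+[io]$", "", c(src, walk)))
    paths[[p]] <- verts
  }
  list(k = k, paths = paths)
}

#' Detect loops (transient split followed by re-merge)
#'
#' A *loop* is a split node whose out-branches reconverge at a common
#' descendant via at least two internally vertex-disjoint directed paths —
#' the signature of a brief erroneous split of one object. One loop is
#' reported per split node, at its earliest reconvergence (smallest
#' (timepoint, image, object) among qualifying merge nodes).
#'
#' @param g a `lineage_graph`.
#' @param max_duration if given, only loops with
#'   `timepoint(merge) - timepoint(split) <= max_duration` are reported
#'   (the default reports all).
#' @return tibble with `split`, `merge`, `duration_frames`, and a
#'   list-column `branches` holding two vertex-disjoint node paths, sorted
#'   by (timepoint of split, split node id).
#' @export
find_loops <- function(g, max_duration = NULL) {
  empty <- tibble::tibble(split = character(), merge = character(),
                          duration_frames = integer(), branches = list())
  if (nrow(g$edges) == 0) return(empty)
  d <- degree_vectors(g)
  tp <- node_tp(g)
  key <- node_key(g)
  adj <- adjacency_lists(g)
  ig <- as_igraph(g)

  splits <- g$nodes$node_id[d$out_deg[g$nodes$node_id] >= 2]
  out <- list()
  for (u in splits) {
    kids <- adj$children[[u]]
    reach <- lapply(unique(kids), function(v) {
      names(igraph::subcomponent(ig, v, mode = "out"))
    })
    counts <- table(unlist(lapply(reach, unique)))
    cand <- setdiff(names(counts)[counts >= 2], u)
    if (length(cand) == 0) next
    cand <- cand[order(tp[cand], key[cand])]
    for (m in cand) {
      dp <- disjoint_paths(g, u, m, want_paths = TRUE)
      if (dp$k >= 2) {
        dur <- as.integer(tp[[m]] - tp[[u]])
        if (is.null(max_duration) || dur <= max_duration) {
          out[[length(out) + 1]] <- tibble::tibble(
            split = u, merge = m, duration_frames = dur,
            branches = list(dp$paths[1:2]))
        }
        break  # earliest reconvergence found for this split
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- dplyr::bind_rows(out)
  res[order(tp[res$split], key[res$split]), ]
}

#' Detect crossings (merge followed by re-split)
#'
#' A *crossing* is a merge node from which an unbranched chain (every
#' interior node with in-degree = out-degree = 1) leads to a split node —
#' two tracks erroneously fused, travelling together, then re-separating.
#' The degenerate case is a single node with in-degree >= 2 and out-degree
#' >= 2 (merge and split at once, duration 0). A chain interrupted by
#' another merge is not followed further (that merge starts its own
#' candidate chain), so chains are never double-counted.
#'
#' @inheritParams find_loops
#' @return tibble with `merge`, `split`, `duration_frames`, and a
#'   list-column `chain` (the merge-to-split node path), sorted by
#'   (timepoint of merge, merge node id).
#' @export
find_crossings <- function(g, max_duration = NULL) {
  empty <- tibble::tibble(merge = character(), split = character(),
                          duration_frames = integer(), chain = list())
  if (nrow(g$edges) == 0) return(empty)
  d <- degree_vectors(g)
  tp <- node_tp(g)
  key <- node_key(g)
  adj <- adjacency_lists(g)

  merges <- g$nodes$node_id[d$in_deg[g$nodes$node_id] >= 2]
  merges <- merges[order(tp[merges], key[merges])]
  out <- list()
  for (m in merges) {
    s <- NULL; chain <- m
    if (d$out_deg[[m]] >= 2) {
      s <- m
    } else {
      cur <- m
      while (d$out_deg[[cur]] == 1) {
        nxt <- adj$children[[cur]][[1]]
        if (d$in_deg[[nxt]] != 1) break  # another merge interrupts the chain
        chain <- c(chain, nxt)
        if (d$out_deg[[nxt]] >= 2) { s <- nxt; break }
        cur <- nxt
      }
    }
    if (is.null(s)) next
    dur <- as.integer(tp[[s]] - tp[[m]])
    if (!is.null(max_duration) && dur > max_duration) next
    out[[length(out) + 1]] <- tibble::tibble(
      merge = m, split = s, duration_frames = dur, chain = list(chain))
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Detect singleton tracks
#'
#' Flags every weakly connected component whose temporal span (distinct
#' occupied timepoints) is at most `max_length` frames — typically
#' spurious object detections. The threshold is researcher-chosen; the
#' default flags single-frame tracks only.
#'
#' @param g a `lineage_graph`.
#' @param max_length maximum span (frames) for a component to be flagged;
#'   must be >= 1.
#' @return tibble with `component_id`, `length_frames`, and list-column
#'   `nodes`, sorted by first node id.
#' @export
find_singletons <- function(g, max_length = 1) {
  if (!is.numeric(max_length) || max_length < 1) {
    abort_param("max_length must be >= 1")
  }
  comps <- graph_components(g)
  flagged <- comps[comps$span_frames <= max_length, ]
  tibble::tibble(component_id = flagged$component_id,
                 length_frames = flagged$span_frames,
                 nodes = flagged$nodes)
}

#' Track-length statistics
#'
#' Track = weakly connected component; length = its temporal span in
#' distinct occupied timepoints. Percentiles use linear interpolation
#' between closest order statistics (R quantile type 7).
#'
#' @param g a non-empty `lineage_graph`.
#' @return object of class `track_length_stats`: list with `n_tracks`,
#'   `median`, `p10`, `p90`, and `histogram` (tibble length/count).
#' @export
track_length_stats <- function(g) {
  if (nrow(g$nodes) == 0) abort_param("graph has no nodes")
  lens <- graph_components(g)$span_frames
  q <- stats::quantile(lens, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
  tab <- table(lens)
  structure(list(
    n_tracks = length(lens),
    median = q[[2]], p10 = q[[1]], p90 = q[[3]],
    histogram = tibble::tibble(length = as.integer(names(tab)),
                               count = as.integer(tab))),
    class = "track_length_stats")
}

#' @export
print.track_length_stats <- function(x, ...) {
  cat(sprintf("<track_length_stats> %d tracks; median %g frames (p10 %g, p90 %g)\n",
              x$n_tracks, x$median, x$p10, x$p90))
  invisible(x)
}

#' Prune singleton tracks into a corrected graph
#'
#' Removes every node of every component flagged by [find_singletons()]
#' (and all incident edges). The input graph is left unmodified; pruning
#' is idempotent, and components above the threshold are untouched.
#'
#' @inheritParams find_singletons
#' @return list with `graph` (the pruned `lineage_graph`) and `removed`
#'   (character vector of removed node ids, sorted).
#' @export
prune_singletons <- function(g, max_length = 1) {
  flags <- find_singletons(g, max_length)
  removed <- sort(unlist(flags$nodes, use.names = FALSE))
  if (is.null(removed)) removed <- character(0)
  list(graph = drop_nodes(g, removed), removed = removed)
}

#' Run the full topology QC
#'
#' Evaluates all three graph deviations plus track-length statistics in
#' one pass, the way they are assessed when a dataset is first loaded.
#' `flagged_nodes` is the union of all member nodes of all deviations,
#' for highlighting in the display renderers.
#'
#' @param g a `lineage_graph`.
#' @param singleton_max_length span threshold for singletons (frames).
#' @param max_duration optional transience cutoff for loops and crossings.
#' @return object of class `qc_report`: list with `loops`, `crossings`,
#'   `singletons` (tibbles), `stats` (`track_length_stats`),
#'   `flagged_nodes` (sorted character), and `params`.
#' @export
qc_report <- function(g, singleton_max_length = 1, max_duration = NULL) {
  loops <- find_loops(g, max_duration)
  crossings <- find_crossings(g, max_duration)
  singletons <- find_singletons(g, singleton_max_length)
  stats <- track_length_stats(g)

  loop_nodes <- unique(unlist(lapply(loops$branches, unlist), use.names = FALSE))
  cross_nodes <- unique(unlist(crossings$chain, use.names = FALSE))
  singleton_nodes <- unique(unlist(singletons$nodes, use.names = FALSE))
  flagged <- sort(unique(c(loop_nodes, cross_nodes, singleton_nodes)))
  if (is.null(flagged)) flagged <- character(0)

  structure(list(
    loops = loops, crossings = crossings, singletons = singletons,
    stats = stats, flagged_nodes = flagged,
    flag_type = list(loop = loop_nodes %||% character(0),
                     crossing = cross_nodes %||% character(0),
                     singleton = singleton_nodes %||% character(0)),
    params = list(singleton_max_length = singleton_max_length,
                  max_duration = max_duration)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  loops:      %d\n", nrow(x$loops)))
  cat(sprintf("  crossings:  %d\n", nrow(x$crossings)))
  cat(sprintf("  singletons: %d (span <= %g)\n", nrow(x$singletons),
              x$params$singleton_max_length))
  cat(sprintf("  tracks:     %d; median length %g (p10 %g, p90 %g)\n",
              x$stats$n_tracks, x$stats$median, x$stats$p10, x$stats$p90))
  invisible(x)
}

#' Tidy a QC report into one row per detected deviation
#'
#' @param x a `qc_report`.
#' @param ... unused.
#' @return tibble with `type` (loop/crossing/singleton), `node_a`,
#'   `node_b` (split/merge, merge/split, or first node/NA),
#'   `duration_frames`, `n_nodes`.
#' @export
tidy.qc_report <- function(x, ...) {
  rows <- list()
  if (nrow(x$loops)) {
    rows$loops <- tibble::tibble(
      type = "loop", node_a = x$loops$split, node_b = x$loops$merge,
      duration_frames = x$loops$duration_frames,
      n_nodes = vapply(x$loops$branches,
                       function(b) length(unique(unlist(b))), integer(1)))
  }
  if (nrow(x$crossings)) {
    rows$crossings <- tibble::tibble(
      type = "crossing", node_a = x$crossings$merge, node_b = x$crossings$split,
      duration_frames = x$crossings$duration_frames,
      n_nodes = lengths(x$crossings$chain))
  }
  if (nrow(x$singletons)) {
    rows$singletons <- tibble::tibble(
      type = "singleton",
      node_a = vapply(x$singletons$nodes, `[[`, character(1), 1),
      node_b = NA_character_,
      duration_frames = x$singletons$length_frames,
      n_nodes = lengths(x$singletons$nodes))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(type = character(), node_a = character(),
                          node_b = character(), duration_frames = integer(),
                          n_nodes = integer()))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a QC report
#'
#' @inheritParams tidy.qc_report
#' @return one-row tibble: deviation counts, flagged-node count, and
#'   track-length statistics.
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_loops = nrow(x$loops), n_crossings = nrow(x$crossings),
    n_singletons = nrow(x$singletons),
    n_flagged_nodes = length(x$flagged_nodes),
    n_tracks = x$stats$n_tracks, median_length = x$stats$median,
    p10_length = x$stats$p10, p90_length = x$stats$p90)
}

#' Serialize a QC report to JSON
#'
#' Stable key order and full numeric precision: identical inputs yield
#' byte-identical files. Schema is versioned.
#'
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  x <- list(
    schema = "trackqc-qc-report", version = "1.0",
    params = list(
      singleton_max_length = report$params$singleton_max_length,
      max_duration = report$params$max_duration),
    loops = lapply(seq_len(nrow(report$loops)), function(i) list(
      split = report$loops$split[i], merge = report$loops$merge[i],
      duration_frames = report$loops$duration_frames[i],
      branches = report$loops$branches[[i]])),
    crossings = lapply(seq_len(nrow(report$crossings)), function(i) list(
      merge = report$crossings$merge[i], split = report$crossings$split[i],
      duration_frames = report$crossings$duration_frames[i],
      chain = report$crossings$chain[[i]])),
    singletons = lapply(seq_len(nrow(report$singletons)), function(i) list(
      length_frames = report$singletons$length_frames[i],
      nodes = report$singletons$nodes[[i]])),
    stats = list(n_tracks = report$stats$n_tracks,
                 median = report$stats$median, p10 = report$stats$p10,
                 p90 = report$stats$p90,
                 histogram = list(length = report$stats$histogram$length,
                                  count = report$stats$histogram$count)),
    flagged_nodes = report$flagged_nodes)
  write_json_stable(x, path)
}
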