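# Directed lineage graphs over object observations: construction,
# components, branch-free trajectory segments, degrees, and export.

#' Build the lineage graph of a tracking dataset
#'
#' One node per object observation, one directed edge per relationship row
#' (parent to child, strictly forward in time). Edges that bridge a
#' temporal gap (LAP-style gap closing) are single edges with
#' `frame_gap > 1`; no phantom nodes are interpolated. Relationships
#' between objects of different imaging groups are rejected.
#'
#' @param ds a validated [tracking_dataset()].
#' @return an object of class `lineage_graph`: a list with tibbles `nodes`
#'   (node_id, image_index, object_index, timepoint, group_index, x, y,
#'   feature columns) and `edges` (parent, child, frame_gap), plus
#'   `feature_names`.
#' @export
build_graph <- function(ds) {
  img <- ds$images[c("image_index", "group_index", "timepoint")]
  nodes <- ds$objects %>%
    dplyr::mutate(node_id = node_id(.data$image_index, .data$object_index)) %>%
    dplyr::left_join(img, by = "image_index") %>%
    dplyr::select("node_id", "image_index", "object_index", "timepoint",
                  "group_index", "x", "y", dplyr::all_of(ds$feature_names))
  nodes <- order_nodes(nodes)

  rel <- ds$relationships
  if (nrow(rel) > 0) {
    lu_t <- stats::setNames(nodes$timepoint, nodes$node_id)
    lu_g <- stats::setNames(nodes$group_index, nodes$node_id)
    parent <- node_id(rel$parent_image_index, rel$parent_object_index)
    child <- node_id(rel$child_image_index, rel$child_object_index)
    if (any(lu_g[parent] != lu_g[child])) {
      bad <- which(lu_g[parent] != lu_g[child])[1]
      abort_integrity(sprintf(
        "relationship %s -> %s crosses imaging groups", parent[bad], child[bad]))
    }
    edges <- tibble::tibble(
      parent = parent, child = child,
      frame_gap = as.integer(lu_t[child] - lu_t[parent]))
    edges <- edges[order(lu_t[edges$parent], edges$parent, edges$child), ]
  } else {
    edges <- tibble::tibble(parent = character(), child = character(),
                            frame_gap = integer())
  }

  structure(list(nodes = nodes, edges = edges,
                 feature_names = ds$feature_names),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> %d nodes, %d edges, %d timepoints\n",
              nrow(x$nodes), nrow(x$edges),
              dplyr::n_distinct(x$nodes$timepoint)))
  invisible(x)
}

# igraph view of the lineage graph (vertex names = node ids).
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges[c("parent", "child")]),
    directed = TRUE,
    vertices = data.frame(name = g$nodes$node_id))
}

# in/out degree named vectors, computed from the edge tibble.
degree_vectors <- function(g) {
  ids <- g$nodes$node_id
  ind <- table(factor(g$edges$child, levels = ids))
  outd <- table(factor(g$edges$parent, levels = ids))
  list(in_deg = stats::setNames(as.integer(ind), ids),
       out_deg = stats::setNames(as.integer(outd), ids))
}

# children / parents as named lists of node-id vectors, children sorted by
# (timepoint, image_index, object_index) for determinism.
adjacency_lists <- function(g) {
  e <- g$edges
  ord <- match(e$child, g$nodes$node_id)
  e <- e[order(match(e$parent, g$nodes$node_id), ord), ]
  ch <- split(e$child, factor(e$parent, levels = g$nodes$node_id))
  e2 <- g$edges[order(match(g$edges$child, g$nodes$node_id),
                      match(g$edges$parent, g$nodes$node_id)), ]
  pa <- split(e2$parent, factor(e2$child, levels = g$nodes$node_id))
  list(children = ch, parents = pa)
}

#' Node degrees
#'
#' @param g a `lineage_graph`.
#' @return tibble with `node_id`, `in_degree`, `out_degree`, one row per
#'   node in deterministic (timepoint, image, object) order.
#' @export
node_degrees <- function(g) {
  d <- degree_vectors(g)
  tibble::tibble(node_id = g$nodes$node_id,
                 in_degree = unname(d$in_deg[g$nodes$node_id]),
                 out_degree = unname(d$out_deg[g$nodes$node_id]))
}

#' Weakly connected components ("tracks")
#'
#' Components of the undirected view of the lineage graph are the unit of
#' track-length statistics and singleton detection: splits and merges keep
#' a cell family in one component, so path enumeration is never needed.
#' `span_frames` counts distinct occupied timepoints (gap frames are not
#' counted).
#'
#' @param g a `lineage_graph`.
#' @return tibble with `component_id` (1..k, ordered by each component's
#'   smallest (timepoint, image, object) member), `n_nodes`, `span_frames`,
#'   and list-columns `nodes` (node ids, deterministic order) and
#'   `root_nodes` (in-degree-0 members).
#' @export
graph_components <- function(g) {
  if (nrow(g$nodes) == 0) {
    return(tibble::tibble(component_id = integer(), n_nodes = integer(),
                          span_frames = integer(), nodes = list(),
                          root_nodes = list()))
  }
  memb <- igraph::components(as_igraph(g), mode = "weak")$membership
  memb <- memb[g$nodes$node_id]  # nodes are already in deterministic order
  first_seen <- !duplicated(memb)
  relabel <- stats::setNames(seq_len(sum(first_seen)), memb[first_seen])
  comp <- unname(relabel[as.character(memb)])

  d <- degree_vectors(g)
  tp <- stats::setNames(g$nodes$timepoint, g$nodes$node_id)
  ids_by_comp <- split(g$nodes$node_id, comp)
  tibble::tibble(
    component_id = as.integer(names(ids_by_comp)),
    n_nodes = unname(lengths(ids_by_comp)),
    span_frames = unname(vapply(ids_by_comp,
                                function(ids) length(unique(tp[ids])),
                                integer(1))),
    nodes = unname(ids_by_comp),
    root_nodes = unname(lapply(ids_by_comp,
                               function(ids) ids[d$in_deg[ids] == 0]))
  ) %>% dplyr::arrange(.data$component_id)
}

#' Maximal branch-free trajectory segments
#'
#' Decomposes the graph into maximal unbranched directed paths: every edge
#' belongs to exactly one segment, and split/merge nodes terminate
#' segments (appearing in each incident segment). Isolated nodes form
#' single-node segments. These are the polylines of the XYT plot.
#'
#' @param g a `lineage_graph`.
#' @return tibble with `segment_id`, list-column `nodes` (ordered node
#'   ids), `n_nodes`, and `branch_free = TRUE`.
#' @export
branch_free_segments <- function(g) {
  d <- degree_vectors(g)
  adj <- adjacency_lists(g)
  segs <- list()

  # an edge (u, v) starts a segment iff u is not a pass-through node
  for (u in g$nodes$node_id) {
    if (d$out_deg[[u]] == 0) next
    starts_here <- d$in_deg[[u]] != 1 || d$out_deg[[u]] != 1
    if (!starts_here) next
    for (v in adj$children[[u]]) {
      seg <- c(u, v)
      w <- v
      while (d$in_deg[[w]] == 1 && d$out_deg[[w]] == 1) {
        w <- adj$children[[w]][[1]]
        seg <- c(seg, w)
      }
      segs[[length(segs) + 1]] <- seg
    }
  }
  iso <- g$nodes$node_id[d$in_deg == 0 & d$out_deg == 0]
  for (u in iso) segs[[length(segs) + 1]] <- u

  if (length(segs) == 0) {
    return(tibble::tibble(segment_id = integer(), nodes = list(),
                          n_nodes = integer(), branch_free = logical()))
  }
  key <- match(vapply(segs, `[[`, character(1), 1), g$nodes$node_id)
  key2 <- vapply(segs, function(s) if (length(s) > 1)
    match(s[[2]], g$nodes$node_id) else 0L, integer(1))
  segs <- segs[order(key, key2)]
  tibble::tibble(segment_id = seq_along(segs), nodes = segs,
                 n_nodes = lengths(segs), branch_free = TRUE)
}

# Export -------------------------------------------------------------------

#' Export a lineage graph to GraphML
#'
#' Vertex attributes: timepoint, group_index, x, y and all features; edge
#' attribute: frame_gap.
#'
#' @param g a `lineage_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  vertices <- as.data.frame(g$nodes)
  names(vertices)[names(vertices) == "node_id"] <- "name"
  ig <- igraph::graph_from_data_frame(
    as.data.frame(g$edges), directed = TRUE, vertices = vertices)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export a lineage graph as JSON
#'
#' A stable, documented layout: `nodes` is an array (deterministic node
#' order) of objects with `id`, `timepoint`, `group_index`, `x`, `y` and a
#' `features` object; `edges` is an array of `{parent, child, frame_gap}`.
#'
#' @inheritParams export_graphml
#' @return `path`, invisibly.
#' @export
export_lineage_json <- function(g, path) {
  nodes <- lapply(seq_len(nrow(g$nodes)), function(i) {
    row <- g$nodes[i, ]
    list(id = row$node_id, timepoint = row$timepoint,
         group_index = row$group_index, x = row$x, y = row$y,
         features = as.list(row[g$feature_names]))
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(i) {
    as.list(g$edges[i, c("parent", "child", "frame_gap")])
  })
  write_json_stable(list(schema = "trackqc-lineage", version = "1.0",
                         nodes = nodes, edges = edges), path)
  invisible(path)
}

# Subgraph with the given nodes removed (used by pruning).
drop_nodes <- function(g, remove) {
  keep <- !g$nodes$node_id %in% remove
  e <- g$edges
  e <- e[!(e$parent %in% remove) & !(e$child %in% remove), ]
  structure(list(nodes = g$nodes[keep, ], edges = e,
                 feature_names = g$feature_names),
            class = "lineage_graph")
}
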