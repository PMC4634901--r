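# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: components by flood fill, loop/crossing detection by
# exhaustive simple-path enumeration, means by explicit loops.

oracle_components <- function(g) {
  ids <- g$nodes$node_id
  nbr <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(g$edges))) {
    p <- g$edges$parent[i]; ch <- g$edges$child[i]
    nbr[[p]] <- c(nbr[[p]], ch)
    nbr[[ch]] <- c(nbr[[ch]], p)
  }
  seen <- character(0)
  comps <- list()
  for (s in ids) {
    if (s %in% seen) next
    queue <- s; comp <- character(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(nbr[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# all simple directed paths between two vertex names, via igraph
all_paths <- function(ig, from, to) {
  lapply(igraph::all_simple_paths(ig, from, to = to, mode = "out"),
         function(p) names(p))
}

graph_degrees_named <- function(g) {
  nd <- node_degrees(g)
  list(in_deg = stats::setNames(nd$in_degree, nd$node_id),
       out_deg = stats::setNames(nd$out_degree, nd$node_id))
}

lg_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges[c("parent", "child")]), directed = TRUE,
    vertices = data.frame(name = g$nodes$node_id))
}

# loop oracle: per split node, the earliest node reachable by two
# internally node-disjoint directed paths
oracle_loops <- function(g) {
  d <- graph_degrees_named(g)
  ig <- lg_igraph(g)
  tp <- stats::setNames(g$nodes$timepoint, g$nodes$node_id)
  key <- stats::setNames(seq_len(nrow(g$nodes)), g$nodes$node_id)
  splits <- g$nodes$node_id[d$out_deg[g$nodes$node_id] >= 2]
  out <- list()
  for (u in splits) {
    best <- NULL
    for (m in g$nodes$node_id[tp[g$nodes$node_id] > tp[[u]]]) {
      paths <- all_paths(ig, u, m)
      if (length(paths) < 2) next
      found <- FALSE
      for (i in seq_along(paths)) {
        for (j in seq_along(paths)) {
          if (i >= j) next
          inter <- intersect(paths[[i]][-c(1, length(paths[[i]]))],
                             paths[[j]][-c(1, length(paths[[j]]))])
          if (length(inter) == 0) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found && (is.null(best) || tp[[m]] < tp[[best]] ||
                    (tp[[m]] == tp[[best]] && key[[m]] < key[[best]]))) {
        best <- m
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- data.frame(split = u, merge = best)
    }
  }
  if (length(out) == 0) {
    return(data.frame(split = character(), merge = character()))
  }
  res <- do.call(rbind, out)
  res[order(tp[res$split], key[res$split]), , drop = FALSE]
}

# crossing oracle: merge m and split s joined by a path whose nodes after
# m have in-degree 1 and whose nodes before s have out-degree 1
oracle_crossings <- function(g) {
  d <- graph_degrees_named(g)
  ig <- lg_igraph(g)
  ids <- g$nodes$node_id
  merges <- ids[d$in_deg[ids] >= 2]
  splits <- ids[d$out_deg[ids] >= 2]
  out <- list()
  for (m in merges) {
    for (s in splits) {
      ok <- if (m == s) {
        TRUE
      } else {
        any(vapply(all_paths(ig, m, s), function(p) {
          k <- length(p)
          all(d$out_deg[p[1:(k - 1)]] == 1) && all(d$in_deg[p[2:k]] == 1)
        }, logical(1)))
      }
      if (ok) out[[length(out) + 1]] <- data.frame(merge = m, split = s)
    }
  }
  if (length(out) == 0) {
    return(data.frame(merge = character(), split = character()))
  }
  do.call(rbind, out)
}

# naive per-timepoint feature means
oracle_timepoint_means <- function(ds, feature) {
  tps <- sort(unique(ds$images$timepoint))
  sapply(tps, function(t) {
    imgs <- ds$images$image_index[ds$images$timepoint == t]
    v <- ds$objects[[feature]][ds$objects$image_index %in% imgs]
    if (length(v) == 0) NA_real_ else sum(v) / length(v)
  })
}

# percentile by linear interpolation between closest order statistics
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
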