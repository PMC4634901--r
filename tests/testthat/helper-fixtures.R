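# Fixtures are always built in code, never stored.

# A lineage graph from a compact description: `tp` is a named integer
# vector (node label -> timepoint), `edges` a data.frame(from, to) of
# labels. Returns the graph, the dataset, and the label -> node_id map.
make_graph <- function(tp, edges = NULL) {
  labs <- names(tp)
  tps <- sort(unique(unname(tp)))
  images <- tibble::tibble(image_index = seq_along(tps), timepoint = tps)
  oi <- stats::ave(seq_along(labs), tp, FUN = seq_along)
  objects <- tibble::tibble(
    image_index = match(unname(tp), tps),
    object_index = as.integer(oi),
    x = 10 * seq_along(labs), y = 5 * seq_along(labs),
    f = as.numeric(seq_along(labs)))
  id <- stats::setNames(node_id(objects$image_index, objects$object_index), labs)
  rel <- if (!is.null(edges) && nrow(edges) > 0) {
    tibble::tibble(
      parent_image_index = objects$image_index[match(edges$from, labs)],
      parent_object_index = objects$object_index[match(edges$from, labs)],
      child_image_index = objects$image_index[match(edges$to, labs)],
      child_object_index = objects$object_index[match(edges$to, labs)])
  } else NULL
  ds <- tracking_dataset(images, objects, rel)
  list(g = build_graph(ds), ds = ds, id = id)
}

chain_tp <- function(n, labels = letters[seq_len(n)], t0 = 0) {
  stats::setNames(t0 + seq_len(n) - 1, labels)
}
chain_edges <- function(labels) {
  data.frame(from = labels[-length(labels)], to = labels[-1])
}

# the toy database: 3 images, 6 objects, 4 relationships
toy_dataset <- function() {
  images <- tibble::tibble(image_index = 1:3, timepoint = 0:2)
  objects <- tibble::tibble(
    image_index = c(1, 1, 2, 2, 3, 3),
    object_index = c(1, 2, 1, 2, 1, 2),
    x = c(10, 40, 12, 41, 14, 43),
    y = c(20, 50, 21, 52, 23, 55),
    Intensity_Mean = c(0.5, 0.8, 0.55, 0.82, 0.6, 0.85),
    Area = c(100, 120, 101, 119, 98, 121))
  rel <- tibble::tibble(
    parent_image_index = c(1, 1, 2, 2),
    parent_object_index = c(1, 2, 1, 2),
    child_image_index = c(2, 2, 3, 3),
    child_object_index = c(1, 2, 1, 2))
  tracking_dataset(images, objects, rel)
}

# Random sparse DAG over <= n nodes with splits and merges, as a
# lineage_graph. Sparse enough that exhaustive path enumeration stays
# cheap in the oracles.
random_dag <- function(n, seed) {
  set.seed(seed)
  n_t <- max(3, round(n / 4))
  tp <- sort(sample(0:(n_t - 1), n, replace = TRUE))
  labs <- paste0("n", seq_len(n))
  names(tp) <- labs
  from <- character(0); to <- character(0)
  for (i in seq_len(n)) {
    prev <- which(tp < tp[i] & tp >= tp[i] - 2)
    if (length(prev) == 0) next
    k <- sample(0:2, 1, prob = c(0.25, 0.6, 0.15))
    k <- min(k, length(prev))
    if (k > 0) {
      par <- sample(prev, k)
      from <- c(from, labs[par]); to <- c(to, rep(labs[i], k))
    }
  }
  make_graph(tp, data.frame(from = from, to = to))
}

write_raw_sqlite <- function(path, image, object, relationship,
                             names = c("image", "object", "relationship")) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, names[1], as.data.frame(image))
  DBI::dbWriteTable(con, names[2], as.data.frame(object))
  DBI::dbWriteTable(con, names[3], as.data.frame(relationship))
  path
}
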