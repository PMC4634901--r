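test_that("a diamond split/re-merge is reported as exactly one loop", {
  tp <- c(u = 0, a = 1, b = 1, v = 2)
  ed <- data.frame(from = c("u", "u", "a", "b"), to = c("a", "b", "v", "v"))
  fx <- make_graph(tp, ed)
  loops <- find_loops(fx$g)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$split, unname(fx$id[["u"]]))
  expect_equal(loops$merge, unname(fx$id[["v"]]))
  expect_equal(loops$duration_frames, 2L)
  # the two reported branches are internally vertex-disjoint
  br <- loops$branches[[1]]
  expect_length(intersect(br[[1]][-c(1, length(br[[1]]))],
                          br[[2]][-c(1, length(br[[2]]))]), 0)
})

test_that("chains and pure division trees contain no loops", {
  fx <- make_graph(chain_tp(10), chain_edges(letters[1:10]))
  expect_equal(nrow(find_loops(fx$g)), 0)

  tp <- c(u = 0, a = 1, b = 1, a1 = 2, a2 = 2, b1 = 2, b2 = 2)
  ed <- data.frame(from = c("u", "u", "a", "a", "b", "b"),
                   to = c("a", "b", "a1", "a2", "b1", "b2"))
  fx2 <- make_graph(tp, ed)
  expect_equal(nrow(find_loops(fx2$g)), 0)
})

test_that("unequal-branch loops report the earliest reconvergence and honor max_duration", {
  # one branch direct (gap edge), one through two intermediates
  tp <- c(u = 0, a = 1, b = 2, v = 3)
  ed <- data.frame(from = c("u", "a", "b", "u"), to = c("a", "b", "v", "v"))
  fx <- make_graph(tp, ed)
  loops <- find_loops(fx$g)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$duration_frames, 3L)
  expect_equal(nrow(find_loops(fx$g, max_duration = 2)), 0)
  expect_equal(nrow(find_loops(fx$g, max_duration = 3)), 1)
})

test_that("a merge-chain-split is reported as one crossing with its chain", {
  tp <- c(a = 0, b = 0, m = 1, c = 2, s = 3, d = 4, e = 4)
  ed <- data.frame(from = c("a", "b", "m", "c", "s", "s"),
                   to = c("m", "m", "c", "s", "d", "e"))
  fx <- make_graph(tp, ed)
  cr <- find_crossings(fx$g)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$merge, unname(fx$id[["m"]]))
  expect_equal(cr$split, unname(fx$id[["s"]]))
  expect_equal(cr$chain[[1]], unname(fx$id[c("m", "c", "s")]))
  expect_equal(cr$duration_frames, 2L)
  expect_equal(nrow(find_crossings(fx$g, max_duration = 1)), 0)
})

test_that("a merge with no subsequent split is not a crossing", {
  tp <- c(a = 0, b = 0, m = 1, c = 2, d = 3)
  ed <- data.frame(from = c("a", "b", "m", "c"), to = c("m", "m", "c", "d"))
  fx <- make_graph(tp, ed)
  expect_equal(nrow(find_crossings(fx$g)), 0)
})

test_that("a single node with in-degree 2 and out-degree 2 is a duration-0 crossing", {
  tp <- c(a = 0, b = 0, m = 1, c = 2, d = 2)
  ed <- data.frame(from = c("a", "b", "m", "m"), to = c("m", "m", "c", "d"))
  fx <- make_graph(tp, ed)
  cr <- find_crossings(fx$g)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$merge, cr$split)
  expect_equal(cr$duration_frames, 0L)
})

test_that("loop and crossing detectors agree with brute-force oracles on random DAGs", {
  for (seed in 1:30) {
    g <- random_dag(50, seed)$g
    loops <- find_loops(g)
    want_l <- oracle_loops(g)
    expect_equal(paste(loops$split, loops$merge),
                 paste(want_l$split, want_l$merge), info = paste("seed", seed))
    cr <- find_crossings(g)
    want_c <- oracle_crossings(g)
    expect_setequal(paste(cr$merge, cr$split),
                    paste(want_c$merge, want_c$split))
  }
})

test_that("singleton detection flags exactly the short-span components", {
  fx <- make_graph(c(z = 3))
  expect_equal(nrow(find_singletons(fx$g, 1)), 1)

  tp <- c(chain_tp(4), z = 0)
  fx2 <- make_graph(tp, chain_edges(letters[1:4]))
  flags <- find_singletons(fx2$g, 3)
  expect_equal(nrow(flags), 1)  # only the isolated node; the 4-frame chain survives
  expect_equal(flags$nodes[[1]], unname(fx2$id[["z"]]))

  expect_error(find_singletons(fx2$g, 0), class = "trackqc_parameter_error")

  sim <- simulate_tracking(n_initial = 5, n_frames = 10, n_singletons = 4, seed = 11)
  got <- find_singletons(build_graph(sim$dataset), 1)
  expect_equal(nrow(got), 4)
  expect_setequal(unlist(got$nodes), sim$truth$injected_singletons)
})

test_that("track-length statistics use interpolated order statistics", {
  fx <- make_graph(chain_tp(5), chain_edges(letters[1:5]))
  st <- track_length_stats(fx$g)
  expect_equal(st$n_tracks, 1)
  expect_equal(c(st$p10, st$median, st$p90), c(5, 5, 5))

  # ten chains of lengths 1..10 -> median 5.5
  tp <- integer(0); ed <- NULL
  for (k in 1:10) {
    labs <- paste0("c", k, "_", seq_len(k))
    tp <- c(tp, chain_tp(k, labs))
    if (k > 1) ed <- rbind(ed, chain_edges(labs))
  }
  fx2 <- make_graph(tp, ed)
  st2 <- track_length_stats(fx2$g)
  expect_equal(st2$n_tracks, 10)
  expect_equal(st2$median, 5.5)
  expect_equal(st2$p10, oracle_quantile(1:10, 0.1))
  expect_equal(st2$p90, oracle_quantile(1:10, 0.9))
  expect_equal(sum(st2$histogram$count), st2$n_tracks)
  expect_equal(st2$histogram$count, rep(1L, 10))

  empty <- make_graph(c(z = 0))$g
  empty$nodes <- empty$nodes[0, ]
  expect_error(track_length_stats(empty), class = "trackqc_parameter_error")
})

test_that("pruning removes flagged components, is idempotent, and spares long tracks", {
  sim <- simulate_tracking(n_initial = 4, n_frames = 10, n_singletons = 2, seed = 5)
  g <- build_graph(sim$dataset)
  pr <- prune_singletons(g, 1)
  expect_equal(length(pr$removed), 2)
  expect_equal(nrow(pr$graph$nodes), nrow(g$nodes) - 2)
  expect_equal(nrow(find_singletons(pr$graph, 1)), 0)
  # input graph untouched
  expect_equal(nrow(g$nodes), nrow(sim$dataset$objects))
  # idempotence
  pr2 <- prune_singletons(pr$graph, 1)
  expect_equal(length(pr2$removed), 0)
  expect_identical(pr2$graph$nodes, pr$graph$nodes)
  # soundness: no removed node belongs to a long component
  comps <- graph_components(g)
  long_nodes <- unlist(comps$nodes[comps$span_frames > 1])
  expect_length(intersect(pr$removed, long_nodes), 0)
})

test_that("qc_report aggregates detectors and is byte-deterministic as JSON", {
  clean <- simulate_tracking(n_initial = 5, n_frames = 10, seed = 2)
  rep0 <- qc_report(build_graph(clean$dataset))
  expect_equal(nrow(rep0$loops), 0)
  expect_equal(nrow(rep0$crossings), 0)
  expect_equal(nrow(rep0$singletons), 0)
  expect_length(rep0$flagged_nodes, 0)

  sim <- simulate_tracking(n_initial = 8, n_frames = 12, n_loops = 2,
                           n_crossings = 1, n_singletons = 3, seed = 9)
  g <- build_graph(sim$dataset)
  rep <- qc_report(g)
  expect_equal(glance(rep)$n_loops, 2)
  expect_equal(glance(rep)$n_crossings, 1)
  expect_equal(glance(rep)$n_singletons, 3)
  expect_true(all(rep$flagged_nodes %in% g$nodes$node_id))
  td <- tidy(rep)
  expect_equal(nrow(td), 6)
  expect_setequal(td$type, c("loop", "crossing", "singleton"))

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_qc_report(rep, f1)
  write_qc_report(qc_report(build_graph(sim$dataset)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
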