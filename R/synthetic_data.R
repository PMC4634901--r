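# Ground-truthed simulator of tracked nuclei: Gaussian random-walk motion,
# cell divisions, gap-closed disappearances, and injected topology
# artifacts (loops, crossings, singletons) at known, isolated locations —
# so detector counts can be asserted exactly, not statistically.

#' Simulate a tracked time-lapse movie with known ground truth
#'
#' Objects perform Gaussian random walks with reflecting frame boundaries.
#' Divisions replace a track by two children; gap links skip exactly one
#' frame (the object is unobserved, the relationship spans two frames).
#' Artifacts are injected post hoc by rewiring relationship rows on
#' dedicated "host" tracks that never divide or gap, one host per loop and
#' two per crossing, so no two artifacts interact:
#' \itemize{
#'   \item a *loop* adds a two-frame phantom branch that splits off a host
#'     track and re-merges three frames later;
#'   \item a *crossing* fuses two host tracks for three frames (merge,
#'     one unbranched chain node, split) and removes the second track's
#'     observations in between;
#'   \item a *singleton* is a spurious unlinked single-frame object.
#' }
#' Features are smooth per-track sinusoids plus Gaussian noise
#' (`Signal_1..n`), and one column, `Timepoint_Ramp`, deterministically
#' equal to the timepoint (a normalization sanity check: it must become an
#' exact 0-1 ramp). In `synchronized_divisions` mode all non-host tracks
#' divide at the same shared frames (thirds of the movie), emulating the
#' synchronous nuclear divisions of an early embryo.
#'
#' @param n_initial objects present at frame 0.
#' @param n_frames movie length (>= 2; >= 6 when artifacts are injected).
#' @param frame_size `c(W, H)` pixels.
#' @param motion_sigma random-walk step SD, pixels/frame.
#' @param division_prob per-object per-frame division probability.
#' @param gap_prob per-link probability of skipping one frame.
#' @param n_loops,n_crossings,n_singletons injected artifact counts.
#' @param n_features number of sinusoid feature columns.
#' @param synchronized_divisions all non-host tracks divide at shared
#'   frames (ignores `division_prob`).
#' @param seed integer; identical seeds give identical datasets.
#' @return list with `dataset` (a [tracking_dataset()], `frame_size`
#'   attribute set) and `truth`: tibbles/vectors `injected_loops`
#'   (split, merge), `injected_crossings` (merge, split),
#'   `injected_singletons`, `division_events` (node ids).
#' @export
simulate_tracking <- function(n_initial = 10, n_frames = 20,
                              frame_size = c(128, 128), motion_sigma = 2,
                              division_prob = 0, gap_prob = 0,
                              n_loops = 0, n_crossings = 0, n_singletons = 0,
                              n_features = 2, synchronized_divisions = FALSE,
                              seed = 1) {
  if (n_frames < 2) abort_param("n_frames must be >= 2")
  if (division_prob < 0 || division_prob > 1 || gap_prob < 0 || gap_prob > 1) {
    abort_param("probabilities must lie in [0, 1]")
  }
  if (min(n_loops, n_crossings, n_singletons, n_features) < 0) {
    abort_param("counts must be >= 0")
  }
  if (n_initial < 1) abort_param("n_initial must be >= 1")
  n_hosts <- n_loops + 2 * n_crossings
  if (n_hosts > n_initial) {
    abort_param(sprintf(
      "cannot place %d loop(s) and %d crossing(s) with n_initial = %d; increase n_initial to at least %d",
      n_loops, n_crossings, n_initial, n_hosts))
  }
  if (n_hosts > 0 && n_frames < 6) {
    abort_param("artifact injection needs n_frames >= 6; increase n_frames")
  }

  withr::with_seed(seed, {
    W <- frame_size[[1]]; H <- frame_size[[2]]
    reflect <- function(p, lo, hi) {
      while (p < lo || p > hi) {
        if (p < lo) p <- 2 * lo - p
        if (p > hi) p <- 2 * hi - p
      }
      p
    }

    obj <- list()     # frame, track, x, y
    links <- list()   # pf, pt, cf, ct (parent frame/track, child frame/track)
    phases <- list()  # per track: n_features phases
    next_id <- 0L
    new_track <- function(phase = NULL) {
      next_id <<- next_id + 1L
      phases[[as.character(next_id)]] <<-
        if (is.null(phase)) stats::runif(max(n_features, 1), 0, 2 * pi)
        else phase + stats::rnorm(length(phase), 0, 0.1)
      next_id
    }
    emit <- function(frame, track, x, y) {
      obj[[length(obj) + 1]] <<- c(frame, track, x, y)
    }
    link <- function(pf, pt, cf, ct) {
      links[[length(links) + 1]] <<- c(pf, pt, cf, ct)
    }

    # active track state: id, x, y, last emitted frame, host flag, gapping
    tracks <- lapply(seq_len(n_initial), function(i) {
      list(id = new_track(), x = stats::runif(1, W * 0.1, W * 0.9),
           y = stats::runif(1, H * 0.1, H * 0.9),
           last = 0L, host = i <= n_hosts, gapping = FALSE)
    })
    for (tr in tracks) emit(0L, tr$id, tr$x, tr$y)

    sync_frames <- if (synchronized_divisions) {
      unique(pmax(1, round(n_frames * c(1 / 3, 2 / 3))))
    } else integer(0)
    divisions <- character(0)

    for (frame in seq_len(n_frames - 1)) {
      nxt <- list()
      for (tr in tracks) {
        tr$x <- reflect(tr$x + stats::rnorm(1, 0, motion_sigma), 0, W - 1)
        tr$y <- reflect(tr$y + stats::rnorm(1, 0, motion_sigma), 0, H - 1)

        wants_division <- if (synchronized_divisions) {
          frame %in% sync_frames
        } else {
          stats::runif(1) < division_prob
        }
        divide <- !tr$host && !tr$gapping && wants_division
        gap <- !tr$host && !tr$gapping && !divide &&
          frame < n_frames - 1 && stats::runif(1) < gap_prob

        if (divide) {
          divisions <- c(divisions, paste0(tr$last, ":", tr$id))
          ang <- stats::runif(1, 0, pi)
          off <- max(3, 2 * motion_sigma)
          for (s in c(-1, 1)) {
            ch <- list(id = new_track(phases[[as.character(tr$id)]]),
                       x = reflect(tr$x + s * off * cos(ang), 0, W - 1),
                       y = reflect(tr$y + s * off * sin(ang), 0, H - 1),
                       last = frame, host = FALSE, gapping = FALSE)
            emit(frame, ch$id, ch$x, ch$y)
            link(tr$last, tr$id, frame, ch$id)
            nxt[[length(nxt) + 1]] <- ch
          }
        } else if (gap) {
          tr$gapping <- TRUE
          nxt[[length(nxt) + 1]] <- tr
        } else {
          emit(frame, tr$id, tr$x, tr$y)
          link(tr$last, tr$id, frame, tr$id)
          tr$last <- frame
          tr$gapping <- FALSE
          nxt[[length(nxt) + 1]] <- tr
        }
      }
      tracks <- nxt
    }

    obj <- do.call(rbind, obj)
    obj <- data.frame(frame = as.integer(obj[, 1]), track = as.integer(obj[, 2]),
                      x = obj[, 3], y = obj[, 4])
    links <- if (length(links)) {
      l <- do.call(rbind, links)
      data.frame(pf = as.integer(l[, 1]), pt = as.integer(l[, 2]),
                 cf = as.integer(l[, 3]), ct = as.integer(l[, 4]))
    } else data.frame(pf = integer(), pt = integer(), cf = integer(),
                      ct = integer())

    host_ids <- seq_len(n_hosts)
    truth_loops <- list(); truth_cross <- list(); truth_singl <- character(0)

    pos_of <- function(frame, track) {
      i <- which(obj$frame == frame & obj$track == track)[[1]]
      c(obj$x[[i]], obj$y[[i]])
    }

    # loops: hosts 1..n_loops
    for (i in seq_len(n_loops)) {
      h <- host_ids[[i]]
      t0 <- sample(seq(1, n_frames - 4), 1)
      ph <- new_track(phases[[as.character(h)]])
      for (dt in 1:2) {
        p <- pos_of(t0 + dt, h)
        ex <- reflect(p[[1]] + 6, 0, W - 1); ey <- reflect(p[[2]] + 6, 0, H - 1)
        obj <- rbind(obj, data.frame(frame = t0 + dt, track = ph, x = ex, y = ey))
      }
      links <- rbind(links,
                     data.frame(pf = t0, pt = h, cf = t0 + 1, ct = ph),
                     data.frame(pf = t0 + 1, pt = ph, cf = t0 + 2, ct = ph),
                     data.frame(pf = t0 + 2, pt = ph, cf = t0 + 3, ct = h))
      truth_loops[[i]] <- c(split_frame = t0, split_track = h,
                            merge_frame = t0 + 3, merge_track = h)
    }

    # crossings: host pairs (n_loops+1, n_loops+2), ...
    for (i in seq_len(n_crossings)) {
      a <- host_ids[[n_loops + 2 * i - 1]]
      b <- host_ids[[n_loops + 2 * i]]
      t0 <- sample(seq(1, n_frames - 4), 1)
      # remove b's observations during the fused interval
      drop <- obj$track == b & obj$frame >= t0 & obj$frame <= t0 + 2
      obj <- obj[!drop, ]
      ldrop <- (links$ct == b & links$cf >= t0 & links$cf <= t0 + 3) |
        (links$pt == b & links$pf >= t0 & links$pf <= t0 + 2)
      links <- links[!ldrop, ]
      links <- rbind(links,
                     data.frame(pf = t0 - 1, pt = b, cf = t0, ct = a),
                     data.frame(pf = t0 + 2, pt = a, cf = t0 + 3, ct = b))
      truth_cross[[i]] <- c(merge_frame = t0, merge_track = a,
                            split_frame = t0 + 2, split_track = a)
    }

    # singletons: spurious unlinked single-frame detections
    for (i in seq_len(n_singletons)) {
      s <- new_track()
      f <- sample(seq(0, n_frames - 1), 1)
      sx <- stats::runif(1, 0, W - 1); sy <- stats::runif(1, 0, H - 1)
      obj <- rbind(obj, data.frame(frame = f, track = s, x = sx, y = sy))
      truth_singl <- c(truth_singl, paste0(f, ":", s))
    }

    # assemble tables: image_index = frame + 1; object_index by track order
    obj <- obj[order(obj$frame, obj$track), ]
    obj$image_index <- obj$frame + 1L
    obj$object_index <- stats::ave(obj$track, obj$frame,
                                   FUN = seq_along)
    key <- stats::setNames(obj$object_index,
                           paste0(obj$frame, ":", obj$track))
    nid <- function(frame, track) {
      node_id(frame + 1L, key[paste0(frame, ":", track)])
    }

    noise <- function(n) stats::rnorm(n, 0, 0.1)
    objects <- tibble::tibble(
      image_index = obj$image_index, object_index = as.integer(obj$object_index),
      x = obj$x, y = obj$y)
    for (j in seq_len(n_features)) {
      phj <- vapply(as.character(obj$track),
                    function(tk) phases[[tk]][[j]], numeric(1))
      objects[[paste0("Signal_", j)]] <-
        unname(sin(2 * pi * obj$frame / n_frames + phj)) + noise(nrow(obj))
    }
    objects$Timepoint_Ramp <- as.numeric(obj$frame)

    images <- tibble::tibble(image_index = seq_len(n_frames),
                             group_index = 0L,
                             timepoint = seq_len(n_frames) - 1L)
    relationships <- tibble::tibble(
      parent_image_index = links$pf + 1L,
      parent_object_index = as.integer(key[paste0(links$pf, ":", links$pt)]),
      child_image_index = links$cf + 1L,
      child_object_index = as.integer(key[paste0(links$cf, ":", links$ct)]))

    ds <- tracking_dataset(images, objects, relationships)
    attr(ds, "frame_size") <- c(W, H)

    truth <- list(
      injected_loops = tibble::tibble(
        split = vapply(truth_loops, function(l)
          nid(l[["split_frame"]], l[["split_track"]]), character(1)),
        merge = vapply(truth_loops, function(l)
          nid(l[["merge_frame"]], l[["merge_track"]]), character(1))),
      injected_crossings = tibble::tibble(
        merge = vapply(truth_cross, function(l)
          nid(l[["merge_frame"]], l[["merge_track"]]), character(1)),
        split = vapply(truth_cross, function(l)
          nid(l[["split_frame"]], l[["split_track"]]), character(1))),
      injected_singletons = vapply(strsplit(truth_singl, ":"), function(p)
        nid(as.integer(p[[1]]), as.integer(p[[2]])), character(1)),
      division_events = vapply(strsplit(divisions, ":"), function(p)
        nid(as.integer(p[[1]]), as.integer(p[[2]])), character(1)))

    list(dataset = ds, truth = truth)
  })
}

#' Render simulated movie frames as TIFF files
#'
#' Draws each object as an isotropic Gaussian blob whose peak intensity
#' sits exactly at the rounded centroid pixel (overlaps combine by
#' maximum, so each peak stays exact). File paths are written back into
#' the image table, ready for [extract_synchrogram()].
#'
#' @param ds a `tracking_dataset` with centroids inside the frame.
#' @param out_dir output directory (created).
#' @param blob_sigma blob SD in pixels.
#' @param frame_size `c(W, H)`; default: the dataset's `frame_size`
#'   attribute, else derived from the centroid extent.
#' @return the dataset with an `image_path` column pointing at the files.
#' @export
render_frames <- function(ds, out_dir, blob_sigma = 2, frame_size = NULL) {
  frame_size <- frame_size %||% attr(ds, "frame_size") %||%
    c(ceiling(max(ds$objects$x)) + 10, ceiling(max(ds$objects$y)) + 10)
  W <- frame_size[[1]]; H <- frame_size[[2]]
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_io(sprintf("cannot create directory %s", out_dir))

  half <- ceiling(4 * blob_sigma)
  paths <- character(nrow(ds$images))
  for (i in seq_len(nrow(ds$images))) {
    ii <- ds$images$image_index[[i]]
    img <- matrix(0, nrow = H, ncol = W)
    rows <- ds$objects[ds$objects$image_index == ii, ]
    for (j in seq_len(nrow(rows))) {
      r0 <- round(rows$y[[j]]); c0 <- round(rows$x[[j]])  # 0-based
      rr <- max(0, r0 - half):min(H - 1, r0 + half)
      cc <- max(0, c0 - half):min(W - 1, c0 + half)
      blob <- exp(-(outer((rr - r0)^2, (cc - c0)^2, `+`)) /
                    (2 * blob_sigma^2))
      img[rr + 1, cc + 1] <- pmax(img[rr + 1, cc + 1], blob)
    }
    fp <- file.path(out_dir, sprintf("frame_%04d.tif", ii))
    tiff::writeTIFF(img, fp, bits.per.sample = 32L)
    paths[[i]] <- fp
  }
  ds$images$image_path <- paths
  ds
}

#' Write a simulated fixture to disk (tables + ground-truth sidecar)
#'
#' Runs [simulate_tracking()], writes the dataset via [write_dataset()],
#' and stores the ground truth as `<path>.ground_truth.json`.
#'
#' @param path SQLite file or CSV prefix.
#' @param dialect `"csv"` or `"sqlite"`.
#' @param ... passed to [simulate_tracking()].
#' @return (invisibly) list with `dataset`, `truth`, `path`.
#' @export
write_fixture <- function(path, dialect = c("csv", "sqlite"), ...) {
  dialect <- match.arg(dialect)
  sim <- simulate_tracking(...)
  write_dataset(sim$dataset, path, dialect)
  gt <- sim$truth
  write_json_stable(list(
    schema = "trackqc-ground-truth", version = "1.0",
    injected_loops = list(split = gt$injected_loops$split,
                          merge = gt$injected_loops$merge),
    injected_crossings = list(merge = gt$injected_crossings$merge,
                              split = gt$injected_crossings$split),
    injected_singletons = gt$injected_singletons,
    division_events = gt$division_events),
    paste0(path, ".ground_truth.json"))
  invisible(list(dataset = sim$dataset, truth = gt, path = path))
}
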