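# Renderers for the four validated views: lineage tree, XYT plot,
# synchrogram, heatmap. Every renderer writes a machine-readable manifest
# sidecar (<out>.manifest.json) with glyph/segment/patch counts and color
# ranges, so correctness checks never parse pixels. Manifests are
# deterministic for identical inputs.

# When a node belongs to several deviation types, one style must win.
FLAG_PRECEDENCE <- c("crossing", "loop", "singleton")
FLAG_COLORS <- c(crossing = "#d62728", loop = "#9467bd",
                 singleton = "#ff7f0e", none = NA)

#' Compute the lineage-tree layout
#'
#' x = timepoint. Within a component, leaves (out-degree 0) get
#' consecutive integer rows in depth-first order from the roots (children
#' visited in object-index order); every internal node sits at the mean
#' row of its children. Components are stacked vertically with at least a
#' one-row gap. Rare collisions (two parents of the same merge with no
#' other children) are resolved by small deterministic offsets, so no two
#' nodes share a position.
#'
#' @param g a `lineage_graph`.
#' @return object of class `lineage_layout`: tibble with `node_id`, `x`,
#'   `y`, `component_id`; attribute `component_offsets`.
#' @export
layout_lineage <- function(g) {
  comps <- graph_components(g)
  d <- degree_vectors(g)
  adj <- adjacency_lists(g)
  tp <- node_tp(g)
  oi <- stats::setNames(g$nodes$object_index, g$nodes$node_id)
  ii <- stats::setNames(g$nodes$image_index, g$nodes$node_id)

  y <- stats::setNames(rep(NA_real_, nrow(g$nodes)), g$nodes$node_id)
  comp_of <- stats::setNames(rep(NA_integer_, nrow(g$nodes)), g$nodes$node_id)
  offsets <- stats::setNames(numeric(nrow(comps)), comps$component_id)
  offset <- 0

  for (i in seq_len(nrow(comps))) {
    ids <- comps$nodes[[i]]
    comp_of[ids] <- comps$component_id[[i]]
    roots <- comps$root_nodes[[i]]
    roots <- roots[order(tp[roots], ii[roots], oi[roots])]

    # depth-first leaf ordering; children by object_index
    visited <- character(0)
    leaf_row <- 0
    stack <- rev(roots)
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (u %in% visited) next
      visited <- c(visited, u)
      kids <- adj$children[[u]]
      if (length(kids) == 0) {
        y[[u]] <- offset + leaf_row
        leaf_row <- leaf_row + 1
      } else {
        kids <- kids[order(oi[kids], ii[kids])]
        stack <- c(stack, rev(kids))
      }
    }
    # internal rows: children are always later in time, so a single sweep
    # by decreasing timepoint suffices
    internal <- ids[order(-tp[ids])]
    for (u in internal) {
      if (!is.na(y[[u]])) next
      y[[u]] <- mean(y[adj$children[[u]]])
    }
    offsets[[as.character(comps$component_id[[i]])]] <- offset
    offset <- offset + max(1, leaf_row) + 1
  }

  out <- tibble::tibble(node_id = g$nodes$node_id,
                        x = as.numeric(tp[g$nodes$node_id]),
                        y = unname(y[g$nodes$node_id]),
                        component_id = unname(comp_of[g$nodes$node_id]))

  # enforce injectivity: deterministic nudges for coincident nodes
  delta <- 0.3
  repeat {
    key <- paste(out$x, out$y)
    dup <- key %in% key[duplicated(key)]
    if (!any(dup)) break
    out <- out %>%
      dplyr::group_by(.data$x, .data$y) %>%
      dplyr::mutate(y = .data$y + (dplyr::row_number() - 1) * delta) %>%
      dplyr::ungroup()
    delta <- delta / 2
  }

  structure(out, class = c("lineage_layout", class(out)),
            component_offsets = offsets)
}

# flag type per node (highest-precedence deviation it belongs to)
node_flag_types <- function(node_ids, flags) {
  type <- rep("none", length(node_ids))
  if (is.null(flags)) return(type)
  for (ft in rev(FLAG_PRECEDENCE)) {
    type[node_ids %in% flags$flag_type[[ft]]] <- ft
  }
  type
}

#' Lineage tree as a ggplot
#'
#' @param g a `lineage_graph`.
#' @param layout from [layout_lineage()] (computed if omitted).
#' @param colormap optional [feature_colormap()] for node fill.
#' @param flags optional [qc_report()]; flagged nodes are over-colored by
#'   deviation type (crossing over loop over singleton).
#' @return a ggplot object.
#' @export
plot_lineage <- function(g, layout = layout_lineage(g), colormap = NULL,
                         flags = NULL) {
  nodes <- tibble::as_tibble(layout)
  nodes$flag <- node_flag_types(nodes$node_id, flags)
  nodes$value <- if (!is.null(colormap)) {
    colormap$value[match(nodes$node_id, colormap$node_id)]
  } else NA_real_

  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$node_id)
  edges <- tibble::tibble(
    x = nodes$x[pos[g$edges$parent]], y = nodes$y[pos[g$edges$parent]],
    xend = nodes$x[pos[g$edges$child]], yend = nodes$y[pos[g$edges$child]],
    gap = g$edges$frame_gap > 1)

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$gap),
      color = "grey40", linewidth = 0.4) +
    ggplot2::scale_linetype_manual(
      values = c(`FALSE` = "solid", `TRUE` = "dashed"), guide = "none")
  if (!is.null(colormap)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value),
      shape = 21, size = 2, stroke = 0.2, color = "grey30") +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80",
                                    name = attr(colormap, "feature"))
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
      shape = 21, size = 2, fill = "steelblue", color = "grey30")
  }
  flagged <- nodes[nodes$flag != "none", ]
  if (nrow(flagged)) {
    p <- p + ggplot2::geom_point(
      data = flagged,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$flag),
      shape = 1, size = 3.5, stroke = 1.1) +
      ggplot2::scale_color_manual(values = FLAG_COLORS[FLAG_PRECEDENCE],
                                  name = "deviation")
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "timepoint (frames)", y = "lineage row") +
    ggplot2::theme_minimal()
}

#' Render the lineage tree to a file
#'
#' Writes the figure (PNG or SVG by extension) plus a manifest sidecar
#' with node/edge/flag counts.
#'
#' @inheritParams plot_lineage
#' @param out output file (`.png` or `.svg`).
#' @param width,height,dpi device settings.
#' @return the manifest list, invisibly.
#' @export
render_lineage <- function(g, layout = layout_lineage(g), colormap = NULL,
                           flags = NULL, out, width = 8, height = 6,
                           dpi = 150) {
  p <- plot_lineage(g, layout, colormap, flags)
  save_figure(p, out, width, height, dpi)
  ftypes <- node_flag_types(layout$node_id, flags)
  vals <- if (!is.null(colormap)) colormap$value[is.finite(colormap$value)] else NULL
  manifest <- list(
    type = "lineage", n_nodes = nrow(layout), n_edges = nrow(g$edges),
    n_flagged = sum(ftypes != "none"),
    flags = list(crossing = sum(ftypes == "crossing"),
                 loop = sum(ftypes == "loop"),
                 singleton = sum(ftypes == "singleton")),
    flag_precedence = as.list(FLAG_PRECEDENCE),
    color_feature = if (!is.null(colormap)) attr(colormap, "feature") else NULL,
    color_range = if (length(vals)) c(min(vals), max(vals)) else NULL)
  write_manifest(out, manifest)
  invisible(manifest)
}

save_figure <- function(p, out, width, height, dpi) {
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    suppressMessages(ggplot2::ggsave(out, p, width = width, height = height,
                                     dpi = dpi))
    TRUE
  }, error = function(e) {
    abort_io(sprintf("cannot write figure to %s: %s", out, conditionMessage(e)))
  })
  invisible(ok)
}

# XYT plot -------------------------------------------------------------

xyt_vertex_table <- function(g, colormap) {
  segs <- branch_free_segments(g)
  if (nrow(segs) == 0) {
    return(list(segs = segs, verts = tibble::tibble(
      segment_id = integer(), node_id = character(), x = numeric(),
      y = numeric(), t = numeric(), value = numeric())))
  }
  verts <- tibble::tibble(
    segment_id = rep(segs$segment_id, segs$n_nodes),
    node_id = unlist(segs$nodes, use.names = FALSE))
  idx <- match(verts$node_id, g$nodes$node_id)
  verts$x <- g$nodes$x[idx]
  verts$y <- g$nodes$y[idx]
  verts$t <- as.numeric(g$nodes$timepoint[idx])
  verts$value <- if (!is.null(colormap)) {
    colormap$value[match(verts$node_id, colormap$node_id)]
  } else verts$t / max(1, max(verts$t))
  list(segs = segs, verts = verts)
}

#' XYT trajectory plot as a ggplot (isometric projection)
#'
#' One polyline per branch-free trajectory segment through (x, y, t),
#' drawn in a fixed isometric projection; vertex color is the selected
#' feature (default: frame number).
#'
#' @inheritParams plot_lineage
#' @param colormap optional [feature_colormap()].
#' @return a ggplot object.
#' @export
plot_xyt <- function(g, colormap = NULL) {
  vt <- xyt_vertex_table(g, colormap)
  verts <- vt$verts
  rx <- max(diff(range(verts$x)), 1)
  ry <- max(diff(range(verts$y)), 1)
  t01 <- (verts$t - min(verts$t)) / max(1, diff(range(verts$t)))
  verts$px <- verts$x + 0.5 * rx * t01
  verts$py <- verts$y + 0.35 * ry * t01
  ggplot2::ggplot(verts,
                  ggplot2::aes(x = .data$px, y = .data$py,
                               group = .data$segment_id,
                               color = .data$value)) +
    ggplot2::geom_path(linewidth = 0.5) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_color_viridis_c(
      limits = c(0, 1), na.value = "grey80",
      name = if (!is.null(colormap)) attr(colormap, "feature") else "t") +
    ggplot2::labs(x = "x + t (isometric)", y = "y + t (isometric)",
                  title = "XYT trajectories") +
    ggplot2::theme_minimal()
}

#' Render the XYT plot to a file
#'
#' `.png`/`.svg` give the static isometric projection; `.html` writes a
#' standalone, dependency-free page with a drag-to-rotate 3-D canvas view
#' of the same polylines. A manifest sidecar lists segment and vertex
#' counts and the color range.
#'
#' @inheritParams render_lineage
#' @param colormap optional [feature_colormap()].
#' @return the manifest list, invisibly.
#' @export
render_xyt <- function(g, colormap = NULL, out, width = 8, height = 6,
                       dpi = 150) {
  vt <- xyt_vertex_table(g, colormap)
  if (grepl("\\.html$", out, ignore.case = TRUE)) {
    write_xyt_html(vt$verts, out)
    fmt <- "html"
  } else {
    save_figure(plot_xyt(g, colormap), out, width, height, dpi)
    fmt <- "static"
  }
  vals <- vt$verts$value[is.finite(vt$verts$value)]
  manifest <- list(
    type = "xyt", format = fmt,
    n_segments = nrow(vt$segs), n_vertices = nrow(vt$verts),
    color_feature = if (!is.null(colormap)) attr(colormap, "feature") else "timepoint",
    color_range = if (length(vals)) c(min(vals), max(vals)) else NULL)
  write_manifest(out, manifest)
  invisible(manifest)
}

write_xyt_html <- function(verts, out) {
  segs <- split(verts[c("x", "y", "t", "value")], verts$segment_id)
  payload <- jsonlite::toJSON(unname(lapply(segs, function(s)
    list(x = s$x, y = s$y, t = s$t, v = s$value))), digits = NA, na = "null")
  html <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>XYT trajectories</title></head><body>",
    "<p>Drag to rotate. One polyline per branch-free trajectory segment;",
    " color = selected feature (viridis, 0&#8211;1).</p>",
    "<canvas id=\"c\" width=\"900\" height=\"700\" style=\"border:1px solid #ccc\"></canvas>",
    "<script>",
    paste0("const SEG = ", payload, ";"),
    "const cv = document.getElementById('c'), cx = cv.getContext('2d');",
    "let ax = -1.0, az = 0.6, drag = false, px = 0, py = 0;",
    "function lims(k){let lo=1e30,hi=-1e30;for(const s of SEG)for(const u of s[k]){if(u<lo)lo=u;if(u>hi)hi=u;}return [lo,hi];}",
    "const LX=lims('x'),LY=lims('y'),LT=lims('t');",
    "function nrm(u,L){return (u-L[0])/Math.max(1e-9,L[1]-L[0])-0.5;}",
    "function proj(x,y,t){",
    " let X=nrm(x,LX),Y=nrm(y,LY),Z=nrm(t,LT);",
    " let x1=X*Math.cos(az)-Y*Math.sin(az), y1=X*Math.sin(az)+Y*Math.cos(az);",
    " let y2=y1*Math.cos(ax)-Z*Math.sin(ax), z2=y1*Math.sin(ax)+Z*Math.cos(ax);",
    " return [450+x1*380, 350+y2*280];}",
    "function vir(v){if(v==null)return '#cccccc';const s=[[68,1,84],[59,82,139],[33,145,140],[94,201,98],[253,231,37]];",
    " const q=Math.min(Math.max(v,0),1)*(s.length-1),i=Math.floor(q),f=q-i,a=s[i],b=s[Math.min(i+1,s.length-1)];",
    " return `rgb(${Math.round(a[0]+f*(b[0]-a[0]))},${Math.round(a[1]+f*(b[1]-a[1]))},${Math.round(a[2]+f*(b[2]-a[2]))})`;}",
    "function draw(){cx.clearRect(0,0,cv.width,cv.height);",
    " for(const s of SEG){for(let i=1;i<s.x.length;i++){",
    "  const p=proj(s.x[i-1],s.y[i-1],s.t[i-1]),q=proj(s.x[i],s.y[i],s.t[i]);",
    "  cx.strokeStyle=vir(s.v[i]);cx.beginPath();cx.moveTo(p[0],p[1]);cx.lineTo(q[0],q[1]);cx.stroke();}",
    "  if(s.x.length==1){const p=proj(s.x[0],s.y[0],s.t[0]);cx.fillStyle=vir(s.v[0]);cx.fillRect(p[0]-1,p[1]-1,3,3);}}}",
    "cv.onmousedown=e=>{drag=true;px=e.clientX;py=e.clientY;};",
    "window.onmouseup=()=>drag=false;",
    "window.onmousemove=e=>{if(!drag)return;az+=(e.clientX-px)*0.01;ax+=(e.clientY-py)*0.01;px=e.clientX;py=e.clientY;draw();};",
    "draw();",
    "</script></body></html>")
  writeLines(html, out, useBytes = TRUE)
  invisible(out)
}

# Synchrogram ----------------------------------------------------------

read_frame <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read frame: %s", path))
  low <- tolower(path)
  img <- if (grepl("\\.tiff?$", low)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", low)) {
    png::readPNG(path)
  } else {
    abort_io(sprintf("unsupported frame format: %s", path))
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

# W x H window of `img` centered at 0-based (row0, col0), zero-padded.
crop_patch <- function(img, row0, col0, W, H) {
  hw <- (W - 1) / 2; hh <- (H - 1) / 2
  patch <- matrix(0, nrow = H, ncol = W)
  r_src <- (row0 - hh):(row0 + hh) + 1  # to 1-based
  c_src <- (col0 - hw):(col0 + hw) + 1
  rok <- r_src >= 1 & r_src <= nrow(img)
  cok <- c_src >= 1 & c_src <= ncol(img)
  if (any(rok) && any(cok)) {
    patch[which(rok), which(cok)] <- img[r_src[rok], c_src[cok]]
  }
  patch
}

#' Extract a synchrogram for one trajectory
#'
#' A synchrogram is the sequence of fixed-size image patches of one cell
#' over time, each patch centered on the cell's centroid so that motion is
#' removed as a visual degree of freedom — tracking mistakes then show up
#' as a sudden change of the centered object. Centroids are rounded to the
#' nearest pixel (ties to even); windows falling outside the frame are
#' zero-padded. Timepoints the trajectory skips (gap closing) produce
#' blank placeholder patches, listed in `missing_frames`.
#'
#' @param ds the `tracking_dataset` the trajectory belongs to.
#' @param frames `NULL` to read files from the image table's `image_path`
#'   column (TIFF or PNG), or a function `(image_index) -> numeric matrix`.
#' @param traj node ids of the trajectory (a character vector, or one row
#'   of [branch_free_segments()]).
#' @param patch `c(W, H)` patch size in pixels; both odd.
#' @return object of class `synchrogram`: list with `node_sequence`,
#'   `patches` (list of H x W matrices in \[0,1\]), `frame_labels`
#'   (timepoints, including gaps), `missing_frames`, `patch_size`.
#' @export
extract_synchrogram <- function(ds, frames = NULL, traj, patch = c(61, 61)) {
  if (is.data.frame(traj)) traj <- traj$nodes[[1]]
  traj <- as.character(unlist(traj, use.names = FALSE))
  W <- patch[[1]]; H <- patch[[2]]
  if (W < 1 || H < 1 || W %% 2 == 0 || H %% 2 == 0) {
    abort_param("patch width and height must be odd positive integers")
  }

  info <- split_node_id(traj) %>%
    dplyr::left_join(ds$objects[c("image_index", "object_index", "x", "y")],
                     by = c("image_index", "object_index")) %>%
    dplyr::left_join(ds$images[c("image_index", "timepoint",
                                 intersect("image_path", names(ds$images)))],
                     by = "image_index") %>%
    dplyr::arrange(.data$timepoint)

  get_frame <- if (is.function(frames)) {
    frames
  } else {
    if (!"image_path" %in% names(ds$images)) {
      abort_io("image table has no image_path column and no frame provider given")
    }
    function(image_index) {
      read_frame(ds$images$image_path[ds$images$image_index == image_index][[1]])
    }
  }

  all_t <- seq(min(info$timepoint), max(info$timepoint))
  patches <- vector("list", length(all_t))
  missing <- integer(0)
  for (k in seq_along(all_t)) {
    t <- all_t[[k]]
    i <- which(info$timepoint == t)
    if (length(i) == 0) {
      patches[[k]] <- matrix(0, nrow = H, ncol = W)
      missing <- c(missing, t)
    } else {
      img <- get_frame(info$image_index[[i[[1]]]])
      patches[[k]] <- crop_patch(img, round(info$y[[i[[1]]]]),
                                 round(info$x[[i[[1]]]]), W, H)
    }
  }

  structure(list(node_sequence = traj, patches = patches,
                 frame_labels = all_t, missing_frames = missing,
                 patch_size = c(W, H)),
            class = "synchrogram")
}

#' @export
print.synchrogram <- function(x, ...) {
  cat(sprintf("<synchrogram> %d patches (%dx%d px), %d gap placeholder(s)\n",
              length(x$patches), x$patch_size[[1]], x$patch_size[[2]],
              length(x$missing_frames)))
  invisible(x)
}

#' Render a synchrogram montage
#'
#' Patches side by side in time order; gap placeholders get a grey frame
#' so a blank is visibly "missing", not "dark cell".
#'
#' @param sg a [extract_synchrogram()] result.
#' @param out output PNG file.
#' @return the manifest list, invisibly.
#' @export
render_synchrogram <- function(sg, out) {
  W <- sg$patch_size[[1]]; H <- sg$patch_size[[2]]
  n <- length(sg$patches)
  montage <- matrix(0, nrow = H, ncol = n * W)
  for (k in seq_len(n)) {
    p <- pmin(pmax(sg$patches[[k]], 0), 1)
    if (sg$frame_labels[[k]] %in% sg$missing_frames) {
      p[c(1, H), ] <- 0.5
      p[, c(1, W)] <- 0.5
    }
    montage[, ((k - 1) * W + 1):(k * W)] <- p
  }
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(montage, out)
  manifest <- list(type = "synchrogram", n_patches = n,
                   n_missing = length(sg$missing_frames),
                   patch_width = W, patch_height = H,
                   frame_labels = sg$frame_labels)
  write_manifest(out, manifest)
  invisible(manifest)
}

# Heatmap --------------------------------------------------------------

#' Per-timepoint feature heatmap as a ggplot
#'
#' @param m a normalized [timepoint_feature_matrix()].
#' @return a ggplot object (timepoints on x, features on y in matrix
#'   order; missing cells grey).
#' @export
plot_heatmap <- function(m) {
  if (!is_normalized(m)) abort_param("heatmap matrix must be normalized first")
  feats <- heatmap_features(m)
  long <- tibble::as_tibble(m) %>%
    tidyr::pivot_longer(dplyr::all_of(feats), names_to = "feature",
                        values_to = "value") %>%
    dplyr::mutate(feature = factor(.data$feature, levels = rev(feats)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$feature,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey70",
                                  name = "normalized\nmean") +
    ggplot2::labs(x = "timepoint (frames)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_heatmap
#' @param object a `heatmap_matrix`.
#' @param ... unused.
#' @export
autoplot.heatmap_matrix <- function(object, ...) plot_heatmap(object)

#' Render the per-timepoint feature heatmap to a file
#'
#' @param m a normalized `heatmap_matrix`.
#' @param out output file (`.png` or `.svg`).
#' @param width,height,dpi device settings.
#' @return the manifest list, invisibly.
#' @export
render_heatmap <- function(m, out, width = 8, height = 5, dpi = 150) {
  p <- plot_heatmap(m)
  save_figure(p, out, width, height, dpi)
  feats <- heatmap_features(m)
  vals <- unlist(tibble::as_tibble(m)[feats], use.names = FALSE)
  manifest <- list(
    type = "heatmap", n_timepoints = nrow(m), n_features = length(feats),
    n_missing_cells = sum(!is.finite(vals)), normalized = is_normalized(m),
    value_range = if (any(is.finite(vals)))
      c(min(vals[is.finite(vals)]), max(vals[is.finite(vals)])) else NULL)
  write_manifest(out, manifest)
  invisible(manifest)
}
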