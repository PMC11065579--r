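# Fiber-network architecture: segmentation -> skeleton -> graph -> the six
# descriptors (covered area ratio, mean fiber diameter, node density, mean
# pore size, porosity, orientation index).

#' Segment fibers in a micrograph
#'
#' Processing cascade for SEM-like fibrous images: intensity normalization,
#' 3x3 median equalization, locally adaptive Otsu thresholding on tiles with
#' bilinear threshold interpolation (global Otsu for images smaller than one
#' tile), one morphological closing with a 3-px disc, and removal of
#' connected specks below `min_object_px`.
#'
#' Fibers are assumed bright on a dark background; set `invert = TRUE` for
#' the opposite polarity.  Descriptors downstream are invariant to affine
#' intensity transforms because the image is min-max normalized first.
#'
#' @param img A [micrograph()] or numeric matrix.
#' @param pixel_size_um Pixel size, um/px (taken from `img` if attached).
#' @param median_window Odd median-filter window (default 3).
#' @param otsu_tile_px Tile edge for local Otsu (default 64).
#' @param min_object_px Minimum connected-object area kept, px.
#' @param invert Set when fibers are dark on bright.
#' @param halfmax_refine After thresholding, keep only pixels above the
#'   midpoint between the local background and the local intensity peak, so
#'   the mask approximates each fiber's full-width-at-half-maximum support
#'   (the width the diameter descriptor is defined on).
#' @param peak_radius_px Radius of the running-maximum window used to
#'   estimate the local profile peak.
#' @return Logical fiber mask with the pixel size attached.  A constant
#'   image yields an all-background mask with a warning.
#' @export
segment_fibers <- function(img, pixel_size_um = NULL, median_window = 3L,
                           otsu_tile_px = 64L, min_object_px = 16L,
                           invert = FALSE, halfmax_refine = TRUE,
                           peak_radius_px = 15L) {
  ps <- attr(img, "pixel_size_um") %||% pixel_size_um
  x <- unclass(img)
  if (!is.matrix(x) || !is.numeric(x))
    stop_ecm("`img` must be a numeric matrix or micrograph.", "invalid_input")
  if (median_window %% 2 != 1 || median_window < 1)
    stop_ecm("`median_window` must be a positive odd integer.",
             "invalid_parameter")
  rng <- range(x)
  if (diff(rng) == 0) {
    warn("Constant image: returning an empty fiber mask.")
    return(structure(matrix(FALSE, nrow(x), ncol(x)), pixel_size_um = ps))
  }
  x <- (x - rng[1]) / (rng[2] - rng[1])
  if (invert) x <- 1 - x
  if (median_window == 3L) {
    x <- median3x3(x)
  } else if (median_window > 1) {
    x <- EBImage::medianFilter(x, size = (median_window - 1) / 2)
  }
  thr <- local_otsu_surface(x, otsu_tile_px)
  mask <- x > thr
  mask <- EBImage::closing(mask, EBImage::makeBrush(3, "disc")) > 0
  if (min_object_px > 0 && any(mask)) {
    lab <- cpp_label8(mask)
    sizes <- tabulate(lab[lab > 0], attr(lab, "n_labels"))
    keep <- sizes >= min_object_px
    mask[lab > 0] <- keep[lab[lab > 0]]
  }
  # refine to the half-maximum support that defines fiber diameter: keep
  # only pixels above the midpoint between local background and the local
  # profile peak (grey-scale dilation, corrected for the noise-maximum
  # bias of the running maximum).  Removal-only, so background stays clean.
  if (halfmax_refine && any(mask) && any(!mask)) {
    bg <- median(x[!mask])
    s_bg <- stats::mad(x[!mask])
    localpeak <- EBImage::dilate(
      x, EBImage::makeBrush(2L * peak_radius_px + 1L, "disc")) - 2.5 * s_bg
    mask <- mask & (x > bg + 0.5 * (pmax(localpeak, bg) - bg))
    mask <- EBImage::closing(mask, EBImage::makeBrush(3, "disc")) > 0
  }
  structure(mask, pixel_size_um = ps)
}

# Vectorized 3x3 median by a 19-exchange sorting network (Paeth), with
# replicated borders; much faster than a generic rank filter.
median3x3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  p <- vector("list", 9)
  k <- 1L
  for (dj in 0:2) for (di in 0:2) {
    p[[k]] <- xp[di + seq_len(nr), dj + seq_len(nc)]
    k <- k + 1L
  }
  sort2 <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    p[[j]] <<- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
  }
  sort2(2, 3); sort2(5, 6); sort2(8, 9)
  sort2(1, 2); sort2(4, 5); sort2(7, 8)
  sort2(2, 3); sort2(5, 6); sort2(8, 9)
  sort2(1, 4); sort2(6, 9); sort2(5, 8)
  sort2(4, 7); sort2(2, 5); sort2(3, 6)
  sort2(5, 8); sort2(5, 3); sort2(7, 5)
  sort2(5, 3)
  p[[5]]
}

# Per-tile Otsu thresholds bilinearly interpolated to a full-image surface.
local_otsu_surface <- function(x, tile_px) {
  nr <- nrow(x); nc <- ncol(x)
  global <- EBImage::otsu(x, range = c(0, 1))
  if (min(nr, nc) < tile_px) return(matrix(global, nr, nc))
  n_tr <- max(1L, floor(nr / tile_px))
  n_tc <- max(1L, floor(nc / tile_px))
  rb <- floor(seq(0, nr, length.out = n_tr + 1L))
  cb <- floor(seq(0, nc, length.out = n_tc + 1L))
  th <- matrix(NA_real_, n_tr, n_tc)
  for (i in seq_len(n_tr)) for (j in seq_len(n_tc)) {
    tl <- x[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
    if (diff(range(tl)) < 1e-8) next  # flat tile: fall back to global
    # a tile may only lower the threshold if it plausibly contains
    # foreground; otherwise local Otsu would split pure background noise
    if (stats::quantile(tl, 0.99) <= global) next
    th[i, j] <- EBImage::otsu(tl, range = c(0, 1))
  }
  th[is.na(th)] <- global
  rc <- (rb[-1] + rb[-length(rb)]) / 2
  cc <- (cb[-1] + cb[-length(cb)]) / 2
  interp_rows <- function(v, at) {
    if (length(v) == 1L) return(rep(v, length(at)))
    stats::approx(rc, v, xout = at, rule = 2)$y
  }
  half <- apply(th, 2, interp_rows, at = seq_len(nr) - 0.5)
  half <- matrix(half, nrow = nr)
  out <- t(apply(half, 1, function(v) {
    if (length(v) == 1L) return(rep(v, nc))
    stats::approx(cc, v, xout = seq_len(nc) - 0.5, rule = 2)$y
  }))
  matrix(out, nr, nc)
}

#' Extract the fiber network graph from a binary mask
#'
#' Thins the mask to a one-pixel medial axis (Zhang-Suen), prunes terminal
#' spurs shorter than `spur_prune_px`, merges junction-pixel clusters within
#' `node_merge_px` into nodes, and traces the skeleton branches between
#' nodes / free ends into segments.  Per-segment diameter is twice the mean
#' Euclidean distance transform of the mask along the segment (with a -1 px
#' quantization correction), and per-segment orientation is the principal
#' direction of its pixel chain.
#'
#' @param mask Binary fiber mask (from [segment_fibers()] or a generator
#'   truth mask).
#' @param pixel_size_um Pixel size, um/px.
#' @param spur_prune_px Terminal branches shorter than this are removed.
#' @param node_merge_px Junction pixels closer than this merge into one node.
#' @param prune Optional segment-table refinement, off by default: on a
#'   skeleton-traced graph the long branches are real fibers, and dropping
#'   them destroys junction incidence (see the methods vignette).
#'   `"length"` drops segments longer than `max_length_factor` times the
#'   median branch length; `"delaunay"` additionally requires segment end
#'   nodes to be empty-diametral-circle (Gabriel) neighbours of the node
#'   set, a conservative subset of Delaunay adjacency.
#' @param max_length_factor Multiplier for the length rule.
#' @param diameter_stat Per-segment summary of the sampled distance
#'   transform: the median (default) is robust to inflation where a segment
#'   passes junction zones; `"mean"` is the plain average.
#' @return A `fiber_network` object: tibbles `nodes` (centroid positions)
#'   and `segments` (pixel count, length, mean diameter, orientation), the
#'   `skeleton` and `mask` matrices, and `pixel_size_um`.
#' @export
skeletonize_network <- function(mask, pixel_size_um = NULL,
                                spur_prune_px = 2, node_merge_px = 3,
                                prune = c("none", "length", "delaunay"),
                                max_length_factor = 3,
                                diameter_stat = c("median", "mean")) {
  prune <- match.arg(prune)
  diameter_stat <- match.arg(diameter_stat)
  ps <- pixel_size_of(mask, pixel_size_um)
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  empty <- function() {
    structure(list(
      nodes = tibble(node = integer(0), row = numeric(0), col = numeric(0),
                     n_px = integer(0), n_branches = integer(0),
                     junction = logical(0)),
      segments = tibble(segment = integer(0), n_px = integer(0),
                        length_px = numeric(0), length_um = numeric(0),
                        mean_diameter_px = numeric(0),
                        mean_diameter_um = numeric(0),
                        orientation_deg = numeric(0),
                        node_a = integer(0), node_b = integer(0)),
      skeleton = matrix(FALSE, nr, nc), mask = mask, pixel_size_um = ps),
      class = "fiber_network")
  }
  if (!any(mask)) return(empty())

  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  sk <- cpp_thin(pad)[2:(nr + 1L), 2:(nc + 1L)]
  if (!any(sk)) return(empty())

  parts <- trace_parts(sk, node_merge_px)
  segs <- parts$segments
  # spur removal is bookkeeping, not skeleton surgery: short terminal
  # branches are dropped from the segment table (and from junction branch
  # counts) while the skeleton keeps its topology.  Erasing spur pixels and
  # re-thinning can cascade into eating junction cores.
  if (spur_prune_px > 0 && nrow(segs) > 0) {
    spur <- segs$terminal & segs$length_px < spur_prune_px &
      # keep short isolated strokes (no junction involved)
      !(is.na(segs$node_a) & is.na(segs$node_b) & segs$length_px >= 2)
    segs <- segs[!spur, , drop = FALSE]
  }
  if (nrow(segs) == 0 && nrow(parts$nodes) == 0) return(empty())

  # merge branch pieces across pass-through clusters (junction-pixel
  # clusters with exactly two incident branches are thinning artefacts on a
  # single fiber, not intersections), so a straight fiber stays one segment
  merged <- merge_passthrough(segs, parts, nrow(parts$nodes))
  segs <- merged$segments
  seg_lab <- merged$seg_lab

  edt <- as.numeric(EBImage::distmap(mask))
  dim(edt) <- dim(mask)
  diam_stat <- if (diameter_stat == "median") median else mean
  segs$mean_diameter_px <- vapply(segs$segment, function(s) {
    idx <- which(seg_lab == s)
    max(1, 2 * diam_stat(edt[idx]) - 1)
  }, numeric(1))
  segs$mean_diameter_um <- segs$mean_diameter_px * ps
  segs$length_um <- segs$length_px * ps

  nodes <- parts$nodes

  keep <- rep(TRUE, nrow(segs))
  real <- segs$length_px >= spur_prune_px
  if (prune != "none" && sum(real) > 2) {
    med <- median(segs$length_px[real])
    keep <- segs$length_px <= max_length_factor * med
    if (prune == "delaunay" && nrow(nodes) >= 3) {
      keep <- keep & gabriel_ok(segs, nodes)
    }
  }
  segs <- segs[keep, , drop = FALSE]
  segs$segment <- seq_len(nrow(segs))

  # a cluster of junction pixels is a true network intersection only if at
  # least 3 branches are incident; 2-branch clusters are pass-through
  # thinning artefacts (staircase duplicates) along a single fiber
  ends <- c(segs$node_a, segs$node_b)
  ends <- ends[!is.na(ends)]
  nodes$n_branches <- tabulate(ends, nbins = max(nrow(nodes), 1L))[
    seq_len(nrow(nodes))]
  nodes$junction <- nodes$n_branches >= 3L

  structure(list(
    nodes = nodes,
    segments = segs[, c("segment", "n_px", "length_px", "length_um",
                        "mean_diameter_px", "mean_diameter_um",
                        "orientation_deg", "node_a", "node_b")],
    skeleton = sk, mask = mask, pixel_size_um = ps),
    class = "fiber_network")
}

# Merge branch pieces separated only by pass-through clusters (exactly two
# incident branches) back into whole segments, repainting a merged label
# image so lengths/orientations/diameters are computed on whole fibers.
merge_passthrough <- function(segs, parts, n_nodes) {
  seg_lab <- parts$seg_lab
  nr <- nrow(seg_lab); nc <- ncol(seg_lab)
  if (nrow(segs) == 0)
    return(list(segments = segs[, c("segment", "n_px", "length_px",
                                    "orientation_deg", "node_a", "node_b",
                                    "terminal")],
                seg_lab = seg_lab))
  n_row <- nrow(segs)
  ends <- data.frame(row = rep(seq_len(n_row), 2L),
                     node = c(segs$node_a, segs$node_b))
  ends <- ends[!is.na(ends$node), , drop = FALSE]
  inc <- split(ends$row, ends$node)
  parent <- seq_len(n_row)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pass <- integer(0)
  for (nm in names(inc)) {
    rows <- inc[[nm]]
    if (length(rows) == 2L && rows[1] != rows[2]) {
      ra <- find_root(rows[1]); rb <- find_root(rows[2])
      if (ra != rb) parent[rb] <- ra
      pass <- c(pass, as.integer(nm))
    }
  }
  root <- vapply(seq_len(n_row), find_root, integer(1))
  gid <- match(root, unique(root))
  n_new <- max(gid)
  # repaint labels: member segments plus absorbed pass-through clusters
  smap <- integer(max(segs$segment))
  smap[segs$segment] <- gid
  new_lab <- matrix(c(0L, smap)[seg_lab + 1L], nr, nc)
  if (length(pass) > 0) {
    cmap <- integer(n_nodes)
    for (nm in pass) cmap[nm] <- gid[inc[[as.character(nm)]][1]]
    node_add <- matrix(c(0L, cmap)[parts$node_lab + 1L], nr, nc)
    new_lab <- new_lab + node_add
  }
  lens <- cpp_path_lengths(new_lab, n_new)
  idx <- which(new_lab > 0)
  lab_v <- new_lab[idx]
  n_px <- tabulate(lab_v, n_new)
  ord <- order(lab_v)
  rows_v <- ((idx - 1L) %% nr)[ord]
  cols_v <- ((idx - 1L) %/% nr)[ord]
  bounds <- c(0L, cumsum(n_px))
  orient <- numeric(n_new)
  for (g in seq_len(n_new)) {
    ii <- (bounds[g] + 1L):bounds[g + 1L]
    orient[g] <- chain_orientation(cols_v[ii], rows_v[ii])
  }
  # surviving end clusters per merged segment (pass clusters are interior)
  node_a <- rep(NA_integer_, n_new)
  node_b <- rep(NA_integer_, n_new)
  for (i in seq_len(n_row)) {
    g <- gid[i]
    for (e in c(segs$node_a[i], segs$node_b[i])) {
      if (is.na(e) || e %in% pass) next
      if (is.na(node_a[g])) node_a[g] <- e
      else if (node_a[g] != e && is.na(node_b[g])) node_b[g] <- e
    }
  }
  list(segments = tibble(
    segment = seq_len(n_new), n_px = n_px,
    length_px = pmax(lens, n_px - 1, 0),
    orientation_deg = orient, node_a = node_a, node_b = node_b,
    terminal = is.na(node_a) | is.na(node_b)),
    seg_lab = new_lab)
}

# Core tracer: skeleton -> junction clusters (nodes) + branch components
# (segments) with per-segment path length, orientation, terminal flag.
trace_parts <- function(sk, node_merge_px = 3) {
  nr <- nrow(sk); nc <- ncol(sk)
  deg <- neighbor_count(sk)
  node_px <- sk & deg >= 3
  # junction clusters closer than node_merge_px become one node: label the
  # dilated junction mask, then read labels back on the junction pixels
  dil_lab <- if (any(node_px)) {
    brush <- EBImage::makeBrush(max(1L, node_merge_px %/% 2L * 2L + 1L),
                                "disc")
    cpp_label8(EBImage::dilate(node_px, brush) > 0)
  } else {
    cpp_label8(node_px)
  }
  node_lab <- dil_lab
  node_lab[!node_px] <- 0L
  attr(node_lab, "n_labels") <- attr(dil_lab, "n_labels")
  n_nodes <- attr(node_lab, "n_labels")
  # merge junction clusters separated by < node_merge_px: dilate then label
  nodes <- if (n_nodes > 0) {
    idx <- which(node_px)
    tibble(cluster = node_lab[idx],
           row = (idx - 1) %% nr, col = (idx - 1) %/% nr) |>
      dplyr::summarise(row = mean(.data$row), col = mean(.data$col),
                       n_px = dplyr::n(), .by = "cluster") |>
      dplyr::arrange(.data$cluster) |>
      dplyr::transmute(node = dplyr::row_number(), row = .data$row,
                       col = .data$col, n_px = .data$n_px)
  } else {
    tibble(node = integer(0), row = numeric(0), col = numeric(0),
           n_px = integer(0))
  }
  seg_lab <- cpp_label8(sk & !node_px)
  n_seg <- attr(seg_lab, "n_labels")
  if (n_seg == 0) {
    return(list(nodes = nodes, seg_lab = seg_lab, node_lab = node_lab,
                segments = tibble(segment = integer(0), n_px = integer(0),
                                  length_px = numeric(0),
                                  orientation_deg = numeric(0),
                                  node_a = integer(0), node_b = integer(0),
                                  terminal = logical(0))))
  }
  lens <- cpp_path_lengths(seg_lab, n_seg)
  idx <- which(seg_lab > 0)
  lab_v <- seg_lab[idx]
  rows <- (idx - 1) %% nr
  cols <- (idx - 1) %/% nr
  ord <- order(lab_v)
  lab_v <- lab_v[ord]; rows <- rows[ord]; cols <- cols[ord]
  bounds <- c(0, cumsum(tabulate(lab_v, n_seg)))
  orient <- numeric(n_seg)
  npx <- integer(n_seg)
  for (s in seq_len(n_seg)) {
    ii <- (bounds[s] + 1):bounds[s + 1]
    npx[s] <- length(ii)
    orient[s] <- chain_orientation(cols[ii], rows[ii])
  }
  # attach segments to node clusters via dilated adjacency
  node_adj <- segment_node_links(seg_lab, node_lab, n_seg)
  # map raw junction-cluster ids to merged node ids (1:1 here)
  segments <- tibble(
    segment = seq_len(n_seg), n_px = npx,
    length_px = pmax(lens, npx - 1, 0) + 0,
    orientation_deg = orient,
    node_a = node_adj$a, node_b = node_adj$b,
    terminal = is.na(node_adj$a) | is.na(node_adj$b))
  list(nodes = nodes, seg_lab = seg_lab, node_lab = node_lab,
       segments = segments)
}

neighbor_count <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- sk
  acc <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    acc <- acc + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  acc
}

# Principal axial direction (degrees in [0, 180)) of a pixel chain,
# x = columns, y = rows growing downward (converted to math convention).
chain_orientation <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  xm <- x - mean(x); ym <- -(y - mean(y))
  mu20 <- mean(xm^2); mu02 <- mean(ym^2); mu11 <- mean(xm * ym)
  (atan2(2 * mu11, mu20 - mu02) / 2 * 180 / pi) %% 180
}

# For each segment, the (up to two) junction clusters its end pixels touch.
segment_node_links <- function(seg_lab, node_lab, n_seg) {
  nr <- nrow(seg_lab); nc <- ncol(seg_lab)
  a <- rep(NA_integer_, n_seg); b <- rep(NA_integer_, n_seg)
  if (attr(node_lab, "n_labels") == 0)
    return(list(a = a, b = b))
  idx <- which(seg_lab > 0)
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  for (d in seq_len(8)) {
    di <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)[d]
    dj <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)[d]
    rr <- ri + di; cc <- ci + dj
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nl <- integer(length(idx))
    nl[ok] <- node_lab[cbind(rr[ok], cc[ok])]
    hit <- which(nl > 0L)
    for (h in hit) {
      s <- seg_lab[idx[h]]
      if (is.na(a[s])) a[s] <- nl[h]
      else if (a[s] != nl[h] && is.na(b[s])) b[s] <- nl[h]
    }
  }
  list(a = a, b = b)
}

# Gabriel-graph adjacency test: end nodes of a segment must have an empty
# circle on their connecting diameter (conservative Delaunay subset).
gabriel_ok <- function(segs, nodes) {
  ok <- rep(TRUE, nrow(segs))
  for (k in seq_len(nrow(segs))) {
    na <- segs$node_a[k]; nb <- segs$node_b[k]
    if (is.na(na) || is.na(nb)) next  # free-end segments are kept
    mx <- (nodes$col[na] + nodes$col[nb]) / 2
    my <- (nodes$row[na] + nodes$row[nb]) / 2
    r2 <- ((nodes$col[na] - nodes$col[nb])^2 +
             (nodes$row[na] - nodes$row[nb])^2) / 4
    others <- setdiff(seq_len(nrow(nodes)), c(na, nb))
    if (length(others) == 0) next
    d2 <- (nodes$col[others] - mx)^2 + (nodes$row[others] - my)^2
    ok[k] <- all(d2 >= r2 * (1 - 1e-9))
  }
  ok
}

#' Estimate the number of fiber intersections in a network
#'
#' Thinning does not map crossings to junction pixels one-to-one: an X
#' crossing of thick fibers splits into two Y-junctions joined by a short
#' bridge, a shallow crossing stretches into a long band, and several
#' fibers meeting in a dense blob merge into one multi-arm cluster.  This
#' estimator therefore counts crossings from junction-complex arithmetic:
#'
#' * junction clusters (>= 3 incident branches) joined by bridges shorter
#'   than `bridge_factor` times the local fiber diameter (capped at
#'   `bridge_max_px`) are grouped into complexes;
#' * a single cluster with `A` external arms traversed by `A/2` fibers
#'   contributes `choose(A/2, 2)` crossings (1 for an X, 3 for a compact
#'   3-fiber blob), a lone 3-arm cluster contributes 1/2 (one half of a
#'   stretched crossing, or a fiber end meeting another fiber);
#' * an extended multi-cluster complex contributes `(A - 2) / 2` with a
#'   floor of the per-cluster sum, which counts a bridged Y-Y pair once
#'   and a chain of crossings once per crossing.
#'
#' @param net A `fiber_network`.
#' @param bridge_factor,bridge_max_px Bridge-length rule (px).
#' @return Estimated crossing count (non-negative, may be half-integral).
#' @export
estimate_intersections <- function(net, bridge_factor = 2.5,
                                   bridge_max_px = 15) {
  nd <- net$nodes
  sg <- net$segments
  if (nrow(nd) == 0 || nrow(sg) == 0) return(0)
  isj <- nd$n_branches >= 3L
  if (!any(isj)) return(0)
  parent <- seq_len(nrow(nd))
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  bridge <- !is.na(sg$node_a) & !is.na(sg$node_b) &
    sg$node_a != sg$node_b &
    isj[pmax(sg$node_a, 1L)] & isj[pmax(sg$node_b, 1L)] &
    sg$length_px < pmin(bridge_factor * sg$mean_diameter_px, bridge_max_px)
  for (k in which(bridge)) {
    ra <- find_root(sg$node_a[k]); rb <- find_root(sg$node_b[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nrow(nd)), find_root, integer(1))
  arms <- rep(0, nrow(nd))       # external arms per complex root
  arms_all <- rep(0, nrow(nd))   # incident segments per cluster (w/ bridges)
  for (k in seq_len(nrow(sg))) {
    for (e in c(sg$node_a[k], sg$node_b[k])) {
      if (is.na(e) || !isj[e]) next
      arms_all[e] <- arms_all[e] + 1
      if (!bridge[k]) arms[roots[e]] <- arms[roots[e]] + 1
    }
  }
  total <- 0
  for (cc in unique(roots[isj])) {
    mem <- which(isj & roots == cc)
    A <- arms[cc]
    est <- if (length(mem) == 1L) {
      if (A < 3) 0 else if (A == 3) 0.5 else (A / 2) * (A / 2 - 1) / 2
    } else {
      max((A - 2) / 2, sum(pmax(arms_all[mem] - 2, 0)) / 2)
    }
    total <- total + est
  }
  total
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf("<fiber_network> %d nodes, %d segments, %d x %d px @ %.4g um/px\n",
              nrow(x$nodes), nrow(x$segments), nrow(x$mask), ncol(x$mask),
              x$pixel_size_um))
  invisible(x)
}

#' Architecture descriptors of a fiber network
#'
#' Computes the six descriptors of a fibrous scaffold image:
#' \describe{
#'   \item{covered_area_ratio}{fiber-mask pixels / total pixels.}
#'   \item{porosity}{1 - covered_area_ratio (mask complement).}
#'   \item{mean_fiber_diameter_um}{length-weighted mean of segment diameters.}
#'   \item{node_density_per_mm2}{fiber intersections per mm^2 of image.}
#'   \item{mean_pore_size_mm2}{mean area of background components not
#'     touching the image border (also reported in um^2).}
#'   \item{orientation_index_pct}{100 x the length-weighted mean resultant of
#'     doubled segment orientations about the principal direction: 0 for an
#'     isotropic network, 100 for a fully aligned one.}
#' }
#'
#' @param net A `fiber_network` from [skeletonize_network()].
#' @return One-row tibble of descriptors plus counts (`n_nodes`,
#'   `n_segments`, `n_pores`) and the principal direction.  With zero
#'   segments the diameter and orientation are `NA` and `degenerate` is set.
#' @export
compute_descriptors <- function(net) {
  if (!inherits(net, "fiber_network"))
    stop_ecm("`net` must be a fiber_network.", "invalid_input")
  ps <- net$pixel_size_um
  npx <- length(net$mask)
  car <- sum(net$mask) / npx
  area_mm2 <- npx * (ps * 1e-3)^2
  segs <- net$segments
  if (nrow(segs) > 0) {
    w <- pmax(segs$length_px, 1)
    mean_diam <- sum(w * segs$mean_diameter_um) / sum(w)
    th <- segs$orientation_deg[!is.na(segs$orientation_deg)]
    wth <- w[!is.na(segs$orientation_deg)]
    oi <- 100 * axial_resultant(th, wth)
    pdir <- axial_mean_deg(th, wth)
  } else {
    mean_diam <- NA_real_; oi <- NA_real_; pdir <- NA_real_
  }
  pores <- pore_areas_px(net$mask)
  n_junctions <- round(estimate_intersections(net))
  tibble(
    covered_area_ratio = car,
    porosity = 1 - car,
    mean_fiber_diameter_um = mean_diam,
    node_density_per_mm2 = n_junctions / area_mm2,
    mean_pore_size_mm2 = if (length(pores)) mean(pores) * (ps * 1e-3)^2
                         else NA_real_,
    mean_pore_size_um2 = if (length(pores)) mean(pores) * ps^2 else NA_real_,
    orientation_index_pct = oi,
    principal_orientation_deg = pdir,
    n_nodes = n_junctions,
    n_segments = nrow(segs),
    n_pores = length(pores),
    degenerate = nrow(segs) == 0
  )
}

# Areas (px) of background components that do not touch the image border.
pore_areas_px <- function(mask) {
  bg <- EBImage::bwlabel(!mask)  # 4-connected background, dual of 8-conn fg
  n <- max(bg)
  if (n == 0) return(numeric(0))
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0], n)
  keep <- setdiff(seq_len(n), border[border > 0])
  sizes[keep]
}

#' Full fiber-architecture analysis of one micrograph
#'
#' Convenience wrapper: [segment_fibers()] then [skeletonize_network()] then
#' [compute_descriptors()].
#'
#' @inheritParams segment_fibers
#' @param ... Passed on to [skeletonize_network()].
#' @return One-row descriptor tibble with the `fiber_network` attached as
#'   attribute `network`.
#' @export
analyze_fibers <- function(img, pixel_size_um = NULL, median_window = 3L,
                           otsu_tile_px = 64L, min_object_px = 16L,
                           invert = FALSE, halfmax_refine = TRUE,
                           peak_radius_px = 15L, ...) {
  ps <- pixel_size_of(img, pixel_size_um)
  mask <- segment_fibers(img, pixel_size_um = ps,
                         median_window = median_window,
                         otsu_tile_px = otsu_tile_px,
                         min_object_px = min_object_px, invert = invert,
                         halfmax_refine = halfmax_refine,
                         peak_radius_px = peak_radius_px)
  net <- skeletonize_network(mask, pixel_size_um = ps, ...)
  out <- compute_descriptors(net)
  attr(out, "network") <- net
  out
}
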