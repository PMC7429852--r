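#' Regular DVC node grid
#'
#' Nodes are laid out at `start + margin + k * ns` along each axis, where the
#' margin `cw + search_range` keeps every correlation window and its search
#' region inside the ROI.  With the protocol settings CW +/-10 / NS 10,
#' adjacent windows overlap by 50% of their extent.
#'
#' @param roi an [roi_spec] (in parent-volume voxel coordinates).
#' @param ns node spacing, voxels.
#' @param cw correlation-window half-width, voxels.
#' @param search_range integer search bound, voxels.
#' @param guard extra face margin in voxels beyond `cw + search_range`,
#'   keeping windows clear of boundary-affected voxels (image-filter
#'   support, interpolation support, translation fill); windows touching
#'   such voxels carry displacement estimates biased toward the interior.
#' @return An object of class `node_grid` with 0-based per-axis node
#'   coordinate vectors, the grid shape, and the overlap fraction
#'   `max(0, (2*cw - ns) / (2*cw))`.
#' @export
make_node_grid <- function(roi, ns, cw, search_range, guard = 0L) {
  stopifnot(inherits(roi, "roi_spec"), ns >= 1, cw >= 1, search_range >= 0,
            guard >= 0)
  margin <- cw + search_range + as.integer(guard)
  nodes <- lapply(1:3, function(a) {
    lo <- roi$start[a] + margin
    hi <- roi$start[a] + roi$shape[a] - 1L - margin
    if (hi < lo + ns) stop("ROI too small for >= 2 nodes per axis")
    seq.int(lo, hi, by = ns)
  })
  structure(list(nodes_z = nodes[[1]], nodes_y = nodes[[2]],
                 nodes_x = nodes[[3]],
                 shape = vapply(nodes, length, 1L),
                 ns = as.integer(ns), cw = as.integer(cw),
                 search_range = as.integer(search_range),
                 overlap = max(0, (2 * cw - ns) / (2 * cw))),
            class = "node_grid")
}

#' Integer-voxel window correlation at one node
#'
#' Exhaustive zero-normalized cross-correlation (ZNCC) search over all
#' integer displacements in `[-search_range, search_range]^3`.  Ties are
#' broken by the smallest displacement magnitude, then lexicographically.
#'
#' @param ref_volume,def_volume [image_volume]s of identical shape.
#' @param node 0-based voxel coordinates (z, y, x) of the grid node.
#' @param cw window half-width, voxels.
#' @param search_range search bound, voxels.
#' @return List with `u` (integer 3-vector), `cc`, `cube` (3x3x3 CC values
#'   around the optimum) and `ok`; `ok = FALSE` for zero-variance windows or
#'   windows touching the volume boundary.
#' @export
correlate_window <- function(ref_volume, def_volume, node, cw, search_range) {
  stopifnot(identical(dim(ref_volume$data), dim(def_volume$data)))
  cpp_zncc_search(ref_volume$data, def_volume$data, dim(ref_volume$data),
                  as.integer(node), as.integer(cw), as.integer(search_range))
}

#' Sub-voxel peak of a 3x3x3 correlation-coefficient cube
#'
#' Fits the 27-coefficient tri-quadratic polynomial that exactly
#' interpolates the CC values at the 27 integer offsets around the best
#' integer displacement, and returns its stationary point when that point is
#' a strict local maximum inside the open cube `(-1, 1)^3`.  Otherwise the
#' caller falls back to gradient-based optimization.
#'
#' @param cc_cube numeric 3x3x3 array of CC values (offsets -1, 0, +1 per
#'   axis, (z, y, x) order).
#' @return List with `offset` (numeric 3-vector) and `ok` (logical).
#' @export
subpixel_triquadratic <- function(cc_cube) {
  if (any(!is.finite(cc_cube))) return(list(offset = c(0, 0, 0), ok = FALSE))
  V <- rbind(c(1, -1, 1), c(1, 0, 0), c(1, 1, 1))
  Vi <- solve(V)
  C <- cc_cube
  C <- apply(C, c(2, 3), function(v) Vi %*% v)            # axis 1
  C <- aperm(apply(C, c(1, 3), function(v) Vi %*% v), c(2, 1, 3))  # axis 2
  C <- aperm(apply(C, c(1, 2), function(v) Vi %*% v), c(2, 3, 1))  # axis 3
  pw <- function(t) c(1, t, t * t)
  dpw <- function(t) c(0, 1, 2 * t)
  d2pw <- function(t) c(0, 0, 2)
  gradhess <- function(p) {
    bz <- pw(p[1]); by <- pw(p[2]); bx <- pw(p[3])
    dz <- dpw(p[1]); dy <- dpw(p[2]); dx <- dpw(p[3])
    zz <- d2pw(p[1]); yy <- d2pw(p[2]); xx <- d2pw(p[3])
    tens <- function(a, b, c) sum(C * (a %o% b %o% c))
    g <- c(tens(dz, by, bx), tens(bz, dy, bx), tens(bz, by, dx))
    H <- matrix(c(tens(zz, by, bx), tens(dz, dy, bx), tens(dz, by, dx),
                  tens(dz, dy, bx), tens(bz, yy, bx), tens(bz, dy, dx),
                  tens(dz, by, dx), tens(bz, dy, dx), tens(bz, by, xx)), 3, 3)
    list(g = g, H = H)
  }
  p <- c(0, 0, 0)
  for (it in 1:40) {
    gh <- gradhess(p)
    step <- tryCatch(solve(gh$H, -gh$g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(offset = c(0, 0, 0), ok = FALSE))
    p <- p + step
    if (max(abs(p)) > 2) return(list(offset = c(0, 0, 0), ok = FALSE))
    if (max(abs(step)) < 1e-12) break
  }
  gh <- gradhess(p)
  eig <- eigen(0.5 * (gh$H + t(gh$H)), symmetric = TRUE, only.values = TRUE)$values
  if (any(eig >= 0) || any(abs(p) >= 1))
    return(list(offset = c(0, 0, 0), ok = FALSE))
  list(offset = as.numeric(p), ok = TRUE)
}

#' Numerical sub-voxel refinement
#'
#' Maximizes the ZNCC over a continuous displacement within +/-1 voxel of
#' the integer estimate; the deformed window is resampled by cubic B-spline
#' interpolation at each trial displacement and the objective is ascended
#' by per-axis parabolic steps with a shrinking bracket (converging well
#' below 1e-3 voxel).  The result never degrades the integer-search CC: if
#' refinement ends lower, the integer displacement is returned.
#'
#' @inheritParams correlate_window
#' @param initial_u integer displacement from [correlate_window]; the
#'   search is bounded to +/-1 voxel around it.
#' @param start starting displacement (e.g. the tri-quadratic estimate);
#'   defaults to `initial_u`.
#' @param def_coef optional precomputed cubic B-spline coefficient volume of
#'   the deformed image (for repeated calls); computed when `NULL`.
#' @return List with `u` (numeric 3-vector) and `cc`.
#' @export
subpixel_optimize <- function(ref_volume, def_volume, node, cw, initial_u,
                              start = initial_u, def_coef = NULL) {
  dimv <- dim(ref_volume$data)
  node <- as.integer(node); cw <- as.integer(cw)
  if (is.null(def_coef))
    def_coef <- cpp_bspline_coef3(def_volume$data, dimv)
  res <- cpp_subpixel_refine(ref_volume$data, def_coef, dimv, node, cw,
                             as.integer(initial_u), as.numeric(start))
  cc_int <- cpp_zncc_subvoxel(ref_volume$data, def_coef, dimv, node, cw,
                              as.numeric(initial_u))
  if (!is.finite(res$cc) || (is.finite(cc_int) && res$cc < cc_int))
    return(list(u = as.numeric(initial_u), cc = cc_int))
  list(u = as.numeric(res$u), cc = res$cc)
}

#' Run local DVC between two load steps
#'
#' For each node of the regular grid: windows with too little bone or no
#' intensity variance are failed; otherwise an exhaustive integer ZNCC
#' search is refined to sub-voxel precision by the tri-quadratic
#' interpolation of the CC cube, falling back to gradient-based optimization
#' when the interpolant has no interior maximum.  The CC is re-evaluated at
#' the final sub-voxel displacement.
#'
#' @param ref_volume,def_volume preprocessed [image_volume]s, same shape.
#' @param mask optional logical bone mask (windows below
#'   `config$min_bone_fraction` bone are skipped).
#' @param config a [dvc_config].
#' @param roi optional [roi_spec]; defaults to the full volume.
#' @return An object of class `displacement_field`: node grid, per-node
#'   displacement array `u` (grid dims x 3, voxels), `cc`, and `status`
#'   (`"ok"`, `"fallback"`, `"failed"`).
#' @export
run_dvc <- function(ref_volume, def_volume, mask = NULL, config = dvc_config(),
                    roi = NULL) {
  stopifnot(inherits(ref_volume, "image_volume"),
            identical(dim(ref_volume$data), dim(def_volume$data)))
  d <- dim(ref_volume$data)
  if (is.null(roi)) roi <- roi_spec(c(0L, 0L, 0L), d)
  if (config$prefilter_sigma > 0) {
    ref_volume$data <- array(cpp_gauss_smooth3(ref_volume$data, d,
                                               config$prefilter_sigma), dim = d)
    def_volume$data <- array(cpp_gauss_smooth3(def_volume$data, d,
                                               config$prefilter_sigma), dim = d)
  }
  guard <- ceiling(3 * config$prefilter_sigma) + 2L  # filter + spline support
  grid <- make_node_grid(roi, config$ns, config$cw, config$search_range,
                         guard = guard)
  g <- grid$shape
  u <- array(NA_real_, dim = c(g, 3))
  cc <- array(NA_real_, dim = g)
  status <- array("failed", dim = g)
  cw <- config$cw
  dimv <- dim(ref_volume$data)
  def_coef <- cpp_bspline_coef3(def_volume$data, dimv)
  nwin <- (2 * cw + 1)^3
  for (kx in seq_len(g[3])) for (ky in seq_len(g[2])) for (kz in seq_len(g[1])) {
    node <- c(grid$nodes_z[kz], grid$nodes_y[ky], grid$nodes_x[kx])
    if (!is.null(mask)) {
      i <- (node[1] - cw):(node[1] + cw) + 1L
      j <- (node[2] - cw):(node[2] + cw) + 1L
      k <- (node[3] - cw):(node[3] + cw) + 1L
      if (sum(mask[i, j, k]) / nwin < config$min_bone_fraction) next
    }
    res <- cpp_zncc_search(ref_volume$data, def_volume$data, dimv,
                           as.integer(node), cw, config$search_range)
    if (!res$ok) next
    if (res$cc >= 1 - 1e-12) {
      # exact match: CC = 1 is the global ZNCC maximum, nothing to refine
      u[kz, ky, kx, ] <- res$u
      cc[kz, ky, kx] <- res$cc
      status[kz, ky, kx] <- "ok"
      next
    }
    sp <- subpixel_triquadratic(res$cube)
    # gradient refinement of the tri-quadratic estimate suppresses the
    # peak-locking bias of the interpolated CC cube; when the interpolant
    # has no interior maximum the optimizer starts from the integer peak
    start <- if (sp$ok) res$u + sp$offset else res$u
    opt <- subpixel_optimize(ref_volume, def_volume, node, cw, res$u,
                             start = start, def_coef = def_coef)
    uu <- opt$u; ccf <- opt$cc
    st <- if (sp$ok) "ok" else "fallback"
    if (!is.finite(ccf) || ccf < res$cc - 1e-6) { uu <- res$u; ccf <- res$cc }
    u[kz, ky, kx, ] <- uu
    cc[kz, ky, kx] <- ccf
    status[kz, ky, kx] <- st
  }
  if (!any(status != "failed")) stop("no valid DVC nodes")
  structure(list(grid = grid, u = u, cc = cc, status = status,
                 voxel_size = ref_volume$voxel_size),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  g <- x$grid$shape
  nok <- sum(x$status != "failed")
  cat(sprintf("<displacement_field> %d x %d x %d nodes (NS %d, CW +/-%d), %d valid\n",
              g[1], g[2], g[3], x$grid$ns, x$grid$cw, nok))
  if (nok > 0)
    cat(sprintf("  median CC %.4f\n", median(x$cc[x$status != "failed"])))
  invisible(x)
}
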