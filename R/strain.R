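# Stack the (2r+1)^3 neighborhood of a 3D array into an extra dimension,
# NA-padded at faces; used by the displacement-field filters.
neighborhood_stack <- function(arr, r = 1L, include_center = TRUE) {
  g <- dim(arr)
  offs <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  if (!include_center) offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  out <- array(NA_real_, dim = c(g, nrow(offs)))
  for (m in seq_len(nrow(offs))) {
    o <- as.integer(offs[m, ])
    src <- lapply(1:3, function(a) {
      i <- seq_len(g[a]) + o[a]
      i[i >= 1 & i <= g[a]]
    })
    dst <- lapply(1:3, function(a) src[[a]] - o[a])
    out[dst[[1]], dst[[2]], dst[[3]], m] <-
      arr[src[[1]], src[[2]], src[[3]]]
  }
  out
}

apply_margin_median <- function(stack) {
  g <- dim(stack)
  apply(stack, 1:3, median, na.rm = TRUE)
}

#' Filter a displacement field (outlier removal + median)
#'
#' Componentwise, a node is an outlier when its value deviates from the
#' median `m` of its 26 surrounding nodes by more than
#' `outlier_factor * max(|m|, outlier_floor)` ("diverged more than double
#' from the median of the surrounding points", with an absolute floor that
#' keeps near-zero medians from rejecting everything in a still region).
#' Outlier components are replaced by `m` and the node is marked
#' `"filtered"`; an outlier with fewer than 2 valid neighbors is failed.
#' A componentwise 3^3 median filter (R = `median_radius`) over valid nodes
#' follows.
#'
#' @param field a `displacement_field` from [run_dvc()].
#' @param outlier_factor deviation factor (default 2).
#' @param median_radius radius of the final median filter (default 1).
#' @param outlier_floor absolute floor in voxels (default 0.1).
#' @return The filtered `displacement_field`.
#' @export
filter_displacement_field <- function(field, outlier_factor = 2,
                                      median_radius = 1L, outlier_floor = 0.1) {
  stopifnot(inherits(field, "displacement_field"))
  g <- field$grid$shape
  u <- field$u
  status <- field$status
  valid <- status != "failed"
  u_masked <- u
  for (a in 1:3) {
    ua <- u[, , , a]; ua[!valid] <- NA_real_
    u_masked[, , , a] <- ua
  }
  # outlier pass: median over the 26 surrounding nodes
  nvalid <- NULL
  for (a in 1:3) {
    st <- neighborhood_stack(u_masked[, , , a], 1L, include_center = FALSE)
    m <- apply(st, 1:3, median, na.rm = TRUE)
    if (is.null(nvalid)) nvalid <- apply(st, 1:3, function(v) sum(is.finite(v)))
    dev <- abs(u_masked[, , , a] - m)
    thr <- outlier_factor * pmax(abs(m), outlier_floor)
    out <- valid & is.finite(m) & dev > thr
    kill <- out & nvalid < 2
    repl <- out & !kill
    ua <- u_masked[, , , a]
    ua[repl] <- m[repl]
    ua[kill] <- NA_real_
    u_masked[, , , a] <- ua
    status[repl & status != "filtered"] <- "filtered"
    status[kill] <- "failed"
  }
  valid <- status != "failed"
  # median pass (R = median_radius) over valid nodes.  The median replaces
  # the value only where the full symmetric stencil is valid: the median of
  # a complete stencil reproduces linear fields exactly, whereas a sparse
  # or truncated stencil pulls values toward the valid cluster and
  # systematically shrinks strains at cluster and grid boundaries.
  if (median_radius > 0) {
    r <- as.integer(median_radius)
    if (all(g > 2 * r)) {
      stv <- neighborhood_stack(valid + 0, r, include_center = TRUE)
      full <- apply(stv, 1:3, function(v) all(is.finite(v)) && all(v == 1))
      for (a in 1:3) {
        st <- neighborhood_stack(u_masked[, , , a], r, include_center = TRUE)
        m <- apply(st, 1:3, median, na.rm = TRUE)
        ua <- u_masked[, , , a]
        sel <- valid & full
        ua[sel] <- m[sel]
        u_masked[, , , a] <- ua
      }
    }
  }
  field$u <- u_masked
  field$status <- status
  field
}

#' Green-Lagrange strain tensors on the node grid
#'
#' Each grid cell of 8 neighboring nodes is an isoparametric trilinear
#' hexahedral element.  The displacement gradient is evaluated at the
#' element center from the trilinear shape-function derivatives (exact for
#' affine displacement fields), giving `F = I + du/dX`,
#' `E = (FtF - I) / 2`, and the volumetric strain `det(F) - 1` (positive =
#' expansion, negative = compression).  Elements with any failed corner node
#' are invalid.  Displacements and spacings are both in voxels of the same
#' grid, so strains are dimensionless at any resolution.
#'
#' @param field a filtered `displacement_field`.
#' @return An object of class `strain_field` with per-element arrays:
#'   `E` (dims x 6; E11, E22, E33, E12, E13, E23 with axes 1,2,3 = z,y,x),
#'   `F` (dims x 3 x 3), `volumetric` (det(F) - 1), `valid`, `cc` (min over
#'   the 8 corner nodes), and element centers in voxels.
#' @export
green_strain <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  g <- field$grid$shape
  ns <- field$grid$ns
  e <- g - 1L
  if (any(e < 1L)) stop("need at least 2 nodes per axis")
  corner <- function(arr, cz, cy, cx)
    arr[seq_len(e[1]) + cz, seq_len(e[2]) + cy, seq_len(e[3]) + cx, drop = FALSE]
  face_diff <- function(arr, axis) {
    # mean over the +axis face minus mean over the -axis face
    acc <- array(0, dim = e)
    corners <- expand.grid(cz = 0:1, cy = 0:1, cx = 0:1)
    hi <- corners[corners[, axis] == 1, ]
    lo <- corners[corners[, axis] == 0, ]
    for (q in 1:4) {
      acc <- acc + corner(arr, hi$cz[q], hi$cy[q], hi$cx[q]) / 4 -
                   corner(arr, lo$cz[q], lo$cy[q], lo$cx[q]) / 4
    }
    acc
  }
  G <- vector("list", 9)  # G[[3*(b-1)+a]] = d u_a / d X_b
  for (a in 1:3) {
    ua <- field$u[, , , a]
    for (b in 1:3) G[[3 * (b - 1) + a]] <- face_diff(ua, b) / ns
  }
  Fm <- function(i, j) G[[3 * (j - 1) + i]] + (i == j)
  # E = (FtF - I)/2, FtF[j,k] = sum_i F[i,j] F[i,k]
  ftf <- function(j, k) Fm(1, j) * Fm(1, k) + Fm(2, j) * Fm(2, k) + Fm(3, j) * Fm(3, k)
  E <- array(NA_real_, dim = c(e, 6))
  E[, , , 1] <- (ftf(1, 1) - 1) / 2
  E[, , , 2] <- (ftf(2, 2) - 1) / 2
  E[, , , 3] <- (ftf(3, 3) - 1) / 2
  E[, , , 4] <- ftf(1, 2) / 2
  E[, , , 5] <- ftf(1, 3) / 2
  E[, , , 6] <- ftf(2, 3) / 2
  detF <- Fm(1, 1) * (Fm(2, 2) * Fm(3, 3) - Fm(2, 3) * Fm(3, 2)) -
          Fm(1, 2) * (Fm(2, 1) * Fm(3, 3) - Fm(2, 3) * Fm(3, 1)) +
          Fm(1, 3) * (Fm(2, 1) * Fm(3, 2) - Fm(2, 2) * Fm(3, 1))
  Farr <- array(NA_real_, dim = c(e, 3, 3))
  for (i in 1:3) for (j in 1:3) Farr[, , , i, j] <- Fm(i, j)
  nodev <- field$status != "failed"
  valid <- array(TRUE, dim = e)
  ccmin <- array(Inf, dim = e)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    valid <- valid & corner(nodev, cz, cy, cx)
    ccmin <- pmin(ccmin, corner(field$cc, cz, cy, cx))
  }
  ccmin[!valid] <- NA_real_
  valid <- valid & apply(is.finite(E), 1:3, all)
  if (!any(valid)) stop("no valid strain elements")
  vol <- detF - 1
  vol[!valid] <- NA_real_
  centers <- list(z = field$grid$nodes_z[seq_len(e[1])] + ns / 2,
                  y = field$grid$nodes_y[seq_len(e[2])] + ns / 2,
                  x = field$grid$nodes_x[seq_len(e[3])] + ns / 2)
  structure(list(E = E, F = Farr, volumetric = vol, valid = valid, cc = ccmin,
                 centers = centers, ns = ns, voxel_size = field$voxel_size),
            class = "strain_field")
}

#' Volumetric strain det(F) - 1 per element
#'
#' @param strain_field a `strain_field` from [green_strain()].
#' @return 3D array of volumetric strains; invalid elements are `NA`.
#' @export
volumetric_strain <- function(strain_field) {
  stopifnot(inherits(strain_field, "strain_field"))
  strain_field$volumetric
}

#' Gate a field by correlation coefficient
#'
#' Only nodes/elements whose correlation coefficient exceeds `cc_min` enter
#' downstream statistics.  For a strain field the element CC is the minimum
#' over its 8 corner nodes (conservative).
#'
#' @param x a `displacement_field` or `strain_field`.
#' @param cc_min CC gate, default 0.95.
#' @return Same class as `x` with gated nodes/elements invalidated.
#' @export
mask_by_correlation <- function(x, cc_min = 0.95) {
  if (inherits(x, "displacement_field")) {
    drop <- is.na(x$cc) | x$cc <= cc_min
    x$status[drop] <- "failed"
    for (a in 1:3) { ua <- x$u[, , , a]; ua[drop] <- NA_real_; x$u[, , , a] <- ua }
    x$cc[drop] <- NA_real_
    return(x)
  }
  if (inherits(x, "strain_field")) {
    drop <- is.na(x$cc) | x$cc <= cc_min
    x$valid <- x$valid & !drop
    x$volumetric[!x$valid] <- NA_real_
    return(x)
  }
  stop("unsupported type")
}
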