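# Shared fixtures and independent oracles.  Fixtures are generated in code;
# the heavier ones are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 64^3 textured phantom shared by several DVC tests
small_phantom <- function() {
  fixture("small_phantom", function() {
    generate_trabecular_phantom(
      phantom_spec(shape = c(64L, 64L, 64L), correlation_length = 60,
                   noise_sd = 0, seed = 11L))
  })
}

# smooth pure-texture volume (no binary structure): easy correlation target
smooth_volume <- function(shape = c(48L, 48L, 48L), seed = 5L) {
  set.seed(seed)
  raw <- array(rnorm(prod(shape)), dim = shape)
  sm <- raw
  for (i in 1:2) {
    k <- dim(sm)
    tmp <- array(trabstrain:::cpp_gauss_smooth3(sm, k, 2.0), dim = k)
    sm <- tmp
  }
  sm <- 128 + 50 * sm / sd(sm)
  image_volume(sm, 3.6)
}

# --- independent oracles ---

# exhaustive zero-normalized cross-correlation over integer offsets
oracle_zncc_search <- function(ref, def, node, cw, sr) {
  win <- function(vol, ctr) {
    i <- (ctr[1] - cw):(ctr[1] + cw) + 1L
    j <- (ctr[2] - cw):(ctr[2] + cw) + 1L
    k <- (ctr[3] - cw):(ctr[3] + cw) + 1L
    as.vector(vol[i, j, k])
  }
  rw <- win(ref, node)
  best <- NULL
  for (oz in -sr:sr) for (oy in -sr:sr) for (ox in -sr:sr) {
    dw <- win(def, node + c(oz, oy, ox))
    if (sd(dw) == 0 || sd(rw) == 0) next
    cc <- cor(rw, dw)
    cand <- list(u = c(oz, oy, ox), cc = cc)
    if (is.null(best) || cc > best$cc ||
        (cc == best$cc && sum(cand$u^2) < sum(best$u^2))) best <- cand
  }
  best
}

# brute-force largest-inscribed-sphere thickness (same convention as the
# implementation: sphere radius = center-to-center distance to nearest
# background voxel, coverage d(v, c) < r, thickness = 2 r)
oracle_local_thickness <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  th <- array(0, dim = d)
  if (nrow(bg) == 0L || nrow(idx) == 0L) return(th)
  r2 <- vapply(seq_len(nrow(idx)), function(i) {
    min(colSums((t(bg) - idx[i, ])^2))
  }, numeric(1))
  for (i in seq_len(nrow(idx))) {
    ri2 <- r2[i]
    dia <- 2 * sqrt(ri2)
    d2 <- colSums((t(idx) - idx[i, ])^2)
    cover <- d2 < ri2
    th[idx[cover, , drop = FALSE]] <- pmax(th[idx[cover, , drop = FALSE]], dia)
  }
  th
}

# exact two-sided signed-rank p by enumeration over all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}

# discrete Euclidean ball enumeration
oracle_ball_count <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(z = -r:r, y = -r:r, x = -r:r)
  sum(g$z^2 + g$y^2 + g$x^2 <= radius^2)
}

# Standard crack-segmentation fixture: textured phantom with one slit of
# intermediate gray inserted in a thin strut; thresholds bracket the slit
# gray by construction (background 60 < low 80 < slit 90 < high 115 < bone).
crack_fixture <- function() {
  fixture("crack_fixture", function() {
    ph <- generate_trabecular_phantom(
      phantom_spec(shape = c(80L, 80L, 80L), noise_sd = 2, seed = 21L))
    # slit seeded at the deepest interior bone voxel so the whole slit sits
    # clear of the structure surfaces the edge band masks out
    edt2 <- array(trabstrain:::cpp_edt2(!ph$bone_mask, dim(ph$bone_mask)),
                  dim(ph$bone_mask))
    inb <- array(FALSE, dim(edt2)); inb[17:64, 17:64, 17:64] <- TRUE
    site <- which(edt2 == max(edt2[inb]) & inb, arr.ind = TRUE)[1, ] - 1
    cs <- crack_spec(center = site, normal = c(1, 0, 0), thickness = 3,
                     extent = 14, gray = 90)
    out <- insert_cracks(ph$volume, list(cs), ph$bone_mask)
    list(phantom = ph, volume = out$volume, truth = out$crack_mask)
  })
}
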