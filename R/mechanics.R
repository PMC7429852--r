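#' Convert a load-displacement record to apparent stress-strain
#'
#' Stress is force over the nominal cross-section `pi (d/2)^2`; strain is
#' the compliance-corrected displacement over the sample height.
#' Compression is reported with positive signs.
#'
#' @param load_curve data.frame with columns `displacement` (mm) and
#'   `force` (N) (a `time` column is carried through if present).
#' @param diameter,height sample dimensions, mm.
#' @param compliance loading-system compliance, mm/N (subtracted as
#'   `compliance * force` from the displacement).
#' @return A `stress_strain` object: data.frame with `strain`
#'   (dimensionless) and `stress` (MPa) plus the geometry.
#' @export
to_stress_strain <- function(load_curve, diameter, height, compliance = 0) {
  stopifnot(is.data.frame(load_curve),
            all(c("displacement", "force") %in% names(load_curve)))
  if (diameter <= 0 || height <= 0) stop("non-positive sample geometry")
  if (compliance < 0) stop("compliance must be >= 0")
  area <- pi * (diameter / 2)^2
  df <- data.frame(
    strain = (load_curve$displacement - compliance * load_curve$force) / height,
    stress = load_curve$force / area)
  structure(list(curve = df, diameter = diameter, height = height,
                 compliance = compliance),
            class = "stress_strain")
}

as_stress_strain <- function(df) {
  structure(list(curve = df, diameter = NA_real_, height = NA_real_,
                 compliance = 0),
            class = "stress_strain")
}

# Pause (relaxation) samples: near-constant strain with dropping stress,
# from stopping the loading during image acquisition.
detect_pauses <- function(curve, strain_tol = 1e-5) {
  n <- nrow(curve)
  pause <- rep(FALSE, n)
  if (n < 2) return(pause)
  de <- diff(curve$strain); ds <- diff(curve$stress)
  seg <- abs(de) < strain_tol & ds < 0
  pause[-1] <- seg
  pause[-n] <- pause[-n] | seg
  pause
}

# Maximal stable-slope window of the pre-ultimate curve, pauses excluded.
# Sliding windows (widths down from 60% to 20% of the usable record) are
# screened by requiring the least-squares slopes of their two halves to
# agree within `tol`; among the stable windows at the largest width that
# has any, the one with the steepest overall slope is the linear region.
# Least-squares slopes over long windows make the rule noise-tolerant.
linear_region <- function(curve, tol = 0.05) {
  keep <- !detect_pauses(curve)
  iu <- which.max(curve$stress)
  keep[seq_len(nrow(curve)) > iu] <- FALSE
  idx <- which(keep)
  if (length(idx) < 10L) stop("fewer than 10 usable samples")
  e <- curve$strain[idx]; s <- curve$stress[idx]
  m <- length(idx)
  # cumulative sums for O(1) windowed least-squares slopes
  ce <- cumsum(e); cs <- cumsum(s); cee <- cumsum(e * e); ces <- cumsum(e * s)
  wslope <- function(a, b) {   # slope over samples a..b
    n <- b - a + 1
    se <- ce[b] - if (a > 1) ce[a - 1] else 0
    ss <- cs[b] - if (a > 1) cs[a - 1] else 0
    see <- cee[b] - if (a > 1) cee[a - 1] else 0
    ses <- ces[b] - if (a > 1) ces[a - 1] else 0
    den <- see - se * se / n
    if (den <= 0) return(NA_real_)
    (ses - se * ss / n) / den
  }
  step <- max(1L, m %/% 60L)
  for (frac in c(0.6, 0.5, 0.4, 0.3, 0.2)) {
    w <- max(10L, as.integer(frac * m))
    if (w > m) next
    best <- NULL
    for (a in seq.int(1L, m - w + 1L, by = step)) {
      b <- a + w - 1L
      mid <- a + w %/% 2L
      sl <- wslope(a, b)
      s1 <- wslope(a, mid); s2 <- wslope(mid, b)
      if (!is.finite(sl) || sl <= 0 || !is.finite(s1) || !is.finite(s2)) next
      if (abs(s1 - s2) > tol * sl) next
      if (is.null(best) || sl > best$sl) best <- list(a = a, b = b, sl = sl)
    }
    if (!is.null(best)) return(idx[best$a:best$b])
  }
  stop("no rising linear region found")
}

#' Apparent modulus from the linear region
#'
#' Least-squares slope over the maximal stable-slope window of the
#' stress-strain curve, loading pauses excluded.
#'
#' @param ss a `stress_strain` object.
#' @return Modulus in MPa, with attribute `region` (sample indices used).
#' @export
apparent_modulus <- function(ss) {
  stopifnot(inherits(ss, "stress_strain"))
  sel <- linear_region(ss$curve)
  fit <- lm(stress ~ strain, data = ss$curve[sel, ])
  E <- unname(coef(fit)[2])
  attr(E, "region") <- sel
  E
}

#' Toe-region correction
#'
#' Extrapolates the linear part of the curve to zero stress and subtracts
#' that strain intercept from all strains ("delta strain"), removing the
#' low-stiffness toe caused by imperfect platen contact.
#'
#' @param ss a `stress_strain` object.
#' @return List with `ss` (corrected curve), `toe_offset` (strain), and
#'   `modulus` (MPa, from the linear fit).
#' @export
toe_correct <- function(ss) {
  stopifnot(inherits(ss, "stress_strain"))
  sel <- linear_region(ss$curve)
  fit <- lm(stress ~ strain, data = ss$curve[sel, ])
  E <- unname(coef(fit)[2])
  offset <- -unname(coef(fit)[1]) / E
  out <- ss
  out$curve$strain <- ss$curve$strain - offset
  list(ss = out, toe_offset = offset, modulus = E)
}

#' Yield point by the 0.2% strain offset method
#'
#' Intersection of the (toe-corrected) curve with the line of slope equal
#' to the apparent modulus offset by `offset` strain.  The yield strain is
#' reported as toe-corrected delta strain in percent.
#'
#' @param ss a `stress_strain` object (already toe-corrected).
#' @param modulus apparent modulus, MPa.
#' @param offset strain offset (default 0.002).
#' @return List with `yield_stress` (MPa), `yield_strain_pct`, and the
#'   sample index just before the crossing.
#' @export
yield_offset <- function(ss, modulus, offset = 0.002) {
  stopifnot(inherits(ss, "stress_strain"), modulus > 0)
  e <- ss$curve$strain; s <- ss$curve$stress
  iu <- which.max(s)
  gap <- s - modulus * (e - offset)   # curve minus offset line
  tol <- 1e-9 * max(abs(s))
  cross <- which(gap[seq_len(iu - 1)] >= -tol & gap[seq_len(iu)][-1] < -tol)
  if (length(cross) == 0L) stop("no intersection with the offset line before ultimate")
  i <- cross[1]
  f <- gap[i] / (gap[i] - gap[i + 1])
  ey <- e[i] + f * (e[i + 1] - e[i])
  sy <- s[i] + f * (s[i + 1] - s[i])
  list(yield_stress = sy, yield_strain_pct = 100 * ey, index = i)
}

#' Ultimate point and toughness
#'
#' Ultimate stress is the global stress maximum; toughness is the
#' trapezoidal integral of stress over strain from zero (toe-corrected) to
#' the ultimate strain, in MPa x strain = MJ/m^3.  A monotonically rising
#' curve has no interior maximum: the last point is used and flagged.
#'
#' @param ss a `stress_strain` object (toe-corrected).
#' @return List with `ultimate_stress` (MPa), `ultimate_strain_pct`,
#'   `toughness_mj_m3`, and `censored` (TRUE when no interior maximum).
#' @export
ultimate_toughness <- function(ss) {
  stopifnot(inherits(ss, "stress_strain"))
  e <- ss$curve$strain; s <- ss$curve$stress
  # running median (identity on clean monotone data) keeps the global max
  # from riding on the largest noise excursion
  k <- max(1L, length(s) %/% 50L)
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= 3L) s <- stats::runmed(s, k, endrule = "keep")
  iu <- which.max(s)
  censored <- iu == length(s)
  sel <- which(e <= e[iu] & e >= 0)
  tough <- pracma::trapz(e[sel], s[sel])
  list(ultimate_stress = s[iu], ultimate_strain_pct = 100 * e[iu],
       toughness_mj_m3 = tough, censored = censored)
}

#' Full bulk-mechanics summary of one loading record
#'
#' Compliance correction, toe correction, apparent modulus, 0.2%-offset
#' yield, ultimate stress/strain, toughness.
#'
#' @param load_curve data.frame with `displacement` (mm) and `force` (N),
#'   or a ready `stress_strain` object (then geometry args are ignored).
#' @param diameter,height,compliance see [to_stress_strain()].
#' @return A one-row data.frame (class `mechanical_summary`).
#' @export
mechanical_summary <- function(load_curve, diameter = 7.1, height = 6.3,
                               compliance = 0) {
  ss <- if (inherits(load_curve, "stress_strain")) load_curve
        else to_stress_strain(load_curve, diameter, height, compliance)
  tc <- toe_correct(ss)
  E <- tc$modulus
  y <- yield_offset(tc$ss, E)
  u <- ultimate_toughness(tc$ss)
  out <- data.frame(apparent_modulus_mpa = E,
                    toe_offset_strain = tc$toe_offset,
                    yield_stress_mpa = y$yield_stress,
                    yield_strain_pct = y$yield_strain_pct,
                    ultimate_stress_mpa = u$ultimate_stress,
                    ultimate_strain_pct = u$ultimate_strain_pct,
                    toughness_mj_m3 = u$toughness_mj_m3,
                    ultimate_censored = u$censored)
  class(out) <- c("mechanical_summary", class(out))
  out
}
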