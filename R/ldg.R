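#' Fit a hyperbolic tangent to a latitudinal richness profile
#'
#' Least-squares fit of `alpha(lat) = alpha_min + d_alpha * tanh(theta *
#' (|lat| - lat0))` on one hemisphere's profile against absolute latitude,
#' using bounded Levenberg-Marquardt with four multi-starts (both slope signs
#' crossed with lat0 at the latitude quartiles). Two slope summaries are
#' reported: the raw `theta` and the maximum gradient `|theta * d_alpha|`
#' (attained at `lat0`); two width summaries: the transition midpoint `lat0`
#' and the tanh transition width `2 / |theta|`. Fits are canonicalized to
#' `theta > 0` (flipping the sign of `d_alpha`), since the curve is invariant
#' under flipping both.
#'
#' @param lat Latitudes (degrees; sign ignored, absolute value used).
#' @param value Richness (or any metric) per latitude; NAs dropped.
#' @param hemisphere Label stored in the result ("N" or "S").
#' @return List of class `ldg_fit`: `alpha_min`, `d_alpha`, `theta`, `lat0`,
#'   `slope_raw`, `slope_max`, `width_mid`, `width_tanh`, `rss`, `converged`,
#'   `hemisphere`, `n`.
#' @export
fit_tanh <- function(lat, value, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  ok <- !is.na(value) & !is.na(lat)
  x <- abs(lat[ok]); y <- value[ok]
  if (length(unique(x)) < 8) stop("need at least 8 latitude bands with data")
  degenerate <- function() {
    structure(list(alpha_min = mean(y), d_alpha = 0, theta = NA_real_,
                   lat0 = NA_real_, slope_raw = NA_real_,
                   slope_max = NA_real_, width_mid = NA_real_,
                   width_tanh = NA_real_, rss = 0, converged = FALSE,
                   hemisphere = hemisphere, n = length(y)),
              class = "ldg_fit")
  }
  if (stats::sd(y) < 1e-12) return(degenerate())
  dat <- data.frame(x = x, y = y)
  rng <- diff(range(y))
  starts <- expand.grid(theta = c(0.05, 0.05),
                        lat0 = stats::quantile(x, c(0.25, 0.75)))
  starts$sgn <- rep(c(1, -1), 2)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(amin = min(y), da = starts$sgn[i] * rng / 2,
               th = starts$theta[i], l0 = unname(starts$lat0[i]))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ amin + da * tanh(th * (x - l0)), data = dat,
                        start = st,
                        lower = c(amin = -Inf, da = -Inf, th = -5, l0 = 0),
                        upper = c(amin = Inf, da = Inf, th = 5, l0 = 90),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(degenerate())
  p <- as.list(stats::coef(best$fit))
  if (!is.na(p$th) && p$th < 0) {       # canonical form: theta > 0
    p$th <- -p$th; p$da <- -p$da
  }
  structure(list(alpha_min = p$amin, d_alpha = p$da, theta = p$th,
                 lat0 = p$l0, slope_raw = p$th,
                 slope_max = abs(p$th * p$da), width_mid = p$l0,
                 width_tanh = 2 / abs(p$th), rss = best$rss,
                 converged = TRUE, hemisphere = hemisphere, n = length(y)),
            class = "ldg_fit")
}

#' @export
print.ldg_fit <- function(x, ...) {
  cat(sprintf(
    "<ldg_fit %s> alpha_min=%.4g d_alpha=%.4g theta=%.4g lat0=%.4g (rss=%.3g, %s)\n",
    x$hemisphere, x$alpha_min, x$d_alpha, x$theta, x$lat0, x$rss,
    if (x$converged) "converged" else "degenerate"))
  invisible(x)
}

#' Simplified Koeppen climate classification
#'
#' Classifies cells from mean annual temperature (MAT, deg C) and mean annual
#' precipitation (MAP, m/yr), evaluated in precedence order A, B, C, D, E:
#' tropical A if MAT > 18 and MAP > 0.6 m/yr; arid B if MAP (in cm/yr) falls
#' below the critical threshold `kappa = 2 * MAT`; temperate C if
#' 5 < MAT < 18 and 0.5 < MAP < 2; continental D if -5 < MAT < 10 and
#' 0.4 < MAP < 1; polar E if MAT < 10; otherwise "none". MAP is taken in
#' m/yr; the cm conversion happens only inside the arid rule (classic Koeppen
#' convention).
#'
#' @param mat Mean annual temperature, deg C (vector/matrix).
#' @param map Mean annual precipitation, m/yr (>= 0).
#' @return Character classes ("A".."E" or "none"), same shape as input.
#' @export
koppen_classify <- function(mat, map) {
  stopifnot(all(map >= 0, na.rm = TRUE))
  out <- rep(NA_character_, length(mat))
  map_cm <- map * 100
  a <- mat > 18 & map > 0.6
  b <- !a & (map_cm < 2 * mat)
  c_ <- !a & !b & (mat > 5 & mat < 18 & map > 0.5 & map < 2)
  d <- !a & !b & !c_ & (mat > -5 & mat < 10 & map > 0.4 & map < 1)
  e <- !a & !b & !c_ & !d & (mat < 10)
  out[which(a)] <- "A"; out[which(b)] <- "B"; out[which(c_)] <- "C"
  out[which(d)] <- "D"; out[which(e)] <- "E"
  out[is.na(out) & !is.na(mat)] <- "none"
  if (is.matrix(mat)) out <- matrix(out, nrow(mat), ncol(mat))
  out
}

#' Dominant Koeppen belt per latitude band through time
#'
#' Classifies every land cell of every slice and reports the modal class per
#' latitude band; ties resolve to the class earliest in the precedence order
#' A < B < C < D < E < none.
#'
#' @param series A `landscape_series`.
#' @return Character matrix (n_lat_bands x n_times, rownames latitudes,
#'   colnames ages); NA where a band has no land.
#' @export
belt_profile <- function(series) {
  n_t <- length(series$times)
  lats <- series$grid$lat
  lev <- c("A", "B", "C", "D", "E", "none")
  out <- matrix(NA_character_, length(lats), n_t,
                dimnames = list(lats, series$times))
  for (ti in seq_len(n_t)) {
    cls <- koppen_classify(series$temperature[, , ti],
                           series$precipitation[, , ti])
    land <- series$land[, , ti]
    for (r in seq_along(lats)) {
      v <- cls[r, land[r, ]]
      if (length(v) == 0) next
      counts <- table(factor(v, levels = lev))
      out[r, ti] <- lev[which.max(counts)]   # which.max takes first on ties
    }
  }
  out
}
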