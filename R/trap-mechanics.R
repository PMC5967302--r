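# Optical-trap mechanics: passive stiffness calibration by the equipartition
# theorem (thermal position variance of the trapped bead), force from bead
# displacement (F = k dx), tether force-extension curves, and least-squares
# fitting of the first linear region of a force-extension curve.

#' Thermal energy k_B T
#'
#' @param temperature Absolute temperature in K (>= 0).
#' @return k_B T in pN um (k_B = 1.380649e-5 pN um / K).
#' @examples
#' thermal_energy(298.15)  # 4.1164e-3 pN um
#' @export
thermal_energy <- function(temperature) {
  if (!.is_num(temperature) || temperature < 0) {
    stop("`temperature` must be a single number >= 0 K", call. = FALSE)
  }
  .kB * temperature
}

#' Trap stiffness by equipartition calibration
#'
#' Positions are mean-centred; the position variance is obtained either by a
#' Gaussian fit to the position histogram (default, Freedman-Diaconis
#' binning, nonlinear least squares on bin centres) or as the unbiased sample
#' variance; the stiffness is `k = k_B T / variance` per axis. If the
#' Gaussian fit does not converge the direct variance is used with a warning.
#'
#' @param track A `bead_track` (data frame with `x_um`, optionally `y_um`),
#'   at least 100 samples.
#' @param temperature Absolute temperature in K. Default 296.15 K (23 C room
#'   temperature).
#' @param method `"gaussian_fit"` (default) or `"direct_variance"`.
#' @return A `trap_calibration` list: `k_x` (pN/um), `k_y` (if `y_um`
#'   present), `variance_x`, `variance_y` (um^2), `temperature`, `n_frames`,
#'   `method`.
#' @examples
#' trk <- simulate_trapped_bead(stiffness = 7.29, n_frames = 10000, seed = 7)
#' stiffness_equipartition(trk, temperature = 296.15)$k_x
#' @export
stiffness_equipartition <- function(track, temperature = 296.15,
                                    method = c("gaussian_fit",
                                               "direct_variance")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(track), "x_um" %in% names(track))
  .check_positive(temperature, "temperature")
  n <- nrow(track)
  if (n < 100L) stop("need at least 100 samples to calibrate", call. = FALSE)

  one_axis <- function(x) {
    x <- x - mean(x)
    v_direct <- stats::var(x)
    if (!is.finite(v_direct) || v_direct < .Machine$double.eps) {
      stop("degenerate track: position variance is (near) zero",
           call. = FALSE)
    }
    used <- method
    v <- v_direct
    if (method == "gaussian_fit") {
      v <- tryCatch({
        h <- graphics::hist(x, breaks = "FD", plot = FALSE)
        df <- data.frame(mid = h$mids, count = h$counts)
        fit <- minpack.lm::nlsLM(
          count ~ A * exp(-(mid - mu)^2 / (2 * s2)), data = df,
          start = list(A = max(df$count), mu = 0, s2 = v_direct),
          lower = c(0, -Inf, v_direct * 1e-4),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        s2 <- stats::coef(fit)[["s2"]]
        if (!is.finite(s2) || s2 <= 0) stop("bad fit")
        s2
      }, error = function(e) {
        warning("Gaussian fit did not converge; falling back to direct variance")
        used <<- "direct_variance"
        v_direct
      })
    }
    list(variance = v, method = used)
  }

  ax <- one_axis(track$x_um)
  out <- list(k_x = thermal_energy(temperature) / ax$variance,
              variance_x = ax$variance,
              temperature = temperature, n_frames = n, method = ax$method)
  if ("y_um" %in% names(track)) {
    ay <- one_axis(track$y_um)
    out$k_y <- thermal_energy(temperature) / ay$variance
    out$variance_y <- ay$variance
  }
  class(out) <- "trap_calibration"
  out
}

#' @export
print.trap_calibration <- function(x, ...) {
  cat(sprintf("Trap calibration (%s, %d frames, T = %.2f K)\n",
              x$method, x$n_frames, x$temperature))
  cat(sprintf("  k_x = %.3f pN/um (variance %.4g um^2)\n",
              x$k_x, x$variance_x))
  if (!is.null(x$k_y)) {
    cat(sprintf("  k_y = %.3f pN/um (variance %.4g um^2)\n",
                x$k_y, x$variance_y))
  }
  invisible(x)
}

#' Force on the trapped bead from its displacement
#'
#' `F = k * dx`; the sign of the displacement is preserved.
#'
#' @param k Trap stiffness in pN/um (> 0).
#' @param dx Bead deviation(s) from the trap centre in um.
#' @return Force(s) in pN.
#' @export
force_from_displacement <- function(k, dx) {
  .check_positive(k, "k")
  k * dx
}

#' Build a tether force-extension curve
#'
#' Bead deviation is measured from its pre-pull mean (baseline window before
#' stage-motion onset); force is `k_x * deviation`; the extension axis is the
#' stage displacement from pull onset (the controlled quantity), or the
#' tether extension `stage - deviation` with `axis = "tether"`. Stage
#' positions are linearly interpolated onto the bead timestamps.
#'
#' @param bead A `bead_track` (`t_s`, `x_um`).
#' @param stage A `stage_track` (`t_s`, `stage_um`).
#' @param calib A `trap_calibration` (or a list with `k_x` in pN/um).
#' @param baseline_window Length of the pre-onset window used to zero the
#'   bead deviation, s.
#' @param axis `"stage"` (default) or `"tether"`.
#' @param motion_tol Stage displacement (um) above which motion is declared.
#' @return A data frame of class `force_extension` with `t_s`,
#'   `extension_um`, `force_pN` (samples from pull onset onward) and
#'   attributes `onset_s`, `k_x`, `axis`.
#' @export
force_extension_curve <- function(bead, stage, calib, baseline_window = 0.5,
                                  axis = c("stage", "tether"),
                                  motion_tol = 1e-9) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(bead), all(c("t_s", "x_um") %in% names(bead)),
            is.data.frame(stage), all(c("t_s", "stage_um") %in% names(stage)))
  k <- calib$k_x
  .check_positive(k, "calib$k_x")
  t0 <- max(min(bead$t_s), min(stage$t_s))
  t1 <- min(max(bead$t_s), max(stage$t_s))
  if (t0 >= t1) stop("bead and stage tracks do not overlap in time",
                     call. = FALSE)
  keep <- bead$t_s >= t0 & bead$t_s <= t1
  tb <- bead$t_s[keep]
  xb <- bead$x_um[keep]
  st <- stats::approx(stage$t_s, stage$stage_um, xout = tb)$y

  moving <- which(abs(st - st[1]) > motion_tol)
  onset <- if (length(moving) == 0L) tb[1] else tb[moving[1]]
  base_idx <- tb >= onset - baseline_window & tb < onset
  baseline <- if (any(base_idx)) mean(xb[base_idx]) else xb[1]

  sel <- tb >= onset
  dx <- xb[sel] - baseline
  ext <- st[sel] - stats::approx(stage$t_s, stage$stage_um, xout = onset)$y
  if (axis == "tether") ext <- ext - dx
  out <- data.frame(t_s = tb[sel], extension_um = ext,
                    force_pN = force_from_displacement(k, dx))
  class(out) <- c("force_extension", "data.frame")
  attr(out, "onset_s") <- onset
  attr(out, "k_x") <- k
  attr(out, "axis") <- axis
  out
}

#' Fit the first linear region of a force-extension curve
#'
#' Returns the ordinary least-squares fit over the longest prefix window
#' (starting at pull onset) whose coefficient of determination is at least
#' `r2_min` with at least `min_points` samples. The localization resolution
#' of the region end depends on `r2_min` and the sampling density: on long
#' dense prefixes a few off-line points barely move R^2, so use a strict
#' `r2_min` for noiseless data.
#'
#' @param curve A `force_extension` data frame (or any data frame with
#'   `extension_um`, `force_pN`).
#' @param r2_min Minimum R^2 for an acceptable window (default 0.98).
#' @param min_points Minimum window length (default 10).
#' @return List with `slope` (pN/um), `intercept` (pN), `bounds` (first and
#'   last index of the window), `r2`, `n`.
#' @export
linear_region_fit <- function(curve, r2_min = 0.98, min_points = 10L) {
  stopifnot(is.data.frame(curve),
            all(c("extension_um", "force_pN") %in% names(curve)))
  min_points <- .check_count(min_points, "min_points", min = 2L)
  x <- curve$extension_um
  y <- curve$force_pN
  N <- length(x)
  if (N < min_points) {
    stop(sprintf("curve has %d points; need at least %d", N, min_points),
         call. = FALSE)
  }
  # prefix sums give O(1) least squares per window
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  best <- 0L
  best_r2 <- NA_real_
  for (n in min_points:N) {
    Sxx <- cxx[n] - cx[n]^2 / n
    Syy <- cyy[n] - cy[n]^2 / n
    Sxy <- cxy[n] - cx[n] * cy[n] / n
    if (Sxx <= 0) next
    sse <- Syy - Sxy^2 / Sxx
    # exact-line guard: R^2 = 1 when residuals vanish to rounding
    r2 <- if (Syy <= .Machine$double.eps * max(cyy[n], 1)) {
      1
    } else {
      1 - sse / Syy
    }
    if (r2 >= r2_min) {
      best <- n
      best_r2 <- r2
    }
  }
  if (best == 0L) {
    stop("no linear region: no prefix window reaches the R^2 criterion",
         call. = FALSE)
  }
  n <- best
  Sxx <- cxx[n] - cx[n]^2 / n
  Sxy <- cxy[n] - cx[n] * cy[n] / n
  slope <- Sxy / Sxx
  intercept <- (cy[n] - slope * cx[n]) / n
  list(slope = slope, intercept = intercept, bounds = c(1L, n),
       r2 = best_r2, n = n)
}
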