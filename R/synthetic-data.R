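# Synthetic-data generators: every analysis stage in the package can be
# exercised against fixtures with known ground truth, because the study's
# microscopy, optical-trap and cytometry data are not deposited in a public
# archive. Each generator takes an explicit integer seed and leaves the
# caller's RNG state untouched.

#' Stokes drag coefficient for a sphere in water
#'
#' Drag `gamma = 6 * pi * eta * r` expressed in pN s / um. The default bead
#' diameter matches the streptavidin-coated polystyrene beads used for tether
#' pulling (1.76 um); the default viscosity is that of water at 23 C.
#'
#' @param diameter_um Bead diameter in micrometres.
#' @param viscosity_pa_s Dynamic viscosity in Pa s.
#' @return Drag coefficient in pN s / um.
#' @examples
#' stokes_drag()          # ~0.0155 pN s/um for the 1.76-um bead
#' @export
stokes_drag <- function(diameter_um = 1.76, viscosity_pa_s = 0.000933) {
  .check_positive(diameter_um, "diameter_um")
  .check_positive(viscosity_pa_s, "viscosity_pa_s")
  # 6 pi eta r with eta in Pa s and r in um comes out directly in pN s / um.
  6 * pi * viscosity_pa_s * (diameter_um / 2)
}

#' Simulate an equilibrium trapped-bead trajectory
#'
#' Positions of a bead in a harmonic optical trap follow overdamped Langevin
#' dynamics; the update uses the exact Ornstein-Uhlenbeck discretization
#' \deqn{x_{t+dt} = x_t e^{-dt/\tau} + N\!\left(0,\ \sigma^2 (1 - e^{-2 dt/\tau})\right)}
#' with relaxation time \eqn{\tau = \gamma/k} and stationary variance
#' \eqn{\sigma^2 = k_B T / k}, so there is no Euler step-size bias at any
#' `dt`. The defaults reproduce the passive-calibration recording conditions:
#' 1000 frames/s for 10 s at the calibrated stiffness.
#'
#' @param stiffness Trap stiffness k in pN/um.
#' @param temperature Absolute temperature in K.
#' @param drag Drag coefficient gamma in pN s/um; defaults to Stokes drag for
#'   the 1.76-um bead in water.
#' @param dt Frame interval in seconds.
#' @param n_frames Number of positions to return (>= 2).
#' @param x0 Initial position in um (deviation from trap centre).
#' @param seed Integer seed; fixes the track completely.
#' @return A data frame of class `bead_track` with columns `t_s`, `x_um` and
#'   attributes `frame_rate` (Hz) and `params`.
#' @examples
#' trk <- simulate_trapped_bead(seed = 1)
#' var(trk$x_um)            # ~ k_B T / k
#' @export
simulate_trapped_bead <- function(stiffness = 7.29, temperature = 296.15,
                                  drag = stokes_drag(), dt = 1e-3,
                                  n_frames = 10000L, x0 = 0, seed = 1L) {
  .check_positive(stiffness, "stiffness")
  .check_nonneg(temperature, "temperature")
  .check_positive(drag, "drag")
  .check_positive(dt, "dt")
  n_frames <- .check_count(n_frames, "n_frames", min = 2L)
  if (!.is_num(x0)) stop("`x0` must be a single finite number", call. = FALSE)

  tau <- drag / stiffness
  a <- exp(-dt / tau)
  svar <- .kB * temperature / stiffness     # stationary variance, um^2
  x <- .with_seed(seed, {
    innov <- if (svar > 0) {
      stats::rnorm(n_frames - 1L, mean = 0, sd = sqrt(svar * (1 - a^2)))
    } else {
      numeric(n_frames - 1L)
    }
    # x_i = a^i x0 + sum_j a^(i-j) innov_j ; recursive filter does the sum.
    c(x0, x0 * a^seq_len(n_frames - 1L) +
        as.numeric(stats::filter(innov, a, method = "recursive")))
  })
  out <- data.frame(t_s = (seq_len(n_frames) - 1) * dt, x_um = x)
  class(out) <- c("bead_track", "data.frame")
  attr(out, "frame_rate") <- 1 / dt
  attr(out, "params") <- list(stiffness = stiffness, temperature = temperature,
                              drag = drag, dt = dt, n_frames = n_frames,
                              x0 = x0, seed = seed)
  out
}

#' Simulate a tether-pulling experiment
#'
#' The stage moves at constant `speed` away from the stationary trap after a
#' stationary dwell; the membrane tether is modelled as a Hookean spring of
#' stiffness `tether_stiffness` in series with the trap, so the bead
#' displacement solves the force balance
#' `k * dx = k_t * (stage - dx)`, i.e. `dx = stage * k_t / (k + k_t)`.
#' Optional Gaussian position noise emulates tracking error. The tether model
#' is a deliberate stand-in: the experimental record specifies only the pull
#' speed and that the first part of the force-extension curve is linear.
#'
#' @param trap_stiffness Trap stiffness k in pN/um.
#' @param tether_stiffness Tether stiffness k_t in pN/um (0 = no tether).
#' @param speed Stage speed in um/s (>= 0).
#' @param duration Total record length in s.
#' @param dt Sampling interval in s (default 10 ms, the tether-pull camera
#'   interval).
#' @param noise_sd Gaussian position noise SD in um.
#' @param dwell Pre-pull stationary time in s (gives the force-extension
#'   baseline window support).
#' @param seed Integer seed.
#' @return List with `bead` (a `bead_track`: `x_um` is the bead displacement
#'   from the trap centre), `stage` (a `stage_track` with `t_s`, `stage_um`),
#'   and the ground-truth `tether_stiffness`, `trap_stiffness`, `dwell`.
#' @export
simulate_tether_pull <- function(trap_stiffness = 7.29, tether_stiffness = 10,
                                 speed = 1, duration = 10, dt = 0.01,
                                 noise_sd = 0, dwell = 0.5, seed = 1L) {
  .check_positive(trap_stiffness, "trap_stiffness")
  .check_nonneg(tether_stiffness, "tether_stiffness")
  .check_nonneg(speed, "speed")
  .check_positive(duration, "duration")
  .check_positive(dt, "dt")
  .check_nonneg(noise_sd, "noise_sd")
  .check_nonneg(dwell, "dwell")

  t_s <- seq(0, duration, by = dt)
  stage <- speed * pmax(t_s - dwell, 0)
  dx <- stage * tether_stiffness / (trap_stiffness + tether_stiffness)
  if (noise_sd > 0) {
    dx <- dx + .with_seed(seed, stats::rnorm(length(dx), 0, noise_sd))
  }
  bead <- data.frame(t_s = t_s, x_um = dx)
  class(bead) <- c("bead_track", "data.frame")
  attr(bead, "frame_rate") <- 1 / dt
  stage_df <- data.frame(t_s = t_s, stage_um = stage)
  class(stage_df) <- c("stage_track", "data.frame")
  list(bead = bead, stage = stage_df,
       tether_stiffness = tether_stiffness, trap_stiffness = trap_stiffness,
       dwell = dwell)
}

# Rasterize a filled rotated ellipse over pixel centres. Coordinates are
# 0-based row/col pixel centres: x_um = col0 * pixel_size, y_um = row0 *
# pixel_size. Returns a logical matrix of `shape`.
.raster_ellipse <- function(shape, center_um, semi_um, theta, pixel_size) {
  a <- semi_um[1]; b <- semi_um[2]
  r_max <- max(a, b) / pixel_size
  cr <- center_um[2] / pixel_size  # row index (0-based) of centre (y)
  cc <- center_um[1] / pixel_size  # col index (x)
  rows <- max(1L, floor(cr - r_max)):min(shape[1], ceiling(cr + r_max) + 2L)
  cols <- max(1L, floor(cc - r_max)):min(shape[2], ceiling(cc + r_max) + 2L)
  y <- (rows - 1) * pixel_size - center_um[2]
  x <- (cols - 1) * pixel_size - center_um[1]
  X <- matrix(x, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  Y <- matrix(y, nrow = length(rows), ncol = length(cols))
  u <- cos(theta) * X + sin(theta) * Y
  v <- -sin(theta) * X + cos(theta) * Y
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m <- matrix(FALSE, shape[1], shape[2])
  m[rows, cols] <- inside
  m
}

#' Specify one cell of a synthetic field
#'
#' @param center Cell centre in um, `c(x, y)` (x along columns, y along rows,
#'   0-based pixel centres).
#' @param semi_axes Ellipse semi-axes in um, `c(a, b)`.
#' @param orientation Major-axis angle in radians.
#' @param nucleus_count Number of nuclei to place in the cell.
#' @param is_differentiated Logical MyHC-positivity flag.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(center, semi_axes, orientation = 0,
                      nucleus_count = 1L, is_differentiated = TRUE) {
  if (length(center) != 2L || !all(is.finite(center)))
    stop("`center` must be two finite numbers (um)", call. = FALSE)
  if (length(semi_axes) != 2L || any(semi_axes <= 0))
    stop("`semi_axes` must be two positive numbers (um)", call. = FALSE)
  nucleus_count <- .check_count(nucleus_count, "nucleus_count", min = 1L)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation),
                 nucleus_count = nucleus_count,
                 is_differentiated = isTRUE(is_differentiated)),
            class = "cell_spec")
}

#' Generate a synthetic multinucleated-cell field
#'
#' Rasterizes each cell as a filled ellipse into a label mask, places nucleus
#' centroids by rejection sampling inside an eroded copy of each cell's mask
#' (so centroid-to-label assignment is unambiguous), and renders a MyHC
#' immunofluorescence channel in which differentiated (MyHC+) cells are
#' bright. Ground-truth morphometry is computed from the specification by
#' direct counting and shipped with the fixture.
#'
#' @param cells List of [cell_spec()] objects. Cells must not overlap after
#'   rasterization and must fit inside the image.
#' @param image_shape Image size in pixels, `c(rows, cols)`.
#' @param pixel_size Pixel size in um/pixel.
#' @param background_level,cell_level MyHC channel intensities (a.u.) outside
#'   cells / inside MyHC+ cells. MyHC- cells stay at background level.
#' @param noise_sd Gaussian intensity noise SD (a.u.).
#' @param seed Integer seed.
#' @param config [morphometry_config()] used for the ground-truth summary.
#' @return List with `label_mask` (integer matrix, 0 = background), `nuclei`
#'   (data frame `x_px`, `y_px`, `true_label`; 0-based pixel-centre
#'   coordinates), `channel` (numeric matrix), `truth_cells` (per-cell table
#'   of nucleus counts, areas and aspect ratios), and `truth_summary`
#'   (fusion / elongation / differentiation percentages by direct counting).
#' @export
generate_syncytium_field <- function(cells, image_shape = c(400L, 400L),
                                     pixel_size = 0.5,
                                     background_level = 10, cell_level = 100,
                                     noise_sd = 0, seed = 1L,
                                     config = morphometry_config(
                                       pixel_size = pixel_size)) {
  .check_positive(pixel_size, "pixel_size")
  .check_nonneg(background_level, "background_level")
  .check_nonneg(cell_level, "cell_level")
  .check_nonneg(noise_sd, "noise_sd")
  if (length(cells) < 1L) stop("need at least one cell", call. = FALSE)
  cells <- lapply(cells, function(cl) {
    if (!inherits(cl, "cell_spec")) do.call(cell_spec, cl) else cl
  })
  shape <- as.integer(image_shape)

  label_mask <- matrix(0L, shape[1], shape[2])
  masks <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    m <- .raster_ellipse(shape, cl$center, cl$semi_axes, cl$orientation,
                         pixel_size)
    # precondition: the ellipse must fit strictly inside the image
    span <- max(cl$semi_axes)
    if (cl$center[1] - span < 0 || cl$center[2] - span < 0 ||
        cl$center[1] + span > (shape[2] - 1) * pixel_size ||
        cl$center[2] + span > (shape[1] - 1) * pixel_size) {
      stop(sprintf("cell %d does not fit inside the image", i), call. = FALSE)
    }
    if (!any(m)) stop(sprintf("cell %d rasterizes to zero pixels", i),
                      call. = FALSE)
    if (any(label_mask[m] != 0L)) {
      stop(sprintf("cell %d overlaps an earlier cell after rasterization", i),
           call. = FALSE)
    }
    label_mask[m] <- i
    masks[[i]] <- m
  }

  # Nuclei: uniform over pixels of the eroded cell mask (fallback to the full
  # mask when erosion empties a thin cell).
  nuclei <- .with_seed(seed, {
    out <- lapply(seq_along(cells), function(i) {
      er <- EBImage::erode(masks[[i]] * 1, EBImage::makeBrush(5, "disc"))
      px <- which(er > 0.5, arr.ind = TRUE)
      if (nrow(px) == 0L) px <- which(masks[[i]], arr.ind = TRUE)
      k <- cells[[i]]$nucleus_count
      idx <- px[sample.int(nrow(px), k, replace = nrow(px) < k), , drop = FALSE]
      data.frame(x_px = idx[, 2] - 1, y_px = idx[, 1] - 1, true_label = i)
    })
    do.call(rbind, out)
  })

  channel <- matrix(background_level, shape[1], shape[2])
  for (i in seq_along(cells)) {
    if (cells[[i]]$is_differentiated) channel[masks[[i]]] <- cell_level
  }
  if (noise_sd > 0) {
    channel <- channel + .with_seed(seed + 1L,
      matrix(stats::rnorm(length(channel), 0, noise_sd), shape[1], shape[2]))
    channel <- pmax(channel, 0)  # detector floor: no negative intensities
  }

  truth_cells <- data.frame(
    label = seq_along(cells),
    nucleus_count = vapply(cells, function(cl) cl$nucleus_count, integer(1)),
    area_px = vapply(masks, sum, numeric(1)),
    area_um2 = vapply(masks, sum, numeric(1)) * pixel_size^2,
    area_um2_analytic = vapply(cells, function(cl)
      pi * cl$semi_axes[1] * cl$semi_axes[2], numeric(1)),
    aspect_ratio = vapply(cells, function(cl)
      max(cl$semi_axes) / min(cl$semi_axes), numeric(1)),
    is_differentiated = vapply(cells, function(cl) cl$is_differentiated,
                               logical(1))
  )
  list(label_mask = label_mask, nuclei = nuclei, channel = channel,
       truth_cells = truth_cells,
       truth_summary = .truth_summary(truth_cells, config),
       pixel_size = pixel_size, seed = seed)
}

# Ground-truth field summary by direct counting over the per-cell truth
# table. Deliberately plain sums, independent of the morphometry module's
# index functions, so pipeline-vs-truth tests compare two routes.
.truth_summary <- function(tc, config) {
  d <- tc[tc$is_differentiated, , drop = FALSE]
  total_nuclei <- sum(tc$nucleus_count)
  data.frame(
    fusion_index = 100 *
      sum(d$nucleus_count[d$nucleus_count >= config$fusion_nuclei_threshold]) /
      sum(d$nucleus_count),
    elongation_index = 100 *
      sum(d$area_um2[d$aspect_ratio >= config$elongation_ar_threshold]) /
      sum(d$area_um2),
    differentiation_index = 100 * sum(d$nucleus_count) / total_nuclei,
    n_syncytia = nrow(d),
    n_nuclei_total = total_nuclei
  )
}

#' Draw a random non-overlapping field specification
#'
#' Convenience sampler used by the analysis drivers and tests: places 3-6
#' elliptical cells without overlap by bounded rejection sampling. Aspect
#' ratios are drawn away from the elongation decision boundary (uniform on
#' [1.3, 2.5] or [3.6, 5.5]) so the ground-truth elongation classification
#' is unambiguous under rasterization; minor semi-axes stay at 7-10 um
#' (realistic myotube half-widths, and wide enough that image-moment aspect
#' ratios are resolved at 0.5 um/px); nucleus counts straddle the fusion
#' thresholds.
#'
#' @param seed Integer seed.
#' @param image_shape,pixel_size As in [generate_syncytium_field()].
#' @param n_cells Number of cells (default drawn from 3:6).
#' @param p_differentiated Probability a cell is MyHC+.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A list of [cell_spec()] objects.
#' @export
random_field_cells <- function(seed, image_shape = c(400L, 400L),
                               pixel_size = 0.5, n_cells = NULL,
                               p_differentiated = 0.8, max_tries = 200L) {
  .with_seed(seed, {
    if (is.null(n_cells)) n_cells <- sample(3:6, 1)
    w_um <- (image_shape[2] - 1) * pixel_size
    h_um <- (image_shape[1] - 1) * pixel_size
    placed <- list()
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ar <- if (stats::runif(1) < 0.5) stats::runif(1, 1.3, 2.5)
              else stats::runif(1, 3.6, 5.5)
        b <- stats::runif(1, 7, 10)           # minor semi-axis, um
        a <- b * ar                           # major semi-axis, um
        ctr <- c(stats::runif(1, a + 2, w_um - a - 2),
                 stats::runif(1, a + 2, h_um - a - 2))
        # conservative non-overlap: centre separation > sum of major axes
        clear <- all(vapply(placed, function(p)
          sqrt(sum((p$center - ctr)^2)) > a + max(p$semi_axes) + 2,
          logical(1)))
        if (clear) {
          nk <- sample(c(1L, sample(2:30, 1), sample(40:80, 1)), 1,
                       prob = c(0.3, 0.4, 0.3))
          placed[[length(placed) + 1L]] <- cell_spec(
            center = ctr, semi_axes = c(a, b),
            orientation = stats::runif(1, 0, pi),
            nucleus_count = nk,
            is_differentiated = stats::runif(1) < p_differentiated)
          ok <- TRUE
          break
        }
      }
      if (!ok) break  # field is simply less crowded
    }
    if (length(placed) == 0L)
      stop("could not place any cell; image too small", call. = FALSE)
    # a field selected for analysis always contains a MyHC+ object
    if (!any(vapply(placed, function(p) p$is_differentiated, logical(1)))) {
      placed[[1]]$is_differentiated <- TRUE
    }
    placed
  })
}

#' Generate a synthetic cortical-enrichment image
#'
#' One elliptical cell whose pixels within `cortex_depth` of the cell edge
#' (Euclidean distance transform) take `cortex_level` and whose interior
#' takes `interior_level`, plus optional Gaussian noise; background is 0.
#' Emulates peripheral F-actin / NMIIA accumulation imaged in a single
#' optical section.
#'
#' @param image_shape Image size in pixels `c(rows, cols)`.
#' @param pixel_size um/pixel.
#' @param center,semi_axes,orientation Cell geometry (um / radians).
#' @param cortex_depth Cortical band depth in um; must be smaller than the
#'   minor semi-axis.
#' @param cortex_level,interior_level Intensities (a.u., >= 0).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param seed Integer seed.
#' @return List with `mask` (logical matrix), `image` (numeric matrix) and
#'   the generating parameters.
#' @export
generate_cortical_image <- function(image_shape = c(200L, 200L),
                                    pixel_size = 0.5,
                                    center = c(50, 50), semi_axes = c(40, 25),
                                    orientation = 0, cortex_depth = 1.5,
                                    cortex_level = 100, interior_level = 20,
                                    noise_sd = 0, seed = 1L) {
  .check_positive(pixel_size, "pixel_size")
  .check_positive(cortex_depth, "cortex_depth")
  .check_nonneg(cortex_level, "cortex_level")
  .check_nonneg(interior_level, "interior_level")
  .check_nonneg(noise_sd, "noise_sd")
  if (cortex_depth >= min(semi_axes)) {
    stop("`cortex_depth` must be smaller than the minor semi-axis",
         call. = FALSE)
  }
  shape <- as.integer(image_shape)
  mask <- .raster_ellipse(shape, center, semi_axes, orientation, pixel_size)
  if (!any(mask)) stop("cell rasterizes to zero pixels", call. = FALSE)
  d_um <- EBImage::distmap(mask * 1) * pixel_size  # distance to background
  img <- matrix(0, shape[1], shape[2])
  img[mask] <- ifelse(d_um[mask] <= cortex_depth, cortex_level, interior_level)
  if (noise_sd > 0) {
    img <- img + .with_seed(seed,
      matrix(stats::rnorm(length(img), 0, noise_sd), shape[1], shape[2]))
    img <- pmax(img, 0)  # detector floor: no negative intensities
  }
  list(mask = mask, image = img, pixel_size = pixel_size,
       cortex_depth = cortex_depth, cortex_level = cortex_level,
       interior_level = interior_level, seed = seed)
}

#' Generate a synthetic Fura2 ratio trace
#'
#' Baseline before agonist onset, then a saturating rise (optionally with
#' exponential decay back towards baseline). The response is normalized so
#' its peak equals `amplitude` exactly; the kinetic form is a generic
#' agonist-response shape, not taken from any measured trace. Default
#' sampling is every 10 s, the time-lapse interval used for ratiometric
#' calcium imaging.
#'
#' @param baseline Pre-stimulus ratio (F340/F380).
#' @param amplitude Peak response above baseline (0 = flat trace).
#' @param onset Agonist onset time in s; must not exceed `duration`.
#' @param rise Rise time constant in s.
#' @param decay Decay time constant in s; `Inf` (default) gives a sustained
#'   plateau.
#' @param sampling_interval Sampling interval in s.
#' @param duration Trace duration in s; samples are t = 0, dt, ..., duration.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A data frame of class `trace` with `t_s`, `value` and attribute
#'   `amplitude` (programmed ground truth).
#' @export
generate_fura2_trace <- function(baseline = 1.0, amplitude = 0.8, onset = 120,
                                 rise = 10, decay = Inf,
                                 sampling_interval = 10, duration = 600,
                                 noise_sd = 0, seed = 1L) {
  .check_positive(sampling_interval, "sampling_interval")
  if (duration < sampling_interval)
    stop("`duration` must be >= `sampling_interval`", call. = FALSE)
  .check_nonneg(amplitude, "amplitude")
  .check_positive(rise, "rise")
  .check_nonneg(noise_sd, "noise_sd")
  if (onset > duration) stop("`onset` lies beyond `duration`", call. = FALSE)

  t_s <- seq(0, duration, by = sampling_interval)
  s <- pmax(t_s - onset, 0)
  g <- (1 - exp(-s / rise))
  if (is.finite(decay)) {
    g <- g * exp(-s / decay)
    # peak of the continuous response, used to normalize to `amplitude`
    s_peak <- rise * log1p(decay / rise)
    g_peak <- (1 - exp(-s_peak / rise)) * exp(-s_peak / decay)
    g <- g / g_peak
  }
  value <- baseline + amplitude * g
  if (noise_sd > 0) {
    value <- value + .with_seed(seed, stats::rnorm(length(value), 0, noise_sd))
  }
  out <- data.frame(t_s = t_s, value = value)
  class(out) <- c("trace", "data.frame")
  attr(out, "amplitude") <- amplitude
  attr(out, "baseline") <- baseline
  out
}

#' Generate a bimodal intensity population
#'
#' Mixture of two log-normal components emulating negative and positive cell
#' populations in a flow-cytometry histogram (e.g. annexin V labelling). Each
#' cell is independently positive with probability `positive_fraction`.
#'
#' @param n_cells Number of cells.
#' @param positive_fraction Probability of the positive component, in [0, 1].
#' @param neg_meanlog,neg_sdlog Log-intensity parameters of the negative
#'   component.
#' @param pos_meanlog,pos_sdlog Log-intensity parameters of the positive
#'   component.
#' @param seed Integer seed.
#' @return Numeric intensity vector with attribute `is_positive` (logical
#'   ground-truth labels).
#' @export
generate_intensity_population <- function(n_cells = 10000L,
                                          positive_fraction = 0.2,
                                          neg_meanlog = log(100),
                                          neg_sdlog = 0.35,
                                          pos_meanlog = log(2000),
                                          pos_sdlog = 0.35, seed = 1L) {
  n_cells <- .check_count(n_cells, "n_cells", min = 1L)
  if (!.is_num(positive_fraction) || positive_fraction < 0 ||
      positive_fraction > 1) {
    stop("`positive_fraction` must be in [0, 1]", call. = FALSE)
  }
  .with_seed(seed, {
    pos <- stats::runif(n_cells) < positive_fraction
    x <- numeric(n_cells)
    x[!pos] <- stats::rlnorm(sum(!pos), neg_meanlog, neg_sdlog)
    x[pos] <- stats::rlnorm(sum(pos), pos_meanlog, pos_sdlog)
    attr(x, "is_positive") <- pos
    x
  })
}
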