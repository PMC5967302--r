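# Cortex-versus-cytoplasm enrichment score for peripheral actomyosin signal.
# The cell edge is divided into rectangles orthogonal to the periphery; in
# each rectangle's inward fluorescence profile the score takes the peak
# intensity within 0-5 um of the edge and the mean intensity 2-7 um deeper
# than the peak position, and averages peak/mean over all rectangles.

#' Cortical-profile configuration
#'
#' The 0-5 um peak band (from the cell edge) and the 2-7 um mean band (from
#' the peak position) are the published definition; rectangle geometry and
#' profile sampling are not specified there and default to values that fit
#' both bands with margin.
#'
#' @param peak_band Interval from the cell edge, um, searched for the peak.
#' @param mean_band Interval measured from the peak position, um, averaged
#'   for the cytoplasmic reference.
#' @param rectangle_width Width of each sampling rectangle along the
#'   boundary, um.
#' @param rectangle_spacing Spacing of rectangle anchors along the boundary,
#'   um.
#' @param profile_depth Inward profile depth, um; must cover
#'   `peak_band[2] + mean_band[2]`.
#' @param profile_step Profile sampling step, um.
#' @return A `cortical_config` list.
#' @export
cortical_config <- function(peak_band = c(0, 5), mean_band = c(2, 7),
                            rectangle_width = 1, rectangle_spacing = 2,
                            profile_depth = 12, profile_step = 0.2) {
  stopifnot(length(peak_band) == 2L, length(mean_band) == 2L)
  if (peak_band[1] < 0 || peak_band[1] >= peak_band[2])
    stop("`peak_band` must satisfy 0 <= start < end", call. = FALSE)
  if (mean_band[1] >= mean_band[2])
    stop("`mean_band` must satisfy start < end", call. = FALSE)
  .check_positive(rectangle_width, "rectangle_width")
  .check_positive(rectangle_spacing, "rectangle_spacing")
  .check_positive(profile_step, "profile_step")
  if (profile_depth < peak_band[2] + mean_band[2]) {
    stop("`profile_depth` must be at least peak_band end + mean_band end",
         call. = FALSE)
  }
  structure(list(peak_band = peak_band, mean_band = mean_band,
                 rectangle_width = rectangle_width,
                 rectangle_spacing = rectangle_spacing,
                 profile_depth = profile_depth, profile_step = profile_step),
            class = "cortical_config")
}

#' Sample anchors and inward normals along a mask boundary
#'
#' The outer contour (after hole filling) is resampled at approximately
#' equidistant arclength positions; at each anchor the inward normal is the
#' normalized gradient of the Euclidean distance transform of the mask
#' (robust at corners), sign-checked by probing the mask a small step inward.
#'
#' @param mask Logical or 0/1 matrix, a single cell.
#' @param pixel_size um/pixel.
#' @param spacing Anchor spacing along the boundary, um.
#' @param phase Arclength offset of the first anchor, um (used to test
#'   stability under contour re-sampling).
#' @return Data frame with `anchor_row0`, `anchor_col0` (0-based pixel
#'   coordinates, possibly fractional) and unit inward normal components
#'   `n_row`, `n_col`; attribute `perimeter_um`.
#' @export
boundary_samples <- function(mask, pixel_size, spacing = 2, phase = 0) {
  .check_positive(pixel_size, "pixel_size")
  .check_positive(spacing, "spacing")
  m <- EBImage::fillHull((mask != 0) * 1)
  if (sum(m) == 0L) stop("empty mask", call. = FALSE)
  ctr <- EBImage::ocontour(m)
  ctr <- ctr[[which.max(vapply(ctr, nrow, integer(1)))]]  # outer contour
  # ocontour returns 0-based (dim1, dim2) = (row0, col0) for a matrix input
  pts <- rbind(ctr, ctr[1, , drop = FALSE])  # close the polygon
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2)) * pixel_size
  s_cum <- c(0, cumsum(seg))
  perimeter <- s_cum[length(s_cum)]
  if (perimeter < spacing) {
    stop("mask perimeter smaller than one anchor spacing", call. = FALSE)
  }
  s_anchor <- seq(phase %% spacing, perimeter - 1e-9, by = spacing)
  # linear interpolation along the closed contour
  idx <- findInterval(s_anchor, s_cum, rightmost.closed = TRUE)
  frac <- (s_anchor - s_cum[idx]) / pmax(seg[idx], 1e-12)
  anchor <- pts[idx, , drop = FALSE] * (1 - frac) +
    pts[idx + 1L, , drop = FALSE] * frac

  # inward normals from the gradient of the (Gaussian-regularized) Euclidean
  # distance transform; smoothing tames the staircase of the raster contour
  D <- EBImage::gblur(EBImage::distmap(m), sigma = 2)
  grad_at <- function(r0, c0) {
    r <- round(r0) + 1L; c <- round(c0) + 1L
    rp <- min(r + 1L, nrow(D)); rm <- max(r - 1L, 1L)
    cp <- min(c + 1L, ncol(D)); cm <- max(c - 1L, 1L)
    c(D[rp, c] - D[rm, c], D[r, cp] - D[r, cm])
  }
  centroid <- c(mean(which(m > 0, arr.ind = TRUE)[, 1]) - 1,
                mean(which(m > 0, arr.ind = TRUE)[, 2]) - 1)
  normals <- t(vapply(seq_len(nrow(anchor)), function(i) {
    g <- grad_at(anchor[i, 1], anchor[i, 2])
    if (sqrt(sum(g^2)) < 1e-9) g <- centroid - anchor[i, ]  # flat spot
    g <- g / sqrt(sum(g^2))
    # sign check: step inward and probe the mask
    for (step in c(1.5, 3, 5)) {
      p <- anchor[i, ] + step * g
      r <- round(p[1]) + 1L; c <- round(p[2]) + 1L
      if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m)) {
        if (m[r, c] > 0) return(g)
        p2 <- anchor[i, ] - step * g
        r2 <- round(p2[1]) + 1L; c2 <- round(p2[2]) + 1L
        if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m) &&
            m[r2, c2] > 0) {
          return(-g)
        }
      }
    }
    g
  }, numeric(2)))
  out <- data.frame(anchor_row0 = anchor[, 1], anchor_col0 = anchor[, 2],
                    n_row = normals[, 1], n_col = normals[, 2])
  attr(out, "perimeter_um") <- perimeter
  out
}

# Mask-aware bilinear interpolation at fractional 0-based (row0, col0)
# points. Weights of out-of-mask or out-of-image neighbours are dropped and
# the remainder renormalized; a point keeping less than `min_weight` of its
# bilinear mass is NA (treated as outside the mask). Keeps profiles of
# uniform cells exactly flat up to the cell edge.
.mask_bilinear <- function(image, mask, row0, col0, min_weight = 0.25) {
  nr <- nrow(image); nc <- ncol(image)
  r1 <- floor(row0); c1 <- floor(col0)
  fr <- row0 - r1; fc <- col0 - c1
  val <- numeric(length(row0))
  for (q in seq_along(row0)) {
    rr <- c(r1[q], r1[q] + 1, r1[q], r1[q] + 1) + 1L
    cc <- c(c1[q], c1[q], c1[q] + 1, c1[q] + 1) + 1L
    w <- c((1 - fr[q]) * (1 - fc[q]), fr[q] * (1 - fc[q]),
           (1 - fr[q]) * fc[q], fr[q] * fc[q])
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ok[ok] <- mask[cbind(rr[ok], cc[ok])] > 0
    if (sum(w[ok]) < min_weight) {
      val[q] <- NA_real_
    } else {
      val[q] <- sum(w[ok] * image[cbind(rr[ok], cc[ok])]) / sum(w[ok])
    }
  }
  val
}

#' Inward fluorescence profile of one boundary rectangle
#'
#' Intensities are averaged across the rectangle's width at each inward
#' distance, using mask-aware bilinear interpolation; sample points falling
#' outside the mask are excluded rather than zero-filled.
#'
#' @param image Intensity matrix.
#' @param mask Logical or 0/1 matrix.
#' @param anchor Numeric `c(row0, col0)`, 0-based pixel coordinates on the
#'   boundary.
#' @param normal Unit inward normal `c(n_row, n_col)`.
#' @param pixel_size um/pixel.
#' @param config [cortical_config()].
#' @return Data frame with `distance_um` (0 to `profile_depth` in steps of
#'   `profile_step`) and `intensity` (NA where the whole width falls outside
#'   the mask).
#' @export
edge_profile <- function(image, mask, anchor, normal, pixel_size,
                         config = cortical_config()) {
  .check_positive(pixel_size, "pixel_size")
  nl <- sqrt(sum(normal^2))
  if (abs(nl - 1) > 1e-6) stop("`normal` must be unit length", call. = FALSE)
  d_um <- seq(0, config$profile_depth, by = config$profile_step)
  tangent <- c(-normal[2], normal[1])
  n_w <- max(3L, ceiling(config$rectangle_width / (0.5 * pixel_size)) + 1L)
  w_um <- seq(-config$rectangle_width / 2, config$rectangle_width / 2,
              length.out = n_w)
  intensity <- vapply(d_um, function(d) {
    r0 <- anchor[1] + (d / pixel_size) * normal[1] +
      (w_um / pixel_size) * tangent[1]
    c0 <- anchor[2] + (d / pixel_size) * normal[2] +
      (w_um / pixel_size) * tangent[2]
    v <- .mask_bilinear(image, (mask != 0) * 1, r0, c0)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(distance_um = d_um, intensity = intensity)
}

#' Cortex/cytoplasm enrichment ratio of a cell
#'
#' For every valid boundary rectangle: peak = maximum profile intensity at
#' distances within `peak_band` of the edge; mean = mean profile intensity
#' between `mean_band[1]` and `mean_band[2]` um deeper than the peak
#' position; the score is the average of peak/mean over rectangles.
#' Rectangles whose peak or mean band lies entirely outside the mask are
#' flagged invalid and excluded; rectangles with non-positive mean are
#' excluded with a count.
#'
#' @param image Intensity matrix.
#' @param mask Logical or 0/1 matrix for the cell.
#' @param pixel_size um/pixel.
#' @param config [cortical_config()].
#' @param phase Arclength offset of the first rectangle, um.
#' @return List with `ratio`, `n_rectangles_used`, `n_invalid`,
#'   `n_zero_mean` and `rectangles` (per-rectangle data frame with anchor,
#'   peak, peak position, mean, ratio).
#' @export
cortex_cytoplasm_ratio <- function(image, mask, pixel_size,
                                   config = cortical_config(), phase = 0) {
  anchors <- boundary_samples(mask, pixel_size,
                              spacing = config$rectangle_spacing,
                              phase = phase)
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    prof <- edge_profile(image, mask,
                         anchor = c(anchors$anchor_row0[i],
                                    anchors$anchor_col0[i]),
                         normal = c(anchors$n_row[i], anchors$n_col[i]),
                         pixel_size = pixel_size, config = config)
    in_peak <- prof$distance_um >= config$peak_band[1] &
      prof$distance_um <= config$peak_band[2] & !is.na(prof$intensity)
    if (!any(in_peak)) {
      return(data.frame(anchor_row0 = anchors$anchor_row0[i],
                        anchor_col0 = anchors$anchor_col0[i],
                        peak = NA_real_, peak_position_um = NA_real_,
                        mean = NA_real_, ratio = NA_real_,
                        status = "invalid"))
    }
    pk_idx <- which(in_peak)[which.max(prof$intensity[in_peak])]
    pk <- prof$intensity[pk_idx]
    d_pk <- prof$distance_um[pk_idx]
    in_mean <- prof$distance_um >= d_pk + config$mean_band[1] &
      prof$distance_um <= d_pk + config$mean_band[2] & !is.na(prof$intensity)
    if (!any(in_mean)) {
      return(data.frame(anchor_row0 = anchors$anchor_row0[i],
                        anchor_col0 = anchors$anchor_col0[i],
                        peak = pk, peak_position_um = d_pk,
                        mean = NA_real_, ratio = NA_real_,
                        status = "invalid"))
    }
    mn <- mean(prof$intensity[in_mean])
    status <- if (mn <= 0) "zero_mean" else "ok"
    data.frame(anchor_row0 = anchors$anchor_row0[i],
               anchor_col0 = anchors$anchor_col0[i],
               peak = pk, peak_position_um = d_pk, mean = mn,
               ratio = if (mn > 0) pk / mn else NA_real_,
               status = status)
  })
  rect <- do.call(rbind, rows)
  used <- rect$status == "ok"
  if (!any(used)) stop("no valid boundary rectangles", call. = FALSE)
  n_zero <- sum(rect$status == "zero_mean")
  if (n_zero > 0L) {
    warning(sprintf("%d rectangle(s) excluded for non-positive mean", n_zero))
  }
  list(ratio = mean(rect$ratio[used]),
       n_rectangles_used = sum(used),
       n_invalid = sum(rect$status == "invalid"),
       n_zero_mean = n_zero,
       rectangles = rect)
}
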