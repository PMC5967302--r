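# Per-syncytium morphometry and the three field-level indices used to score
# myotube formation: fusion (nuclei in large multinucleate MyHC+ cells over
# all MyHC+ nuclei), polarized elongation (area of MyHC+ cells with aspect
# ratio >= 3 over total MyHC+ area) and differentiation (MyHC+ nuclei over
# all nuclei in the field).

#' Morphometry configuration
#'
#' @param fusion_nuclei_threshold Minimum nucleus count for a syncytium to
#'   count as "fused" in the fusion index. Published datasets use 16 (human
#'   primary myoblasts), 26 (mouse primary myoblasts) or 50 (C2C12 cells).
#' @param elongation_ar_threshold Aspect-ratio threshold for the polarized
#'   elongation index (default 3).
#' @param pixel_size Pixel size in um/pixel.
#' @param myhc_threshold Intensity threshold classifying a labelled object as
#'   MyHC+ from the mean of the MyHC channel within the object; `NULL` means
#'   all objects are treated as MyHC+ (or the caller supplies flags).
#' @param multinucleated_only If `TRUE`, restrict the elongation index to
#'   multinucleated (>= 2 nuclei) MyHC+ objects. The published definition
#'   does not say; default is every MyHC+ object.
#' @return A `morphometry_config` list.
#' @export
morphometry_config <- function(fusion_nuclei_threshold = 16L,
                               elongation_ar_threshold = 3,
                               pixel_size = 1,
                               myhc_threshold = NULL,
                               multinucleated_only = FALSE) {
  .check_count(fusion_nuclei_threshold, "fusion_nuclei_threshold", min = 1L)
  .check_positive(elongation_ar_threshold, "elongation_ar_threshold")
  .check_positive(pixel_size, "pixel_size")
  structure(list(fusion_nuclei_threshold = as.integer(fusion_nuclei_threshold),
                 elongation_ar_threshold = elongation_ar_threshold,
                 pixel_size = pixel_size,
                 myhc_threshold = myhc_threshold,
                 multinucleated_only = isTRUE(multinucleated_only)),
            class = "morphometry_config")
}

#' Area, best-fit-ellipse aspect ratio and centroid of a mask region
#'
#' The best-fit ellipse is defined by the second central moments of the
#' filled region: its axes are `4 * sqrt(eigenvalues)` of the pixel-coordinate
#' covariance (the standard image-moments convention, which reproduces the
#' semi-axes of an ideal filled ellipse), and the aspect ratio is the
#' major/minor axis ratio. Area is the pixel count times `pixel_size^2`.
#'
#' @param region Logical or numeric matrix; non-zero pixels form the region.
#' @param pixel_size um/pixel.
#' @return List with `area_um2`, `aspect_ratio` (>= 1), `centroid_um`
#'   (`c(x, y)`, 0-based pixel-centre convention), `major_um`, `minor_um`
#'   (full axis lengths).
#' @examples
#' m <- matrix(FALSE, 50, 50); m[10:40, 20:30] <- TRUE
#' ellipse_metrics(m, pixel_size = 1)$aspect_ratio
#' @export
ellipse_metrics <- function(region, pixel_size = 1) {
  .check_positive(pixel_size, "pixel_size")
  px <- which(region != 0, arr.ind = TRUE)
  n <- nrow(px)
  if (is.null(n) || n == 0L) stop("empty region", call. = FALSE)
  col0 <- px[, 2] - 1  # x
  row0 <- px[, 1] - 1  # y
  centroid <- c(mean(col0), mean(row0)) * pixel_size
  # population (divide-by-n) second central moments with the standard
  # pixel-spread correction (+1/12 per axis: each pixel is a unit square,
  # not a point mass)
  cxx <- mean((col0 - mean(col0))^2) + 1 / 12
  cyy <- mean((row0 - mean(row0))^2) + 1 / 12
  cxy <- mean((col0 - mean(col0)) * (row0 - mean(row0)))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  aspect <- if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) {
    if (ev[1] <= .Machine$double.eps) 1 else Inf
  } else {
    sqrt(ev[1] / ev[2])
  }
  list(area_um2 = n * pixel_size^2,
       aspect_ratio = aspect,
       centroid_um = centroid,
       major_um = 4 * sqrt(ev[1]) * pixel_size,
       minor_um = 4 * sqrt(ev[2]) * pixel_size)
}

#' Assign nucleus centroids to labelled objects
#'
#' Each centroid is assigned to the label of the pixel containing it
#' (0-based pixel-centre coordinates; the containing pixel is the nearest
#' pixel centre). Centroids on background are counted as unassigned, never
#' silently dropped.
#'
#' @param label_mask Integer matrix, 0 = background.
#' @param nuclei Data frame with columns `x_px`, `y_px` (0-based pixel
#'   coordinates: x along columns, y along rows).
#' @return List with `counts` (named integer vector over every label present
#'   in the mask, including zero-count labels), `unassigned` (count of
#'   background centroids) and `assignments` (per-nucleus label vector).
#' @export
assign_nuclei <- function(label_mask, nuclei) {
  stopifnot(is.matrix(label_mask), is.data.frame(nuclei),
            all(c("x_px", "y_px") %in% names(nuclei)))
  if (nrow(nuclei) == 0L) {
    labs <- sort(unique(label_mask[label_mask != 0]))
    return(list(counts = stats::setNames(integer(length(labs)), labs),
                unassigned = 0L, assignments = integer(0)))
  }
  rows <- round(nuclei$y_px) + 1
  cols <- round(nuclei$x_px) + 1
  bad <- which(rows < 1 | rows > nrow(label_mask) |
               cols < 1 | cols > ncol(label_mask) |
               !is.finite(rows) | !is.finite(cols))
  if (length(bad) > 0L) {
    stop(sprintf("nucleus centroid(s) outside image bounds at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  assignments <- label_mask[cbind(rows, cols)]
  labs <- sort(unique(label_mask[label_mask != 0]))
  counts <- vapply(labs, function(l) sum(assignments == l), integer(1))
  list(counts = stats::setNames(counts, labs),
       unassigned = sum(assignments == 0L),
       assignments = assignments)
}

# Shared guard: records table with required columns.
.check_records <- function(records, cols) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(cols, names(records))
  if (length(miss) > 0L) {
    stop("`records` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Fusion index of a microscopic field
#'
#' Percentage of nuclei residing in multinucleate MyHC+ cells containing at
#' least `fusion_nuclei_threshold` nuclei, over the total number of nuclei in
#' MyHC+ cells. MyHC- records are excluded from numerator and denominator.
#'
#' @param records Data frame of per-syncytium records with columns
#'   `nucleus_count` and `is_differentiated`.
#' @param config [morphometry_config()].
#' @return Fusion index in percent.
#' @examples
#' r <- data.frame(nucleus_count = c(60, 10, 5), is_differentiated = TRUE)
#' fusion_index(r, morphometry_config(fusion_nuclei_threshold = 50))  # 80
#' @export
fusion_index <- function(records, config = morphometry_config()) {
  .check_records(records, c("nucleus_count", "is_differentiated"))
  d <- records[records$is_differentiated, , drop = FALSE]
  denom <- sum(d$nucleus_count)
  if (denom <= 0) {
    stop("fusion index undefined: no nuclei in MyHC+ cells", call. = FALSE)
  }
  100 * sum(d$nucleus_count[d$nucleus_count >=
                              config$fusion_nuclei_threshold]) / denom
}

#' Polarized elongation index of a microscopic field
#'
#' Percentage of the summed area of MyHC+ cells with best-fit-ellipse aspect
#' ratio at least `elongation_ar_threshold`, over the total MyHC+ area.
#'
#' @param records Data frame with columns `area_um2`, `aspect_ratio`,
#'   `is_differentiated` (and `nucleus_count` if
#'   `config$multinucleated_only`).
#' @param config [morphometry_config()].
#' @return Elongation index in percent.
#' @export
elongation_index <- function(records, config = morphometry_config()) {
  .check_records(records, c("area_um2", "aspect_ratio", "is_differentiated"))
  d <- records[records$is_differentiated, , drop = FALSE]
  if (config$multinucleated_only) {
    .check_records(records, "nucleus_count")
    d <- d[d$nucleus_count >= 2L, , drop = FALSE]
  }
  denom <- sum(d$area_um2)
  if (denom <= 0) {
    stop("elongation index undefined: zero MyHC+ area", call. = FALSE)
  }
  100 * sum(d$area_um2[d$aspect_ratio >= config$elongation_ar_threshold]) /
    denom
}

#' Differentiation index of a microscopic field
#'
#' Percentage of nuclei in MyHC+ cells over the total number of nuclei in the
#' field (including nuclei outside MyHC+ cells).
#'
#' @param records Data frame with columns `nucleus_count`,
#'   `is_differentiated`.
#' @param total_nuclei_in_field Total nuclei counted in the field (> 0).
#' @return Differentiation index in percent.
#' @export
differentiation_index <- function(records, total_nuclei_in_field) {
  .check_records(records, c("nucleus_count", "is_differentiated"))
  if (!.is_num(total_nuclei_in_field) || total_nuclei_in_field <= 0) {
    stop("differentiation index undefined: zero total nuclei", call. = FALSE)
  }
  100 * sum(records$nucleus_count[records$is_differentiated]) /
    total_nuclei_in_field
}

#' Summarize one field's indices
#'
#' @inheritParams differentiation_index
#' @param config [morphometry_config()].
#' @return One-row data frame: `fusion_index`, `elongation_index`,
#'   `differentiation_index`, `n_syncytia` (MyHC+ objects),
#'   `n_nuclei_total`.
#' @export
field_summary <- function(records, total_nuclei_in_field,
                          config = morphometry_config()) {
  data.frame(
    fusion_index = fusion_index(records, config),
    elongation_index = elongation_index(records, config),
    differentiation_index = differentiation_index(records,
                                                  total_nuclei_in_field),
    n_syncytia = sum(records$is_differentiated),
    n_nuclei_total = total_nuclei_in_field
  )
}

#' Full morphometry of one field from a label mask and nuclei centroids
#'
#' Builds per-syncytium records (nucleus counts by centroid containment,
#' areas and aspect ratios by image moments, MyHC status from the mean MyHC
#' channel intensity within each object when a channel is supplied) and the
#' field-level index summary.
#'
#' @param label_mask Integer matrix, 0 = background.
#' @param nuclei Data frame `x_px`, `y_px` (0-based pixel coordinates).
#' @param config [morphometry_config()]; `config$pixel_size` converts areas.
#' @param channel Optional MyHC channel matrix; objects with mean in-object
#'   intensity >= `config$myhc_threshold` are MyHC+. Without a channel all
#'   objects are MyHC+.
#' @return List with `records` (per-syncytium data frame), `summary`
#'   (from [field_summary()], total nuclei = `nrow(nuclei)`) and
#'   `n_unassigned` (nuclei on background).
#' @export
analyze_field <- function(label_mask, nuclei, config = morphometry_config(),
                          channel = NULL) {
  asn <- assign_nuclei(label_mask, nuclei)
  labs <- as.integer(names(asn$counts))
  recs <- lapply(seq_along(labs), function(i) {
    l <- labs[i]
    em <- ellipse_metrics(label_mask == l, config$pixel_size)
    diff_flag <- if (is.null(channel)) {
      TRUE
    } else {
      if (is.null(config$myhc_threshold)) {
        stop("supply `myhc_threshold` in the config to classify from a channel",
             call. = FALSE)
      }
      mean(channel[label_mask == l]) >= config$myhc_threshold
    }
    data.frame(label = l, nucleus_count = asn$counts[[i]],
               area_um2 = em$area_um2, aspect_ratio = em$aspect_ratio,
               centroid_x_um = em$centroid_um[1],
               centroid_y_um = em$centroid_um[2],
               is_differentiated = diff_flag)
  })
  records <- do.call(rbind, recs)
  list(records = records,
       summary = field_summary(records, nrow(nuclei), config),
       n_unassigned = asn$unassigned)
}
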