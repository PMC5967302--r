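# Fixture builders shared across test files. The ellipse rasterizer here is
# an independent re-implementation (direct inequality over all pixels, no
# bounding box, 1-based centre convention converted explicitly) used as an
# oracle against the package's generators.

oracle_ellipse_mask <- function(nrow, ncol, center_rc, semi_px, theta = 0) {
  rc <- expand.grid(row = seq_len(nrow), col = seq_len(ncol))
  x <- rc$col - center_rc[2]
  y <- rc$row - center_rc[1]
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  matrix((u / semi_px[1])^2 + (v / semi_px[2])^2 <= 1, nrow, ncol)
}

# Three-cell field with nucleus counts chosen so the fusion index at a
# >= 50 threshold is 80% by direct enumeration (60 of 75 MyHC+ nuclei).
three_cell_field <- function(seed = 1, noise_sd = 0) {
  generate_syncytium_field(
    cells = list(
      cell_spec(center = c(40, 40), semi_axes = c(30, 8),
                orientation = 0.3, nucleus_count = 60),
      cell_spec(center = c(115, 40), semi_axes = c(20, 12),
                orientation = 1.2, nucleus_count = 10),
      cell_spec(center = c(60, 115), semi_axes = c(25, 6),
                orientation = 2.0, nucleus_count = 5)
    ),
    image_shape = c(320L, 320L), pixel_size = 0.5,
    noise_sd = noise_sd, seed = seed,
    config = morphometry_config(fusion_nuclei_threshold = 50L,
                                pixel_size = 0.5)
  )
}

# Cortical ring cell: minor semi-axis comfortably deeper than the default
# 12-um profile depth so every rectangle's bands stay inside the mask.
ring_cell <- function(cortex_level = 100, interior_level = 20,
                      cortex_depth = 1.5, noise_sd = 0, seed = 1) {
  generate_cortical_image(
    image_shape = c(220L, 220L), pixel_size = 0.5,
    center = c(52, 52), semi_axes = c(45, 32),
    orientation = 0.4, cortex_depth = cortex_depth,
    cortex_level = cortex_level, interior_level = interior_level,
    noise_sd = noise_sd, seed = seed
  )
}
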