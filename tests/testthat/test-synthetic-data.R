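# Generators: exactness of the Ornstein-Uhlenbeck discretization, tether
# spring algebra, field/cortical/trace/population ground-truth bookkeeping,
# and seed-determinism of every generator.

test_that("trapped-bead simulation is noiseless at T = 0 and seed-deterministic", {
  trk <- simulate_trapped_bead(temperature = 0, x0 = 0, n_frames = 500,
                               seed = 3)
  expect_true(all(trk$x_um == 0))

  a <- simulate_trapped_bead(n_frames = 2000, seed = 11)
  b <- simulate_trapped_bead(n_frames = 2000, seed = 11)
  expect_identical(a$x_um, b$x_um)
  expect_false(identical(
    a$x_um, simulate_trapped_bead(n_frames = 2000, seed = 12)$x_um))
})

test_that("trapped-bead sample variance matches equipartition closed form", {
  # dt = 0.1 s >> tau ~ 2 ms: samples effectively independent, so the SE of
  # the sample variance is var * sqrt(2 / n).
  k <- 7.29; temp <- 298.15; n <- 1e5
  trk <- simulate_trapped_bead(stiffness = k, temperature = temp, dt = 0.1,
                               n_frames = n, seed = 42)
  v_expected <- 1.380649e-5 * temp / k     # ~5.65e-4 um^2
  se <- v_expected * sqrt(2 / n)
  expect_lt(abs(var(trk$x_um) - v_expected), 3 * se)
  expect_lt(abs(mean(trk$x_um)), 3 * sqrt(v_expected / n))
})

test_that("trapped-bead lag autocorrelation decays as exp(-k dt / gamma)", {
  gam <- stokes_drag()
  k <- 7.29; dt <- 1e-3
  trk <- simulate_trapped_bead(stiffness = k, drag = gam, dt = dt,
                               n_frames = 5e4, seed = 5)
  x <- trk$x_um
  for (lag in 1:3) {
    r_hat <- cor(x[seq_len(length(x) - lag)], x[-seq_len(lag)])
    expect_equal(r_hat, exp(-k * lag * dt / gam), tolerance = 0.05)
  }
})

test_that("trapped-bead simulation rejects invalid parameters", {
  expect_error(simulate_trapped_bead(stiffness = 0), "stiffness")
  expect_error(simulate_trapped_bead(dt = -1), "dt")
  expect_error(simulate_trapped_bead(drag = 0), "drag")
  expect_error(simulate_trapped_bead(n_frames = 1), "n_frames")
})

test_that("tether pull obeys the series-spring balance", {
  # no tether: bead never moves
  tp0 <- simulate_tether_pull(tether_stiffness = 0, noise_sd = 0)
  expect_true(all(tp0$bead$x_um == 0))

  # k = k_t = 10: force vs stage displacement has slope k k_t/(k+k_t) = 5
  tp <- simulate_tether_pull(trap_stiffness = 10, tether_stiffness = 10,
                             noise_sd = 0)
  moving <- tp$stage$stage_um > 0
  force <- 10 * tp$bead$x_um
  fit <- lm(force[moving] ~ tp$stage$stage_um[moving])
  expect_equal(unname(coef(fit)[2]), 5, tolerance = 1e-12)

  # force vs tether extension (stage - dx) has slope k_t for any stiffnesses
  tp2 <- simulate_tether_pull(trap_stiffness = 7.29, tether_stiffness = 3.1,
                              noise_sd = 0)
  ext <- tp2$stage$stage_um - tp2$bead$x_um
  f2 <- 7.29 * tp2$bead$x_um
  fit2 <- lm(f2[ext > 0] ~ ext[ext > 0])
  expect_equal(unname(coef(fit2)[2]), 3.1, tolerance = 1e-10)

  expect_error(simulate_tether_pull(speed = -1), "speed")
})

test_that("syncytium field ships exact ground truth and valid nuclei", {
  fld <- three_cell_field(seed = 7)
  expect_equal(fld$truth_summary$fusion_index, 80)       # 60 / 75
  expect_equal(fld$truth_summary$n_nuclei_total, 75)
  expect_equal(fld$truth_cells$aspect_ratio,
               c(30 / 8, 20 / 12, 25 / 6))

  # every nucleus centroid sits on a pixel of its own cell
  lab_at <- fld$label_mask[cbind(round(fld$nuclei$y_px) + 1,
                                 round(fld$nuclei$x_px) + 1)]
  expect_identical(lab_at, fld$nuclei$true_label)

  # truth table equals brute-force recomputation from the emitted mask
  expect_identical(fld$truth_cells$area_px,
                   as.numeric(tabulate(fld$label_mask[fld$label_mask > 0])))

  # all-mononucleated field has fusion index 0
  mono <- generate_syncytium_field(
    cells = list(cell_spec(c(30, 30), c(12, 6), nucleus_count = 1),
                 cell_spec(c(80, 80), c(12, 6), nucleus_count = 1)),
    image_shape = c(240L, 240L), pixel_size = 0.5, seed = 1)
  expect_equal(mono$truth_summary$fusion_index, 0)

  # determinism
  expect_identical(three_cell_field(seed = 7)$nuclei, fld$nuclei)
})

test_that("syncytium field rejects overlap and out-of-image cells", {
  expect_error(generate_syncytium_field(
    cells = list(cell_spec(c(40, 40), c(20, 10)),
                 cell_spec(c(45, 40), c(20, 10))),
    image_shape = c(240L, 240L), pixel_size = 0.5),
    "overlap")
  expect_error(generate_syncytium_field(
    cells = list(cell_spec(c(5, 5), c(20, 10))),
    image_shape = c(240L, 240L), pixel_size = 0.5),
    "fit inside")
})

test_that("random field cells respect non-overlap and the AR guard band", {
  for (s in 1:5) {
    cells <- random_field_cells(seed = s)
    ars <- vapply(cells, function(cl) max(cl$semi_axes) / min(cl$semi_axes),
                  numeric(1))
    expect_true(all(ars < 2.6 | ars > 3.5))
    # rasterization must succeed without overlap errors
    expect_no_error(generate_syncytium_field(cells, seed = s))
  }
})

test_that("cortical image generator builds the specified ring", {
  ci <- ring_cell()
  d <- EBImage::distmap(ci$mask * 1) * 0.5
  expect_true(all(ci$image[ci$mask & d <= 1.5] == 100))
  expect_true(all(ci$image[ci$mask & d > 1.5] == 20))
  expect_true(all(ci$image[!ci$mask] == 0))

  # equal levels give a uniform cell
  u <- ring_cell(cortex_level = 50, interior_level = 50)
  expect_true(all(u$image[u$mask] == 50))

  # determinism under noise
  n1 <- ring_cell(noise_sd = 3, seed = 9)
  n2 <- ring_cell(noise_sd = 3, seed = 9)
  expect_identical(n1$image, n2$image)

  expect_error(generate_cortical_image(semi_axes = c(40, 5),
                                       cortex_depth = 6),
               "cortex_depth")
})

test_that("fura2 trace generator honours its programmed response", {
  flat <- generate_fura2_trace(amplitude = 0, noise_sd = 0)
  expect_true(all(flat$value == flat$value[1]))

  tr <- generate_fura2_trace(baseline = 1.0, amplitude = 0.8, onset = 60,
                             rise = 10, duration = 600,
                             sampling_interval = 10, noise_sd = 0)
  expect_equal(nrow(tr), 61)                       # t = 0..600 inclusive
  expect_equal(delta_ratio(tr, t_ref = 60), 0.8)   # plateau - baseline
  expect_error(generate_fura2_trace(onset = 700, duration = 600), "onset")
})

test_that("intensity population mixes the two components as specified", {
  neg_only <- generate_intensity_population(n_cells = 500,
                                            positive_fraction = 0, seed = 2)
  expect_false(any(attr(neg_only, "is_positive")))

  x <- generate_intensity_population(n_cells = 1e5, positive_fraction = 0.2,
                                     seed = 3)
  gate <- positive_threshold(
    generate_intensity_population(n_cells = 2e4, positive_fraction = 0,
                                  seed = 4))
  se <- 100 * sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(fraction_positive(x, gate) - 20), 3 * se + 1)

  expect_identical(
    as.numeric(generate_intensity_population(n_cells = 100, seed = 5)),
    as.numeric(generate_intensity_population(n_cells = 100, seed = 5)))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_trapped_bead(n_frames = 100, seed = 1))
  invisible(generate_intensity_population(n_cells = 10, seed = 1))
  expect_identical(.Random.seed, before)
})
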