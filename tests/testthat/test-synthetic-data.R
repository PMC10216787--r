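test_that("acquisition geometry validates its invariants", {
  g <- acquisition_geometry()
  expect_equal(g$pixels, round(sqrt(78974.6) / 0.3))
  expect_lt(abs((g$pixels * g$pixel_size)^2 - g$field_area) / g$field_area,
            0.01)
  expect_error(acquisition_geometry(field_area = -1), "positive")
  expect_error(acquisition_geometry(n_planes = 0), "positive")
  # inconsistent area/pixel combination (square assumption broken)
  expect_error(acquisition_geometry(field_area = 100, pixel_size = 30),
               "zero pixels|inconsistent")
})

test_that("an empty scene renders to pure background with empty labels", {
  g <- small_geom(64, n_planes = 2)
  sc <- synthetic_scene(g, n_organoids = 0, n_debris = 0,
                        background = c(0, 0), seed = 1)
  st <- render_scene(sc)
  expect_true(all(st$channels$hoechst == 0))
  expect_true(all(st$channels$caspase == 0))
  expect_true(all(st$truth$organoid_labels == 0))
  expect_equal(nrow(st$truth$plane_areas), 0)
  # with noise on, images are noise-only but labels stay empty
  sc2 <- synthetic_scene(g, n_organoids = 0, n_debris = 0, seed = 1)
  st2 <- render_scene(sc2)
  expect_gt(max(st2$channels$hoechst), 0)
  expect_true(all(st2$truth$nucleus_labels == 0))
})

test_that("identical seeds give bit-identical scenes and stacks", {
  sc1 <- demo_scene(seed = 7)
  sc2 <- demo_scene(seed = 7)
  expect_identical(sc1$cells, sc2$cells)
  st1 <- render_scene(sc1)
  st2 <- render_scene(sc2)
  expect_identical(st1$channels, st2$channels)
  expect_identical(st1$truth$organoid_labels, st2$truth$organoid_labels)
  # and a different seed gives a different field
  st3 <- render_scene(demo_scene(seed = 8))
  expect_false(identical(st1$channels$hoechst, st3$channels$hoechst))
})

test_that("ground-truth label area matches the analytic disc area", {
  g <- small_geom(96, n_planes = 1)
  sc <- synthetic_scene(g, n_organoids = 1, nuclei_per_organoid = c(1, 1),
                        n_debris = 0, background = c(0, 0), seed = 2)
  st <- render_scene(sc)
  r <- 2 * sc$params$nucleus_sigma / g$pixel_size  # disc radius, px
  a_true <- pi * r^2
  a_lab <- sum(st$truth$nucleus_labels > 0)
  # rasterisation error is at most a one-pixel ring around the disc
  expect_lt(abs(a_lab - a_true), 2 * pi * r + 4)
  expect_equal(st$truth$organoid_areas$max_area,
               a_lab * g$pixel_size^2)
})

test_that("every ground-truth nucleus sits on a local Hoechst maximum", {
  st <- render_scene(demo_scene(seed = 11))
  cells <- st$truth$cells
  ps <- st$geometry$pixel_size
  ok <- mapply(function(x, y, p) {
    ix <- round(x / ps + 0.5); iy <- round(y / ps + 0.5)
    pl <- st$channels$hoechst[, , p]
    win <- pl[max(1, ix - 2):min(nrow(pl), ix + 2),
              max(1, iy - 2):min(ncol(pl), iy + 2)]
    pl[ix, iy] >= 0.8 * max(win) && pl[ix, iy] > 10 * 5  # well above bg
  }, cells$x, cells$y, cells$plane)
  expect_true(all(ok))
})

test_that("death mode determines which channels are high", {
  sc <- demo_scene(seed = 3, n_organoids = 4,
                   death_probs = c(viable = 0.25, apoptotic = 0.25,
                                   necrotic = 0.25, late_apoptotic = 0.25))
  cells <- sc$cells
  hi <- function(x) x > sqrt(sc$params$intensity_low *
                               sc$params$intensity_high)
  expect_true(all(hi(cells$caspase_mu) ==
                    (cells$death_mode %in% c("apoptotic", "late_apoptotic"))))
  expect_true(all(hi(cells$pi_mu) ==
                    (cells$death_mode %in% c("necrotic", "late_apoptotic"))))
})

test_that("viable-cell channel noise obeys the mean+2SD tail product", {
  # lognormal intensities are normal on the log scale, so the fraction of
  # viable cells below both per-channel mean+2SD thresholds converges to
  # pnorm(2)^2 when thresholds are fitted on the log scale
  g <- small_geom(64, n_planes = 1)
  sc <- synthetic_scene(g, n_organoids = 0, n_debris = 0, seed = 5)
  set.seed(5)
  n <- 4000
  ca <- draw_viable <- stats::rlnorm(n, log(sc$params$intensity_low),
                                     sc$params$intensity_sdlog)
  pi_ <- stats::rlnorm(n, log(sc$params$intensity_low),
                       sc$params$intensity_sdlog)
  rec <- nucleus_records(ca, pi_)
  thr <- fit_viable_thresholds(rec, scale = "log")
  frac <- mean(log10(ca) <= thr["t_caspase"] & log10(pi_) <= thr["t_pi"])
  expect_lt(abs(frac - pnorm(2)^2), 0.02)
})

test_that("noiseless plate readings follow the closed-form signal model", {
  lay <- demo_layout(doses = c(0.1, 1, 10, 100), n_reps = 2)
  tr <- plate_truth(lay, true_4pl = list(top = 1, bottom = 0, ic50 = 1,
                                         hill = 1.3),
                    baseline = 100, growth_rate = 2^(1 / 10), noise_cv = 0,
                    seed = 4)
  sim <- simulate_plate(tr, timepoints = c(-4, 0, 10))
  unt <- sim[sim$control_role == "untreated", ]
  expect_equal(unt$reading, 100 * 2^(unt$day / 10))
  # 4PL midpoint: treated wells at the IC50 read half the untreated signal
  at_ic50 <- sim[sim$day == 10 & sim$dose == 1 &
                   sim$control_role == "none", ]
  expect_equal(at_ic50$reading, rep(0.5 * 100 * 2, nrow(at_ic50)))
  # staurosporine wells are scaled to near zero at day 10
  st10 <- sim[sim$day == 10 & sim$control_role == "staurosporine", ]
  expect_true(all(st10$reading <= 0.1 * 100 * 2))
  expect_error(plate_truth(lay, noise_cv = -0.1), "noise_cv")
})

test_that("simulated replicate noise reproduces the requested CV", {
  lay <- rbind(demo_layout()[demo_layout()$control_role != "none", ][0, ],
               data.frame(well = sprintf("C%d", 1:6), treatment = "none",
                          dose = 0, control_role = "untreated"),
               data.frame(well = "C7", treatment = "stauro", dose = 0,
                          control_role = "staurosporine"))
  tr <- plate_truth(lay, noise_cv = 0.05, seed = 9)
  sim <- simulate_plate(tr, timepoints = 10)
  r <- sim$reading[sim$control_role == "untreated"]
  cv <- sd(r) / mean(r)
  expect_gt(cv, 0.01)   # sampling band for n = 6 at true CV 0.05
  expect_lt(cv, 0.12)
})
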