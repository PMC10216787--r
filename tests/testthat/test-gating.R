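test_that("viable thresholds are mean + 2 SD per channel", {
  r <- nucleus_records(c(1, 2, 3), c(2, 4, 6))
  thr <- fit_viable_thresholds(r)
  expect_equal(unname(thr), c(4, 8))
  # zero-variance: threshold collapses onto the constant
  rc <- nucleus_records(rep(5, 10), rep(2, 10))
  expect_equal(unname(fit_viable_thresholds(rc)), c(5, 2))
  expect_error(fit_viable_thresholds(nucleus_records(1, 1)), "at least 2")
  # log scale works in log10 units
  rl <- nucleus_records(c(10, 100, 1000), c(10, 100, 1000))
  expect_equal(unname(fit_viable_thresholds(rl, scale = "log")),
               rep(2 + 2 * sd(1:3), 2))
})

test_that("mean+2SD both-channel rule captures the normal tail product", {
  set.seed(123)
  n <- 10000
  rec <- nucleus_records(rnorm(n, 100, 10), rnorm(n, 80, 8))
  thr <- fit_viable_thresholds(rec)
  model <- fit_gate_lines(NULL, thr)
  frac <- mean(classify_nuclei(rec, model) == "viable")
  expect_lt(abs(frac - pnorm(2)^2), 0.01)
})

test_that("axis-aligned extremes classify into the expected sectors", {
  model <- fit_gate_lines(NULL, c(t_caspase = 10, t_pi = 8))
  pts <- nucleus_records(c(0, 100, 0, 100, 10, 5),
                         c(0, 0, 80, 80, 8, 3))
  cls <- classify_nuclei(pts, model)
  expect_equal(as.character(cls),
               c("viable", "apoptotic", "necrotic", "late_apoptotic",
                 "viable", "viable"))   # thresholds are inclusive
  expect_error(classify_nuclei(pts, list(t_caspase = 1)), "gating_model")
  expect_error(fit_gate_lines(NULL, c(t_caspase = 1, t_pi = 1),
                              angles = c(apoptotic = 70, necrotic = 20)),
               "angles")
})

test_that("classification matches a brute-force geometric oracle", {
  model <- fit_gate_lines(NULL, c(t_caspase = 50, t_pi = 40))
  set.seed(99)
  pts <- nucleus_records(runif(1000, 0, 200), runif(1000, 0, 160))
  got <- as.character(classify_nuclei(pts, model))
  # independent oracle: explicit point-in-region tests via line-side signs
  side <- function(theta, dx, dy) {     # >0 above the ray at angle theta
    cos(theta * pi / 180) * dy - sin(theta * pi / 180) * dx
  }
  oracle <- mapply(function(ca, pi_) {
    if (ca <= 50 && pi_ <= 40) return("viable")
    dx <- max(ca - 50, 0); dy <- max(pi_ - 40, 0)
    if (side(model$theta_apoptotic, dx, dy) < 0) "apoptotic"
    else if (side(model$theta_necrotic, dx, dy) > 0) "necrotic"
    else "late_apoptotic"
  }, pts$mean_caspase, pts$mean_pi)
  expect_identical(got, unname(oracle))
})

test_that("the four classes partition the intensity quadrant", {
  model <- fit_gate_lines(NULL, c(t_caspase = 1, t_pi = 1))
  set.seed(7)
  pts <- nucleus_records(rexp(500), rexp(500))
  cls <- classify_nuclei(pts, model)
  expect_false(anyNA(cls))
  cnt <- summarize_death(pts, model)
  expect_equal(cnt$n_viable + cnt$n_apoptotic + cnt$n_necrotic + cnt$n_late,
               500)
  expect_equal(cnt$f_viable + cnt$f_apoptotic + cnt$f_necrotic + cnt$f_late,
               1, tolerance = 1e-9)
  # raising either threshold never decreases the viable count
  for (dt in c(0.2, 1, 5)) {
    m2 <- fit_gate_lines(NULL, c(t_caspase = 1 + dt, t_pi = 1))
    expect_gte(sum(classify_nuclei(pts, m2) == "viable"),
               sum(cls == "viable"))
  }
  # counts are invariant to record order
  perm <- sample(nrow(pts))
  expect_equal(summarize_death(pts[perm, ], model)[-1],
               cnt[-1])
  # empty well: all zero counts
  empty <- summarize_death(pts[0, ], model)
  expect_equal(empty$n_total, 0)
  expect_equal(empty$n_viable, 0)
})

test_that("log-scale gating is invariant to global intensity rescaling", {
  set.seed(42)
  rec <- nucleus_records(rlnorm(2000, log(100), 0.3),
                         rlnorm(2000, log(100), 0.3))
  thr <- fit_viable_thresholds(rec, scale = "log")
  m <- fit_gate_lines(NULL, thr, scale = "log")
  cls1 <- classify_nuclei(rec, m)
  rec2 <- rec
  rec2$mean_caspase <- rec$mean_caspase * 37
  rec2$mean_pi <- rec$mean_pi * 37
  thr2 <- fit_viable_thresholds(rec2, scale = "log")
  m2 <- fit_gate_lines(NULL, thr2, scale = "log")
  expect_identical(classify_nuclei(rec2, m2), cls1)
})

test_that("gate-line calibration recovers well-separated death modes", {
  make_day10 <- function(shift = 0) {
    set.seed(101)
    n <- 600
    ang <- c(rnorm(n / 3, 5, 2), rnorm(n / 3, 40, 4), rnorm(n / 3, 75, 2))
    ang <- pmin(pmax(ang + shift, 0.1), 89.9) * pi / 180
    r <- runif(n, 20, 120)
    list(rec = nucleus_records(10 + r * cos(ang), 10 + r * sin(ang)),
         mode = rep(c("apoptotic", "late_apoptotic", "necrotic"),
                    each = n / 3))
  }
  d10 <- make_day10()
  thr <- c(t_caspase = 10, t_pi = 10)
  m <- fit_gate_lines(d10$rec, thr, calibrate = "cluster")
  cls <- as.character(classify_nuclei(d10$rec, m))
  for (mode in unique(d10$mode)) {
    expect_gt(mean(cls[d10$mode == mode] == mode), 0.95)
  }
  # equivariance: rotating the dead points about the anchor shifts both
  # calibrated angles by the same amount
  d10b <- make_day10(shift = 10)
  mb <- fit_gate_lines(d10b$rec, thr, calibrate = "cluster")
  expect_lt(abs((mb$theta_apoptotic - m$theta_apoptotic) - 10), 1)
  expect_lt(abs((mb$theta_necrotic - m$theta_necrotic) - 10), 1)
  mq <- fit_gate_lines(d10b$rec, thr, calibrate = "quantile")
  mq0 <- fit_gate_lines(d10$rec, thr, calibrate = "quantile")
  expect_lt(abs((mq$theta_apoptotic - mq0$theta_apoptotic) - 10), 1)
  # no dead cells: default angles with a warning
  viable_only <- nucleus_records(c(1, 2, 3), c(1, 2, 3))
  expect_warning(
    mf <- fit_gate_lines(viable_only, c(t_caspase = 10, t_pi = 10),
                         calibrate = "cluster"),
    "no dead cells")
  expect_equal(mf$theta_apoptotic, 30)
})

test_that("staurosporine positive control is detected", {
  model <- fit_gate_lines(NULL, c(t_caspase = 10, t_pi = 10))
  set.seed(8)
  dead <- nucleus_records(rlnorm(200, log(100), 0.3),
                          rlnorm(200, log(100), 0.3),
                          well_id = rep(c("S1", "S2"), each = 100))
  alive <- nucleus_records(rlnorm(200, log(2), 0.3),
                           rlnorm(200, log(2), 0.3),
                           well_id = rep(c("U1", "U2"), each = 100))
  v <- validate_positive_control(dead, alive, model)
  expect_true(v$pass)
  expect_gt(v$dead_fraction_stauro, 0.9)
  # identical distributions fail
  v2 <- validate_positive_control(alive, alive, model)
  expect_false(v2$pass)
  expect_error(validate_positive_control(alive[0, ], alive, model),
               "non-empty")
})
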