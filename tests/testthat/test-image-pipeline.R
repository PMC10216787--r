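test_that("channel combination is zero-preserving and proportional", {
  g <- small_geom(32, n_planes = 2)
  zero <- array(0, c(32, 32, 2))
  st <- image_stack(list(hoechst = zero, caspase = zero, pi = zero), g)
  expect_true(all(combine_channels(st, 1) == 0))
  one <- zero; one[10:20, 10:20, 1] <- seq_len(121)
  st2 <- image_stack(list(hoechst = one, caspase = zero, pi = zero), g)
  comb <- combine_channels(st2, 1)
  expect_equal(comb * max(one[, , 1]), one[, , 1])
  expect_error(combine_channels(st2, 3), "range")
  expect_error(image_stack(list(hoechst = one, caspase = zero,
                                pi = array(0, c(16, 16, 2))), g),
               "identical shape")
})

test_that("ground-truth organoid footprints lie in the combined support", {
  st <- render_scene(demo_scene(seed = 13))
  for (p in unique(st$truth$plane_areas$plane)) {
    comb <- combine_channels(st, p)
    fg <- st$truth$organoid_labels[, , p] > 0
    bg_level <- median(comb[!fg])
    expect_gt(min(comb[fg]), bg_level)
  }
})

test_that("organoid segmentation filters debris and keeps true organoids", {
  # blank image: no regions
  g <- small_geom(64, n_planes = 1)
  blank <- segment_organoids(matrix(0, 64, 64), g)
  expect_equal(nrow(blank$organoids), 0)
  expect_error(segment_organoids(matrix(0, 64, 64), g, gaussian_sigma = 0),
               "sigma")

  # 5 organoids >= 400 um^2 and 10 sub-threshold debris specks:
  # exactly the 5 organoids survive the default 250 um^2 filter
  gg <- small_geom(320, n_planes = 1)
  sc <- synthetic_scene(gg, n_organoids = 5,
                        nuclei_per_organoid = c(12, 16), n_debris = 10,
                        seed = 21)
  st <- render_scene(sc)
  stopifnot(all(st$truth$organoid_areas$max_area >= 400),
            all(sc$debris$area < 250))
  seg <- segment_organoids(combine_channels(st, 1), gg)
  expect_equal(nrow(seg$organoids), 5)
  expect_true(all(seg$organoids$area >= 250))
  # with the filter off, the debris specks appear as extra regions
  seg0 <- segment_organoids(combine_channels(st, 1), gg, min_area = 0)
  expect_gt(nrow(seg0$organoids), 5)
})

test_that("raising min_area never increases the organoid count", {
  st <- render_scene(demo_scene(seed = 17))
  comb <- combine_channels(st, st$truth$plane_areas$plane[1])
  counts <- vapply(c(0, 100, 250, 500, 1000), function(a)
    nrow(segment_organoids(comb, st$geometry, min_area = a)$organoids),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("nucleus segmentation recovers well-separated nuclei exactly", {
  # empty organoid mask: zero nuclei
  g <- small_geom(64, n_planes = 1)
  res <- segment_nuclei(matrix(1, 64, 64), matrix(0L, 64, 64), g)
  expect_equal(nrow(res$nuclei), 0)

  # N nuclei at the default 4-sigma grid spacing, N <= 25
  for (n in c(5, 25)) {
    gg <- small_geom(256, n_planes = 1)
    sc <- synthetic_scene(gg, n_organoids = 1,
                          nuclei_per_organoid = c(n, n), n_debris = 0,
                          seed = n)
    st <- render_scene(sc)
    seg <- segment_organoids(combine_channels(st, 1), gg)
    nu <- segment_nuclei(st$channels$hoechst[, , 1], seg$labels, gg)
    expect_equal(nrow(nu$nuclei), n)
  }
})

test_that("nuclei are assigned by centroid with nearest-organoid fallback", {
  lab <- matrix(0L, 20, 20)
  lab[2:8, 2:8] <- 1L; lab[14:19, 14:19] <- 2L
  # centroid inside organoid 1; centroid in no-man's land nearer organoid 2
  org <- organoscreen:::assign_to_organoid(c(5, 12.8), c(5, 12.8), lab)
  expect_identical(org, c(1L, 2L))
})

test_that("intensity extraction is exact, local and mode-consistent", {
  g <- small_geom(32, n_planes = 1)
  const <- array(3.5, c(32, 32, 1))
  hoechst <- array(1, c(32, 32, 1))
  pi_ch <- array(0.25, c(32, 32, 1))
  st <- image_stack(list(hoechst = hoechst, caspase = const, pi = pi_ch), g)
  lab <- matrix(0L, 32, 32); lab[3:6, 3:6] <- 1L; lab[20:25, 20:25] <- 2L
  nuclei <- data.frame(nucleus_id = 1:2, organoid_id = 1L)
  rec <- extract_intensities(st, lab, 1, nuclei)
  expect_equal(rec$mean_caspase, c(3.5, 3.5))
  expect_equal(rec$mean_pi, c(0.25, 0.25))

  # locality: swapping two disjoint labels swaps the records only
  st$channels$caspase[3:6, 3:6, 1] <- 7
  rec_a <- extract_intensities(st, lab, 1, nuclei)
  lab2 <- lab; lab2[lab == 1L] <- 2L; lab2[lab == 2L] <- 1L
  rec_b <- extract_intensities(st, lab2, 1, nuclei)
  expect_equal(rec_a$mean_caspase[1], rec_b$mean_caspase[2])
  expect_equal(rec_a$mean_caspase[2], rec_b$mean_caspase[1])

  # a nucleus with an empty mask region is skipped with a warning
  expect_warning(
    extract_intensities(st, lab, 1,
                        data.frame(nucleus_id = 1:3, organoid_id = 1L)),
    "empty mask")

  # generator ground truth: apoptotic nuclei read caspase > PI
  sc <- demo_scene(seed = 31, n_organoids = 2,
                   death_probs = c(viable = 0, apoptotic = 1, necrotic = 0,
                                   late_apoptotic = 0))
  stx <- render_scene(sc)
  out <- process_stack(stx)
  expect_true(all(out$nuclei$mean_caspase > out$nuclei$mean_pi))
})

test_that("pipeline recovers ground truth on noiseless separated fields", {
  sc <- demo_scene(seed = 41, background = c(0, 0))
  st <- render_scene(sc)
  out <- process_stack(st)
  # region count per plane equals ground truth exactly
  truth <- st$truth$plane_areas
  expect_equal(nrow(out$organoids), nrow(truth))
  for (p in unique(truth$plane)) {
    a_seg <- sort(out$organoids$area[out$organoids$plane == p])
    a_tru <- sort(truth$area[truth$plane == p])
    expect_equal(length(a_seg), length(a_tru))
    expect_true(all(abs(a_seg - a_tru) / a_tru < 0.10))
  }
  # partition: every nucleus belongs to exactly one organoid and the
  # per-organoid counts sum to the number of nucleus records
  expect_equal(sum(out$organoids$n_nuclei), nrow(out$nuclei))
  key_n <- paste(out$nuclei$plane, out$nuclei$organoid_id)
  key_o <- paste(out$organoids$plane, out$organoids$organoid_id)
  expect_true(all(key_n %in% key_o))
  # intensities on ground-truth-separated nuclei match the nominal means
  # within the shot-to-shot spread of the generator
  expect_equal(nrow(out$nuclei), nrow(sc$cells))
})

test_that("well quantification is additive with plane duplication", {
  st <- render_scene(demo_scene(seed = 43))
  out <- process_stack(st)
  wl <- quantify_well(out$organoids, out$nuclei, st$geometry)
  expect_equal(wl$n_nuclei, nrow(out$nuclei))
  expect_equal(wl$n_organoids, nrow(out$organoids))
  expect_equal(wl$sampled_area, st$geometry$field_area)

  # duplicating every plane (as a second field) doubles the counts and
  # leaves the mean organoid size unchanged
  org2 <- out$organoids; org2$field_id <- 2L
  nuc2 <- out$nuclei; nuc2$field_id <- 2L
  wl2 <- quantify_well(rbind(out$organoids, org2), rbind(out$nuclei, nuc2),
                       st$geometry)
  expect_equal(wl2$n_nuclei, 2 * wl$n_nuclei)
  expect_equal(wl2$n_organoids, 2 * wl$n_organoids)
  expect_equal(wl2$mean_area, wl$mean_area)
  expect_error(quantify_well(out$organoids[0, ], out$nuclei[0, ],
                             st$geometry),
               "no fields")

  # with default noise, sampled nuclei counts stay within 15% of truth
  stn <- render_scene(demo_scene(seed = 47))
  outn <- process_stack(stn)
  truth_n <- nrow(stn$truth$cells)
  expect_lt(abs(nrow(outn$nuclei) - truth_n) / truth_n, 0.15)
})
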