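test_that("matcher agrees with the double-loop oracle on a fixed image", {
  set.seed(1)
  img <- matrix(runif(32 * 32, 0, 100), 32, 32)
  tpl <- matrix(runif(81, 0, 100), 9, 9)
  m <- match_template_ncc(img, tpl)
  o <- oracle_zncc(img, tpl)
  expect_identical(m$x, o$x)
  expect_identical(m$y, o$y)
  expect_equal(m$score, o$score, tolerance = 1e-12)
})

test_that("matcher scores a planted exact copy of the template as 1", {
  set.seed(2)
  img <- matrix(runif(64 * 64, 0, 10), 64, 64)
  tpl <- matrix(runif(49, 50, 150), 7, 7)
  img[20:26, 31:37] <- tpl   # top-left (x=30, y=19) 0-based
  m <- match_template_ncc(img, tpl)
  expect_equal(m$score, 1, tolerance = 1e-12)
  expect_equal(c(m$x, m$y), c(30, 19))
})

test_that("ZNCC is invariant to local gain and offset", {
  set.seed(3)
  img <- matrix(runif(40 * 40, 0, 100), 40, 40)
  tpl <- img[11:19, 21:29]
  m0 <- match_template_ncc(img, tpl)
  m1 <- match_template_ncc(3.7 * img + 42, tpl)
  expect_equal(m1$scores, m0$scores, tolerance = 1e-9)
  expect_identical(c(m1$x, m1$y), c(m0$x, m0$y))
})

test_that("ties break toward the smallest (y, then x) offset", {
  # periodic image: the template recurs at many offsets with score 1
  img <- matrix(rep(c(1, 5, 2, 8), length.out = 20 * 20), 20, 20)
  tpl <- img[1:4, 1:4]
  m <- match_template_ncc(img, tpl)
  expect_equal(c(m$x, m$y), c(0, 0))
  o <- oracle_zncc(img, tpl)
  expect_equal(c(o$x, o$y), c(0, 0))
})

test_that("constant windows score 0 and constant templates are rejected", {
  img <- matrix(7, 16, 16); img[10:12, 10:12] <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  tpl <- matrix(c(1, 2, 3, 4), 2, 2)
  m <- match_template_ncc(img, tpl)
  expect_true(any(m$scores == 0))
  expect_error(match_template_ncc(img, matrix(5, 3, 3)), "constant template")
  expect_error(neuron_template(matrix(1, 4, 4)), "constant template")
})

test_that("search regions restrict the scan and reject out-of-image regions", {
  set.seed(4)
  img <- matrix(runif(30 * 30), 30, 30)
  tpl <- img[3:7, 3:7]
  # restricted to the right half, the left-half planted copy is invisible
  m <- match_template_ncc(img, tpl, region(15, 0, 30, 30))
  expect_gte(m$x, 15)
  expect_error(match_template_ncc(img, tpl, region(20, 0, 40, 30)),
               "outside the image")
  expect_error(match_template_ncc(img, tpl, region(0, 0, 4, 30)),
               "template larger")
})

test_that("autofocus picks the true plane on a noise-free stack", {
  sc <- scene_params(z_true_um = 45)
  s <- simulate_worm_session(sc, z_plan = seq(0, 100, 5),
                             noise = noise_config(FALSE))
  tpl <- make_template(sc)
  af <- autofocus_z(s$zstack, tpl)
  expect_true(af$found)
  expect_equal(af$z_index, s$truth$z_plane)
  expect_equal(af$z_um, 45)
  expect_equal(length(af$scores), 21)
})

test_that("autofocus rejects a neuron-free stack as not found", {
  sc <- scene_params(donor_peak = 0, acceptor_peak = 0)  # autofluor only
  s <- simulate_worm_session(sc, z_plan = seq(0, 100, 10),
                             noise = noise_config(FALSE))
  tpl <- make_template(scene_params())
  af <- autofocus_z(s$zstack, tpl)
  expect_false(af$found)
  expect_true(is.na(af$z_index))
  expect_true(all(af$scores < 0.5))
})

test_that("edge detector finds the neuron without a template", {
  sc <- scene_params()
  fr <- ideal_frame(sc)
  hit <- detect_neuron_edge(fr, config = detection_config(mode = "edge"))
  expect_false(is.null(hit))
  expect_lt(abs(hit$x - sc$neuron_x), 2)
  expect_lt(abs(hit$y - sc$neuron_y), 2)
})

test_that("edge detector returns NULL on a featureless frame", {
  flat <- matrix(80, 64, 64)
  expect_null(detect_neuron_edge(flat))
})

test_that("orientation classification works in both detection modes", {
  tpl <- make_template(scene_params())
  head_fr <- ideal_frame(scene_params(neuron_x = 18))
  tail_fr <- ideal_frame(scene_params(neuron_x = 46,
                                      orientation = "tail_first"))
  cfg_t <- detection_config(mode = "template")
  cfg_e <- detection_config(mode = "edge")
  expect_equal(classify_orientation(head_fr, tpl, cfg_t), "head")
  expect_equal(classify_orientation(tail_fr, tpl, cfg_t), "tail")
  expect_equal(classify_orientation(head_fr, config = cfg_e), "head")
  expect_equal(classify_orientation(tail_fr, config = cfg_e), "tail")
  expect_equal(classify_orientation(matrix(80, 64, 64), tpl, cfg_t), "none")
})

test_that("age routes worms to the appropriate detection mode", {
  expect_equal(mode_for_age(2), "edge")
  expect_equal(mode_for_age(4), "edge")
  expect_equal(mode_for_age(5), "template")
  expect_equal(mode_for_age(12), "template")
})

test_that("entry detection compares trap region against background", {
  fr <- matrix(80, 64, 64)
  cfg <- detection_config()
  expect_false(detect_entry(fr, cfg$entry_region, cfg$background_region, 50))
  fr2 <- fr
  fr2[10:60, 55:64] <- 400   # worm body filling the entry region
  expect_true(detect_entry(fr2, cfg$entry_region, cfg$background_region, 50))
  expect_error(detect_entry(fr, region(0, 0, 10, 10), region(5, 5, 15, 15),
                            50), "disjoint")
})

test_that("brightness QC buckets intensities against the bounds", {
  expect_equal(qc_brightness(100, c(300, 1800)), "too_dim")
  expect_equal(qc_brightness(900, c(300, 1800)), "pass")
  expect_equal(qc_brightness(5000, c(300, 1800)), "too_bright")
  expect_error(qc_brightness(1, c(10, 5)), "ordered")
})

test_that("regions are 0-based half-open and crop correctly", {
  img <- matrix(seq_len(25), 5, 5)
  rg <- region(1, 2, 4, 5)     # cols 2..4, rows 3..5 (1-based)
  expect_equal(dim(crop_region(img, rg)), c(3, 3))
  expect_equal(crop_region(img, rg), img[3:5, 2:4])
  expect_true(regions_disjoint(region(0, 0, 3, 3), region(3, 0, 6, 3)))
  expect_false(regions_disjoint(region(0, 0, 4, 4), region(3, 3, 6, 6)))
})
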