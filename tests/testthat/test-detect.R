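ic <- imaging_config()

test_that("a blank image yields no detections", {
  empty <- manual_population(numeric(0), numeric(0), numeric(0))
  img <- render_frame(empty, ic, "membrane", seed = 1)
  expect_equal(nrow(threshold_detect(img)), 0L)
  prot <- render_frame(empty, ic, "protein", seed = 2)
  expect_equal(nrow(detect_frame(img, prot)), 0L)
})

test_that("size constraints keep 8 and 15 um disks but reject 3 and 25 um", {
  # 25 um exceeds both the sampler range and the detector maximum; render
  # lumen disks directly to exercise the constraint
  pop <- manual_population(c(25, 64, 25, 96), c(25, 96, 96, 30),
                           c(3, 8, 15, 25), phenotype = "lumen",
                           mode = "static_lumen")
  prot <- render_frame(pop, ic, "protein", noise = FALSE)
  det <- detect_frame(NULL, prot, detection_params(detect_channel = "protein"))
  expect_equal(nrow(det), 2L)
  expect_equal(sort(det$equiv_diameter_um), c(8, 15), tolerance = 0.05)
})

test_that("circularity closed forms: circle 1, square pi/4, 2:1 ellipse ~0.84", {
  expect_equal(circularity(pi * 4^2, 2 * pi * 4), 1)
  expect_equal(circularity(9, 12), pi / 4)
  # Ramanujan perimeter for a=2, b=1
  a <- 2; b <- 1
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_equal(circularity(pi * a * b, per), 8 * pi^2 / per^2, tolerance = 1e-9)
  expect_equal(circularity(pi * a * b, per), 0.841, tolerance = 1e-3)
  expect_error(circularity(1, 0), "positive")
})

test_that("circularity is scale invariant", {
  a <- 7.3; p <- 11.1
  for (k in c(0.1, 3, 117))
    expect_lt(abs(circularity(a * k^2, p * k) - circularity(a, p)), 1e-9)
})

test_that("ring score separates membrane from lumen localization", {
  mk <- function(phenotype, mode) {
    pop <- manual_population(64, 64, 10, phenotype = phenotype, mode = mode)
    mem <- render_frame(pop, ic, "membrane", noise = FALSE)
    prot <- render_frame(pop, ic, "protein", noise = FALSE)
    detect_frame(mem, prot)
  }
  det_mem <- mk("membrane", "static_membrane")
  expect_equal(det_mem$cls, 2L)
  expect_gte(det_mem$ring_score, 3)
  det_lum <- mk("lumen", "static_lumen")
  expect_equal(det_lum$cls, 1L)
  expect_lt(det_lum$ring_score, 1.5)
})

test_that("a spatially uniform reporter image scores R = 1, class 1", {
  pop <- manual_population(64, 64, 10)
  mem <- render_frame(pop, ic, "membrane", noise = FALSE)
  det <- threshold_detect(mem)
  flat <- matrix(500, 512, 512)
  attr(flat, "px_um") <- 0.25
  out <- classify_localization(mem, flat, det)
  expect_equal(out$ring_score, 1)
  expect_equal(out$cls, 1L)
})

test_that("classification is invariant to affine intensity changes", {
  pop <- manual_population(64, 64, 10, phenotype = "membrane")
  mem <- render_frame(pop, ic, "membrane", noise = FALSE)
  prot <- render_frame(pop, ic, "protein", seed = 5)
  det <- threshold_detect(mem)
  base <- classify_localization(mem, prot, det)
  prot2 <- prot * 3.7 + 250
  attr(prot2, "px_um") <- 0.25
  shifted <- classify_localization(mem, prot2, det)
  expect_equal(shifted$ring_score, base$ring_score, tolerance = 0.01)
  expect_equal(shifted$cls, base$cls)
})

test_that("the video filter applies the aspect and area rules", {
  det <- data.frame(aspect_ratio = c(0.6, 0.7, 1.0, 1.3, 1.4, 1.0),
                    area_um2 = c(50, 50, 36, 50, 50, 37))
  kept <- video_filter(det)
  expect_equal(kept$aspect_ratio, c(0.7, 1.3, 1.0))
  expect_true(all(kept$area_um2 >= 37))
})

test_that("detection reaches precision and recall >= 0.95 on sparse FOVs", {
  cfg <- population_config(genotype_spec("minD", "membrane"), 1,
                           p_expression = 1, diameter_median = 7,
                           diameter_range = c(4.5, 15),
                           liposomes_per_fov = c(15L, 15L), min_gap_um = 2,
                           n_fov = 3L)
  pop <- sample_population(cfg, seed = 31)
  prec <- c(); rec <- c(); n_det <- 0L; n_gt <- 0L
  for (f in 1:3) {
    pf <- pop[pop$fov == f, ]
    attr(pf, "genotypes") <- attr(pop, "genotypes")
    mem <- render_frame(pf, ic, "membrane", seed = f)
    prot <- render_frame(pf, ic, "protein", seed = f + 10)
    det <- detect_frame(mem, prot)
    interior <- pf[pf$x_um > pf$diameter_um / 2 + 1.5 &
                   pf$x_um < 128 - pf$diameter_um / 2 - 1.5 &
                   pf$y_um > pf$diameter_um / 2 + 1.5 &
                   pf$y_um < 128 - pf$diameter_um / 2 - 1.5, ]
    m <- match_detections(det, pf, interior)
    prec <- c(prec, m$precision); rec <- c(rec, m$recall)
    n_det <- n_det + nrow(det); n_gt <- n_gt + nrow(pf)
  }
  expect_gte(mean(prec), 0.95)
  expect_gte(mean(rec), 0.95)
  # detections never exceed ground truth on non-overlapping renders
  expect_lte(n_det, n_gt)
})

test_that("a saturated image raises a degenerate-input error", {
  img <- matrix(6e4, 128, 128)
  attr(img, "px_um") <- 0.25
  expect_error(threshold_detect(img, detection_params(threshold_value = 10)),
               "degenerate")
})

test_that("detections export to CSV and YOLO formats", {
  pop <- manual_population(c(40, 90), c(40, 90), c(8, 10))
  mem <- render_frame(pop, ic, "membrane", noise = FALSE)
  prot <- render_frame(pop, ic, "protein", noise = FALSE)
  det <- detect_frame(mem, prot)
  csv <- tempfile(fileext = ".csv"); yolo <- tempfile(fileext = ".txt")
  write_detections_csv(det, csv)
  write_detections_yolo(det, yolo)
  expect_equal(nrow(read.csv(csv)), nrow(det))
  lines <- readLines(yolo)
  expect_length(lines, nrow(det))
  vals <- as.numeric(strsplit(lines[1], " ")[[1]])
  expect_length(vals, 6L)
  expect_true(all(vals[2:5] >= 0 & vals[2:5] <= 1))
})
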