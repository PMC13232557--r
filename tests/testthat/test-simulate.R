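test_that("degenerate single-genotype mixture gives every liposome that genotype", {
  cfg <- population_config(genotype_spec("YFP", "lumen"), 1,
                           p_expression = 1, liposomes_per_fov = c(50L, 50L),
                           n_fov = 2L)
  pop <- sample_population(cfg, seed = 1)
  expect_equal(unique(pop$genotype), "YFP")
  expect_true(all(pop$expressing))
  expect_equal(nrow(pop), 100L)
})

test_that("1:39 mixture fractions follow the exact binomial law", {
  cfg <- two_gene_config(n_fov = 250L)
  pop <- sample_population(cfg, seed = 7)
  n <- nrow(pop)
  k <- sum(pop$genotype == "YFP")
  ci <- qbinom(c(0.005, 0.995), n, 1 / 40)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("expressing-reporter fraction sits in the 1-2% band at p = 0.6", {
  cfg <- two_gene_config(n_fov = 250L)
  pop <- sample_population(cfg, seed = 11)
  f <- mean(pop$genotype == "YFP" & pop$expressing)
  expect_gte(f, 0.01)
  expect_lte(f, 0.02)
})

test_that("population invariants: diameters in [2,20], centers in FOV, spacing", {
  cfg <- two_gene_config(n_fov = 3L, per_fov = c(60L, 60L))
  pop <- sample_population(cfg, seed = 3)
  expect_true(all(pop$diameter_um >= 2 & pop$diameter_um <= 20))
  expect_true(all(pop$x_um >= 0 & pop$x_um <= 128 &
                  pop$y_um >= 0 & pop$y_um <= 128))
  for (f in unique(pop$fov)) {
    pf <- pop[pop$fov == f, ]
    d <- as.matrix(dist(pf[, c("x_um", "y_um")]))
    mind <- outer(pf$diameter_um / 2, pf$diameter_um / 2, `+`) + 1
    diag(d) <- Inf
    expect_true(all(d >= mind - 1e-9))
  }
})

test_that("configuration errors are caught", {
  expect_error(population_config(genotype_spec("a"), 0.9), "sum to 1")
  expect_error(genotype_spec("a", mts_variant = "ACGT"), "6 nt")
  expect_error(assign_oscillation(5, c(pulsing = -1, circling = 2)),
               "non-negative")
  # an FOV that cannot fit the requested liposomes errors with its index
  crowded <- population_config(genotype_spec("a"), 1,
                               diameter_median = 18, diameter_sigma = 0.05,
                               liposomes_per_fov = c(60L, 60L), n_fov = 1L)
  expect_error(sample_population(crowded, seed = 1), "crowded")
})

test_that("oscillation assignment: modes follow weights, periods in [15,45]", {
  w <- c(pulsing = 1, pole_to_pole = 1, circling = 1)
  osc <- assign_oscillation(9000, w, seed = 5)
  tab <- table(osc$mode)
  for (m in names(w)) {
    ci <- qbinom(c(0.005, 0.995), 9000, 1 / 3)
    expect_gte(tab[[m]], ci[1])
    expect_lte(tab[[m]], ci[2])
  }
  expect_true(all(osc$period_s >= 15 & osc$period_s <= 45))
  expect_true(all(osc$phase >= 0 & osc$phase < 2 * pi))
  only <- assign_oscillation(50, c(static_lumen = 1), seed = 6)
  expect_true(all(only$mode == "static_lumen"))
  expect_true(all(is.na(only$period_s)))
})

test_that("membrane fraction: defined constants and square-wave pulsing", {
  expect_equal(membrane_fraction(list(mode = "static_lumen"), 10)$m, 0.05)
  expect_equal(membrane_fraction(list(mode = "static_membrane"), 0)$m, 0.9)
  osc <- list(mode = "pulsing", period_s = 24, phase = 0)
  ms <- vapply(c(0, 12, 24, 36, 48), function(t) membrane_fraction(osc, t)$m, 0)
  expect_equal(ms, c(0.9, 0.1, 0.9, 0.1, 0.9))
})

test_that("pole-to-pole cap flips by pi each half period; profiles are periodic", {
  osc <- list(mode = "pole_to_pole", period_s = 30, phase = 0.7,
              axis_angle = 1.1)
  c1 <- membrane_fraction(osc, 3)$cap_center
  c2 <- membrane_fraction(osc, 3 + 15)$cap_center
  expect_equal((c2 - c1) %% (2 * pi), pi, tolerance = 1e-9)
  for (mode in c("pulsing", "pole_to_pole", "circling")) {
    o <- list(mode = mode, period_s = 21.5, phase = 1.3, axis_angle = 0.4)
    for (t in c(0, 5.5, 13)) {
      a <- membrane_fraction(o, t); b <- membrane_fraction(o, t + 21.5)
      expect_equal(a$m, b$m, tolerance = 1e-9)
      if (!is.na(a$cap_center))
        expect_lt(abs((a$cap_center - b$cap_center + pi) %% (2 * pi) - pi), 1e-9)
    }
  }
})

test_that("brownian step: zero scale is a no-op; displacement is Rayleigh", {
  ctr <- cbind(runif(10, 10, 100), runif(10, 10, 100))
  expect_equal(brownian_step(ctr, 10, 0, seed = 1), ctr)
  set.seed(42)
  n <- 10000
  start <- matrix(64, n, 2)
  new <- brownian_step(start, 10, 0.12617, fov_um = 128)
  disp <- sqrt(rowSums((new - start)^2))
  sigma <- 0.12617 * sqrt(10)
  # mean planar displacement: Rayleigh mean sigma*sqrt(pi/2) ~= 0.5 um
  expect_equal(mean(disp), sigma * sqrt(pi / 2), tolerance = 0.02)
  expect_lt(abs(mean(disp) - 0.5), 3 * sd(disp) / sqrt(n))
  ks <- suppressWarnings(ks.test(disp, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("brownian reflection keeps centers inside the FOV", {
  start <- cbind(runif(500, 0, 2), runif(500, 126, 128))
  new <- start
  for (i in 1:20) new <- brownian_step(new, 10, 2, fov_um = 128)
  expect_true(all(new >= 0 & new <= 128))
})

test_that("population CSV round-trips the ground-truth columns", {
  cfg <- two_gene_config(n_fov = 1L, per_fov = c(50L, 50L))
  pop <- sample_population(cfg, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_population_csv(pop, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(pop))
  expect_equal(back$diameter_um, pop$diameter_um)
  expect_equal(back$genotype, pop$genotype)
})
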