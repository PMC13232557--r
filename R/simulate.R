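#' Describe one library genotype
#'
#' A genotype is one clonal DNA species in a (mock) library: the gene it
#' carries, the visual phenotype its expression produces, the amplicon
#' recovered from it by PCR, and (for MTS libraries) the 6-nt variant window.
#'
#' @param name identifier, e.g. `"YFP"` or `"Var7"`.
#' @param phenotype one of `"none"`, `"lumen"`, `"membrane"`, `"oscillatory"`:
#'   where the fluorescent reporter localizes when the gene is expressed.
#'   Non-fluorescent control genes (e.g. btubB) use `"none"`.
#' @param amplicon_length length in bp of the PCR-recovered amplicon.
#' @param mts_variant 6-character nucleotide string (two mutagenized codons of
#'   the MinD membrane targeting sequence) or `""` when not applicable.
#' @param template_share relative template amount per liposome (dimensionless);
#'   populations mixed with "equal amount of template" all use 1.
#' @return a `genotype_spec` list.
#' @export
genotype_spec <- function(name, phenotype = c("none", "lumen", "membrane", "oscillatory"),
                          amplicon_length = 1398L, mts_variant = "", template_share = 1) {
  phenotype <- match.arg(phenotype)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (amplicon_length <= 0) stop("amplicon_length must be positive")
  if (!nchar(mts_variant) %in% c(0L, 6L)) stop("mts_variant must be empty or 6 nt")
  structure(list(name = name, phenotype = phenotype,
                 amplicon_length = as.integer(amplicon_length),
                 mts_variant = toupper(mts_variant), template_share = template_share),
            class = "genotype_spec")
}

#' Configure a liposome population
#'
#' Defines the mixture of clonal populations (volume ratios), the expression
#' probability, the vesicle size distribution and the field-of-view layout.
#' Defaults reflect the experimental regime the pipeline emulates: diameters
#' 2--20 um, 50--150 liposomes per 128x128 um FOV, and 40--80% of liposomes
#' in a clonal sample showing expression (default p = 0.6, the midpoint).
#'
#' @param genotypes list of [genotype_spec()] objects.
#' @param volume_fractions numeric mixing fractions, summing to 1 (a 1:39
#'   volume mix is `c(1, 39) / 40`).
#' @param p_expression per-liposome probability of gene expression above the
#'   detection threshold, independent of genotype.
#' @param diameter_median,diameter_sigma log-normal diameter parameters
#'   (median in um, log-sd), truncated to `diameter_range`.
#' @param diameter_range allowed diameter interval in um.
#' @param liposomes_per_fov integer range `c(min, max)`; the count per FOV is
#'   drawn uniformly from it.
#' @param min_gap_um minimum edge-to-edge gap between liposomes (um); centers
#'   are kept at least `r_i + r_j + min_gap_um` apart.
#' @param n_fov number of fields of view.
#' @param fov_um side of the square FOV in um.
#' @param mode_weights named probability vector over the six dynamic modes,
#'   used for genotypes with `phenotype = "oscillatory"`.
#' @param diffusion_scale Brownian scale in um s^-1/2 per axis. The default
#'   0.12617 gives a mean planar displacement of 0.5 um over 10 s.
#' @param pamcherry_basal basal photoactivatable-reporter level (a.u.).
#' @param seed default seed used by [sample_population()] when none is given.
#' @return a `population_config` list.
#' @export
population_config <- function(genotypes, volume_fractions,
                              p_expression = 0.6,
                              diameter_median = 5, diameter_sigma = 0.45,
                              diameter_range = c(2, 20),
                              liposomes_per_fov = c(50L, 150L),
                              min_gap_um = 1,
                              n_fov = 1L, fov_um = 128,
                              mode_weights = c(static_membrane = 0, static_lumen = 0,
                                               pulsing = 1/3, pole_to_pole = 1/3,
                                               circling = 1/3, halted = 0),
                              diffusion_scale = 0.12617,
                              pamcherry_basal = 10,
                              seed = 1L) {
  if (inherits(genotypes, "genotype_spec")) genotypes <- list(genotypes)
  stopifnot(length(genotypes) == length(volume_fractions))
  if (abs(sum(volume_fractions) - 1) > 1e-9)
    stop("volume fractions must sum to 1")
  if (any(volume_fractions < 0)) stop("volume fractions must be non-negative")
  if (p_expression < 0 || p_expression > 1) stop("p_expression must be in [0,1]")
  stopifnot(length(liposomes_per_fov) == 2L, diff(diameter_range) > 0)
  check_mode_weights(mode_weights)
  structure(list(genotypes = genotypes, volume_fractions = volume_fractions,
                 p_expression = p_expression,
                 diameter_median = diameter_median, diameter_sigma = diameter_sigma,
                 diameter_range = diameter_range,
                 liposomes_per_fov = as.integer(liposomes_per_fov),
                 min_gap_um = min_gap_um,
                 n_fov = as.integer(n_fov), fov_um = fov_um,
                 mode_weights = mode_weights,
                 diffusion_scale = diffusion_scale,
                 pamcherry_basal = pamcherry_basal, seed = seed),
            class = "population_config")
}

OSC_MODES <- c("static_membrane", "static_lumen", "pulsing",
               "pole_to_pole", "circling", "halted")
OSCILLATORY_MODES <- c("pulsing", "pole_to_pole", "circling")

check_mode_weights <- function(w) {
  if (is.null(names(w)) || !all(names(w) %in% OSC_MODES) || anyDuplicated(names(w)))
    stop("mode_weights must be named with the six dynamic modes")
  if (any(w < 0)) stop("mode weights must be non-negative")
  if (sum(w) <= 0) stop("mode weights must have positive sum")
  invisible(w)
}

#' Sample a ground-truth liposome population
#'
#' Draws, for every field of view, a set of liposomes with genotype (by
#' volume fraction), expression flag, truncated log-normal diameter, uniform
#' in-FOV position with a minimum center spacing of `r_i + r_j + min_gap_um`, and a
#' dynamic-mode state per phenotype. Non-expressing liposomes carry their
#' genotype's DNA but show no reporter phenotype.
#'
#' @param config a [population_config()].
#' @param seed integer seed; `NULL` uses `config$seed`.
#' @return a data frame of class `liposome_population`, one row per liposome:
#'   `id, fov, genotype, x_um, y_um, diameter_um, expressing, mode, period_s,
#'   phase, axis_angle, pamcherry_basal, activated, diffusion_scale`, with the
#'   genotype list and the config stored as attributes.
#' @export
sample_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    gnames <- vapply(config$genotypes, `[[`, "", "name")
    phen <- setNames(vapply(config$genotypes, `[[`, "", "phenotype"), gnames)
    fovs <- vector("list", config$n_fov)
    next_id <- 1L
    for (f in seq_len(config$n_fov)) {
      n <- if (config$liposomes_per_fov[1] == config$liposomes_per_fov[2])
        config$liposomes_per_fov[1]
      else sample(config$liposomes_per_fov[1]:config$liposomes_per_fov[2], 1L)
      gt <- gnames[sample.int(length(gnames), n, replace = TRUE,
                              prob = config$volume_fractions)]
      expressing <- runif(n) < config$p_expression
      d <- sample_diameters(n, config)
      pos <- place_liposomes(d / 2, config$fov_um, fov = f,
                             min_gap = if (is.null(config$min_gap_um)) 1 else config$min_gap_um)
      mode <- character(n); period <- rep(NA_real_, n)
      phase <- runif(n, 0, 2 * pi); axis <- runif(n, 0, 2 * pi)
      ph <- ifelse(expressing, phen[gt], "none")
      mode[ph == "none"] <- "static_lumen"     # no reporter signal anyway
      mode[ph == "lumen"] <- "static_lumen"
      mode[ph == "membrane"] <- "static_membrane"
      iosc <- which(ph == "oscillatory")
      if (length(iosc)) {
        osc <- assign_oscillation(length(iosc), config$mode_weights)
        mode[iosc] <- osc$mode
        period[iosc] <- osc$period_s
        phase[iosc] <- osc$phase
      }
      period[mode %in% OSCILLATORY_MODES & is.na(period)] <- runif(
        sum(mode %in% OSCILLATORY_MODES & is.na(period)), 15, 45)
      fovs[[f]] <- data.frame(
        id = seq.int(next_id, next_id + n - 1L), fov = f, genotype = gt,
        x_um = pos[, 1], y_um = pos[, 2], diameter_um = d,
        expressing = expressing, mode = mode, period_s = period,
        phase = phase, axis_angle = axis,
        pamcherry_basal = config$pamcherry_basal, activated = FALSE,
        diffusion_scale = config$diffusion_scale,
        stringsAsFactors = FALSE)
      next_id <- next_id + n
    }
    pop <- do.call(rbind, fovs)
    rownames(pop) <- NULL
    attr(pop, "genotypes") <- config$genotypes
    attr(pop, "config") <- config
    class(pop) <- c("liposome_population", "data.frame")
    pop
  })
}

sample_diameters <- function(n, config) {
  mu <- log(config$diameter_median); s <- config$diameter_sigma
  lo <- config$diameter_range[1]; hi <- config$diameter_range[2]
  d <- numeric(0)
  while (length(d) < n) {
    cand <- exp(rnorm(2L * (n - length(d)) + 8L, mu, s))
    d <- c(d, cand[cand >= lo & cand <= hi])
  }
  d[seq_len(n)]
}

# dart-throwing placement with pairwise spacing r_i + r_j + 1 um
place_liposomes <- function(radii, fov_um, fov = NA, min_gap = 1,
                            max_tries = 4000L) {
  n <- length(radii)
  ord <- order(radii, decreasing = TRUE)   # big first: easier packing
  x <- numeric(n); y <- numeric(n)
  for (k in seq_len(n)) {
    i <- ord[k]; r <- radii[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      px <- runif(1, r, fov_um - r); py <- runif(1, r, fov_um - r)
      if (k == 1L) { placed <- TRUE } else {
        j <- ord[seq_len(k - 1L)]
        mind <- radii[j] + r + min_gap
        if (all((x[j] - px)^2 + (y[j] - py)^2 >= mind^2)) placed <- TRUE
      }
      if (placed) { x[i] <- px; y[i] <- py; break }
    }
    if (!placed)
      stop(sprintf("FOV %s too crowded to satisfy the minimum center spacing", fov))
  }
  cbind(x, y)
}

#' Assign dynamic-mode states
#'
#' Draws dynamic modes from a probability vector over the six modes; the
#' oscillatory modes (pulsing, pole-to-pole, circling) receive a period
#' uniform in 15--45 s and a phase uniform in `[0, 2*pi)`.
#'
#' @param n number of states to draw.
#' @param mode_weights named non-negative weights over the six modes.
#' @param seed optional integer seed.
#' @return data frame with columns `mode`, `period_s` (NA for static modes),
#'   `phase`, `axis_angle`.
#' @export
assign_oscillation <- function(n, mode_weights, seed = NULL) {
  check_mode_weights(mode_weights)
  with_seed(seed, {
    w <- setNames(rep(0, length(OSC_MODES)), OSC_MODES)
    w[names(mode_weights)] <- mode_weights
    mode <- OSC_MODES[sample.int(6L, n, replace = TRUE, prob = w)]
    osc <- mode %in% OSCILLATORY_MODES
    period <- rep(NA_real_, n)
    period[osc] <- runif(sum(osc), 15, 45)
    data.frame(mode = mode, period_s = period,
               phase = runif(n, 0, 2 * pi) %% (2 * pi),
               axis_angle = runif(n, 0, 2 * pi),
               stringsAsFactors = FALSE)
  })
}

#' Membrane-bound fraction and angular profile at time t
#'
#' Gives the fraction `m` of reporter signal on the membrane and the angular
#' weighting of the membrane pool for one dynamic-mode state. Static membrane
#' localization puts 90% of the signal on the membrane, static lumen 5%;
#' pulsing alternates 0.9/0.1 as a square wave of the state's period and
#' phase; pole-to-pole uses a Gaussian angular cap (sd 0.5 rad) whose center
#' flips by pi each half period; circling rotates the cap at `2*pi/period`;
#' halted keeps a frozen cap.
#'
#' @param osc list or one-row data frame with `mode`, `period_s`, `phase`,
#'   `axis_angle`.
#' @param t time in seconds (>= 0).
#' @return list with `m` (fraction in `[0,1]`), `cap_center` (radians, or `NA`
#'   for an angularly uniform membrane pool) and `cap_sigma` (radians).
#' @export
membrane_fraction <- function(osc, t) {
  stopifnot(t >= 0)
  mode <- as.character(osc$mode)
  cap_sigma <- 0.5
  u <- function() ((t / osc$period_s) + osc$phase / (2 * pi)) %% 1
  switch(mode,
    static_membrane = list(m = 0.9, cap_center = NA_real_, cap_sigma = cap_sigma),
    static_lumen    = list(m = 0.05, cap_center = NA_real_, cap_sigma = cap_sigma),
    halted          = list(m = 0.9, cap_center = osc$axis_angle %% (2 * pi),
                           cap_sigma = cap_sigma),
    pulsing         = list(m = if (u() < 0.5) 0.9 else 0.1,
                           cap_center = NA_real_, cap_sigma = cap_sigma),
    pole_to_pole    = list(m = 0.9,
                           cap_center = (osc$axis_angle + pi * (u() >= 0.5)) %% (2 * pi),
                           cap_sigma = cap_sigma),
    circling        = list(m = 0.9,
                           cap_center = (osc$axis_angle + 2 * pi * u()) %% (2 * pi),
                           cap_sigma = cap_sigma),
    stop("unknown mode: ", mode))
}

#' One Brownian step with boundary reflection
#'
#' Per-axis Gaussian increments with standard deviation
#' `diffusion_scale * sqrt(dt)`, reflected at the FOV walls. The default
#' scale gives a mean planar displacement of 0.5 um over 10 s (Rayleigh mean
#' `s * sqrt(dt) * sqrt(pi/2)`).
#'
#' @param centers n x 2 matrix (or length-2 vector) of positions in um.
#' @param dt time step in seconds (> 0).
#' @param diffusion_scale um s^-1/2 per axis (scalar or per-liposome vector).
#' @param fov_um FOV side in um.
#' @param seed optional integer seed.
#' @return matrix of new positions, same shape as input.
#' @export
brownian_step <- function(centers, dt, diffusion_scale, fov_um = 128, seed = NULL) {
  stopifnot(dt > 0)
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  with_seed(seed, {
    n <- nrow(centers)
    s <- diffusion_scale * sqrt(dt)
    new <- centers + matrix(rnorm(2L * n, 0, s), ncol = 2)
    # reflect into [0, L] (fold over period 2L, then mirror)
    new <- abs(new)
    new <- new %% (2 * fov_um)
    new[new > fov_um] <- 2 * fov_um - new[new > fov_um]
    new
  })
}

#' Write a population ground-truth CSV
#'
#' One row per liposome with id, fov, genotype, position, diameter,
#' expression flag, dynamic mode, period and activation state.
#'
#' @param population a `liposome_population`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(population, path) {
  cols <- c("id", "fov", "genotype", "x_um", "y_um", "diameter_um",
            "expressing", "mode", "period_s", "activated")
  write.csv(as.data.frame(population)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.liposome_population <- function(x, ...) {
  cat(sprintf("<liposome_population> %d liposomes in %d FOV(s)\n",
              nrow(x), length(unique(x$fov))))
  tab <- table(x$genotype)
  cat("  genotypes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  expressing: %.1f%%\n", 100 * mean(x$expressing)))
  invisible(x)
}
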