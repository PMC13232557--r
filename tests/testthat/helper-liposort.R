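# shared fixtures and independent oracles

# build a ground-truth population data frame by hand
manual_population <- function(x_um, y_um, diameter_um,
                              genotype = "g", phenotype = "membrane",
                              expressing = TRUE, mode = "static_membrane",
                              period_s = NA_real_, phase = 0, axis_angle = 0,
                              fov = 1L, pamcherry_basal = 10,
                              activated = FALSE, diffusion_scale = 0,
                              fov_um = 128) {
  n <- length(x_um)
  for (nm in c("genotype", "expressing", "mode", "period_s", "phase",
               "axis_angle", "fov", "pamcherry_basal", "activated",
               "diffusion_scale"))
    assign(nm, rep_len(get(nm), n))
  pop <- data.frame(id = seq_len(n), fov = fov, genotype = genotype,
                    x_um = x_um, y_um = y_um, diameter_um = diameter_um,
                    expressing = expressing, mode = mode, period_s = period_s,
                    phase = phase, axis_angle = axis_angle,
                    pamcherry_basal = pamcherry_basal, activated = activated,
                    diffusion_scale = diffusion_scale,
                    stringsAsFactors = FALSE)
  gnames <- unique(pop$genotype)
  phen <- rep_len(phenotype, length(gnames))
  attr(pop, "genotypes") <- lapply(seq_along(gnames), function(i)
    genotype_spec(gnames[i], phen[i]))
  attr(pop, "config") <- list(fov_um = fov_um)
  class(pop) <- c("liposome_population", "data.frame")
  pop
}

# exhaustive minimum-total-distance matching oracle (per frame, anchors fixed)
brute_force_tracks <- function(per_frame, max_disp = 5) {
  f0 <- per_frame[[1]]
  anchors <- cbind(f0$centroid_x_um, f0$centroid_y_um)
  n <- nrow(anchors)
  assign_frames <- lapply(per_frame[-1], function(det) {
    m <- nrow(det)
    dmat <- sqrt(outer(anchors[, 1], det$centroid_x_um, `-`)^2 +
                 outer(anchors[, 2], det$centroid_y_um, `-`)^2)
    dmat[dmat > max_disp] <- NA
    best <- NULL; best_cost <- Inf; best_n <- -1L
    perms <- gtools_permutations(m)
    for (p in seq_len(nrow(perms))) {
      # assignment: track i -> detection perms[p, i] (first n columns), or NA
      asg <- perms[p, seq_len(min(n, m))]
      cost <- 0; cnt <- 0L; ok <- TRUE
      asg_full <- rep(NA_integer_, n)
      for (i in seq_len(min(n, m))) {
        d <- dmat[i, asg[i]]
        if (!is.na(d)) { cost <- cost + d; cnt <- cnt + 1L; asg_full[i] <- asg[i] }
      }
      # maximize matches first, then minimize total distance
      if (cnt > best_n || (cnt == best_n && cost < best_cost)) {
        best <- asg_full; best_cost <- cost; best_n <- cnt
      }
    }
    best
  })
  assign_frames
}

# all permutations of 1..m (m <= 8)
gtools_permutations <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(m - 1L)
  out <- matrix(0L, 0, m)
  for (k in seq_len(m)) {
    block <- cbind(k, matrix(setdiff(seq_len(m), k)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# closed-form probability that a pulsing liposome (uniform random phase) shows
# both membrane states across the sampled frame times
pulsing_dynamic_probability <- function(period, frame_times) {
  # state_i(u) = [frac(t_i/period + u) < 0.5]; piecewise constant in u
  br <- sort(unique(c(outer(c(0, 0.5), -frame_times / period, `+`)) %% 1))
  br <- c(br, br[1] + 1)
  p <- 0
  for (k in seq_len(length(br) - 1)) {
    u <- (br[k] + br[k + 1]) / 2
    s <- ((frame_times / period + u) %% 1) < 0.5
    if (any(s) && !all(s)) p <- p + (br[k + 1] - br[k])
  }
  p
}

# radial mean-intensity profile of an image around a center (um)
radial_profile <- function(img, cx, cy, bin_um = 0.25, max_r = 15) {
  px <- attr(img, "px_um")
  xs <- (seq_len(ncol(img)) - 0.5) * px
  ys <- (seq_len(nrow(img)) - 0.5) * px
  dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  bins <- floor(dist / bin_um)
  keep <- dist <= max_r
  means <- tapply(img[keep], bins[keep], mean)
  data.frame(r_um = (as.numeric(names(means)) + 0.5) * bin_um,
             intensity = as.numeric(means))
}

# match detections to ground truth by centroid distance; precision is judged
# against all liposomes, recall against the detectable (interior) subset
match_detections <- function(det, gt_all, gt_detectable = gt_all, tol_um = 2) {
  dmat <- function(gt) sqrt(outer(gt$x_um, det$centroid_x_um, `-`)^2 +
                            outer(gt$y_um, det$centroid_y_um, `-`)^2)
  list(precision = if (nrow(det) && nrow(gt_all))
         mean(apply(dmat(gt_all), 2, min) <= tol_um) else NA_real_,
       recall = if (nrow(det) && nrow(gt_detectable))
         mean(apply(dmat(gt_detectable), 1, min) <= tol_um) else NA_real_)
}

two_gene_config <- function(n_fov = 1L, per_fov = c(100L, 100L),
                            p_expression = 0.6) {
  population_config(
    genotypes = list(genotype_spec("YFP", "lumen"),
                     genotype_spec("btubB", "none")),
    volume_fractions = c(1, 39) / 40,
    p_expression = p_expression,
    liposomes_per_fov = per_fov, n_fov = n_fov)
}
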