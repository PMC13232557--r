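#' Imaging calibration
#'
#' Physical and detector calibration of the synthetic confocal render:
#' a 128x128 um FOV imaged at 512x512 px (0.25 um/px), Gaussian PSF,
#' per-channel gains, a constant detector offset, Poisson shot noise and
#' Gaussian read noise, quantized to 16 bit. Default frame times follow the
#' time-lapse protocol of 12-s intervals over 48 s (5 frames).
#'
#' Channel gain semantics: `membrane` is the per-pixel annulus amplitude
#' (total membrane-dye signal therefore scales with circumference);
#' `protein` is the per-pixel lumen amplitude of a fully luminal reporter in
#' a confocal section (the total reporter budget of a liposome is
#' `gain * disk area`, redistributed between membrane and lumen by the
#' dynamic-mode membrane fraction without creating or destroying signal);
#' `pamcherry` multiplies the liposome's basal level (x20 when activated).
#'
#' @param fov_um FOV side (um).
#' @param image_px image side (px); `image_px * px_um` must equal `fov_um`.
#' @param px_um pixel size (um).
#' @param psf_sigma_um Gaussian PSF sigma (um).
#' @param channel_gains named vector for `membrane`, `protein`, `pamcherry`.
#' @param background_offset detector offset (counts).
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param frame_times_s strictly increasing acquisition times (s).
#' @param bit_depth bits per pixel (16).
#' @return an `imaging_config` list.
#' @export
imaging_config <- function(fov_um = 128, image_px = 512L, px_um = 0.25,
                           psf_sigma_um = 0.3,
                           channel_gains = c(membrane = 300, protein = 400,
                                             pamcherry = 20),
                           background_offset = 100, read_noise_sd = 20,
                           frame_times_s = seq(0, 48, by = 12),
                           bit_depth = 16L) {
  if (abs(image_px * px_um - fov_um) > 1e-9)
    stop("image_px * px_um must equal fov_um")
  if (is.unsorted(frame_times_s, strictly = TRUE))
    stop("frame_times_s must be strictly increasing")
  stopifnot(all(c("membrane", "protein", "pamcherry") %in% names(channel_gains)))
  structure(list(fov_um = fov_um, image_px = as.integer(image_px), px_um = px_um,
                 psf_sigma_um = psf_sigma_um, channel_gains = channel_gains,
                 background_offset = background_offset,
                 read_noise_sd = read_noise_sd, frame_times_s = frame_times_s,
                 bit_depth = as.integer(bit_depth)),
            class = "imaging_config")
}

CHANNELS <- c("membrane", "protein", "pamcherry")
ANNULUS_W_UM <- 0.3    # membrane annulus FWHM-ish width before PSF
ANNULUS_SIGMA <- 0.15  # Gaussian radial profile sigma (um); avoids raster gaps

# phenotype lookup for a population's genotypes
genotype_phenotypes <- function(population) {
  g <- attr(population, "genotypes")
  setNames(vapply(g, `[[`, "", "phenotype"), vapply(g, `[[`, "", "name"))
}

# ideal (pre-PSF, pre-noise, no offset) image of one FOV's liposomes
render_ideal <- function(pop_fov, config, channel, t) {
  npx <- config$image_px; px <- config$px_um
  img <- matrix(0, npx, npx)  # [row, col]
  if (nrow(pop_fov) == 0) return(img)
  phen <- genotype_phenotypes(pop_fov)
  gains <- config$channel_gains
  for (i in seq_len(nrow(pop_fov))) {
    r <- pop_fov$diameter_um[i] / 2
    cx <- pop_fov$x_um[i]; cy <- pop_fov$y_um[i]
    ext <- r + 4 * ANNULUS_SIGMA
    c0 <- max(1L, floor((cx - ext) / px) + 1L); c1 <- min(npx, ceiling((cx + ext) / px))
    r0 <- max(1L, floor((cy - ext) / px) + 1L); r1 <- min(npx, ceiling((cy + ext) / px))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    xs <- (cols - 0.5) * px; ys <- (rows - 0.5) * px
    dx <- outer(xs - cx, rep(1, length(rows)))          # [col, row]
    dy <- outer(rep(1, length(cols)), ys - cy)
    dist <- sqrt(dx^2 + dy^2)
    disk <- dist <= r
    ringw <- exp(-0.5 * ((dist - r) / ANNULUS_SIGMA)^2)
    ann <- ringw > 0.01
    add <- matrix(0, length(cols), length(rows))
    if (channel == "membrane") {
      add <- add + gains["membrane"] * ringw
    } else if (channel == "pamcherry") {
      lev <- pop_fov$pamcherry_basal[i] * if (pop_fov$activated[i]) 20 else 1
      add[disk] <- add[disk] + gains["pamcherry"] * lev
    } else if (channel == "protein") {
      if (isTRUE(pop_fov$expressing[i]) && phen[pop_fov$genotype[i]] != "none") {
        prof <- membrane_fraction(pop_fov[i, ], t)
        n_disk <- sum(disk); n_ann <- sum(ann)
        total <- gains["protein"] * n_disk
        if (n_disk > 0) add[disk] <- add[disk] + (1 - prof$m) * total / n_disk
        if (n_ann > 0) {
          w <- ringw[ann]
          if (!is.na(prof$cap_center)) {
            theta <- atan2(dy[ann], dx[ann])
            dth <- (theta - prof$cap_center + pi) %% (2 * pi) - pi
            w <- w * exp(-0.5 * (dth / prof$cap_sigma)^2)
          }
          add[ann] <- add[ann] + prof$m * total * w / sum(w)
        } else if (n_disk > 0) {
          add[disk] <- add[disk] + prof$m * total / n_disk
        }
      }
    } else stop("unknown channel: ", channel)
    # add[col, row] -> img[row, col]
    img[rows, cols] <- img[rows, cols] + t(add)
  }
  img
}

#' Render one channel of one FOV at time t
#'
#' Draws the ideal image (membrane annuli with a Gaussian radial profile of
#' sigma 0.15 um, about 0.3 um wide; reporter signal
#' split between annulus and lumen by the dynamic-mode membrane fraction;
#' photoactivatable-reporter lumen disks, x20 when activated), convolves it
#' with the Gaussian PSF, then applies Poisson shot noise, Gaussian read
#' noise and the detector offset, and quantizes to 16 bit. `noise = FALSE`
#' returns the blurred ideal image plus offset, unquantized.
#'
#' @param pop_fov rows of a `liposome_population` for a single FOV.
#' @param config an [imaging_config()].
#' @param channel one of `"membrane"`, `"protein"`, `"pamcherry"`.
#' @param t acquisition time (s); drives oscillation phases.
#' @param noise apply the detector noise model?
#' @param seed optional integer seed for the noise draws.
#' @return numeric matrix `image_px` x `image_px` (rows = y), with
#'   attributes `px_um` and `channel`.
#' @export
render_frame <- function(pop_fov, config, channel = CHANNELS, t = 0,
                         noise = TRUE, seed = NULL) {
  channel <- match.arg(channel)
  ideal <- render_ideal(pop_fov, config, channel, t)
  sig_px <- config$psf_sigma_um / config$px_um
  blurred <- if (max(ideal) > 0)
    EBImage::gblur(ideal, sigma = sig_px) else ideal
  blurred[blurred < 0] <- 0
  img <- if (noise) {
    with_seed(seed, {
      shot <- matrix(rpois(length(blurred), blurred), nrow(blurred))
      round(shot + rnorm(length(blurred), 0, config$read_noise_sd) +
              config$background_offset)
    })
  } else blurred + config$background_offset
  maxv <- 2^config$bit_depth - 1
  img[img < 0] <- 0; img[img > maxv] <- maxv
  attr(img, "px_um") <- config$px_um
  attr(img, "channel") <- channel
  img
}

#' Render a multi-channel time-lapse of one FOV
#'
#' Renders the requested channels at every frame time; liposome centers
#' advance by Brownian steps between frames and oscillation phases advance
#' with elapsed time.
#'
#' @param pop_fov rows of a `liposome_population` for one FOV.
#' @param config an [imaging_config()].
#' @param channels channels to render.
#' @param noise apply the detector noise model?
#' @param seed integer seed driving both motion and noise.
#' @return a `frame_stack`: list with `fov_id`, `times`, `channels` (named
#'   list of per-frame image lists), `positions` (per-frame center matrices)
#'   and `config`.
#' @export
render_video <- function(pop_fov, config, channels = c("membrane", "protein"),
                         noise = TRUE, seed = NULL) {
  times <- config$frame_times_s
  nfr <- length(times)
  seeds <- if (is.null(seed)) rep(list(NULL), nfr * length(channels) + nfr)
           else as.list(derive_seeds(seed, nfr * length(channels) + nfr))
  si <- 1L
  centers <- as.matrix(pop_fov[, c("x_um", "y_um")])
  out <- lapply(channels, function(ch) vector("list", nfr))
  names(out) <- channels
  pos <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    if (k > 1) {
      dt <- times[k] - times[k - 1]
      centers <- brownian_step(centers, dt, pop_fov$diffusion_scale,
                               fov_um = config$fov_um, seed = seeds[[si]])
    }
    si <- si + 1L
    pop_fov$x_um <- centers[, 1]; pop_fov$y_um <- centers[, 2]
    pos[[k]] <- centers
    for (ch in channels) {
      out[[ch]][[k]] <- render_frame(pop_fov, config, ch, t = times[k],
                                     noise = noise, seed = seeds[[si]])
      si <- si + 1L
    }
  }
  structure(list(fov_id = pop_fov$fov[1], times = times, channels = out,
                 positions = pos, config = config),
            class = "frame_stack")
}

#' Write a frame stack as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major: all frames (in time order) of the first
#' channel, then the next channel. The sidecar records the calibration and
#' the page order.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  maxv <- 2^stack$config$bit_depth - 1
  pages <- list()
  for (ch in names(stack$channels))
    for (img in stack$channels[[ch]])
      pages[[length(pages) + 1L]] <- unclass(img) / maxv
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(fov_id = stack$fov_id, times_s = stack$times,
               channel_order = names(stack$channels),
               page_order = "channel-major, frames in time order",
               px_um = stack$config$px_um, fov_um = stack$config$fov_um,
               bit_depth = stack$config$bit_depth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar next to it).
#' @return a list with `times`, `channels` (named list of image lists) and
#'   the sidecar metadata.
#' @export
read_frame_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  maxv <- 2^side$bit_depth - 1
  nfr <- length(side$times_s)
  channels <- list()
  for (j in seq_along(side$channel_order)) {
    ch <- side$channel_order[j]
    channels[[ch]] <- lapply(seq_len(nfr), function(k) {
      img <- round(pages[[(j - 1L) * nfr + k]] * maxv)
      attr(img, "px_um") <- side$px_um
      attr(img, "channel") <- ch
      img
    })
  }
  list(fov_id = side$fov_id, times = side$times_s, channels = channels,
       meta = side)
}

#' Write a preview PNG of one rendered frame
#'
#' Linear contrast stretch to the image's own range; for documentation only.
#'
#' @param img rendered image matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_preview_png <- function(img, path) {
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  EBImage::writeImage(EBImage::Image(t(scaled)), path, type = "png")
  invisible(path)
}
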