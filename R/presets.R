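#' Preset experiment configurations
#'
#' Fully-populated configurations encoding the four experiment designs the
#' pipeline emulates:
#' \describe{
#'   \item{`fig2_yfp_mock`}{Two-gene mock library (YFP reporter vs
#'     non-fluorescent control) mixed at a 1:39 volume ratio, intensity
#'     selection on the reporter channel, 84-uW photoactivation with
#'     stimulation not restricted to the FOV center, 15% FACS recovery,
#'     3 replicates.}
#'   \item{`fig3_mind_mock`}{minD vs control mock library with the
#'     membrane-recruited eGFP-MinC reporter; per-replicate volume ratios
#'     1:9, 1:39, 1:39; class-2 (membrane localization) selection at 34 uW.}
#'   \item{`fig4_dynamics`}{Min-oscillation time lapse: 12-s intervals over
#'     48 s (5 frames), two-class detection, 5-um nearest-neighbor linking,
#'     dynamic (class-change) events stimulated at the FOV center, 34 uW.}
#'   \item{`fig5_mts_library`}{Nine-variant MTS library (two functional
#'     membrane binders), class-2 selection at 34 uW, post-sort variant
#'     quantification by synthetic amplicon sequencing.}
#' }
#' Field-of-view counts are desk-scale choices (tens of FOVs rather than
#' thousands) that keep full runs to minutes while leaving enough sorted
#' liposomes for stable fractions.
#'
#' @param name preset name.
#' @param seed master seed stored in the config.
#' @param n_fov optional override of the per-replicate FOV count.
#' @return an [experiment_config()].
#' @export
preset <- function(name = c("fig2_yfp_mock", "fig3_mind_mock",
                            "fig4_dynamics", "fig5_mts_library"),
                   seed = 1L, n_fov = NULL) {
  name <- match.arg(name)
  switch(name,
    fig2_yfp_mock = {
      pop <- population_config(
        genotypes = list(genotype_spec("YFP", "lumen"),
                         genotype_spec("btubB", "none")),
        volume_fractions = c(1, 39) / 40,
        n_fov = if (is.null(n_fov)) 150L else n_fov)
      experiment_config(
        population = pop,
        detection = detection_params(detect_channel = "protein"),
        laser = laser_model(84),
        facs = facs_model(recovery_prob = 0.15),
        mode = "static", policy = "anywhere", qualify = "all",
        replicates = 3L, seed = seed)
    },
    fig3_mind_mock = {
      pop <- population_config(
        genotypes = list(genotype_spec("minD", "membrane"),
                         genotype_spec("btubB", "none")),
        volume_fractions = c(1, 39) / 40,
        n_fov = if (is.null(n_fov)) 40L else n_fov)
      experiment_config(
        population = pop,
        detection = detection_params(detect_channel = "membrane"),
        laser = laser_model(34),
        facs = facs_model(recovery_prob = 0.15),
        mode = "static", policy = "anywhere", qualify = "class2",
        replicates = 3L, seed = seed,
        volume_fraction_schedule = list(c(1, 9) / 10, c(1, 39) / 40,
                                        c(1, 39) / 40))
    },
    fig4_dynamics = {
      pop <- population_config(
        genotypes = list(genotype_spec("minDE", "oscillatory"),
                         genotype_spec("minD_btubB", "membrane")),
        volume_fractions = c(0.5, 0.5),
        n_fov = if (is.null(n_fov)) 4L else n_fov)
      experiment_config(
        population = pop,
        detection = detection_params(detect_channel = "membrane"),
        tracker = tracker_params(),
        laser = laser_model(34),
        facs = facs_model(recovery_prob = 0.15),
        mode = "video", policy = "center_only",
        replicates = 3L, seed = seed)
    },
    fig5_mts_library = {
      lib <- mts_variant_library()
      gts <- lapply(seq_len(nrow(lib)), function(i)
        genotype_spec(lib$name[i],
                      phenotype = if (lib$functional[i]) "membrane" else "lumen",
                      mts_variant = lib$mts[i]))
      pop <- population_config(
        genotypes = gts, volume_fractions = rep(1 / 9, 9),
        n_fov = if (is.null(n_fov)) 20L else n_fov)
      experiment_config(
        population = pop,
        detection = detection_params(detect_channel = "membrane"),
        laser = laser_model(34),
        facs = facs_model(recovery_prob = 0.15),
        mode = "static", policy = "anywhere", qualify = "class2",
        replicates = 3L, seed = seed,
        sequencing_reads = 2000L)
    })
}

#' List available presets
#'
#' @return character vector of preset names.
#' @export
preset_list <- function() c("fig2_yfp_mock", "fig3_mind_mock",
                            "fig4_dynamics", "fig5_mts_library")
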