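#' Load an experiment configuration from a YAML or JSON document
#'
#' The document either names a `preset` (with optional top-level overrides
#' `seed`, `replicates`, `n_fov`, `mode`, `policy`, `qualify`,
#' `sequencing_reads`) or provides the stage configurations explicitly under
#' `population`, `imaging`, `detection`, `tracker`, `laser`, `facs`, each a
#' mapping of the corresponding constructor's arguments (genotypes as a list
#' of [genotype_spec()] argument mappings).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an [experiment_config()].
#' @export
load_experiment_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(doc$preset)) {
    cfg <- preset(doc$preset,
                  seed = if (!is.null(doc$seed)) as.integer(doc$seed) else 1L,
                  n_fov = doc$n_fov)
    for (f in c("replicates", "mode", "policy", "qualify", "sequencing_reads"))
      if (!is.null(doc[[f]])) cfg[[f]] <- doc[[f]]
    return(cfg)
  }
  if (is.null(doc$population)) stop("config must name a preset or a population")
  poparg <- doc$population
  poparg$genotypes <- lapply(poparg$genotypes, function(g)
    do.call(genotype_spec, g))
  poparg$volume_fractions <- as.numeric(poparg$volume_fractions)
  if (!is.null(poparg$mode_weights))
    poparg$mode_weights <- unlist(poparg$mode_weights)
  args <- list(population = do.call(population_config, poparg))
  build <- list(imaging = imaging_config, detection = detection_params,
                tracker = tracker_params, laser = laser_model,
                facs = facs_model)
  for (nm in names(build))
    if (!is.null(doc[[nm]])) args[[nm]] <- do.call(build[[nm]], doc[[nm]])
  for (f in c("mode", "policy", "qualify", "replicates", "seed",
              "sequencing_reads", "save_images"))
    if (!is.null(doc[[f]])) args[[f]] <- doc[[f]]
  do.call(experiment_config, args)
}
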