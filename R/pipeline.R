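#' Experiment configuration
#'
#' Bundles all stage configurations of an end-to-end screening-and-sorting
#' experiment: population simulation, imaging, detection, tracking,
#' photoactivation, FACS, the stimulation policy, and replication.
#'
#' @param population a [population_config()].
#' @param imaging an [imaging_config()].
#' @param detection a [detection_params()].
#' @param tracker a [tracker_params()] (video mode).
#' @param laser a [laser_model()].
#' @param facs a [facs_model()].
#' @param mode `"static"` (single frame per FOV) or `"video"` (time lapse
#'   with tracking and dynamic-event calling).
#' @param policy stimulation policy, `"center_only"` or `"anywhere"`.
#' @param qualify which detections qualify in static mode: `"all"`
#'   (intensity selection) or `"class2"` (membrane-localized reporter).
#' @param replicates number of replicate experiments.
#' @param seed master seed; every stage seed derives from it.
#' @param volume_fraction_schedule optional list of per-replicate volume
#'   fraction vectors (e.g. 1:9, 1:39, 1:39 mixes).
#' @param sequencing_reads if positive and all genotypes carry a 6-nt MTS
#'   window, pre- and post-sort pools are additionally quantified by
#'   synthetic amplicon sequencing with this many reads.
#' @param save_images write per-FOV TIFF stacks into the run directory?
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(population, imaging = imaging_config(),
                              detection = detection_params(),
                              tracker = tracker_params(),
                              laser = laser_model(), facs = facs_model(),
                              mode = c("static", "video"),
                              policy = c("anywhere", "center_only"),
                              qualify = c("all", "class2"),
                              replicates = 1L, seed = 1L,
                              volume_fraction_schedule = NULL,
                              sequencing_reads = 0L,
                              save_images = FALSE) {
  mode <- match.arg(mode); policy <- match.arg(policy)
  qualify <- match.arg(qualify)
  stopifnot(inherits(population, "population_config"), replicates >= 1)
  if (!is.null(volume_fraction_schedule) &&
      length(volume_fraction_schedule) != replicates)
    stop("volume_fraction_schedule must have one entry per replicate")
  structure(list(population = population, imaging = imaging,
                 detection = detection, tracker = tracker, laser = laser,
                 facs = facs, mode = mode, policy = policy, qualify = qualify,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 volume_fraction_schedule = volume_fraction_schedule,
                 sequencing_reads = as.integer(sequencing_reads),
                 save_images = save_images),
            class = "experiment_config")
}

# screen one FOV: returns list(detections, targets)
screen_fov <- function(pop_fov, config, seed) {
  seeds <- derive_seeds(seed, 3L)
  if (config$mode == "static") {
    # the membrane channel is only consumed when it drives detection
    mem <- if (config$detection$detect_channel == "membrane")
      render_frame(pop_fov, config$imaging, "membrane", t = 0,
                   seed = seeds[1]) else NULL
    prot <- render_frame(pop_fov, config$imaging, "protein", t = 0,
                         seed = seeds[2])
    det <- detect_frame(mem, prot, config$detection)
    tgt <- select_targets(det, policy = config$policy,
                          fov_um = config$imaging$fov_um,
                          qualify = config$qualify)
    list(detections = det, targets = tgt, tracks = NULL)
  } else {
    stack <- render_video(pop_fov, config$imaging,
                          channels = c("membrane", "protein"),
                          seed = seeds[1])
    dets <- lapply(seq_along(stack$times), function(k)
      video_filter(detect_frame(stack$channels$membrane[[k]],
                                stack$channels$protein[[k]],
                                config$detection)))
    tp <- config$tracker; tp$frame_count <- length(stack$times)
    tracks <- link_tracks(dets, tp)
    tgt <- select_targets(tracks, policy = config$policy,
                          fov_um = config$imaging$fov_um)
    det_flat <- do.call(rbind, lapply(seq_along(dets), function(k)
      if (nrow(dets[[k]])) cbind(frame = k, dets[[k]]) else NULL))
    list(detections = det_flat, targets = tgt, tracks = tracks,
         stack = if (config$save_images) stack else NULL)
  }
}

run_replicate <- function(config, rep, rep_seed, outdir = NULL) {
  seeds <- derive_seeds(rep_seed, 5L)
  popcfg <- config$population
  if (!is.null(config$volume_fraction_schedule))
    popcfg$volume_fractions <- config$volume_fraction_schedule[[rep]]
  pop <- sample_population(popcfg, seed = seeds[1])
  gnames <- vapply(popcfg$genotypes, `[[`, "", "name")
  shares <- setNames(vapply(popcfg$genotypes, `[[`, 0, "template_share"), gnames)
  tab <- table(factor(pop$genotype, levels = gnames))
  counts_pre <- as.numeric(tab) * shares[gnames]
  names(counts_pre) <- gnames

  fov_seeds <- derive_seeds(seeds[2], popcfg$n_fov)
  all_det <- list(); all_tgt <- list()
  for (f in seq_len(popcfg$n_fov)) {
    pf <- pop[pop$fov == f, , drop = FALSE]
    attr(pf, "genotypes") <- attr(pop, "genotypes")
    res <- screen_fov(pf, config, fov_seeds[f])
    if (!is.null(res$detections) && nrow(res$detections))
      all_det[[length(all_det) + 1L]] <- cbind(fov = f, res$detections)
    if (nrow(res$targets))
      all_tgt[[length(all_tgt) + 1L]] <- cbind(fov = f, res$targets)
    if (!is.null(res$stack) && !is.null(outdir))
      write_frame_stack(res$stack, file.path(outdir, sprintf("fov_%03d.tiff", f)))
  }
  detections <- if (length(all_det)) do.call(rbind, all_det) else NULL
  targets <- if (length(all_tgt)) do.call(rbind, all_tgt) else
    data.frame(fov = integer(0), x_um = numeric(0), y_um = numeric(0))

  act <- photoactivate(pop, targets, config$laser, seed = seeds[3])
  events <- facs_measure(act$population, config$facs, seed = seeds[4])
  gates <- config$facs$gates
  if (is.null(gates)) {
    ref_events <- facs_measure(pop, config$facs, seed = seeds[5])
    gates <- derive_gates(ref_events)
  }
  sorted <- gate_and_sort(events, gates)

  phen <- genotype_phenotypes(pop)
  truth_ids <- pop$id[pop$expressing & phen[pop$genotype] != "none"]
  act_ids <- act$population$id[act$population$activated]
  cm <- confusion_metrics(act_ids, truth_ids, pop$id)

  post_ids <- sorted$sorted_ids
  counts_post <- as.numeric(table(factor(
    pop$genotype[match(post_ids, pop$id)], levels = gnames))) * shares[gnames]
  names(counts_post) <- gnames
  empty_sort <- sum(counts_post) == 0
  vt <- if (!empty_sort) fractions_and_fold(counts_pre, counts_post) else NULL

  seqres <- NULL
  if (config$sequencing_reads > 0 && !empty_sort) {
    mts <- vapply(popcfg$genotypes, `[[`, "", "mts_variant")
    if (all(nchar(mts) == 6L)) {
      vtab <- data.frame(name = gnames, mts = mts, stringsAsFactors = FALSE)
      mk <- function(fr, sd) {
        reads <- generate_reads(fr / sum(fr), config$sequencing_reads,
                                error_rate = 0.005, junk_frac = 0.05,
                                variants = vtab, seed = sd)
        cv <- count_variants(filter_reads(reads), variants = vtab)
        cts <- setNames(rep(0, length(gnames)), gnames)
        known <- intersect(names(cv$counts), gnames)
        cts[known] <- cv$counts[known]
        list(counts = cts, qc = cv$qc)
      }
      sseeds <- derive_seeds(seeds[4] + 1L, 2L)
      pre <- mk(counts_pre, sseeds[1]); post <- mk(counts_post, sseeds[2])
      seqres <- list(variant_table = fractions_and_fold(pre$counts, post$counts),
                     qc = list(pre = pre$qc, post = post$qc))
    }
  }

  rep_res <- list(
    replicate = rep,
    screened = nrow(pop),
    stimulated = nrow(targets),
    activated = length(act_ids),
    events = nrow(events),
    sorted = length(post_ids),
    quadrants = sorted$quadrants,
    facs_precision = sorted$precision,
    activation_precision = cm$precision,
    sensitivity = cm$sensitivity,
    empty_sort = empty_sort,
    gates = gates,
    variant_table = vt,
    sequencing = seqres)

  if (!is.null(outdir)) {
    write_population_csv(act$population, file.path(outdir, "population.csv"))
    if (!is.null(detections))
      write_detections_csv(detections, file.path(outdir, "detections.csv"))
    write.csv(targets, file.path(outdir, "targets.csv"), row.names = FALSE)
    write_events_csv(sorted$events, file.path(outdir, "events.csv"))
    if (!is.null(vt))
      write.csv(vt, file.path(outdir, "variants.csv"), row.names = FALSE)
  }
  rep_res
}

#' Run an end-to-end screening-and-sorting experiment
#'
#' Executes simulate -> render -> detect (-> track in video mode) ->
#' select targets -> photoactivate -> FACS -> gate/sort -> quantify for each
#' replicate; the run is deterministic given the config seed. A failing
#' replicate is logged and skipped; the others continue.
#'
#' @param config an [experiment_config()] (or a preset name, see
#'   [preset()]).
#' @param outdir optional run directory for per-stage artifacts
#'   (`config.json`, per-replicate CSVs, `report.json`, `log.txt`).
#' @return a `run_report`: per-replicate results plus aggregate mean/SD of
#'   the post-sort fraction and fold enrichment per genotype.
#' @export
run_experiment <- function(config, outdir = NULL) {
  if (is.character(config)) config <- preset(config)
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- if (!is.null(outdir)) file.path(outdir, "log.txt") else NULL
  logmsg <- function(...) {
    msg <- sprintf(...)
    if (!is.null(logf)) cat(msg, "\n", file = logf, append = TRUE, sep = "")
    invisible(msg)
  }
  logmsg("run_experiment seed=%d replicates=%d mode=%s policy=%s",
         config$seed, config$replicates, config$mode, config$policy)
  logmsg("laser %g uW p_off=%.5f (neighbor_mean=%.3f)", config$laser$power_uW,
         config$laser$p_off, config$laser$neighbor_mean)
  rep_seeds <- derive_seeds(config$seed, config$replicates)
  reps <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    rdir <- if (!is.null(outdir)) {
      d <- file.path(outdir, sprintf("replicate_%d", r))
      dir.create(d, showWarnings = FALSE); d
    } else NULL
    reps[[r]] <- tryCatch(
      run_replicate(config, r, rep_seeds[r], rdir),
      error = function(e) {
        logmsg("replicate %d failed: %s", r, conditionMessage(e))
        list(replicate = r, failed = TRUE, error = conditionMessage(e))
      })
    if (is.null(reps[[r]]$failed))
      logmsg("replicate %d: screened=%d stimulated=%d sorted=%d", r,
             reps[[r]]$screened, reps[[r]]$stimulated, reps[[r]]$sorted)
  }
  ok <- Filter(function(x) is.null(x$failed) && !isTRUE(x$empty_sort), reps)
  aggregate <- if (length(ok))
    summarize_replicates(lapply(ok, `[[`, "variant_table")) else NULL
  report <- structure(list(replicates = reps, aggregate = aggregate,
                           config_summary = list(
                             mode = config$mode, policy = config$policy,
                             qualify = config$qualify, seed = config$seed,
                             n_fov = config$population$n_fov,
                             p_off = config$laser$p_off,
                             recovery_prob = config$facs$recovery_prob)),
                      class = "run_report")
  if (!is.null(outdir)) {
    jsonlite::write_json(serialize_report(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(config_summary_full(config),
                         file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

serialize_report <- function(report) {
  list(config = report$config_summary,
       replicates = lapply(report$replicates, function(r) {
         if (!is.null(r$failed)) return(list(replicate = r$replicate,
                                             failed = TRUE, error = r$error))
         list(replicate = r$replicate, screened = r$screened,
              stimulated = r$stimulated, activated = r$activated,
              events = r$events, sorted = r$sorted,
              quadrants = as.list(r$quadrants),
              facs_precision = r$facs_precision,
              activation_precision = r$activation_precision,
              sensitivity = r$sensitivity, empty_sort = r$empty_sort,
              variant_table = r$variant_table)
       }),
       aggregate = report$aggregate)
}

config_summary_full <- function(config) {
  lapply(config, function(x) if (is.list(x)) unclass(x) else x)
}

#' @export
print.run_report <- function(x, ...) {
  ok <- Filter(function(r) is.null(r$failed), x$replicates)
  cat(sprintf("<run_report> %d replicate(s), mode %s, policy %s\n",
              length(x$replicates), x$config_summary$mode,
              x$config_summary$policy))
  for (r in ok) {
    cat(sprintf("  rep %d: screened %d, stimulated %d, activated %d, sorted %d",
                r$replicate, r$screened, r$stimulated, r$activated, r$sorted))
    if (!is.null(r$variant_table)) {
      top <- r$variant_table[which.max(r$variant_table$fold_enrichment), ]
      cat(sprintf("; %s: %.1f%% -> %.1f%% (%.1f-fold)", top$genotype,
                  100 * top$frac_pre, 100 * top$frac_post,
                  top$fold_enrichment))
    }
    cat("\n")
  }
  if (!is.null(x$aggregate)) {
    cat("  aggregate (mean +/- SD across replicates):\n")
    for (i in seq_len(nrow(x$aggregate)))
      cat(sprintf("    %s: post %.1f +/- %.1f%%, fold %.1f +/- %.1f\n",
                  x$aggregate$genotype[i],
                  100 * x$aggregate$frac_post_mean[i],
                  100 * x$aggregate$frac_post_sd[i],
                  x$aggregate$fold_mean[i], x$aggregate$fold_sd[i]))
  }
  invisible(x)
}
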