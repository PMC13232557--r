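#' Per-genotype fractions and fold enrichment
#'
#' Computes presort and post-sort fractions from non-negative counts over a
#' common genotype set and per-genotype fold enrichment
#' `frac_post / frac_pre`. A zero presort fraction with a positive post-sort
#' count is flagged rather than reported as infinite.
#'
#' @param counts_pre,counts_post named non-negative count vectors over the
#'   same genotype set.
#' @return a `variant_table` data frame: `genotype`, `count_pre`,
#'   `count_post`, `frac_pre`, `frac_post`, `fold_enrichment`, `flagged`.
#' @export
fractions_and_fold <- function(counts_pre, counts_post) {
  if (is.null(names(counts_pre)) || is.null(names(counts_post)))
    stop("counts must be named by genotype")
  if (!setequal(names(counts_pre), names(counts_post)))
    stop("pre and post counts must cover the same genotype set")
  counts_post <- counts_post[names(counts_pre)]
  if (any(counts_pre < 0) || any(counts_post < 0))
    stop("counts must be non-negative")
  tot_pre <- sum(counts_pre); tot_post <- sum(counts_post)
  if (tot_pre == 0 || tot_post == 0)
    stop("zero total count in one condition")
  frac_pre <- counts_pre / tot_pre
  frac_post <- counts_post / tot_post
  flagged <- frac_pre == 0 & counts_post > 0
  fold <- ifelse(frac_pre > 0, frac_post / frac_pre, NA_real_)
  structure(data.frame(genotype = names(counts_pre),
                       count_pre = as.numeric(counts_pre),
                       count_post = as.numeric(counts_post),
                       frac_pre = as.numeric(frac_pre),
                       frac_post = as.numeric(frac_post),
                       fold_enrichment = as.numeric(fold),
                       flagged = flagged,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("variant_table", "data.frame"))
}

#' Summarize fold enrichment across replicate tables
#'
#' Per-replicate fold enrichment is computed before averaging; the summary
#' reports mean and SD across replicates per genotype.
#'
#' @param tables list of `variant_table`s (replicates).
#' @return data frame with per-genotype mean and SD of fractions and fold.
#' @export
summarize_replicates <- function(tables) {
  g <- tables[[1]]$genotype
  getcol <- function(col) vapply(tables, function(tb)
    tb[[col]][match(g, tb$genotype)], numeric(length(g)))
  fp <- matrix(getcol("frac_pre"), nrow = length(g))
  fq <- matrix(getcol("frac_post"), nrow = length(g))
  fe <- matrix(getcol("fold_enrichment"), nrow = length(g))
  data.frame(genotype = g,
             frac_pre_mean = rowMeans(fp), frac_pre_sd = apply(fp, 1, stats::sd),
             frac_post_mean = rowMeans(fq), frac_post_sd = apply(fq, 1, stats::sd),
             fold_mean = rowMeans(fe), fold_sd = apply(fe, 1, stats::sd),
             stringsAsFactors = FALSE)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(concentration). A perfect-doubling
#' assay has slope `-1/log10(2)` (about -3.3219); the amplification
#' efficiency `10^(-1/slope) - 1` is reported but not used for correction.
#'
#' @param concentration_pM template concentrations (pM), at least 3 distinct.
#' @param cq quantification-cycle values.
#' @return a `standard_curve` list: `slope` (Cq per log10 pM), `intercept`
#'   (Cq at 1 pM), `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(concentration_pM, cq) {
  stopifnot(length(concentration_pM) == length(cq))
  if (length(unique(concentration_pM)) < 3)
    stop("need at least 3 distinct concentrations")
  fit <- lm(cq ~ log10(concentration_pM))
  sl <- unname(coef(fit)[2])
  # summary.lm warns on exact fits, which are legitimate calibration inputs
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = sl, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / sl) - 1),
            class = "standard_curve")
}

#' Concentration from a Cq value
#'
#' Inverts the standard curve: `10^((cq - intercept) / slope)`.
#'
#' @param cq Cq value(s).
#' @param curve a [fit_standard_curve()] result (slope must be negative).
#' @return concentration(s) in pM.
#' @export
qpcr_concentration <- function(cq, curve) {
  if (curve$slope >= 0) stop("invalid curve: slope must be negative")
  10^((cq - curve$intercept) / curve$slope)
}

#' Filter reads by length
#'
#' Keeps reads whose sequence length lies in the closed window (1100--1400
#' bp by default, the recovery window for the 1398-bp amplicon).
#'
#' @param records read table with a `sequence` column.
#' @param length_window `c(min, max)` in bp.
#' @return the kept records.
#' @export
filter_reads <- function(records, length_window = c(1100, 1400)) {
  if (!is.data.frame(records) || is.null(records$sequence))
    stop("records must be a data frame with a sequence column")
  len <- nchar(records$sequence)
  out <- records[len >= length_window[1] & len <= length_window[2], ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MTS window extractor configuration
#'
#' Anchored extraction of the 6-nt variant window: exact 12-nt flank match
#' in either orientation (reverse complement searched), replacing read
#' mapping for desk-scale determinism.
#'
#' @param left_flank,right_flank anchor sequences flanking the window
#'   (defaults come from the shipped synthetic reference).
#' @param window_nt window length (6).
#' @param length_window read-length filter window in bp.
#' @return an `mts_extractor` list.
#' @export
mts_extractor <- function(left_flank = NULL, right_flank = NULL,
                          window_nt = 6L, length_window = c(1100, 1400)) {
  if (is.null(left_flank) || is.null(right_flank)) {
    ref <- mts_reference()
    if (is.null(left_flank))
      left_flank <- substr(ref$sequence, ref$window_start - 12,
                           ref$window_start - 1)
    if (is.null(right_flank))
      right_flank <- substr(ref$sequence, ref$window_end + 1,
                            ref$window_end + 12)
  }
  if (!nzchar(left_flank) || !nzchar(right_flank))
    stop("flanks must be non-empty")
  if (window_nt != 6L) stop("the variant window is 6 nt")
  structure(list(left_flank = toupper(left_flank),
                 right_flank = toupper(right_flank),
                 window_nt = as.integer(window_nt),
                 length_window = length_window),
            class = "mts_extractor")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# locate a unique exact flank pair in one sequence; NA when absent/ambiguous
extract_window_one <- function(seq, ex) {
  find_all <- function(pat, s) {
    m <- gregexpr(pat, s, fixed = TRUE)[[1]]
    m[m > 0]
  }
  lf <- find_all(ex$left_flank, seq)
  rf <- find_all(ex$right_flank, seq)
  if (length(lf) > 1 || length(rf) > 1) return(list(status = "ambiguous_flank"))
  if (length(lf) == 1 && length(rf) == 1) {
    ws <- lf + nchar(ex$left_flank)
    if (rf - ws == ex$window_nt)
      return(list(status = "ok", window = substr(seq, ws, ws + ex$window_nt - 1)))
    return(list(status = "flank_spacing"))
  }
  list(status = "missing_flank")
}

#' Count MTS variants in length-filtered reads
#'
#' For each read, locates the left and right 12-nt flank anchors by exact
#' match (trying both orientations via reverse complement), extracts the
#' 6-nt window between them, and tallies windows. Reads with missing or
#' ambiguous anchors, wrong flank spacing, or an N in the window are
#' discarded and accounted for in the QC statistics.
#'
#' @param records length-filtered read table with a `sequence` column.
#' @param extractor an [mts_extractor()].
#' @param variants optional data frame with `name` and `mts`: tallied
#'   windows matching a known variant are labeled with its name; unknown
#'   windows are kept under their sequence.
#' @return list with `counts` (named vector), `qc` (named discard counts:
#'   `ok`, `missing_flank`, `ambiguous_flank`, `flank_spacing`,
#'   `ambiguous_base`) and `windows` (per-read window or `NA`).
#' @export
count_variants <- function(records, extractor = mts_extractor(),
                           variants = mts_variant_library()) {
  n <- nrow(records)
  windows <- rep(NA_character_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    s <- toupper(records$sequence[i])
    res <- extract_window_one(s, extractor)
    if (res$status != "ok") {
      res2 <- extract_window_one(revcomp_chr(s), extractor)
      if (res2$status == "ok" ||
          (res$status == "missing_flank" && res2$status != "missing_flank"))
        res <- res2
    }
    if (res$status == "ok" && grepl("N", res$window, fixed = TRUE))
      res <- list(status = "ambiguous_base")
    status[i] <- res$status
    if (res$status == "ok") windows[i] <- res$window
  }
  tally <- table(windows[!is.na(windows)])
  cn <- names(tally)
  if (!is.null(variants)) {
    hit <- match(cn, variants$mts)
    cn[!is.na(hit)] <- variants$name[hit[!is.na(hit)]]
  }
  counts <- setNames(as.numeric(tally), cn)
  qc_levels <- c("ok", "missing_flank", "ambiguous_flank", "flank_spacing",
                 "ambiguous_base")
  qc <- setNames(vapply(qc_levels, function(lv) sum(status == lv), 0L),
                 qc_levels)
  list(counts = counts, qc = qc, windows = windows)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table>\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f Cq/log10(pM), intercept %.2f, R^2 %.4f, efficiency %.1f%%\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}
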