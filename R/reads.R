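#' Synthetic reference amplicon for the MTS variant library
#'
#' Loads the synthetic 1398-bp reference amplicon shipped with the package.
#' The 6-nt MTS window (two mutagenized codons of the MinD membrane targeting
#' sequence) sits at the position encoded in the FASTA header; the sequence
#' itself is synthetic (randomly generated once), since only the amplicon
#' length, the window size and the flank-anchoring logic matter to the
#' pipeline.
#'
#' @return list with `sequence` (character), `window_start`, `window_end`
#'   (1-based, inclusive) and `wt` (the wild-type 6-nt window).
#' @export
mts_reference <- function() {
  path <- system.file("extdata", "mts_amplicon_synthetic.fa", package = "liposort")
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)[1]
  gv <- function(key) as.integer(sub(sprintf(".*%s=(\\d+).*", key), "\\1", hdr))
  list(sequence = as.character(ss[[1]]),
       window_start = gv("window_start"), window_end = gv("window_end"),
       wt = sub(".*wt=([ACGT]+).*", "\\1", hdr))
}

#' The nine-variant MTS mock library
#'
#' A mock library of nine MTS variants mirroring a two-codon mutagenesis of
#' the hydrophobic patch: Var1 is the wild type (FL) and Var7 (LH) is the
#' second membrane-binding variant; the remaining variants substitute charged
#' residues and are non-functional membrane binders.
#'
#' @return data frame with `name`, `mts` (6-nt window) and `functional`.
#' @export
mts_variant_library <- function() {
  data.frame(
    name = paste0("Var", 1:9),
    mts = c("TTTCTG",  # Var1 F L  (wild type)
            "GATAAA",  # Var2 D K
            "CGTGAA",  # Var3 R E
            "AAACGT",  # Var4 K R
            "GAAGAT",  # Var5 E D
            "CGTCGT",  # Var6 R R
            "CTGCAT",  # Var7 L H  (functional)
            "GATCTG",  # Var8 D L
            "AAAGAA"), # Var9 K E
    functional = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Generate synthetic amplicon reads
#'
#' Synthesizes long-read-style FASTQ records from a mixture of MTS variants:
#' each read is the full-length reference amplicon with the variant's 6-nt
#' window substituted, per-base substitution errors at `error_rate`, Gaussian
#' length jitter applied by trimming the read ends, a random orientation
#' (half the reads are reverse-complemented), and an optional fraction of
#' off-length junk reads. Base qualities are fixed at Q20.
#'
#' @param variant_fractions named numeric vector of variant fractions
#'   (summing to 1); names must exist in `variants$name`.
#' @param n_reads number of reads (>= 0).
#' @param error_rate per-base substitution probability.
#' @param length_model list with `mean` and `sd` of the read length in bp;
#'   lengths are capped at the amplicon length.
#' @param junk_frac fraction of junk reads with lengths outside 1100--1400 bp.
#' @param variants data frame with `name` and `mts`; default
#'   [mts_variant_library()].
#' @param reference a [mts_reference()]-style list.
#' @param seed optional integer seed.
#' @return data frame with `id`, `sequence`, `quality`, `true_variant`.
#' @export
generate_reads <- function(variant_fractions, n_reads, error_rate = 0.005,
                           length_model = list(mean = 1398, sd = 30),
                           junk_frac = 0, variants = mts_variant_library(),
                           reference = mts_reference(), seed = NULL) {
  stopifnot(n_reads >= 0)
  if (abs(sum(variant_fractions) - 1) > 1e-9)
    stop("variant fractions must sum to 1")
  unknown <- setdiff(names(variant_fractions), variants$name)
  if (length(unknown)) stop("unknown variant name(s): ", paste(unknown, collapse = ", "))
  if (n_reads == 0)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), true_variant = character(0),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    ref <- reference$sequence; L0 <- nchar(ref)
    ws <- reference$window_start; we <- reference$window_end
    vnames <- names(variant_fractions)
    pick <- vnames[sample.int(length(vnames), n_reads, replace = TRUE,
                              prob = variant_fractions)]
    junk <- runif(n_reads) < junk_frac
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      if (junk[i]) {
        jl <- if (runif(1) < 0.5) sample(300:1000, 1L) else sample(1450:1800, 1L)
        seqs[i] <- paste(sample(c("A", "C", "G", "T"), jl, replace = TRUE),
                         collapse = "")
        next
      }
      mts <- variants$mts[match(pick[i], variants$name)]
      s <- paste0(substr(ref, 1, ws - 1), mts, substr(ref, we + 1, L0))
      len <- min(L0, max(200L, round(rnorm(1, length_model$mean, length_model$sd))))
      cut <- L0 - len
      if (cut > 0) {
        left <- sample(0:cut, 1L)
        s <- substr(s, left + 1, left + len)
      }
      if (error_rate > 0) {
        ch <- strsplit(s, "")[[1]]
        hit <- which(runif(length(ch)) < error_rate)
        if (length(hit)) {
          for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          s <- paste(ch, collapse = "")
        }
      }
      seqs[i] <- s
    }
    flip <- runif(n_reads) < 0.5
    if (any(flip))
      seqs[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
    data.frame(id = sprintf("read_%06d", seq_len(n_reads)),
               sequence = seqs,
               quality = vapply(nchar(seqs), function(n)
                 paste(rep("5", n), collapse = ""), ""),  # Q20
               true_variant = ifelse(junk, NA_character_, pick),
               stringsAsFactors = FALSE)
  })
}

#' Write reads as 4-line FASTQ
#'
#' @param reads data frame from [generate_reads()] (columns `id`, `sequence`,
#'   `quality`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (plain or gzipped).
#' @return data frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(ss), sequence = as.character(ss),
             quality = as.character(Biostrings::quality(ss)),
             stringsAsFactors = FALSE)
}
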