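#' Minimum SNP count for an ROH run
#'
#' The false-positive-controlled minimum number of consecutive homozygous
#' SNPs: l = ln(alpha / (n_snps * n_individuals)) / ln(1 - mean_het),
#' rounded down by default. alpha is the tolerated rate of false-positive
#' runs, n_snps and n_individuals give the number of tests, and mean_het is
#' the average SNP heterozygosity. The same count is used as the sliding
#' window size and as the minimum SNPs per emitted run.
#'
#' @param alpha tolerated false-positive rate (0.05).
#' @param n_snps SNPs per individual.
#' @param n_individuals genotyped individuals.
#' @param mean_het mean SNP heterozygosity, in (0, 1).
#' @param rounding "floor" (default) or "ceiling".
#' @return integer SNP count.
#' @export
min_run_snps <- function(alpha, n_snps, n_individuals, mean_het,
                         rounding = c("floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (n_snps < 1 || n_individuals < 1) stop("counts must be >= 1")
  if (mean_het <= 0 || mean_het >= 1)
    stop("mean_het must be strictly between 0 and 1")
  l <- log(alpha / (n_snps * n_individuals)) / log(1 - mean_het)
  as.integer(if (rounding == "floor") floor(l) else ceiling(l))
}

#' Parameters for sliding-window ROH detection
#'
#' Defaults follow common array practice: at most one heterozygous and one
#' missing call per window, 1 Mb maximum gap between consecutive SNPs, 1 Mb
#' minimum run length, at least 1 SNP per 500 kb, a 5% false-positive rate
#' in the window-size formula, and a 5% window-coverage threshold for
#' calling a SNP in-run.
#'
#' @param max_het_in_window allowed heterozygous calls per window.
#' @param max_missing_in_window allowed missing calls per window.
#' @param max_gap_bp maximum gap between consecutive SNPs in a run.
#' @param min_length_bp minimum run length.
#' @param min_density_bp maximum bp per SNP inside a run (500 kb = at least
#'   1 SNP every 500 kb).
#' @param alpha false-positive rate fed to [min_run_snps()].
#' @param window_overlap_threshold minimum fraction of eligible windows
#'   covering a SNP for it to be in-run.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(max_het_in_window = 1L, max_missing_in_window = 1L,
                       max_gap_bp = 1e6, min_length_bp = 1e6,
                       min_density_bp = 5e5, alpha = 0.05,
                       window_overlap_threshold = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(max_het_in_window >= 0, max_missing_in_window >= 0,
            max_gap_bp >= 0, min_length_bp >= 0, min_density_bp > 0,
            window_overlap_threshold >= 0)
  structure(list(max_het_in_window = as.integer(max_het_in_window),
                 max_missing_in_window = as.integer(max_missing_in_window),
                 max_gap_bp = max_gap_bp, min_length_bp = min_length_bp,
                 min_density_bp = min_density_bp, alpha = alpha,
                 window_overlap_threshold = window_overlap_threshold),
            class = "roh_params")
}

# greedy left-maximal segmentation of one in-run stretch, honouring the
# per-run het/missing allowances and the maximum gap
split_stretch <- function(idx, het, miss, pos, params) {
  out <- list()
  i <- 1L
  n <- length(idx)
  while (i <= n) {
    hets <- 0L; misses <- 0L
    j <- i
    hets <- het[i]; misses <- miss[i]
    while (j < n) {
      gap_ok <- pos[j + 1L] - pos[j] <= params$max_gap_bp
      h2 <- hets + het[j + 1L]; m2 <- misses + miss[j + 1L]
      if (!gap_ok || h2 > params$max_het_in_window ||
          m2 > params$max_missing_in_window) break
      j <- j + 1L; hets <- h2; misses <- m2
    }
    out[[length(out) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  out
}

#' Detect runs of homozygosity by sliding window
#'
#' A window of `window_snps` SNPs (by default the [min_run_snps()] value for
#' the panel) slides one SNP at a time along each chromosome of each
#' individual. A window is eligible when it contains at most
#' `max_het_in_window` heterozygous and `max_missing_in_window` missing
#' calls; a SNP is in-run when the fraction of eligible windows covering it
#' is at least `window_overlap_threshold`. Maximal stretches of in-run SNPs
#' are segmented greedily from the left so that every emitted run respects
#' the het/missing allowances and the maximum gap, then filtered by minimum
#' length, minimum SNP count and SNP density. Segment bounds are the
#' positions of the first and last SNP in the run (1-based inclusive);
#' length is end - start + 1.
#'
#' @param panel a `genotype_panel` (QC-filtered; missing calls allowed up to
#'   the window allowance).
#' @param params a [roh_params()].
#' @param window_snps window size override; default computes
#'   [min_run_snps()] from the panel's dimensions and mean heterozygosity.
#' @return data.frame: individual, chr, start_bp, end_bp, n_snps, length_bp,
#'   length_class.
#' @export
detect_roh <- function(panel, params = roh_params(), window_snps = NULL) {
  g <- dosage(panel)
  if (is.null(window_snps)) {
    mean_het <- mean(colMeans(g == 1L, na.rm = TRUE), na.rm = TRUE)
    window_snps <- min_run_snps(params$alpha, n_markers(panel),
                                n_samples(panel), mean_het)
  }
  L <- as.integer(window_snps)
  if (L < 1L) stop("window size must be >= 1 (got ", L, ")")
  res <- list()
  for (j in chrom_index(panel)) {
    S <- length(j)
    if (S < L) {
      warning("chromosome ", panel$map$chr[j[1L]], " has fewer SNPs (", S,
              ") than the window size (", L, "); skipped")
      next
    }
    pos <- panel$map$pos[j]
    nw <- S - L + 1L
    for (i in seq_len(n_samples(panel))) {
      gi <- g[i, j]
      het <- as.integer(!is.na(gi) & gi == 1L)
      miss <- as.integer(is.na(gi))
      ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(miss))
      w <- seq_len(nw)
      elig <- (ch[w + L] - ch[w]) <= params$max_het_in_window &
        (cm[w + L] - cm[w]) <= params$max_missing_in_window
      ce <- c(0L, cumsum(elig))
      s <- seq_len(S)
      lo <- pmax(1L, s - L + 1L); hi <- pmin(s, nw)
      ncov <- hi - lo + 1L
      nelig <- ce[hi + 1L] - ce[lo]
      in_run <- nelig / ncov >= params$window_overlap_threshold
      r <- rle(in_run)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        for (seg in split_stretch(idx, het[idx], miss[idx], pos[idx], params)) {
          a <- idx[seg[1L]]; b <- idx[seg[2L]]
          len <- pos[b] - pos[a] + 1
          nsnp <- b - a + 1L
          if (len >= params$min_length_bp && nsnp >= L &&
              nsnp * params$min_density_bp >= len) {
            res[[length(res) + 1L]] <-
              data.frame(individual = panel$samples[i],
                         chr = panel$map$chr[j[1L]],
                         start_bp = pos[a], end_bp = pos[b],
                         n_snps = nsnp, length_bp = len,
                         stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(res)) {
    out <- data.frame(individual = character(), chr = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE)
    out$length_class <- factor(character(), levels = roh_classes)
    return(out)
  }
  out <- do.call(rbind, res)
  out$length_class <- roh_length_class(out$length_bp)
  rownames(out) <- NULL
  out
}

#' Summarize ROH segments
#'
#' @param segments data.frame from [detect_roh()].
#' @param panel the panel the segments came from.
#' @return list with `class_summary` (count, mean length and share per
#'   length class), `chromosome_summary` (segment count and mean
#'   per-individual coverage percentage of the mapped chromosome length),
#'   `individual_summary` (segment count and total length per individual)
#'   and `overall` (total count, mean length).
#' @export
summarize_roh <- function(segments, panel) {
  cls <- factor(segments$length_class, levels = roh_classes)
  class_summary <- data.frame(
    length_class = roh_classes,
    n = as.integer(table(cls)),
    mean_length_bp = as.numeric(tapply(segments$length_bp, cls, mean)[roh_classes]),
    fraction = as.integer(table(cls)) / max(nrow(segments), 1L))
  chrs <- unique(panel$map$chr)
  chr_len <- vapply(chrs, function(ch) {
    p <- panel$map$pos[panel$map$chr == ch]; max(p) - min(p) + 1
  }, numeric(1))
  nind <- n_samples(panel)
  chromosome_summary <- data.frame(
    chr = chrs,
    n = vapply(chrs, function(ch) sum(segments$chr == ch), integer(1)),
    coverage_pct = vapply(chrs, function(ch) {
      tot <- sum(segments$length_bp[segments$chr == ch])
      100 * (tot / nind) / chr_len[[ch]]
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  ind <- factor(segments$individual, levels = panel$samples)
  individual_summary <- data.frame(
    individual = panel$samples,
    n = as.integer(table(ind)),
    total_length_bp = as.numeric(tapply(segments$length_bp, ind, sum)),
    stringsAsFactors = FALSE)
  individual_summary$total_length_bp[is.na(individual_summary$total_length_bp)] <- 0
  list(class_summary = class_summary,
       chromosome_summary = chromosome_summary,
       individual_summary = individual_summary,
       overall = list(n_segments = nrow(segments),
                      mean_length_bp = mean(segments$length_bp)))
}

#' Write ROH segments as tab-separated text
#' @param segments data.frame from [detect_roh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roh <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
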