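roh_classes <- c("1-5Mb", "5-10Mb", "10-20Mb", ">20Mb")

# length class of an ROH segment: [1,5), [5,10), [10,20), >=20 Mb
roh_length_class <- function(length_bp) {
  cut(length_bp, breaks = c(-Inf, 5e6, 1e7, 2e7, Inf),
      labels = roh_classes, right = FALSE)
}

#' ROH-based inbreeding coefficient
#'
#' F_ROH is the summed length of an individual's ROH segments (optionally
#' restricted to one length class) over the mapped genome length, i.e. the
#' sum over chromosomes of (last - first marker position + 1).
#'
#' @param segments ROH table from [detect_roh()].
#' @param panel the `genotype_panel` the segments came from.
#' @param class one of "total", "1-5Mb", "5-10Mb", "10-20Mb", ">20Mb".
#' @return named numeric vector over all panel samples (0 when an
#'   individual has no segments).
#' @export
f_roh <- function(segments, panel, class = "total") {
  class <- match.arg(class, c("total", roh_classes))
  gl <- genome_length(panel)
  out <- stats::setNames(numeric(n_samples(panel)), panel$samples)
  if (nrow(segments)) {
    seg <- if (class == "total") segments
    else segments[segments$length_class == class, , drop = FALSE]
    if (nrow(seg)) {
      tot <- tapply(seg$length_bp, seg$individual, sum)
      out[names(tot)] <- tot / gl
    }
  }
  out
}

# frequencies and site mask shared by the SNP-based estimators
polymorphic_freq <- function(panel) {
  g <- dosage(panel)
  if (anyNA(g)) stop("panel has missing genotypes; run fill_missing() first")
  p <- colMeans(g) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all SNPs monomorphic")
  list(g = g[, keep, drop = FALSE], p = p[keep])
}

#' Excess-homozygosity inbreeding coefficient (PLINK \code{--het})
#'
#' F_HOM = (O_hom - E_hom) / (L - E_hom) per individual, with
#' E_hom = sum over polymorphic sites of 1 - 2 p q * 2n/(2n - 1) using
#' sample allele frequencies (the small-sample correction PLINK applies),
#' O_hom the observed homozygous-site count, and L the number of sites used.
#'
#' @param panel a `genotype_panel` with no missing genotypes.
#' @return named numeric vector, one coefficient per individual.
#' @export
f_hom <- function(panel) {
  n <- n_samples(panel)
  if (n < 2) stop("need at least 2 individuals")
  pf <- polymorphic_freq(panel)
  e_hom <- sum(1 - 2 * pf$p * (1 - pf$p) * (2 * n / (2 * n - 1)))
  L <- length(pf$p)
  o_hom <- rowSums(pf$g != 1L)
  stats::setNames((o_hom - e_hom) / (L - e_hom), panel$samples)
}

#' VanRaden genomic relationship matrix
#'
#' A = Z Z' / (sum of 2 p_j q_j), where Z is the dosage matrix centred by
#' twice the sample allele frequency. Monomorphic markers are excluded.
#'
#' @param panel a `genotype_panel` with no missing genotypes.
#' @return symmetric samples x samples matrix.
#' @export
vanraden_grm <- function(panel) {
  pf <- polymorphic_freq(panel)
  Z <- sweep(pf$g, 2L, 2 * pf$p)
  A <- tcrossprod(Z) / sum(2 * pf$p * (1 - pf$p))
  dimnames(A) <- list(panel$samples, panel$samples)
  A
}

#' GRM-diagonal inbreeding coefficient
#'
#' F_GRM of individual i is the i-th diagonal element of the VanRaden GRM
#' minus 1.
#'
#' @param panel a `genotype_panel` with no missing genotypes.
#' @return named numeric vector.
#' @export
f_grm <- function(panel) diag(vanraden_grm(panel)) - 1

#' Uniting-gametes inbreeding coefficient
#'
#' F_UNI averages the per-site quantity
#' (x^2 - (1 + 2p) x + 2 p^2) / (2 p q) over polymorphic sites, where x is
#' the dosage — the correlation between uniting gametes (GCTA's
#' \code{--ibc} Fhat3).
#'
#' @param panel a `genotype_panel` with no missing genotypes.
#' @return named numeric vector.
#' @export
f_uni <- function(panel) {
  pf <- polymorphic_freq(panel)
  p <- pf$p
  x <- pf$g
  term <- sweep(x^2, 2L, 2 * p * (1 - p), "/") -
    sweep(x, 2L, (1 + 2 * p) / (2 * p * (1 - p)), "*") +
    matrix(2 * p^2 / (2 * p * (1 - p)), nrow(x), ncol(x), byrow = TRUE)
  stats::setNames(rowMeans(term), panel$samples)
}

#' All eight genomic inbreeding coefficients
#'
#' F_ROH for the total and each length class (1-5, 5-10, 10-20, >20 Mb),
#' plus F_HOM, F_GRM and F_UNI.
#'
#' @param panel a filled `genotype_panel`.
#' @param segments ROH table from [detect_roh()].
#' @return data.frame, one row per individual, eight coefficient columns.
#' @export
inbreeding_coefficients <- function(panel, segments) {
  data.frame(
    individual = panel$samples,
    F_ROH_total = f_roh(segments, panel, "total"),
    F_ROH_1_5 = f_roh(segments, panel, "1-5Mb"),
    F_ROH_5_10 = f_roh(segments, panel, "5-10Mb"),
    F_ROH_10_20 = f_roh(segments, panel, "10-20Mb"),
    F_ROH_gt20 = f_roh(segments, panel, ">20Mb"),
    F_HOM = f_hom(panel),
    F_GRM = f_grm(panel),
    F_UNI = f_uni(panel),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlations among inbreeding coefficients
#'
#' Pairwise Pearson r with two-sided p-values from the t distribution on
#' n - 2 degrees of freedom. Zero-variance coefficients give NA.
#'
#' @param coefficients data.frame from [inbreeding_coefficients()] (the
#'   `individual` column, if present, is ignored) or any numeric matrix of
#'   per-individual coefficients.
#' @return list with matrices `r`, `p`, and `stars` ("**" p < 0.01, "***"
#'   p < 0.001).
#' @export
inbreeding_correlations <- function(coefficients) {
  x <- coefficients
  if (is.data.frame(x)) x <- x[, vapply(x, is.numeric, TRUE), drop = FALSE]
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 individuals")
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  list(r = r, p = p, stars = stars)
}
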