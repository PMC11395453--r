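#' Per-SNP genetic diversity statistics
#'
#' For each marker with allele-2 frequency p (q = 1 - p): observed
#' heterozygosity HO (fraction of heterozygous calls), expected
#' heterozygosity HE = 2pq, minor allele frequency MAF = min(p, q),
#' polymorphism information content PIC = 1 - (p^2 + q^2) - 2 p^2 q^2, and
#' effective allele number Ae = 1 / (p^2 + q^2). The panel summary reports
#' the means and PN, the proportion of polymorphic markers (MAF > 0).
#'
#' @param panel a `genotype_panel` with no missing genotypes (run
#'   [fill_missing()] first).
#' @return list with `per_snp` (data.frame: snp, chr, pos, HO, HE, MAF,
#'   PIC, Ae) and `summary` (named list of means plus PN).
#' @export
snp_diversity <- function(panel) {
  g <- dosage(panel)
  if (anyNA(g)) stop("panel has missing genotypes; run fill_missing() first")
  p <- colMeans(g) / 2
  q <- 1 - p
  per_snp <- data.frame(
    snp = panel$map$snp, chr = panel$map$chr, pos = panel$map$pos,
    HO = colMeans(g == 1L),
    HE = 2 * p * q,
    MAF = pmin(p, q),
    PIC = 1 - (p^2 + q^2) - 2 * p^2 * q^2,
    Ae = 1 / (p^2 + q^2),
    stringsAsFactors = FALSE)
  summary <- list(HO = mean(per_snp$HO), HE = mean(per_snp$HE),
                  MAF = mean(per_snp$MAF), PIC = mean(per_snp$PIC),
                  Ae = mean(per_snp$Ae), PN = mean(per_snp$MAF > 0))
  list(per_snp = per_snp, summary = summary)
}

#' Windowed nucleotide diversity
#'
#' Nucleotide diversity per bp in non-overlapping windows: for each window,
#' pi = sum over sites of 2 * n_ref * n_alt / (n * (n - 1)) divided by the
#' window width, with n the number of sampled chromosomes at the site.
#' Array-ascertained SNPs overstate per-site diversity and omit invariant
#' sequence, so these values are not comparable to sequence-based pi.
#'
#' @param panel a `genotype_panel`.
#' @param window_bp window width (default 50 kb, non-overlapping).
#' @return data.frame: chr, start, end, n_snps, pi.
#' @export
windowed_pi <- function(panel, window_bp = 50000) {
  g <- dosage(panel)
  nchrom <- 2 * colSums(!is.na(g))
  nalt <- colSums(g, na.rm = TRUE)
  contrib <- ifelse(nchrom > 1, 2 * nalt * (nchrom - nalt) /
                      (nchrom * (nchrom - 1)), 0)
  out <- lapply(split(seq_len(n_markers(panel)), panel$map$chr), function(j) {
    pos <- panel$map$pos[j]
    win <- (pos - 1) %/% window_bp
    nwin <- max(win) + 1L
    pi_sum <- numeric(nwin); cnt <- integer(nwin)
    t1 <- tapply(contrib[j], win, sum)
    t2 <- tapply(rep(1L, length(j)), win, length)
    idx <- as.integer(names(t1)) + 1L
    pi_sum[idx] <- t1; cnt[idx] <- t2
    data.frame(chr = panel$map$chr[j[1L]],
               start = (seq_len(nwin) - 1L) * window_bp + 1,
               end = seq_len(nwin) * window_bp,
               n_snps = cnt, pi = pi_sum / window_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Linkage-disequilibrium decay
#'
#' Squared Pearson correlation of genotype dosages (Rogers-Huff style, no
#' phase needed) for every intra-chromosomal marker pair within
#' `max_dist_bp`, averaged in distance bins.
#'
#' @param panel a `genotype_panel` with no missing genotypes.
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp distance bin width.
#' @return data.frame: distance_bp (bin midpoint), mean_r2, n_pairs.
#' @export
ld_decay <- function(panel, max_dist_bp = 500000, bin_bp = 5000) {
  g <- dosage(panel)
  if (anyNA(g)) stop("panel has missing genotypes; run fill_missing() first")
  sds <- apply(g, 2L, stats::sd)
  nbin <- ceiling(max_dist_bp / bin_bp)
  r2_sum <- numeric(nbin); n_pair <- numeric(nbin)
  for (j in chrom_index(panel)) {
    j <- j[sds[j] > 0]
    if (length(j) < 2L) next
    pos <- panel$map$pos[j]
    Z <- scale(g[, j, drop = FALSE])
    n <- nrow(Z)
    for (a in seq_len(length(j) - 1L)) {
      b <- a + 1L
      bmax <- a
      while (bmax < length(j) && pos[bmax + 1L] - pos[a] <= max_dist_bp)
        bmax <- bmax + 1L
      if (bmax < b) next
      idx <- b:bmax
      r <- as.numeric(crossprod(Z[, a], Z[, idx, drop = FALSE])) / (n - 1)
      d <- pos[idx] - pos[a]
      bin <- pmin(pmax(ceiling(d / bin_bp), 1L), nbin)
      for (k in seq_along(idx)) {
        r2_sum[bin[k]] <- r2_sum[bin[k]] + r[k]^2
        n_pair[bin[k]] <- n_pair[bin[k]] + 1
      }
    }
  }
  keep <- n_pair > 0
  data.frame(distance_bp = (which(keep) - 0.5) * bin_bp,
             mean_r2 = r2_sum[keep] / n_pair[keep],
             n_pairs = n_pair[keep])
}

#' LD-based historical effective population size
#'
#' Sved-style inversion of the drift-recombination expectation of r^2. For
#' a distance bin at c Morgans (c = distance_bp * cM_per_Mb * 1e-8),
#' r2_adj = mean_r2 - 1/n corrects for sample size, and
#' Ne = (1 / (4 c)) * (1 / r2_adj - alpha) estimates the effective size
#' about t = 1 / (2 c) generations ago. Bins with non-positive adjusted r^2
#' are dropped. alpha = 2.2 applies the usual adjustment for mutation.
#'
#' @param ld_points data.frame from [ld_decay()].
#' @param n_individuals number of genotyped individuals.
#' @param cM_per_Mb linear genetic map density.
#' @param alpha mutation adjustment constant.
#' @return data.frame: generations_ago, ne, c_morgans, r2_adj.
#' @export
estimate_ne <- function(ld_points, n_individuals, cM_per_Mb = 1.0,
                        alpha = 2.2) {
  if (!nrow(ld_points)) stop("ld_points is empty")
  if (n_individuals < 2) stop("need at least 2 individuals")
  c_m <- ld_points$distance_bp * cM_per_Mb * 1e-8
  r2_adj <- ld_points$mean_r2 - 1 / n_individuals
  keep <- r2_adj > 0
  c_m <- c_m[keep]; r2_adj <- r2_adj[keep]
  out <- data.frame(generations_ago = 1 / (2 * c_m),
                    ne = (1 / (4 * c_m)) * (1 / r2_adj - alpha),
                    c_morgans = c_m, r2_adj = r2_adj)
  out[order(out$generations_ago), , drop = FALSE]
}

#' Principal component analysis of a genotype panel
#'
#' Eigendecomposition of the VanRaden genomic relationship matrix (the GCTA
#' convention). Coordinates are eigenvectors scaled by the square root of
#' their eigenvalues; variance fractions are eigenvalues over their total
#' (negative eigenvalues clamped to zero).
#'
#' @param panel a `genotype_panel` with no missing genotypes.
#' @param n_components number of components to return.
#' @return list with `coordinates` (samples x components), `variance_fraction`
#'   and `eigenvalues`.
#' @export
panel_pca <- function(panel, n_components = 10) {
  if (n_samples(panel) < 2) stop("need at least 2 samples")
  G <- vanraden_grm(panel)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (sum(lam) == 0) stop("zero-variance panel: all markers constant")
  k <- min(n_components, length(lam))
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  rownames(coords) <- panel$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       variance_fraction = lam[seq_len(k)] / sum(lam),
       eigenvalues = lam[seq_len(k)])
}
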