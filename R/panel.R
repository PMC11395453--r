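#' Genotype panel objects
#'
#' A `genotype_panel` holds diploid biallelic genotypes for a set of samples
#' together with a physical marker map. Genotypes are stored as two haplotype
#' matrices (`hap1`, `hap2`; samples in rows, markers in columns) coded 0 for
#' `allele1` and 1 for `allele2`; a missing genotype is `NA` in both matrices.
#' When `phased` is `TRUE` the two matrices are meaningful haplotypes (maternal
#' and paternal gametes); otherwise heterozygotes are stored with an arbitrary
#' 0/1 split and haplotype-based statistics refuse to run.
#'
#' @param map data.frame with columns `chr`, `snp`, `pos` (1-based bp),
#'   `allele1`, `allele2`; positions must be strictly increasing within each
#'   chromosome.
#' @param hap1,hap2 integer matrices (samples x markers) of 0/1/NA allele
#'   codes.
#' @param samples character vector of sample ids (row order of `hap1`).
#' @param phased logical flag; haplotype statistics (EHH, iHS) require `TRUE`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(map, hap1, hap2, samples, phased = FALSE) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("chr", "snp", "pos", "allele1", "allele2")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  map$chr <- as.character(map$chr)
  map$snp <- as.character(map$snp)
  map$pos <- as.numeric(map$pos)
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2)))
    stop("hap1 and hap2 dimensions differ")
  if (nrow(hap1) != length(samples))
    stop("number of samples (", length(samples), ") does not match genotype rows (",
         nrow(hap1), ")")
  if (ncol(hap1) != nrow(map))
    stop("number of markers (", nrow(map), ") does not match genotype columns (",
         ncol(hap1), ")")
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  bad <- which(is.na(hap1) != is.na(hap2))
  if (length(bad))
    stop("half-missing genotype calls at ", length(bad), " cells")
  obj <- list(samples = as.character(samples), map = map,
              hap1 = hap1, hap2 = hap2, phased = isTRUE(phased))
  class(obj) <- "genotype_panel"
  obj
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$samples), "samples x", nrow(x$map),
      "SNPs on", length(unique(x$map$chr)), "chromosome(s);",
      if (x$phased) "phased" else "unphased", "\n")
  miss <- mean(is.na(x$hap1))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
summary.genotype_panel <- function(object, ...) {
  d <- snp_diversity(fill_missing(object))
  cat("genotype_panel summary\n")
  print(object)
  cat(sprintf("  mean HO %.3f  mean HE %.3f  mean MAF %.3f  PN %.3f\n",
              mean(d$per_snp$HO), mean(d$per_snp$HE),
              mean(d$per_snp$MAF), d$summary$PN))
  invisible(d)
}

#' Number of samples / markers in a panel
#' @param panel a `genotype_panel`
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$samples)

#' @rdname n_samples
#' @export
n_markers <- function(panel) nrow(panel$map)

#' Genotype dosage matrix
#'
#' Dosage counts copies of `allele2` (0, 1, 2, or NA for missing).
#'
#' @param panel a `genotype_panel`
#' @return integer matrix, samples x markers.
#' @export
dosage <- function(panel) panel$hap1 + panel$hap2

#' Sample allele frequencies
#'
#' Frequency of `allele2` at each marker, computed over non-missing calls.
#'
#' @param panel a `genotype_panel`
#' @return numeric vector, one entry per marker.
#' @export
allele_freq <- function(panel) {
  g <- dosage(panel)
  colMeans(g, na.rm = TRUE) / 2
}

#' Subset a panel by markers and/or samples
#'
#' @param panel a `genotype_panel`
#' @param snps marker index (integer/logical) to keep; default all.
#' @param samples sample index to keep; default all.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, snps = NULL, samples = NULL) {
  if (is.null(snps)) snps <- seq_len(n_markers(panel))
  if (is.null(samples)) samples <- seq_len(n_samples(panel))
  genotype_panel(panel$map[snps, , drop = FALSE],
                 panel$hap1[samples, snps, drop = FALSE],
                 panel$hap2[samples, snps, drop = FALSE],
                 panel$samples[samples], panel$phased)
}

#' Total mapped genome length of a panel
#'
#' Sum over chromosomes of (last SNP position - first SNP position + 1),
#' the denominator used by ROH-based inbreeding coefficients.
#'
#' @param panel a `genotype_panel`
#' @return length in bp.
#' @export
genome_length <- function(panel) {
  sum(tapply(panel$map$pos, panel$map$chr, function(p) max(p) - min(p) + 1))
}

# internal: marker indices per chromosome, in map order
chrom_index <- function(panel) split(seq_len(n_markers(panel)), panel$map$chr)
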