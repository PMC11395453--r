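# fixture builders shared across test files

# panel from explicit haplotype matrices (samples x markers)
make_panel <- function(hap1, hap2, pos = NULL, chr = NULL, phased = TRUE) {
  m <- ncol(hap1)
  if (is.null(pos)) pos <- seq_len(m) * 1e5
  if (is.null(chr)) chr <- rep("1", m)
  map <- data.frame(chr = as.character(chr),
                    snp = sprintf("s%03d_%s", seq_len(m), chr),
                    pos = pos, allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  genotype_panel(map, hap1, hap2,
                 samples = sprintf("ind_%03d", seq_len(nrow(hap1))),
                 phased = phased)
}

# panel with exact allele-2 dosage counts per SNP (unphased coding)
panel_from_dosage <- function(g, pos = NULL, chr = NULL) {
  h1 <- ifelse(is.na(g), NA_integer_, as.integer(g == 2L))
  h2 <- ifelse(is.na(g), NA_integer_, as.integer(g >= 1L))
  make_panel(h1, h2, pos = pos, chr = chr, phased = FALSE)
}

# small random panel (<= 50 SNPs) with hets and missing calls, for the
# ROH brute-force comparisons
random_small_panel <- function(seed, n_ind = 8, n_snp = NULL) {
  set.seed(seed)
  if (is.null(n_snp)) n_snp <- sample(10:50, 1)
  p <- runif(n_snp, 0.05, 0.95)
  g <- matrix(rbinom(n_ind * n_snp, 2, rep(p, each = n_ind)), n_ind, n_snp)
  g[runif(length(g)) < 0.03] <- NA
  # irregular spacing so gap/density/length filters all matter
  pos <- sort(sample.int(8e6, n_snp))
  panel_from_dosage(g, pos = pos)
}
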