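#' QC thresholds for SNP filtering
#'
#' Defaults are the standard array-QC settings: SNPs are dropped when call
#' rate < 0.95, minor allele frequency < 0.05, or the Hardy-Weinberg exact
#' test p-value < 1e-6, applied in that order.
#'
#' @param min_call_rate minimum per-SNP call rate.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_p_floor minimum Hardy-Weinberg exact-test p-value.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                          hwe_p_floor = 1e-6) {
  v <- c(min_call_rate, min_maf, hwe_p_floor)
  if (any(v < 0 | v > 1)) stop("thresholds must be in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor), class = "qc_thresholds")
}

#' Hardy-Weinberg exact test (Wigginton)
#'
#' Exact two-sided p-value for deviation from Hardy-Weinberg genotype
#' proportions, summing the probabilities of all heterozygote counts no more
#' likely than the observed one (no mid-p adjustment), as in PLINK's
#' `--hardy`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (either homozygote ordering works).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  rare <- 2L * min(n_aa, n_bb) + n_ab
  hets <- seq(rare %% 2L, rare, by = 2L)
  # unnormalized probabilities by the two-sided recurrence around the mode
  np <- length(hets)
  prob <- numeric(np)
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  im <- match(mid, hets)
  prob[im] <- 1
  if (im < np) {
    for (k in im:(np - 1L)) {
      h <- hets[k]
      hom_r <- (rare - h) / 2
      prob[k + 1L] <- prob[k] * 4 * hom_r * (n - h - hom_r) / ((h + 2) * (h + 1))
    }
  }
  if (im > 1L) {
    for (k in im:2L) {
      h <- hets[k]
      hom_r <- (rare - h) / 2
      prob[k - 1L] <- prob[k] * h * (h - 1) /
        (4 * (hom_r + 1) * (n - h - hom_r + 1))
    }
  }
  prob <- prob / sum(prob)
  p <- sum(prob[prob <= prob[match(n_ab, hets)] * (1 + 1e-10)])
  min(p, 1)
}

#' Quality-control filter for a genotype panel
#'
#' Removes SNPs failing, in order: call rate, minor allele frequency, and
#' the Hardy-Weinberg exact test. Each SNP is charged to the first criterion
#' it fails, matching sequential filtering.
#'
#' @param panel a `genotype_panel`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `panel` (surviving SNPs) and `report` (data.frame of
#'   per-criterion removal counts; removed SNP ids in attribute
#'   `removed_snps`).
#' @export
qc_filter <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (n_markers(panel) == 0L) stop("empty panel")
  g <- dosage(panel)
  call_rate <- colMeans(!is.na(g))
  fail_cr <- call_rate < thresholds$min_call_rate
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  fail_maf <- !fail_cr & maf < thresholds$min_maf
  keep_so_far <- which(!fail_cr & !fail_maf)
  fail_hwe <- logical(n_markers(panel))
  for (j in keep_so_far) {
    gj <- g[, j]
    pval <- hwe_exact_p(sum(gj == 0L, na.rm = TRUE),
                        sum(gj == 1L, na.rm = TRUE),
                        sum(gj == 2L, na.rm = TRUE))
    fail_hwe[j] <- pval < thresholds$hwe_p_floor
  }
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) stop("all SNPs removed by QC")
  report <- data.frame(
    criterion = c("call_rate", "maf", "hwe", "kept"),
    n_snps = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe), sum(keep)),
    stringsAsFactors = FALSE)
  attr(report, "removed_snps") <- panel$map$snp[!keep]
  list(panel = subset_panel(panel, snps = which(keep)), report = report)
}

#' Write a QC removal report as tab-separated text
#' @param report the `report` element returned by [qc_filter()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fill missing genotypes with the major-allele homozygote
#'
#' A deliberately simple single-marker fill (not haplotype imputation):
#' every missing call becomes the homozygote of the marker's major allele.
#' Ties go to allele 1.
#'
#' @param panel a `genotype_panel`.
#' @return a `genotype_panel` with no missing calls.
#' @export
fill_missing <- function(panel) {
  miss <- is.na(panel$hap1)
  if (!any(miss)) return(panel)
  p <- allele_freq(panel)
  p[is.nan(p)] <- 0
  fill <- as.integer(p > 0.5)
  fill_mat <- matrix(fill, nrow = n_samples(panel), ncol = n_markers(panel),
                     byrow = TRUE)
  panel$hap1[miss] <- fill_mat[miss]
  panel$hap2[miss] <- fill_mat[miss]
  panel
}

plink_prefix <- function(path) sub("\\.(ped|map|bed|bim|fam|vcf)$", "", path)

#' Write a genotype panel to PLINK or VCF files
#'
#' @param panel a `genotype_panel`.
#' @param path file path; for `ped`/`bed` a prefix (extensions are added),
#'   for `vcf` the output file name.
#' @param format one of "ped", "bed", "vcf".
#' @return the main file written, invisibly.
#' @export
write_panel <- function(panel, path, format = c("ped", "bed", "vcf")) {
  format <- match.arg(format)
  switch(format,
         ped = write_ped(panel, plink_prefix(path)),
         bed = write_bed(panel, plink_prefix(path)),
         vcf = write_vcf(panel, path))
}

#' Read a genotype panel from PLINK or VCF files
#'
#' Marker order is preserved; missing genotypes are kept as missing. PED and
#' BED input is unphased; VCF input is marked phased when every genotype
#' separator is `|`.
#'
#' @param path file path or PLINK prefix.
#' @param format one of "ped", "bed", "vcf".
#' @return a `genotype_panel`.
#' @export
read_panel <- function(path, format = c("ped", "bed", "vcf")) {
  format <- match.arg(format)
  switch(format,
         ped = read_ped(plink_prefix(path)),
         bed = read_bed(plink_prefix(path)),
         vcf = read_vcf(path))
}

write_ped <- function(panel, prefix) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chr, map$snp, 0, map$pos),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  n <- n_samples(panel); m <- n_markers(panel)
  a1 <- map$allele1; a2 <- map$allele2
  al1 <- matrix(a1, n, m, byrow = TRUE); al2 <- matrix(a2, n, m, byrow = TRUE)
  c1 <- ifelse(is.na(panel$hap1), "0", ifelse(panel$hap1 == 1L, al2, al1))
  c2 <- ifelse(is.na(panel$hap2), "0", ifelse(panel$hap2 == 1L, al2, al1))
  geno <- matrix("", n, 2L * m)
  geno[, seq(1L, 2L * m, by = 2L)] <- c1
  geno[, seq(2L, 2L * m, by = 2L)] <- c2
  lines <- paste(panel$samples, panel$samples, 0, 0, 2, -9,
                 apply(geno, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(paste0(prefix, ".ped"))
}

read_map_file <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  mp <- data.table::fread(path, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  if (nrow(mp) == 0L) stop("empty map file: ", path)
  if (ncol(mp) < 4L) stop("malformed map file (need 4 columns): ", path)
  data.frame(chr = mp[[1L]], snp = mp[[2L]], pos = as.numeric(mp[[4L]]),
             stringsAsFactors = FALSE)
}

read_ped <- function(prefix) {
  pedf <- paste0(prefix, ".ped")
  if (!file.exists(pedf)) stop("file does not exist: ", pedf)
  if (file.size(pedf) == 0L) stop("empty ped file: ", pedf)
  map <- read_map_file(paste0(prefix, ".map"))
  ped <- data.table::fread(pedf, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop("malformed ped line: expected ", 6L + 2L * m, " fields, got ",
         ncol(ped), " (map lists ", m, " SNPs)")
  samples <- ped[[2L]]
  n <- nrow(ped)
  c1 <- as.matrix(ped[, 6L + seq(1L, 2L * m, by = 2L), drop = FALSE])
  c2 <- as.matrix(ped[, 6L + seq(2L, 2L * m, by = 2L), drop = FALSE])
  hap1 <- matrix(NA_integer_, n, m); hap2 <- matrix(NA_integer_, n, m)
  allele1 <- character(m); allele2 <- character(m)
  for (j in seq_len(m)) {
    obs <- c(c1[, j], c2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2L)
      stop("triallelic site ", map$snp[j], ": alleles ",
           paste(alleles, collapse = ","))
    if (length(alleles) == 0L) alleles <- c("A", "B")
    if (length(alleles) == 1L) alleles <- c(alleles, setdiff(c("A", "B"), alleles)[1L])
    allele1[j] <- alleles[1L]; allele2[j] <- alleles[2L]
    h1 <- ifelse(c1[, j] == "0", NA_integer_, as.integer(c1[, j] == alleles[2L]))
    h2 <- ifelse(c2[, j] == "0", NA_integer_, as.integer(c2[, j] == alleles[2L]))
    half <- xor(is.na(h1), is.na(h2))
    h1[half] <- NA_integer_; h2[half] <- NA_integer_
    # store unphased het canonically as (0, 1)
    het <- !is.na(h1) & h1 + h2 == 1L
    h1[het] <- 0L; h2[het] <- 1L
    hap1[, j] <- h1; hap2[, j] <- h2
  }
  map$allele1 <- allele1; map$allele2 <- allele2
  genotype_panel(map[, c("chr", "snp", "pos", "allele1", "allele2")],
                 hap1, hap2, samples, phased = FALSE)
}

write_bed <- function(panel, prefix) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chr, map$snp, 0, map$pos, map$allele1, map$allele2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$samples, panel$samples, 0, 0, 2, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  n <- n_samples(panel); m <- n_markers(panel)
  g <- dosage(panel)
  # 2-bit SNP-major codes: 00 hom allele1, 10 het, 11 hom allele2, 01 missing
  code <- matrix(1L, n, m)
  code[g == 0L] <- 0L; code[g == 1L] <- 2L; code[g == 2L] <- 3L
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4L - n
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
  i4 <- seq(1L, nbytes * 4L, by = 4L)
  bytes <- code[i4, , drop = FALSE] + 4L * code[i4 + 1L, , drop = FALSE] +
    16L * code[i4 + 2L, , drop = FALSE] + 64L * code[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.integer(bytes)), con)
  invisible(paste0(prefix, ".bed"))
}

read_bed <- function(prefix) {
  bedf <- paste0(prefix, ".bed")
  if (!file.exists(bedf)) stop("file does not exist: ", bedf)
  if (file.size(bedf) == 0L) stop("empty bed file: ", bedf)
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = "character", data.table = FALSE)
  if (ncol(bim) < 6L) stop("malformed bim file: ", prefix, ".bim")
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character", data.table = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK bed file: ", bedf)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bedf)
  nbytes <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != nbytes * m)
    stop("bed file size mismatch: ", bedf)
  codes <- matrix(0L, nbytes * 4L, m)
  bytemat <- matrix(body, nbytes, m)
  i4 <- seq(1L, nbytes * 4L, by = 4L)
  codes[i4, ] <- bytemat %% 4L
  codes[i4 + 1L, ] <- (bytemat %/% 4L) %% 4L
  codes[i4 + 2L, ] <- (bytemat %/% 16L) %% 4L
  codes[i4 + 3L, ] <- (bytemat %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  g <- matrix(NA_integer_, n, m)
  g[codes == 0L] <- 0L; g[codes == 2L] <- 1L; g[codes == 3L] <- 2L
  hap1 <- matrix(NA_integer_, n, m); hap2 <- matrix(NA_integer_, n, m)
  hap1[!is.na(g)] <- as.integer(g[!is.na(g)] == 2L)
  hap2[!is.na(g)] <- as.integer(g[!is.na(g)] >= 1L)
  map <- data.frame(chr = bim[[1L]], snp = bim[[2L]],
                    pos = as.numeric(bim[[4L]]),
                    allele1 = bim[[5L]], allele2 = bim[[6L]],
                    stringsAsFactors = FALSE)
  genotype_panel(map, hap1, hap2, fam[[2L]], phased = FALSE)
}

write_vcf <- function(panel, path) {
  map <- panel$map
  sep <- if (panel$phased) "|" else "/"
  gt1 <- ifelse(is.na(panel$hap1), ".", panel$hap1)
  gt2 <- ifelse(is.na(panel$hap2), ".", panel$hap2)
  gt <- matrix(paste(gt1, gt2, sep = sep), nrow = n_samples(panel))
  body <- cbind(map$chr, map$pos, map$snp, map$allele1, map$allele2,
                ".", "PASS", ".", "GT", t(gt))
  header <- c("##fileformat=VCFv4.2",
              "##source=ovipop",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

read_vcf <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0L) stop("empty vcf file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  tri <- grepl(",", alt)
  if (any(tri))
    stop("triallelic site ", fix[which(tri)[1L], "ID"], " at ",
         fix[which(tri)[1L], "CHROM"], ":", fix[which(tri)[1L], "POS"])
  gt <- vcfR::extract.gt(v)
  m <- nrow(fix)
  n <- ncol(gt)
  phased <- all(grepl("\\|", gt[!is.na(gt)])) && any(!is.na(gt))
  h1 <- substr(gt, 1L, 1L); h2 <- substr(gt, 3L, 3L)
  to_int <- function(x) ifelse(x %in% c("0", "1"), as.integer(x), NA_integer_)
  hap1 <- t(matrix(to_int(h1), m, n))
  hap2 <- t(matrix(to_int(h2), m, n))
  half <- xor(is.na(hap1), is.na(hap2))
  hap1[half] <- NA_integer_; hap2[half] <- NA_integer_
  map <- data.frame(chr = fix[, "CHROM"], snp = fix[, "ID"],
                    pos = as.numeric(fix[, "POS"]),
                    allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  genotype_panel(map, hap1, hap2, colnames(gt), phased = phased)
}
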