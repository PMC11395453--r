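test_that("roh_islands selects top-incidence SNPs and merges by distance", {
  # 100 SNPs; SNP 50 covered in 99% of individuals, the rest in 1%
  n_ind <- 100
  pos <- seq_len(100) * 1e5
  p <- panel_from_dosage(matrix(0L, n_ind, 100), pos = pos)
  segs <- do.call(rbind, c(
    lapply(1:99, function(i) data.frame(
      individual = p$samples[i], chr = "1", start_bp = pos[50],
      end_bp = pos[50], n_snps = 1L, length_bp = 1,
      stringsAsFactors = FALSE)),
    list(data.frame(individual = p$samples[100], chr = "1",
                    start_bp = pos[10], end_bp = pos[10], n_snps = 1L,
                    length_bp = 1, stringsAsFactors = FALSE))))
  isl <- roh_islands(segs, p, top_fraction = 0.01)
  expect_equal(nrow(isl$islands), 1L)
  expect_equal(isl$islands$start_bp, pos[50])
  expect_equal(isl$islands$end_bp, pos[50])
  expect_equal(isl$islands$peak_incidence, 0.99)
  # merge rule: two selected SNPs 0.5 Mb apart join, 2 Mb apart split
  mk_segs <- function(j1, j2) do.call(rbind, lapply(1:99, function(i) {
    rbind(data.frame(individual = p$samples[i], chr = "1",
                     start_bp = pos[j1], end_bp = pos[j1], n_snps = 1L,
                     length_bp = 1, stringsAsFactors = FALSE),
          data.frame(individual = p$samples[i], chr = "1",
                     start_bp = pos[j2], end_bp = pos[j2], n_snps = 1L,
                     length_bp = 1, stringsAsFactors = FALSE))
  }))
  near <- roh_islands(mk_segs(50, 55), p, top_fraction = 0.02)   # 0.5 Mb
  expect_equal(nrow(near$islands), 1L)
  far <- roh_islands(mk_segs(50, 70), p, top_fraction = 0.02)    # 2 Mb
  expect_equal(nrow(far$islands), 2L)
  # empty input gives an empty island list
  expect_equal(nrow(roh_islands(segs[0, ], p)$islands), 0L)
})

test_that("islands equal a brute-force quantile-and-merge scan", {
  set.seed(14)
  for (rep in 1:5) {
    n_snp <- 120
    pos <- sort(sample.int(3e7, n_snp))
    inc <- round(runif(n_snp, 0, 0.4), 2)
    p <- panel_from_dosage(matrix(0L, 50, n_snp), pos = pos)
    # synthesize segments that reproduce the incidence vector exactly
    segs <- do.call(rbind, lapply(seq_len(n_snp), function(j) {
      k <- round(inc[j] * 50)
      if (k == 0) return(NULL)
      data.frame(individual = p$samples[seq_len(k)], chr = "1",
                 start_bp = pos[j], end_bp = pos[j], n_snps = 1L,
                 length_bp = 1, stringsAsFactors = FALSE)
    }))
    got <- roh_islands(segs, p, top_fraction = 0.05, merge_gap_bp = 1e6)
    want <- oracle_islands(pos, round(round(inc * 50) / 50, 10), 0.05, 1e6)
    expect_equal(got$islands$start_bp, want$start_bp)
    expect_equal(got$islands$end_bp, want$end_bp)
    expect_equal(got$islands$n_snps, want$n_snps)
  }
})

test_that("the sweep-model site distribution reduces to the background far away", {
  set.seed(4)
  k <- sample(1:39, 200, replace = TRUE)
  far <- ovipop:::clr_model_table(k, 40, 1e9)[1, ]
  bg <- ovipop:::clr_model_table(k, 40, 1e9 * 10)[1, ]
  expect_equal(far, bg, tolerance = 1e-9)
  # near the sweep (tiny u) mass concentrates on extreme folded classes
  near <- ovipop:::clr_model_table(k, 40, 1e-4)[1, ]
  expect_gt(near[1], far[1])
})

test_that("monomorphic sites do not change the CLR scan", {
  cfg <- sim_config(n_individuals = 40, n_chromosomes = 1,
                    snps_per_chromosome = 300, chromosome_length_bp = 2e7,
                    n_generations = 30, founder_size = 40, seed = 19)
  p <- fill_missing(simulate_panel(cfg))
  base <- clr_scan(p)
  # overwrite a tenth of the SNPs to be monomorphic
  set.seed(1)
  j <- sample(n_markers(p), 30)
  p2 <- p
  p2$hap1[, j] <- 0L; p2$hap2[, j] <- 0L
  with_mono <- clr_scan(p2)
  keep <- !(seq_len(n_markers(p)) %in% j)
  p3 <- subset_panel(p2, snps = which(keep))
  without <- clr_scan(p3)
  expect_equal(with_mono$grid$clr, without$grid$clr, tolerance = 1e-9)
  expect_error(clr_scan(subset_panel(p, snps = j[1])), "segregating")
})

test_that("neutral CLR peaks stay below a positional permutation null", {
  cfg <- sim_config(n_individuals = 60, n_chromosomes = 1,
                    snps_per_chromosome = 400, chromosome_length_bp = 4e7,
                    n_generations = 40, founder_size = 80, seed = 23)
  p <- fill_missing(simulate_panel(cfg))
  base <- clr_scan(p)
  set.seed(5)
  perm_max <- replicate(6, {
    pp <- p
    o <- sample(n_markers(p))
    pp$hap1 <- pp$hap1[, o]; pp$hap2 <- pp$hap2[, o]
    max(clr_scan(pp)$grid$clr)
  })
  expect_lte(stats::median(base$grid$clr), stats::quantile(perm_max, 0.99))
})

test_that("EHH equals hand enumeration on a six-haplotype fixture", {
  # carriers of allele 1 at the core (marker 3): haplotypes 1-4
  H <- rbind(c(0, 1, 1, 1, 0),
             c(0, 1, 1, 1, 0),
             c(1, 1, 1, 0, 0),
             c(0, 0, 1, 0, 1),
             c(1, 0, 0, 1, 1),
             c(0, 1, 0, 0, 0))
  h1 <- H[c(1, 3, 5), ]; h2 <- H[c(2, 4, 6), ]
  p <- make_panel(h1, h2, pos = (1:5) * 1e4, phased = TRUE)
  e <- ehh(p, 3, 1)
  # by hand: carriers rows 1-4 of H; right to marker 4 -> classes {1,1,0,0}
  # paired as (1,2),(3,4): EHH = (1+1)/6 = 1/3; to marker 5 unchanged pairs
  expect_equal(e$ehh[e$side == "core"], 1)
  expect_equal(e$ehh[e$pos == 4e4], oracle_ehh(H, 1:4, 3, 4))
  expect_equal(e$ehh[e$pos == 5e4], oracle_ehh(H, 1:4, 3, 5))
  expect_equal(e$ehh[e$pos == 2e4], oracle_ehh(H, 1:4, 3, 2))
  expect_equal(e$ehh[e$pos == 1e4], oracle_ehh(H, 1:4, 3, 1))
  # curves live in [0,1], equal 1 at the core, and never increase outward
  rhs <- e$ehh[e$pos >= 3e4]
  lhs <- rev(e$ehh[e$pos <= 3e4])
  expect_true(all(diff(rhs) <= 1e-12) && all(diff(lhs) <= 1e-12))
  expect_true(all(e$ehh >= 0 & e$ehh <= 1))
  # identical carrier haplotypes keep EHH at 1; immediate divergence at 0
  Hsame <- rbind(matrix(1, 4, 5), matrix(0, 2, 5))
  ps <- make_panel(Hsame[c(1, 3, 5), ], Hsame[c(2, 4, 6), ],
                   pos = (1:5) * 1e4, phased = TRUE)
  es <- ehh(ps, 3, 1)
  expect_true(all(es$ehh == 1))
  Hdiff <- rbind(c(0, 1, 0, 0, 0), c(1, 1, 1, 1, 1), c(0, 1, 1, 0, 0),
                 c(1, 1, 0, 1, 0), c(0, 0, 1, 0, 1), c(1, 0, 0, 1, 1))
  pd <- make_panel(Hdiff[c(1, 3, 5), ], Hdiff[c(2, 4, 6), ],
                   pos = (1:5) * 1e4, phased = TRUE)
  ed <- ehh(pd, 2, 1)
  expect_equal(ed$ehh[ed$pos == 3e4], oracle_ehh(Hdiff, 1:4, 2, 3))
  # unphased panels refuse haplotype statistics
  pu <- make_panel(h1, h2, pos = (1:5) * 1e4, phased = FALSE)
  expect_error(ehh(pu, 3, 1), "phased")
  expect_error(ehh(p, 3, 1 - 1), NA)  # other allele also carried by >= 2
})

test_that("iHS standardization and the Gaussian tail transform are exact", {
  cfg <- sim_config(n_individuals = 80, n_chromosomes = 1,
                    snps_per_chromosome = 400, chromosome_length_bp = 2e7,
                    n_generations = 40, founder_size = 60, seed = 29)
  p <- fill_missing(simulate_panel(cfg))
  sc <- ihs_scan(p)
  ok <- !is.na(sc$per_snp$ihs_std)
  expect_gt(sum(ok), 50)
  bins <- floor(sc$per_snp$freq_derived[ok] / 0.025)
  for (b in unique(bins)) {
    v <- sc$per_snp$ihs_std[ok][bins == b]
    if (length(v) >= 2) {
      expect_lt(abs(mean(v)), 1e-6)
      expect_lt(abs(stats::sd(v) - 1), 1e-6)
    }
  }
  # p_iHS formula at the 5% two-sided point
  x <- 1.959964
  expect_equal(-log10(2 * stats::pnorm(-abs(x))), 1.3010, tolerance = 1e-4)
  i <- which(ok)[1]
  xx <- sc$per_snp$ihs_std[i]
  expect_equal(sc$per_snp$p_ihs[i],
               -log10(1 - 2 * abs(stats::pnorm(xx) - 0.5)), tolerance = 1e-9)
  # symmetry: p_ihs depends on |ihs_std| only
  expect_equal(-log10(1 - 2 * abs(stats::pnorm(2.3) - 0.5)),
               -log10(1 - 2 * abs(stats::pnorm(-2.3) - 0.5)))
  # re-standardizing standardized scores is a no-op
  std2 <- sc$per_snp$ihs_std
  for (b in unique(bins)) {
    v <- std2[ok][bins == b]
    if (length(v) >= 2 && stats::sd(v) > 0)
      expect_equal((v - mean(v)) / stats::sd(v), v, tolerance = 1e-6)
  }
  # MAF filter: excluded SNPs carry no score
  expect_true(all(is.na(sc$per_snp$ihs_std[
    pmin(allele_freq(p), 1 - allele_freq(p)) < 0.05])))
})

test_that("a mirror-symmetric core gives iHS exactly zero", {
  # ancestral and derived carrier sets with identical haplotype structure
  blockA <- rbind(c(1, 1, 0, 1, 1), c(1, 1, 0, 1, 1),
                  c(0, 0, 0, 0, 0), c(0, 0, 0, 0, 0))
  blockD <- blockA; blockD[, 3] <- 1
  H <- rbind(blockA, blockD)
  p <- make_panel(H[c(1, 3, 5, 7), ], H[c(2, 4, 6, 8), ],
                  pos = (1:5) * 5e4, phased = TRUE)
  sc <- ihs_scan(p, maf_min = 0.0)
  expect_equal(sc$per_snp$ihs_raw[3], 0, tolerance = 1e-12)
})

test_that("sweep panels outscore their paired neutral panels", {
  peaks <- matrix(NA_real_, 8, 4)
  for (s in 1:8) {
    cfg <- sim_config(n_individuals = 60, n_chromosomes = 1,
                      snps_per_chromosome = 300, chromosome_length_bp = 3e7,
                      n_generations = 40, founder_size = 100, seed = 400 + s)
    p0 <- fill_missing(simulate_panel(cfg))
    set.seed(500 + s)
    ps <- plant_sweep(p0, "1", 1.5e7, 0.95)
    c0 <- clr_scan(p0); c1 <- clr_scan(ps)
    i0 <- ihs_scan(p0); i1 <- ihs_scan(ps)
    peaks[s, ] <- c(max(c0$grid$clr), max(c1$grid$clr),
                    max(i0$windows$score, na.rm = TRUE),
                    max(i1$windows$score, na.rm = TRUE))
  }
  expect_gt(stats::median(peaks[, 2]), stats::median(peaks[, 1]))
  expect_gt(stats::median(peaks[, 4]), stats::median(peaks[, 3]))
})

test_that("consensus regions implement two-of-three interval support", {
  clr <- data.frame(chr = "1", start_bp = 1e6, end_bp = 2e6)
  ihs <- data.frame(chr = "1", start_bp = 1.5e6, end_bp = 3e6)
  roh <- data.frame(chr = "2", start_bp = 1e6, end_bp = 2e6)
  cons <- consensus_regions(roh, clr, ihs)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start_bp, 1.5e6)
  expect_equal(cons$end_bp, 2e6)
  expect_setequal(strsplit(cons$support, ",")[[1]], c("CLR", "iHS"))
  # mutually disjoint lists give nothing
  a <- data.frame(chr = "1", start_bp = 1e6, end_bp = 2e6)
  b <- data.frame(chr = "1", start_bp = 5e6, end_bp = 6e6)
  c3 <- data.frame(chr = "1", start_bp = 9e6, end_bp = 9.5e6)
  expect_equal(nrow(consensus_regions(a, b, c3)), 0L)
  # full three-way support
  allhit <- consensus_regions(a, a, a)
  expect_equal(allhit$n_methods, 3L)
  # empty inputs tolerated
  expect_equal(nrow(consensus_regions(a[0, ], b, c3)), 0L)
})
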