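test_that("min_run_snps evaluates the false-positive formula", {
  # the post-QC array scale: 46,371 SNPs, 830 ewes, mean heterozygosity 0.39
  expect_identical(min_run_snps(0.05, 46371, 830, 0.39), 41L)
  expect_identical(min_run_snps(1.0, 100, 10, 0.5), 9L)
  expect_identical(min_run_snps(1.0, 100, 10, 0.5, rounding = "ceiling"), 10L)
  # numerator zero at the alpha = n_s * n_i boundary
  expect_identical(min_run_snps(1000, 100, 10, 0.5), 0L)
  expect_error(min_run_snps(0.05, 100, 10, 0), "mean_het")
  expect_error(min_run_snps(0.05, 0, 10, 0.4), "counts")
})

test_that("an all-heterozygous individual yields no runs", {
  g <- matrix(1L, 3, 40)
  p <- panel_from_dosage(g, pos = seq_len(40) * 1e5)
  segs <- detect_roh(p, roh_params(), window_snps = 10)
  expect_equal(nrow(segs), 0L)
})

test_that("a planted homozygous region is recovered exactly once", {
  set.seed(21)
  # 60 SNPs at 100 kb spacing; het background, 20-SNP homozygous block
  n_snp <- 60
  g <- matrix(1L, 4, n_snp)
  g[4, 21:40] <- 2L
  # give the other individuals mixed genotypes so the panel is realistic
  g[1:3, ] <- matrix(rbinom(3 * n_snp, 2, 0.5), 3)
  p <- panel_from_dosage(g, pos = seq_len(n_snp) * 1e5)
  segs <- detect_roh(p, roh_params(), window_snps = 10)
  mine <- segs[segs$individual == "ind_004", ]
  # exactly one run containing the planted block; the window rule may pull
  # in at most one flanking heterozygous SNP (still within the allowance)
  expect_equal(nrow(mine), 1L)
  expect_lte(mine$start_bp, 21 * 1e5)
  expect_gte(mine$start_bp, 20 * 1e5)
  expect_gte(mine$end_bp, 40 * 1e5)
  expect_lte(mine$end_bp, 41 * 1e5)
  expect_gte(mine$n_snps, 20L)
  expect_lte(mine$n_snps, 22L)
  # a 0.8 Mb region (9 SNPs at 100 kb) fails the 1 Mb minimum
  g2 <- matrix(1L, 2, n_snp)
  g2[2, 26:34] <- 0L
  p2 <- panel_from_dosage(g2, pos = seq_len(n_snp) * 1e5)
  expect_equal(nrow(detect_roh(p2, roh_params(), window_snps = 5)), 0L)
})

test_that("detector equals the brute-force window scan on small panels", {
  params <- roh_params()
  for (seed in 1:12) {
    p <- random_small_panel(seed)
    L <- max(3L, min(10L, n_markers(p) %/% 3L))
    got <- suppressWarnings(detect_roh(p, params, window_snps = L))
    want <- suppressWarnings(brute_force_roh(p, params, L))
    got <- got[, c("individual", "chr", "start_bp", "end_bp", "n_snps",
                   "length_bp")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("seed", seed))
  }
})

test_that("every emitted segment satisfies the run invariants", {
  set.seed(33)
  cfg <- sim_config(n_individuals = 40, n_chromosomes = 2,
                    snps_per_chromosome = 500, chromosome_length_bp = 3e7,
                    n_generations = 25, founder_size = 60, seed = 13)
  p <- simulate_panel(cfg)
  params <- roh_params()
  segs <- detect_roh(p, params)
  if (nrow(segs)) {
    g <- dosage(p)
    for (k in seq_len(nrow(segs))) {
      i <- match(segs$individual[k], p$samples)
      j <- which(p$map$chr == segs$chr[k] & p$map$pos >= segs$start_bp[k] &
                   p$map$pos <= segs$end_bp[k])
      expect_lte(sum(g[i, j] == 1L, na.rm = TRUE), params$max_het_in_window)
      expect_lte(sum(is.na(g[i, j])), params$max_missing_in_window)
      expect_gte(segs$length_bp[k], params$min_length_bp)
      expect_lte(max(diff(p$map$pos[j])), params$max_gap_bp)
      expect_gte(segs$n_snps[k] * params$min_density_bp, segs$length_bp[k])
    }
    # per-individual segments do not overlap
    for (id in unique(segs$individual)) {
      s <- segs[segs$individual == id, ]
      for (ch in unique(s$chr)) {
        sc <- s[s$chr == ch, ]
        sc <- sc[order(sc$start_bp), ]
        if (nrow(sc) > 1)
          expect_true(all(sc$start_bp[-1] > sc$end_bp[-nrow(sc)]))
      }
    }
  }
})

test_that("raising the minimum length never adds segments", {
  p <- random_small_panel(99, n_ind = 10, n_snp = 50)
  lo <- suppressWarnings(detect_roh(p, roh_params(min_length_bp = 5e5),
                                    window_snps = 5))
  hi <- suppressWarnings(detect_roh(p, roh_params(min_length_bp = 2e6),
                                    window_snps = 5))
  expect_lte(nrow(hi), nrow(lo))
  if (nrow(hi))
    expect_true(all(paste(hi$individual, hi$start_bp) %in%
                      paste(lo$individual, lo$start_bp)))
})

test_that("summaries partition the segments", {
  segs <- data.frame(individual = c("a", "a", "b", "c"),
                     chr = c("1", "2", "1", "2"),
                     start_bp = c(1e6, 1e6, 2e6, 5e6),
                     end_bp = c(3e6, 7e6, 14e6, 30e6),
                     n_snps = c(10L, 20L, 40L, 80L),
                     length_bp = c(2e6, 6e6, 12e6, 25e6),
                     stringsAsFactors = FALSE)
  segs$length_bp <- c(2e6, 6e6, 12e6, 25e6)
  segs$length_class <- c("1-5Mb", "5-10Mb", "10-20Mb", ">20Mb")
  g <- matrix(0L, 3, 4)
  p <- panel_from_dosage(g, pos = c(1e6, 15e6, 16e6, 30e6),
                         chr = c("1", "1", "2", "2"))
  s <- summarize_roh(segs, p)
  expect_equal(s$class_summary$n, c(1L, 1L, 1L, 1L))
  expect_equal(s$overall$mean_length_bp, mean(c(2e6, 6e6, 12e6, 25e6)))
  expect_equal(sum(s$chromosome_summary$n), nrow(segs))
  # chromosome with no segments has zero coverage
  p2 <- panel_from_dosage(matrix(0L, 3, 6),
                          pos = c(1e6, 2e6, 3e6, 1e6, 2e6, 3e6),
                          chr = rep(c("1", "3"), each = 3))
  s2 <- summarize_roh(segs[segs$chr == "1", ], p2)
  expect_equal(s2$chromosome_summary$coverage_pct[
    s2$chromosome_summary$chr == "3"], 0)
})

test_that("chromosomes shorter than the window are skipped with a warning", {
  p <- random_small_panel(7, n_ind = 3, n_snp = 12)
  expect_warning(detect_roh(p, roh_params(), window_snps = 20),
                 "fewer SNPs")
})
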