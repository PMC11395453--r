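test_that("the simulator is deterministic and validates its configuration", {
  cfg <- sim_config(n_individuals = 20, n_chromosomes = 2,
                    snps_per_chromosome = 100, chromosome_length_bp = 1e7,
                    n_generations = 10, founder_size = 30, seed = 42)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_true(p1$phased)
  expect_equal(n_samples(p1), 20L)
  expect_equal(n_markers(p1), 200L)
  expect_error(sim_config(founder_size = 0), "founder_size")
  expect_error(sim_config(mutation_rate = -1), "rates")
})

test_that("no variation source means every SNP stays monomorphic", {
  cfg <- sim_config(n_individuals = 15, n_chromosomes = 1,
                    snps_per_chromosome = 80, mutation_rate = 0,
                    n_generations = 15, founder_size = 20, seed = 3)
  p <- simulate_panel(cfg, founder_freq = 0)
  expect_true(all(dosage(p) == 0L))
  p1 <- simulate_panel(cfg, founder_freq = 1)
  expect_true(all(dosage(p1) == 2L))
})

test_that("drift plus linkage produce decaying LD with distance", {
  cfg <- sim_config(n_individuals = 100, n_chromosomes = 1,
                    snps_per_chromosome = 1000, chromosome_length_bp = 5e7,
                    n_generations = 200, founder_size = 50, seed = 11)
  p <- fill_missing(simulate_panel(cfg))
  ld <- ld_decay(p, max_dist_bp = 5e5, bin_bp = 5000)
  near <- ld$mean_r2[ld$distance_bp <= 20000]
  far <- ld$mean_r2[ld$distance_bp >= 480000]
  expect_gt(mean(near), mean(far))
})

test_that("planted autozygosity is exactly homozygous and local", {
  cfg <- sim_config(n_individuals = 30, n_chromosomes = 2,
                    snps_per_chromosome = 300, chromosome_length_bp = 2e7,
                    n_generations = 20, founder_size = 50, seed = 5)
  p0 <- simulate_panel(cfg)
  p <- plant_autozygosity(p0, "ind_0004", "1", 5e6, 7e6)
  j <- which(p$map$chr == "1" & p$map$pos >= 5e6 & p$map$pos <= 7e6)
  i <- match("ind_0004", p$samples)
  expect_true(all(dosage(p)[i, j] %in% c(0L, 2L)))
  # conservation: everything else untouched
  expect_identical(p$map, p0$map)
  expect_identical(p$hap1, p0$hap1)
  expect_identical(p$hap2[-i, ], p0$hap2[-i, ])
  expect_identical(p$hap2[i, -j], p0$hap2[i, -j])
  # region containing no SNPs leaves the panel unchanged
  gap_lo <- p0$map$pos[5] + 1; gap_hi <- p0$map$pos[6] - 1
  expect_identical(plant_autozygosity(p0, 1, "1", gap_lo, gap_hi), p0)
  expect_error(plant_autozygosity(p0, "nobody", "1", 1, 2), "unknown individual")
  expect_error(plant_autozygosity(p0, 1, "99", 1, 2), "unknown chromosome")
})

test_that("planted sweeps hit the target frequency and raise EHH", {
  cfg <- sim_config(n_individuals = 80, n_chromosomes = 1,
                    snps_per_chromosome = 500, chromosome_length_bp = 5e7,
                    n_generations = 40, founder_size = 80, seed = 9)
  p0 <- simulate_panel(cfg)
  set.seed(1)
  p_fix <- plant_sweep(p0, "1", 2.5e7, 1.0)
  focal <- attr(p_fix, "sweep_snp")
  expect_equal(length(unique(c(p_fix$hap1[, focal], p_fix$hap2[, focal]))), 1L)
  set.seed(2)
  p95 <- plant_sweep(p0, "1", 2.5e7, 0.95)
  focal <- attr(p95, "sweep_snp")
  cnt <- sum(c(p95$hap1[, focal], p95$hap2[, focal]) ==
               names(which.max(table(c(p95$hap1[, focal], p95$hap2[, focal])))))
  n2 <- 2 * n_samples(p95)
  expect_lte(abs(cnt - 0.95 * n2), 1)
  expect_identical(p95$map, p0$map)
  # monomorphic panel has no plantable focal SNP
  mono <- simulate_panel(sim_config(n_individuals = 10, n_chromosomes = 1,
                                    snps_per_chromosome = 20,
                                    mutation_rate = 0, n_generations = 2,
                                    founder_size = 5, seed = 1),
                         founder_freq = 0)
  expect_error(plant_sweep(mono, "1", 1e6, 0.9), "monomorphic")
})

test_that("sweeps raise extended haplotype homozygosity around the core", {
  # carrier-set sizes differ between the swept and neutral panels, so the
  # comparison is averaged over replicate pairs
  swept <- numeric(5); neutral <- numeric(5)
  for (s in 1:5) {
    cfg <- sim_config(n_individuals = 80, n_chromosomes = 1,
                      snps_per_chromosome = 1000,
                      chromosome_length_bp = 2e7, n_generations = 40,
                      founder_size = 80, seed = s)
    p0 <- simulate_panel(cfg)
    set.seed(100 + s)
    p95 <- plant_sweep(p0, "1", 1e7, 0.95)
    focal <- attr(p95, "sweep_snp")
    al <- as.integer(mean(c(p95$hap1[, focal], p95$hap2[, focal])) > 0.5)
    near <- function(pp) {
      e <- ehh(pp, focal, al)
      mean(e$ehh[abs(e$pos - pp$map$pos[focal]) <= 1.5e5 & e$side != "core"])
    }
    swept[s] <- near(p95)
    neutral[s] <- tryCatch(near(p0), error = function(e) NA)
  }
  expect_gt(mean(swept), mean(neutral, na.rm = TRUE))
})

test_that("phenotypes collapse to the mean when all effect sources vanish", {
  cfg <- sim_config(n_individuals = 12, n_chromosomes = 1,
                    snps_per_chromosome = 50, n_generations = 5,
                    founder_size = 20, seed = 2)
  p <- simulate_panel(cfg)
  tr <- trait_config(mean = 2.36, var_additive = 0, var_permanent = 0,
                     var_residual = 0,
                     parity_effects = c("1" = 0, "2" = 0),
                     year_effects = c("2020" = 0, "2021" = 0),
                     season_effects = c(spring = 0, autumn = 0),
                     records_per_individual = 3L, seed = 8)
  ph <- simulate_phenotypes(p, NULL, tr)
  expect_equal(nrow(ph), 36L)
  expect_true(all(ph$litter_size == 2.36))
  expect_error(trait_config(var_additive = -0.1), "negative variance")
})

test_that("realized phenotype variance tracks the configured components", {
  cfg <- sim_config(n_individuals = 150, n_chromosomes = 1,
                    snps_per_chromosome = 400, n_generations = 30,
                    founder_size = 100, seed = 6)
  p <- simulate_panel(cfg)
  tots <- replicate(20, {
    tr <- trait_config(var_additive = 0.1, var_permanent = 0.1,
                       var_residual = 0.8,
                       parity_effects = c("1" = 0), year_effects = c(y = 0),
                       season_effects = c(s = 0),
                       seed = sample.int(1e6, 1))
    stats::var(simulate_phenotypes(p, NULL, tr)$litter_size)
  })
  expect_lt(abs(mean(tots) - 1.0), 3 * stats::sd(tots) / sqrt(length(tots)) + 0.05)
})
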