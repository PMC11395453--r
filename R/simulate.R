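#' Simulation configuration for a forward Wright-Fisher genotype panel
#'
#' @param n_individuals samples in the final, genotyped generation.
#' @param n_chromosomes number of chromosomes.
#' @param snps_per_chromosome markers per chromosome.
#' @param chromosome_length_bp physical length of each chromosome (bp).
#' @param mutation_rate per-site per-gamete flip probability.
#' @param recombination_rate_cM_per_Mb genetic map density (1 cM/Mb default,
#'   the usual mammalian sex-averaged figure).
#' @param n_generations generations of random mating after the founders.
#' @param founder_size breeding population size during burn-in.
#' @param seed integer seed; the seed fully determines the panel.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100, n_chromosomes = 2,
                       snps_per_chromosome = 1000,
                       chromosome_length_bp = 5e7,
                       mutation_rate = 1e-6,
                       recombination_rate_cM_per_Mb = 1,
                       n_generations = 50, founder_size = 100,
                       seed = 1) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              mutation_rate = as.numeric(mutation_rate),
              recombination_rate_cM_per_Mb = as.numeric(recombination_rate_cM_per_Mb),
              n_generations = as.integer(n_generations),
              founder_size = as.integer(founder_size),
              seed = as.integer(seed))
  counts <- c("n_individuals", "n_chromosomes", "snps_per_chromosome",
              "n_generations", "founder_size")
  for (f in counts)
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (cfg$mutation_rate < 0 || cfg$recombination_rate_cM_per_Mb < 0)
    stop("rates must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# one recombinant gamete from a parent's two haplotype rows (bp positions pos)
recombine_gamete <- function(h1, h2, pos, morgans) {
  k <- stats::rpois(1L, morgans)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (k == 0L) return(if (start == 0L) h1 else h2)
  cuts <- sort(stats::runif(k, min = pos[1L], max = pos[length(pos)]))
  phase <- (start + findInterval(pos, cuts)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate a phased genotype panel by forward Wright-Fisher reproduction
#'
#' Founder haplotypes are drawn site-independently with allele frequencies
#' from Beta(0.5, 0.5) (a U-shaped spectrum); `n_generations` of random
#' mating with Poisson recombination and symmetric mutation then build up
#' linkage disequilibrium and drift before the final generation of
#' `n_individuals` genotyped samples is produced.
#'
#' @param config a [sim_config()].
#' @param founder_freq optional scalar or per-marker vector overriding the
#'   Beta-drawn founder allele-2 frequencies (0 or 1 gives monomorphic
#'   founders).
#' @return a phased [genotype_panel()].
#' @export
simulate_panel <- function(config, founder_freq = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$founder_size < 1) stop("zero founder size")
  set.seed(config$seed)
  S <- config$snps_per_chromosome
  L <- config$chromosome_length_bp
  nchr <- config$n_chromosomes
  morgans <- config$recombination_rate_cM_per_Mb * (L / 1e6) / 100
  pos <- lapply(seq_len(nchr), function(ch) sort(sample.int(L, S)))
  freq <- lapply(seq_len(nchr), function(ch) {
    if (is.null(founder_freq)) stats::rbeta(S, 0.5, 0.5)
    else rep_len(founder_freq, S)
  })
  Nf <- config$founder_size
  haps <- lapply(seq_len(nchr), function(ch) {
    matrix(stats::rbinom(2L * Nf * S, 1L, rep(freq[[ch]], each = 2L * Nf)),
           nrow = 2L * Nf, ncol = S)
  })
  sizes <- c(rep(Nf, max(config$n_generations - 1L, 0L)),
             if (config$n_generations >= 1L) config$n_individuals)
  for (N in sizes) {
    Nprev <- nrow(haps[[1L]]) / 2L
    mothers <- sample.int(Nprev, N, replace = TRUE)
    fathers <- sample.int(Nprev, N, replace = TRUE)
    if (Nprev > 1L) {
      # dioecious: an offspring's two parents are distinct individuals
      while (any(same <- fathers == mothers))
        fathers[same] <- sample.int(Nprev, sum(same), replace = TRUE)
    }
    for (ch in seq_len(nchr)) {
      H <- haps[[ch]]
      p <- pos[[ch]]
      out <- matrix(0L, nrow = 2L * N, ncol = S)
      for (i in seq_len(N)) {
        m <- mothers[i]; f <- fathers[i]
        out[2L * i - 1L, ] <- recombine_gamete(H[2L * m - 1L, ], H[2L * m, ], p, morgans)
        out[2L * i, ]      <- recombine_gamete(H[2L * f - 1L, ], H[2L * f, ], p, morgans)
      }
      if (config$mutation_rate > 0) {
        nmut <- stats::rbinom(1L, length(out), config$mutation_rate)
        if (nmut > 0L) {
          idx <- sample.int(length(out), nmut)
          out[idx] <- 1L - out[idx]
        }
      }
      haps[[ch]] <- out
    }
  }
  n <- nrow(haps[[1L]]) / 2L
  odd <- seq(1L, 2L * n, by = 2L)
  hap1 <- do.call(cbind, lapply(haps, function(H) H[odd, , drop = FALSE]))
  hap2 <- do.call(cbind, lapply(haps, function(H) H[odd + 1L, , drop = FALSE]))
  map <- do.call(rbind, lapply(seq_len(nchr), function(ch) {
    data.frame(chr = as.character(ch),
               snp = sprintf("snp_%d_%d", ch, pos[[ch]]),
               pos = pos[[ch]], allele1 = "A", allele2 = "B",
               stringsAsFactors = FALSE)
  }))
  genotype_panel(map, hap1, hap2,
                 samples = sprintf("ind_%04d", seq_len(n)), phased = TRUE)
}

resolve_sample <- function(panel, individual) {
  if (is.character(individual)) {
    i <- match(individual, panel$samples)
    if (is.na(i)) stop("unknown individual: ", individual)
  } else {
    i <- as.integer(individual)
    if (i < 1L || i > n_samples(panel)) stop("unknown individual index: ", individual)
  }
  i
}

#' Plant an autozygous (fully homozygous) segment in one individual
#'
#' Copies the first haplotype over the second across `[start_bp, end_bp]` on
#' the given chromosome, creating exact autozygosity there; everything else
#' (map, roster, other genotypes) is untouched.
#'
#' @param panel a `genotype_panel`.
#' @param individual sample id or index.
#' @param chromosome chromosome id.
#' @param start_bp,end_bp 1-based inclusive region bounds.
#' @return the modified `genotype_panel`.
#' @export
plant_autozygosity <- function(panel, individual, chromosome, start_bp, end_bp) {
  i <- resolve_sample(panel, individual)
  chromosome <- as.character(chromosome)
  if (!chromosome %in% panel$map$chr) stop("unknown chromosome: ", chromosome)
  if (start_bp > end_bp) stop("start_bp > end_bp")
  j <- which(panel$map$chr == chromosome &
               panel$map$pos >= start_bp & panel$map$pos <= end_bp)
  if (length(j)) panel$hap2[i, j] <- panel$hap1[i, j]
  panel
}

# haplotype h in 1..2n -> (sample, matrix name)
hap_slot <- function(h) list(i = (h + 1L) %/% 2L,
                             mat = if (h %% 2L == 1L) "hap1" else "hap2")

#' Plant a selective sweep by haplotype copying
#'
#' Raises the minor allele at the marker nearest `position_bp` to
#' `final_frequency` by copying one carrier haplotype over randomly chosen
#' non-carrier haplotypes. Each copy extends from the focal marker outward
#' over an exponential-length window on either side (mean `1/escape_rate`
#' bp), mimicking recombinational escape, so the extended haplotype
#' homozygosity decays away from the core as in a real sweep. Ground truth
#' (focal site and final frequency) is exact.
#'
#' @param panel a phased `genotype_panel`.
#' @param chromosome chromosome id.
#' @param position_bp approximate focal position; nearest marker is used.
#' @param final_frequency target focal-allele frequency in (0, 1].
#' @param escape_rate per-bp rate of the exponential copy-window extents.
#' @return the modified panel, with attributes `sweep_snp` (marker index)
#'   and `sweep_pos` (bp).
#' @export
plant_sweep <- function(panel, chromosome, position_bp, final_frequency,
                        escape_rate = 1e-6) {
  if (!panel$phased) stop("plant_sweep requires a phased panel")
  if (final_frequency <= 0 || final_frequency > 1)
    stop("final_frequency must be in (0, 1]")
  chromosome <- as.character(chromosome)
  jc <- which(panel$map$chr == chromosome)
  if (!length(jc)) stop("unknown chromosome: ", chromosome)
  poly <- jc[apply(panel$hap1[, jc, drop = FALSE] + panel$hap2[, jc, drop = FALSE],
                   2L, function(x) length(unique(x[!is.na(x)])) > 1L)]
  if (!length(poly)) stop("focal SNP is monomorphic")
  focal <- poly[which.min(abs(panel$map$pos[poly] - position_bp))]
  alle <- c(panel$hap1[, focal], panel$hap2[, focal])
  n2 <- 2L * n_samples(panel)
  # sweep the minor allele
  a <- if (sum(alle == 1L) <= sum(alle == 0L)) 1L else 0L
  carrier_h <- which(alle == a)
  # haplotype index h: 1..n = hap1 rows, n+1..2n = hap2 rows
  donor <- carrier_h[sample.int(length(carrier_h), 1L)]
  target_count <- ceiling(final_frequency * n2)
  need <- target_count - length(carrier_h)
  conv <- if (need > 0L)
    c(setdiff(carrier_h, donor), sample(setdiff(seq_len(n2), carrier_h), need))
  else setdiff(carrier_h, donor)
  # every final carrier gets the donor background over its own escape
  # window, homogenizing the swept class as a hard sweep would
  n <- n_samples(panel)
  posc <- panel$map$pos[jc]
  fpos <- panel$map$pos[focal]
  for (h in conv) {
    left <- fpos - stats::rexp(1L, escape_rate)
    right <- fpos + stats::rexp(1L, escape_rate)
    jj <- jc[posc >= left & posc <= right]
    donor_row <- if (donor <= n) panel$hap1[donor, jj] else panel$hap2[donor - n, jj]
    if (h <= n) panel$hap1[h, jj] <- donor_row
    else panel$hap2[h - n, jj] <- donor_row
  }
  attr(panel, "sweep_snp") <- focal
  attr(panel, "sweep_pos") <- panel$map$pos[focal]
  panel
}

#' Specify a major-gene QTL
#'
#' Models a FecB-type locus: a single marker with an additive per-copy
#' effect on litter size, segregating at a planted frequency.
#'
#' @param chromosome chromosome id.
#' @param position_bp marker position (nearest marker used when planting).
#' @param allele_effect additive effect per copy of allele 2, in trait units.
#' @param planted_frequency target allele-2 frequency in (0, 1).
#' @return list of class `qtl_spec`.
#' @export
qtl_spec <- function(chromosome, position_bp, allele_effect,
                     planted_frequency = 0.4) {
  if (planted_frequency <= 0 || planted_frequency >= 1)
    stop("planted_frequency must be in (0, 1)")
  structure(list(chromosome = as.character(chromosome),
                 position_bp = as.numeric(position_bp),
                 allele_effect = as.numeric(allele_effect),
                 planted_frequency = as.numeric(planted_frequency)),
            class = "qtl_spec")
}

#' Set a single marker's allele frequency (QTL planting)
#'
#' Redraws the genotypes at the marker nearest the QTL position so that the
#' allele-2 count equals `round(2n * planted_frequency)`, with carriers
#' assigned at random. The marker map and all other genotypes are unchanged.
#'
#' @param panel a `genotype_panel`.
#' @param qtl a [qtl_spec()].
#' @return the modified panel, with attribute `qtl_snp` (marker index).
#' @export
plant_qtl <- function(panel, qtl) {
  stopifnot(inherits(qtl, "qtl_spec"))
  jc <- which(panel$map$chr == qtl$chromosome)
  if (!length(jc)) stop("unknown chromosome: ", qtl$chromosome)
  j <- jc[which.min(abs(panel$map$pos[jc] - qtl$position_bp))]
  n2 <- 2L * n_samples(panel)
  k <- round(n2 * qtl$planted_frequency)
  alle <- integer(n2)
  alle[sample.int(n2, k)] <- 1L
  n <- n_samples(panel)
  panel$hap1[, j] <- alle[seq_len(n)]
  panel$hap2[, j] <- alle[n + seq_len(n)]
  attr(panel, "qtl_snp") <- j
  panel
}

#' Trait configuration for repeated litter-size records
#'
#' Defaults reflect a prolific meat-sheep flock: mean litter size 2.36,
#' narrow-sense heritability 0.10 and repeatability 0.20 on a unit-variance
#' latent scale (var_additive = var_permanent = 0.1, var_residual = 0.8),
#' with small parity/year/season offsets.
#'
#' @param mean population mean litter size.
#' @param var_additive,var_permanent,var_residual variance components of the
#'   additive-genetic, permanent-environment and residual effects.
#' @param parity_effects,year_effects,season_effects named numeric maps
#'   level -> additive offset.
#' @param records_per_individual integer scalar (constant count) or vector
#'   of counts sampled uniformly per individual.
#' @param seed integer seed for the phenotype draw.
#' @return list of class `trait_config`.
#' @export
trait_config <- function(mean = 2.36, var_additive = 0.1,
                         var_permanent = 0.1, var_residual = 0.8,
                         parity_effects = c("1" = 0, "2" = 0.15, "3" = 0.2,
                                            "4" = 0.15, "5" = 0.05),
                         year_effects = c("2019" = 0, "2020" = 0.05,
                                          "2021" = -0.05),
                         season_effects = c(spring = 0, summer = -0.05,
                                            autumn = 0.05, winter = 0),
                         records_per_individual = 3L, seed = 1L) {
  if (min(var_additive, var_permanent, var_residual) < 0)
    stop("negative variance component")
  if (!length(parity_effects) || !length(year_effects) || !length(season_effects))
    stop("fixed-effect maps must be non-empty")
  structure(list(mean = mean, var_additive = var_additive,
                 var_permanent = var_permanent, var_residual = var_residual,
                 parity_effects = parity_effects, year_effects = year_effects,
                 season_effects = season_effects,
                 records_per_individual = as.integer(records_per_individual),
                 seed = as.integer(seed)),
            class = "trait_config")
}

#' Simulate repeated litter-size records under the repeatability model
#'
#' Each record is
#' `y = mean + parity + year + season + dosage * allele_effect + a_i + pe_i + e`,
#' with the additive effects `a` drawn jointly with covariance
#' `var_additive * GRM` (VanRaden GRM of the panel, ensuring the generating
#' and estimating models share one relationship matrix), one permanent
#' environment effect `pe_i` per ewe, and an independent residual per
#' record. Records within an individual take parities 1, 2, ... in order;
#' year and season levels are sampled uniformly.
#'
#' @param panel a `genotype_panel`.
#' @param qtl optional [qtl_spec()]; its marker must be present (plant it
#'   first with [plant_qtl()] if needed).
#' @param trait a [trait_config()].
#' @return data.frame of class `phenotype_table` with columns
#'   `individual_id`, `parity`, `year`, `season`, `litter_size`.
#' @export
simulate_phenotypes <- function(panel, qtl = NULL, trait = trait_config()) {
  stopifnot(inherits(trait, "trait_config"))
  if (min(trait$var_additive, trait$var_permanent, trait$var_residual) < 0)
    stop("negative variance component")
  set.seed(trait$seed)
  n <- n_samples(panel)
  qdose <- numeric(n)
  qeff <- 0
  if (!is.null(qtl)) {
    stopifnot(inherits(qtl, "qtl_spec"))
    jc <- which(panel$map$chr == qtl$chromosome)
    if (!length(jc)) stop("QTL chromosome not in panel: ", qtl$chromosome)
    j <- jc[which.min(abs(panel$map$pos[jc] - qtl$position_bp))]
    qdose <- dosage(panel)[, j]
    qeff <- qtl$allele_effect
  }
  a <- numeric(n)
  if (trait$var_additive > 0) {
    G <- vanraden_grm(panel)
    eg <- eigen(G, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    a <- as.numeric(eg$vectors %*% (sqrt(lam * trait$var_additive) * stats::rnorm(n)))
  }
  pe <- stats::rnorm(n, 0, sqrt(trait$var_permanent))
  reps <- if (length(trait$records_per_individual) == 1L)
    rep(trait$records_per_individual, n)
  else sample(trait$records_per_individual, n, replace = TRUE)
  id <- rep(seq_len(n), reps)
  parity_lv <- names(trait$parity_effects)
  rec_no <- sequence(reps)
  parity <- parity_lv[pmin(rec_no, length(parity_lv))]
  year <- sample(names(trait$year_effects), length(id), replace = TRUE)
  season <- sample(names(trait$season_effects), length(id), replace = TRUE)
  e <- stats::rnorm(length(id), 0, sqrt(trait$var_residual))
  y <- trait$mean + trait$parity_effects[parity] + trait$year_effects[year] +
    trait$season_effects[season] + qdose[id] * qeff + a[id] + pe[id] + e
  out <- data.frame(individual_id = panel$samples[id], parity = parity,
                    year = year, season = season,
                    litter_size = as.numeric(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table as tab-separated text
#' @param phenotypes a `phenotype_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path tab-separated file with columns individual_id, parity, year,
#'   season, litter_size.
#' @return a `phenotype_table` data.frame.
#' @export
read_phenotypes <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "character", "character", "numeric"))
  class(out) <- c("phenotype_table", "data.frame")
  out
}
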