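#' ROH islands (high-incidence ROH regions)
#'
#' Per-SNP ROH incidence is the fraction of individuals whose ROH segments
#' cover the SNP. SNPs at or above the top-`top_fraction` empirical
#' quantile (ties included) are selected and consecutive selected SNPs
#' within `merge_gap_bp` on the same chromosome are merged into islands.
#'
#' @param segments ROH table from [detect_roh()].
#' @param panel the `genotype_panel`.
#' @param top_fraction upper tail fraction of the incidence distribution.
#' @param merge_gap_bp maximum distance between selected SNPs in one island.
#' @return list with `islands` (chr, start_bp, end_bp, n_snps,
#'   peak_incidence), `incidence` (per-SNP table) and `cutoff`.
#' @export
roh_islands <- function(segments, panel, top_fraction = 0.01,
                        merge_gap_bp = 1e6) {
  m <- n_markers(panel)
  inc <- numeric(m)
  if (nrow(segments)) {
    for (j in chrom_index(panel)) {
      ch <- panel$map$chr[j[1L]]
      pos <- panel$map$pos[j]
      seg <- segments[segments$chr == ch, , drop = FALSE]
      if (!nrow(seg)) next
      d <- numeric(length(j) + 1L)
      lo <- findInterval(seg$start_bp - 0.5, pos) + 1L
      hi <- findInterval(seg$end_bp + 0.5, pos)
      ok <- lo <= hi
      for (k in which(ok)) {
        d[lo[k]] <- d[lo[k]] + 1
        d[hi[k] + 1L] <- d[hi[k] + 1L] - 1
      }
      inc[j] <- cumsum(d[-length(d)]) / n_samples(panel)
    }
  }
  incidence <- data.frame(snp = panel$map$snp, chr = panel$map$chr,
                          pos = panel$map$pos, incidence = inc,
                          stringsAsFactors = FALSE)
  empty <- data.frame(chr = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      peak_incidence = numeric(), stringsAsFactors = FALSE)
  if (!nrow(segments) || all(inc == 0))
    return(list(islands = empty, incidence = incidence, cutoff = NA_real_))
  cutoff <- stats::quantile(inc, 1 - top_fraction, names = FALSE)
  sel <- which(inc >= cutoff & inc > 0)
  isl <- list()
  for (j in chrom_index(panel)) {
    s <- intersect(sel, j)
    if (!length(s)) next
    pos <- panel$map$pos
    brk <- c(0L, which(diff(pos[s]) > merge_gap_bp), length(s))
    for (k in seq_len(length(brk) - 1L)) {
      grp <- s[(brk[k] + 1L):brk[k + 1L]]
      isl[[length(isl) + 1L]] <- data.frame(
        chr = panel$map$chr[grp[1L]], start_bp = pos[grp[1L]],
        end_bp = pos[grp[length(grp)]], n_snps = length(grp),
        peak_incidence = max(inc[grp]), stringsAsFactors = FALSE)
    }
  }
  islands <- if (length(isl)) do.call(rbind, isl) else empty
  list(islands = islands, incidence = incidence, cutoff = cutoff)
}

# sweep-model probability table for the composite likelihood ratio scan.
# Closed form for the star-like escape mixture: conditional on escape
# probability p_e and pre-sweep derived frequency p,
#   P(D = j) = (1 - p) dbinom(j, n, p_e p) + p dbinom(n - j, n, p_e (1 - p)),
# because the j derived lineages are either all escapees (ancestral
# hitchhiker, prob 1 - p) or the swept lineage block plus derived escapees
# (derived hitchhiker, prob p). Folding and conditioning on segregation
# give the per-site likelihood of the observed folded count.
clr_model_table <- function(k_counts, n, u_grid, max_p_classes = 40L) {
  stopifnot(all(k_counts >= 1), all(k_counts <= n - 1))
  tab_k <- tabulate(k_counts, nbins = n - 1L)
  # symmetric unfolding: weight on pre-sweep derived frequency p = k/n
  w <- (tab_k + rev(tab_k)) / 2
  if (n %% 2L == 0L) w[n %/% 2L] <- tab_k[n %/% 2L]
  w <- w / sum(w)
  pvals <- seq_len(n - 1L) / n
  keep <- which(w > 0)
  if (length(keep) > max_p_classes) {
    # collapse to weighted bins; the mixture over p is smooth
    br <- seq(0, 1, length.out = max_p_classes + 1L)
    cls <- cut(pvals[keep], br, include.lowest = TRUE, labels = FALSE)
    wk <- tapply(w[keep], cls, sum)
    pk <- tapply(w[keep] * pvals[keep], cls, sum) / wk
    pvals <- as.numeric(pk); w <- as.numeric(wk)
  } else {
    pvals <- pvals[keep]; w <- w[keep]
  }
  j <- 0:n
  nhalf <- n %/% 2L
  logT <- matrix(NA_real_, length(u_grid), nhalf)
  for (b in seq_along(u_grid)) {
    pe <- 1 - exp(-u_grid[b])
    pr <- numeric(n + 1L)
    for (ki in seq_along(pvals)) {
      p <- pvals[ki]
      pr <- pr + w[ki] * ((1 - p) * stats::dbinom(j, n, pe * p) +
                            p * stats::dbinom(n - j, n, pe * (1 - p)))
    }
    seg <- pr[2:n]                     # condition on segregating sites
    seg <- seg / sum(seg)
    fold <- seg[seq_len(nhalf)] + rev(seg)[seq_len(nhalf)]
    if (n %% 2L == 0L) fold[nhalf] <- seg[nhalf]
    logT[b, ] <- log(pmax(fold, .Machine$double.xmin))
  }
  logT  # rows: u bins; column f = folded class min(k, n - k)
}

#' Composite likelihood ratio scan for selective sweeps
#'
#' A SweepFinder-style test on the folded site frequency spectrum. The
#' genome-wide folded SFS of segregating sites is the background model; the
#' sweep model distorts it through a star-like escape process in which each
#' lineage escapes the sweep at distance d with probability
#' p_e = 1 - exp(-alpha d). At each grid point the composite log-likelihood
#' is maximized over `alpha_grid` and
#' CLR = 2 (max_alpha logL_sweep - logL_background), clamped at 0 (the
#' background is the full-escape p_e -> 1 limit of the same model,
#' so the null is nested).
#'
#' @param panel a `genotype_panel` with no missing genotypes.
#' @param grid_spacing_bp spacing of test positions (one per 50 kb from the
#'   chromosome start by default).
#' @param alpha_grid sweep intensities (per bp) to maximize over; default 12
#'   log-spaced values covering sweep widths from ~10 kb to ~100 Mb.
#' @param top_fraction upper tail used to flag selected grid points.
#' @param n_u_bins resolution of the precomputed escape-probability table.
#' @return list with `grid` (chr, grid_position_bp, clr, alpha_hat,
#'   selected), `regions` (merged selected intervals) and `cutoff`.
#' @export
clr_scan <- function(panel, grid_spacing_bp = 50000, alpha_grid = NULL,
                     top_fraction = 0.01, n_u_bins = 200L) {
  if (is.null(alpha_grid)) alpha_grid <- 10^seq(-8, -4, length.out = 12)
  g <- dosage(panel)
  if (anyNA(g)) stop("panel has missing genotypes; run fill_missing() first")
  n <- 2L * n_samples(panel)
  k_all <- colSums(g)
  seg_all <- which(k_all >= 1L & k_all <= n - 1L)
  if (length(seg_all) < 2L) stop("fewer than 2 segregating sites in panel")
  u_lo <- 1e-6; u_hi <- 50
  edges <- exp(seq(log(u_lo), log(u_hi), length.out = n_u_bins + 1L))
  u_mid <- sqrt(edges[-1L] * edges[-(n_u_bins + 1L)])
  logT_full <- clr_model_table(k_all[seg_all], n, u_mid)
  # background model: the p_e -> 1 (alpha*d -> Inf) limit of the same table,
  # so the null is nested and distant sites contribute nothing to the CLR
  logT_bg <- clr_model_table(k_all[seg_all], n, 1e9)[1L, ]
  fold_all <- pmin(k_all, n - k_all)
  step <- (log(u_hi) - log(u_lo)) / n_u_bins
  res <- list()
  for (jj in chrom_index(panel)) {
    jseg <- jj[k_all[jj] >= 1L & k_all[jj] <= n - 1L]
    if (length(jseg) < 5L) {
      warning("chromosome ", panel$map$chr[jj[1L]],
              " has fewer than 5 segregating sites; skipped")
      next
    }
    pos <- panel$map$pos[jseg]
    fc <- fold_all[jseg]  # column index into logT (folded class)
    grid <- seq(1, max(pos), by = grid_spacing_bp)
    l_bg <- sum(logT_bg[fc])
    clr <- numeric(length(grid)); ahat <- numeric(length(grid))
    logd_cache <- NULL
    for (gi in seq_along(grid)) {
      d <- abs(pos - grid[gi])
      logd <- log(pmax(d, 1))
      best <- -Inf; besta <- NA_real_
      for (a in alpha_grid) {
        bin <- floor((logd + log(a) - log(u_lo)) / step) + 1
        bin <- pmin(pmax(bin, 1L), n_u_bins)
        ll <- sum(logT_full[cbind(bin, fc)])
        if (ll > best) { best <- ll; besta <- a }
      }
      clr[gi] <- 2 * max(best - l_bg, 0)
      ahat[gi] <- besta
    }
    res[[length(res) + 1L]] <- data.frame(
      chr = panel$map$chr[jj[1L]], grid_position_bp = grid,
      clr = clr, alpha_hat = ahat, stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no chromosome had enough segregating sites")
  out <- do.call(rbind, res)
  cutoff <- stats::quantile(out$clr, 1 - top_fraction, names = FALSE)
  out$selected <- out$clr >= cutoff & out$clr > 0
  regions <- merge_selected_points(out$chr, out$grid_position_bp,
                                   out$selected, grid_spacing_bp)
  list(grid = out, regions = regions, cutoff = cutoff)
}

# merge flagged grid points / windows into intervals, half a spacing around
merge_selected_points <- function(chr, pos, selected, spacing) {
  out <- list()
  for (ch in unique(chr)) {
    p <- sort(pos[chr == ch & selected])
    if (!length(p)) next
    brk <- c(0L, which(diff(p) > spacing), length(p))
    for (k in seq_len(length(brk) - 1L)) {
      grp <- p[(brk[k] + 1L):brk[k + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        chr = ch, start_bp = max(1, min(grp) - spacing / 2),
        end_bp = max(grp) + spacing / 2, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chr = character(), start_bp = numeric(),
                                      end_bp = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at marker m is the probability that two random carrier haplotypes of
#' the core allele are identical at every marker from the core out to m:
#' sum over distinct extended haplotypes h of C(n_h, 2) / C(n_core, 2).
#' EHH is 1 at the core and non-increasing outward.
#'
#' @param panel a phased `genotype_panel`.
#' @param core_snp marker id or index.
#' @param core_allele 0 (allele1) or 1 (allele2).
#' @return data.frame: snp, pos, side ("left"/"core"/"right"), ehh.
#' @export
ehh <- function(panel, core_snp, core_allele) {
  if (!panel$phased) stop("EHH requires a phased panel")
  j <- if (is.character(core_snp)) match(core_snp, panel$map$snp)
  else as.integer(core_snp)
  if (is.na(j) || j < 1L || j > n_markers(panel))
    stop("unknown core SNP: ", core_snp)
  jc <- which(panel$map$chr == panel$map$chr[j])
  H <- rbind(panel$hap1[, jc, drop = FALSE], panel$hap2[, jc, drop = FALSE])
  core_local <- match(j, jc)
  carriers <- which(H[, core_local] == core_allele)
  if (length(carriers) < 2L)
    stop("core allele carried by fewer than 2 haplotypes")
  curve_side <- function(dir) {
    idx <- if (dir > 0) seq(core_local + 1L, length(jc))
    else seq(core_local - 1L, 1L)
    if (core_local + dir < 1L || core_local + dir > length(jc))
      return(NULL)
    ehh_walk(H, carriers, idx)
  }
  nc <- length(carriers)
  left <- curve_side(-1L)
  right <- curve_side(1L)
  build <- function(vals, idx, side) {
    if (is.null(vals)) return(NULL)
    data.frame(snp = panel$map$snp[jc[idx]], pos = panel$map$pos[jc[idx]],
               side = side, ehh = vals, stringsAsFactors = FALSE)
  }
  lidx <- if (core_local > 1L) seq(core_local - 1L, 1L) else integer()
  ridx <- if (core_local < length(jc)) seq(core_local + 1L, length(jc)) else integer()
  out <- rbind(build(left, lidx, "left"),
               data.frame(snp = panel$map$snp[j], pos = panel$map$pos[j],
                          side = "core", ehh = 1, stringsAsFactors = FALSE),
               build(right, ridx, "right"))
  out[order(out$pos), , drop = FALSE]
}

# EHH values along idx (already ordered outward) for the given carrier rows
ehh_walk <- function(H, carriers, idx, cutoff = -1) {
  nc <- length(carriers)
  denom <- nc * (nc - 1) / 2
  grp <- rep(1L, nc)
  out <- numeric(length(idx))
  for (t in seq_along(idx)) {
    key <- grp * 2L + H[carriers, idx[t]]
    grp <- match(key, unique(key))
    cnt <- tabulate(grp)
    e <- sum(cnt * (cnt - 1) / 2) / denom
    out[t] <- e
    if (e < cutoff) return(out[seq_len(t)])
    if (e == 0) { out[seq_along(idx) > t] <- 0; return(out) }
  }
  out
}

# one-sided integrated EHH (trapezoid over bp until EHH < cutoff)
ihh_side <- function(H, carriers, pos_local, core_local, dir, cutoff) {
  S <- length(pos_local)
  idx <- if (dir > 0) {
    if (core_local >= S) return(0)
    seq(core_local + 1L, S)
  } else {
    if (core_local <= 1L) return(0)
    seq(core_local - 1L, 1L)
  }
  vals <- ehh_walk(H, carriers, idx, cutoff = cutoff)
  e_prev <- 1
  p_prev <- pos_local[core_local]
  acc <- 0
  for (t in seq_along(vals)) {
    p_cur <- pos_local[idx[t]]
    acc <- acc + (e_prev + vals[t]) / 2 * abs(p_cur - p_prev)
    if (vals[t] < cutoff) break
    e_prev <- vals[t]; p_prev <- p_cur
  }
  acc
}

#' Integrated haplotype score scan
#'
#' For each SNP with MAF >= `maf_min`, EHH is integrated over physical
#' distance (trapezoid rule, both directions, truncated where EHH drops
#' below `ehh_cutoff`) separately for the ancestral and derived core
#' alleles; ihs_raw = ln(iHH_ancestral / iHH_derived). Raw scores are
#' standardized to mean 0, s.d. 1 within derived-allele-frequency bins of
#' width `freq_bin`, and converted to
#' p_iHS = -log10(1 - 2 |Phi(iHS) - 0.5|), the two-tailed Gaussian tail
#' transform. A windowed test (window `window_bp`, advancing
#' `window_bp - overlap_bp`) scores each window by the mean p_iHS of its
#' SNPs and flags the top `top_fraction` of windows (ties included).
#'
#' Ancestral alleles are unknown on array data; by default the major allele
#' is taken as ancestral (frequency-bin standardization absorbs most of the
#' mispolarization). Supply `ancestral` to override.
#'
#' @param panel a phased `genotype_panel` with no missing genotypes.
#' @param maf_min minimum MAF for a core SNP.
#' @param freq_bin width of the derived-allele-frequency bins.
#' @param ehh_cutoff EHH level at which integration stops.
#' @param window_bp,overlap_bp window size and overlap of the windowed test.
#' @param top_fraction upper tail of window scores flagged as selected.
#' @param ancestral optional integer vector (0/1 per marker) of ancestral
#'   alleles.
#' @return list with `per_snp`, `windows`, `regions` (merged selected
#'   windows) and `cutoff`.
#' @export
ihs_scan <- function(panel, maf_min = 0.05, freq_bin = 0.025,
                     ehh_cutoff = 0.05, window_bp = 5e5, overlap_bp = 1e5,
                     top_fraction = 0.01, ancestral = NULL) {
  if (!panel$phased) stop("iHS requires a phased panel")
  g <- dosage(panel)
  if (anyNA(g)) stop("panel has missing genotypes; run fill_missing() first")
  p2 <- colMeans(g) / 2
  maf <- pmin(p2, 1 - p2)
  if (is.null(ancestral)) ancestral <- as.integer(p2 > 0.5)
  m <- n_markers(panel)
  ihh_a <- rep(NA_real_, m); ihh_d <- rep(NA_real_, m)
  freq_d <- rep(NA_real_, m)
  for (jc in chrom_index(panel)) {
    H <- rbind(panel$hap1[, jc, drop = FALSE], panel$hap2[, jc, drop = FALSE])
    posl <- panel$map$pos[jc]
    for (t in seq_along(jc)) {
      j <- jc[t]
      if (maf[j] < maf_min) next
      anc <- ancestral[j]; der <- 1L - anc
      car_a <- which(H[, t] == anc); car_d <- which(H[, t] == der)
      if (length(car_a) < 2L || length(car_d) < 2L) next
      ia <- ihh_side(H, car_a, posl, t, -1L, ehh_cutoff) +
        ihh_side(H, car_a, posl, t, 1L, ehh_cutoff)
      id <- ihh_side(H, car_d, posl, t, -1L, ehh_cutoff) +
        ihh_side(H, car_d, posl, t, 1L, ehh_cutoff)
      if (ia <= 0 || id <= 0) next
      ihh_a[j] <- ia; ihh_d[j] <- id
      freq_d[j] <- if (der == 1L) p2[j] else 1 - p2[j]
    }
  }
  raw <- log(ihh_a / ihh_d)
  bin <- floor(freq_d / freq_bin)
  std <- rep(NA_real_, m)
  for (b in unique(bin[!is.na(bin) & !is.na(raw)])) {
    sel <- which(bin == b & !is.na(raw))
    if (length(sel) < 2L) next
    s <- stats::sd(raw[sel])
    if (s == 0) next
    std[sel] <- (raw[sel] - mean(raw[sel])) / s
  }
  # 1 - 2|Phi(x) - 0.5| is the two-tailed normal tail 2*pnorm(-|x|)
  p_ihs <- -log10(pmax(2 * stats::pnorm(-abs(std)), .Machine$double.xmin))
  per_snp <- data.frame(snp = panel$map$snp, chr = panel$map$chr,
                        pos = panel$map$pos, freq_derived = freq_d,
                        ihh_a = ihh_a, ihh_d = ihh_d, ihs_raw = raw,
                        ihs_std = std, p_ihs = p_ihs,
                        stringsAsFactors = FALSE)
  step_bp <- window_bp - overlap_bp
  win <- list()
  for (jc in chrom_index(panel)) {
    posl <- panel$map$pos[jc]
    starts <- seq(1, max(posl), by = step_bp)
    for (s0 in starts) {
      inw <- jc[posl >= s0 & posl < s0 + window_bp]
      sc <- p_ihs[inw]
      sc <- sc[!is.na(sc)]
      win[[length(win) + 1L]] <- data.frame(
        chr = panel$map$chr[jc[1L]], start = s0, end = s0 + window_bp - 1,
        n_snps = length(sc),
        score = if (length(sc)) mean(sc) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, win)
  ok <- !is.na(windows$score)
  cutoff <- if (any(ok))
    stats::quantile(windows$score[ok], 1 - top_fraction, names = FALSE)
  else NA_real_
  windows$selected <- ok & windows$score >= cutoff
  regions <- if (any(windows$selected)) {
    w <- windows[windows$selected, , drop = FALSE]
    merge_intervals(data.frame(chr = w$chr, start_bp = w$start,
                               end_bp = w$end, stringsAsFactors = FALSE))
  } else data.frame(chr = character(), start_bp = numeric(),
                    end_bp = numeric(), stringsAsFactors = FALSE)
  list(per_snp = per_snp, windows = windows, regions = regions,
       cutoff = cutoff)
}

# union of possibly-overlapping intervals, per chromosome
merge_intervals <- function(df) {
  if (!nrow(df)) return(df)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    df$chr, IRanges::IRanges(df$start_bp, df$end_bp)))
  data.frame(chr = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Consensus selection regions supported by at least two methods
#'
#' Takes the candidate intervals of the three scans (ROH islands, CLR, iHS
#' windows), computes the genomic footprint covered by two or more methods,
#' and reports each maximal such interval with the set of supporting
#' methods.
#'
#' @param roh_regions,clr_regions,ihs_regions data.frames with columns
#'   `chr`, `start_bp`, `end_bp` (empty data.frames allowed).
#' @return data.frame: chr, start_bp, end_bp, support (comma-separated
#'   method names), n_methods (always >= 2).
#' @export
consensus_regions <- function(roh_regions, clr_regions, ihs_regions) {
  lists <- list(ROH = roh_regions, CLR = clr_regions, iHS = ihs_regions)
  empty <- data.frame(chr = character(), start_bp = numeric(),
                      end_bp = numeric(), support = character(),
                      n_methods = integer(), stringsAsFactors = FALSE)
  chrs <- unique(unlist(lapply(lists, function(df)
    if (!is.null(df) && nrow(df)) unique(df$chr) else character())))
  if (!length(chrs)) return(empty)
  grs <- lapply(lists, function(df) {
    if (is.null(df) || !nrow(df))
      return(GenomicRanges::GRanges(seqlengths = stats::setNames(rep(NA_integer_, length(chrs)), chrs)))
    GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(df$chr, levels = chrs),
      IRanges::IRanges(df$start_bp, df$end_bp)))
  })
  nonempty <- names(grs)[vapply(grs, length, 1L) > 0]
  if (length(nonempty) < 2L) return(empty)
  all_gr <- do.call(c, unname(grs[nonempty]))
  cov <- GenomicRanges::coverage(all_gr)
  sl <- IRanges::slice(cov, lower = 2L, rangesOnly = TRUE)
  cons <- GenomicRanges::GRanges(sl)
  if (!length(cons)) return(empty)
  support <- vapply(seq_along(cons), function(i) {
    hit <- vapply(names(grs), function(nm) {
      length(grs[[nm]]) > 0 &&
        length(GenomicRanges::findOverlaps(cons[i], grs[[nm]])) > 0
    }, logical(1))
    paste(names(grs)[hit], collapse = ",")
  }, character(1))
  data.frame(chr = as.character(GenomicRanges::seqnames(cons)),
             start_bp = GenomicRanges::start(cons),
             end_bp = GenomicRanges::end(cons),
             support = support,
             n_methods = lengths(strsplit(support, ",")),
             stringsAsFactors = FALSE)
}

#' Write consensus/selection regions as BED (0-based half-open)
#' @param regions data.frame with chr, start_bp, end_bp and optionally
#'   support.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chr, as.integer(regions$start_bp - 1),
                   as.integer(regions$end_bp))
  if (!is.null(regions$support)) df$support <- regions$support
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
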