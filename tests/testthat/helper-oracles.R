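# independent brute-force oracles, written with explicit loops and no reuse
# of package internals

# sliding-window ROH scan: every window and every SNP examined directly,
# with the same greedy left-maximal segmentation rule as the detector
brute_force_roh <- function(panel, params, L) {
  g <- panel$hap1 + panel$hap2
  out <- list()
  for (ch in unique(panel$map$chr)) {
    j <- which(panel$map$chr == ch)
    S <- length(j)
    if (S < L) next
    pos <- panel$map$pos[j]
    for (i in seq_along(panel$samples)) {
      gi <- g[i, j]
      het <- !is.na(gi) & gi == 1L
      mis <- is.na(gi)
      nw <- S - L + 1L
      elig <- logical(nw)
      for (w in seq_len(nw)) {
        win <- w:(w + L - 1L)
        elig[w] <- sum(het[win]) <= params$max_het_in_window &&
          sum(mis[win]) <= params$max_missing_in_window
      }
      in_run <- logical(S)
      for (s in seq_len(S)) {
        wcov <- intersect(seq_len(nw), (s - L + 1L):s)
        in_run[s] <- mean(elig[wcov]) >= params$window_overlap_threshold
      }
      s <- 1L
      while (s <= S) {
        if (!in_run[s]) { s <- s + 1L; next }
        e <- s
        while (e < S && in_run[e + 1L]) e <- e + 1L
        # greedy left-maximal segmentation under the run constraints
        a <- s
        while (a <= e) {
          b <- a
          while (b < e &&
                 pos[b + 1L] - pos[b] <= params$max_gap_bp &&
                 sum(het[a:(b + 1L)]) <= params$max_het_in_window &&
                 sum(mis[a:(b + 1L)]) <= params$max_missing_in_window) {
            b <- b + 1L
          }
          len <- pos[b] - pos[a] + 1
          nsnp <- b - a + 1L
          if (len >= params$min_length_bp && nsnp >= L &&
              nsnp * params$min_density_bp >= len) {
            out[[length(out) + 1L]] <- data.frame(
              individual = panel$samples[i], chr = ch,
              start_bp = pos[a], end_bp = pos[b], n_snps = nsnp,
              length_bp = len, stringsAsFactors = FALSE)
          }
          a <- b + 1L
        }
        s <- e + 1L
      }
    }
  }
  if (!length(out)) return(data.frame(individual = character(),
                                      chr = character(),
                                      start_bp = numeric(),
                                      end_bp = numeric(),
                                      n_snps = integer(),
                                      length_bp = numeric()))
  do.call(rbind, out)
}

# Benjamini-Hochberg by direct enumeration of every candidate k
brute_force_bh <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  best_k <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) best_k <- k
  if (best_k == 0L) return(rep(FALSE, m))
  p <= ps[best_k]
}

# all-pairs interval overlap with SNP flanking
brute_force_annotate <- function(queries, genes, flank_bp) {
  hits <- list()
  for (qi in seq_len(nrow(queries))) {
    if ("pos" %in% names(queries)) {
      qs <- max(1, queries$pos[qi] - flank_bp); qe <- queries$pos[qi] + flank_bp
    } else {
      qs <- queries$start_bp[qi]; qe <- queries$end_bp[qi]
    }
    for (gi in seq_len(nrow(genes))) {
      if (queries$chr[qi] != genes$chr[gi]) next
      if (genes$start_bp[gi] <= qe && genes$end_bp[gi] >= qs)
        hits[[length(hits) + 1L]] <- c(qi, gi)
    }
  }
  if (!length(hits)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, hits)
}

# per-site spreadsheet-style evaluation of the three SNP-based inbreeding
# estimators on a small dosage matrix (monomorphic sites excluded)
oracle_inbreeding <- function(g) {
  n <- nrow(g)
  p <- colSums(g) / (2 * n)
  use <- which(p > 0 & p < 1)
  ehom <- 0
  for (j in use) ehom <- ehom + (1 - 2 * p[j] * (1 - p[j]) * (2 * n / (2 * n - 1)))
  f_hom <- numeric(n); f_uni <- numeric(n)
  denom_grm <- 0
  for (j in use) denom_grm <- denom_grm + 2 * p[j] * (1 - p[j])
  f_grm <- numeric(n)
  for (i in seq_len(n)) {
    ohom <- 0; zz <- 0; uni <- 0
    for (j in use) {
      x <- g[i, j]; pj <- p[j]
      if (x != 1) ohom <- ohom + 1
      zz <- zz + (x - 2 * pj)^2
      uni <- uni + (x^2 - (1 + 2 * pj) * x + 2 * pj^2) / (2 * pj * (1 - pj))
    }
    f_hom[i] <- (ohom - ehom) / (length(use) - ehom)
    f_grm[i] <- zz / denom_grm - 1
    f_uni[i] <- uni / length(use)
  }
  list(f_hom = f_hom, f_grm = f_grm, f_uni = f_uni)
}

# exact HWE tail probability by full enumeration over heterozygote counts
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  rare <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# hand EHH: enumerate haplotype classes over the span core..m directly
oracle_ehh <- function(H, carriers, core, m) {
  span <- if (m >= core) core:m else m:core
  keys <- apply(H[carriers, span, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(keys)
  nc <- length(carriers)
  sum(cnt * (cnt - 1) / 2) / (nc * (nc - 1) / 2)
}

# quantile-and-merge island scan on a raw incidence vector
oracle_islands <- function(pos, inc, top_fraction, merge_gap) {
  cutoff <- stats::quantile(inc, 1 - top_fraction, names = FALSE)
  sel <- which(inc >= cutoff & inc > 0)
  if (!length(sel)) return(NULL)
  groups <- list(sel[1])
  for (s in sel[-1]) {
    last <- groups[[length(groups)]]
    if (pos[s] - pos[last[length(last)]] <= merge_gap)
      groups[[length(groups)]] <- c(last, s)
    else groups[[length(groups) + 1L]] <- s
  }
  do.call(rbind, lapply(groups, function(gr)
    data.frame(start_bp = pos[gr[1]], end_bp = pos[gr[length(gr)]],
               n_snps = length(gr))))
}
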