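#' Fit the null animal repeatability model by REML
#'
#' Model: y = W alpha + X beta + Z mu + e, where alpha holds the intercept
#' and parity/year/season fixed effects, beta ~ N(0, G sigma2_a) is the
#' additive polygenic effect with G the genomic relationship matrix,
#' mu ~ N(0, I sigma2_pe) the permanent environment effect (one per ewe),
#' and e ~ N(0, I sigma2_e). The restricted likelihood is profiled on
#' sigma2_e and maximized over the two variance ratios by coordinate-wise
#' golden-section search, declared converged when the restricted
#' log-likelihood changes by less than `tol` (default 1e-6) between sweeps
#' (at most `max_iter` sweeps). All variance components are constrained
#' non-negative; computations reduce to individual-level (q x q) algebra
#' via the Woodbury identity in the eigenbasis of G.
#'
#' @param phenotypes a `phenotype_table` (individual_id, parity, year,
#'   season, litter_size).
#' @param grm genomic relationship matrix with sample ids as dimnames;
#'   every phenotyped individual must appear.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter maximum coordinate sweeps.
#' @return object of class `ovipop_reml`: variance components, heritability
#'   `h2`, `repeatability`, `loglik`, fixed-effect estimates, convergence
#'   flag, plus the factored pieces reused by [snp_tests()].
#' @export
fit_null_repeatability <- function(phenotypes, grm, tol = 1e-6,
                                   max_iter = 200L) {
  ids <- unique(phenotypes$individual_id)
  if (!all(ids %in% rownames(grm)))
    stop("phenotyped individuals missing from the GRM: ",
         paste(utils::head(setdiff(ids, rownames(grm)), 3), collapse = ", "))
  q <- length(ids)
  idx <- match(phenotypes$individual_id, ids)
  counts <- tabulate(idx, nbins = q)
  if (sum(counts >= 2L) < 2L)
    stop("sigma2_pe (permanent environment variance) is not identifiable: ",
         "need at least two individuals with repeated records")
  y <- phenotypes$litter_size
  n <- length(y)
  W <- fixed_design(phenotypes)
  p <- ncol(W)
  if (qr(W)$rank < p) stop("singular fixed-effects design")
  G <- grm[ids, ids]
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors; Dvec <- pmax(eg$values, 0)
  ZtW <- rowsum(W, idx)            # q x p
  Zty <- as.numeric(rowsum(y, idx))
  UtZtW <- crossprod(U, ZtW)
  UtZty <- as.numeric(crossprod(U, Zty))
  WtW <- crossprod(W); Wty <- as.numeric(crossprod(W, y)); yty <- sum(y * y)
  equal_counts <- length(unique(counts)) == 1L
  Sz <- if (equal_counts) NULL else crossprod(U, counts * U)
  r0 <- counts[1L]

  eval_ll <- function(lam) {
    Delta <- lam[1L] * Dvec + lam[2L]
    act <- Delta > 1e-12
    if (!any(act)) {
      a <- WtW; b <- Wty; cc <- yty; logdetH <- 0
    } else {
      Da <- Delta[act]
      if (equal_counts) {
        minv <- 1 / (1 / Da + r0)     # diagonal M
        logdetM <- sum(log(1 / Da + r0))
        Xa <- UtZtW[act, , drop = FALSE]; ya <- UtZty[act]
        a <- WtW - crossprod(Xa, minv * Xa)
        b <- Wty - as.numeric(crossprod(Xa, minv * ya))
        cc <- yty - sum(ya * minv * ya)
      } else {
        M <- Sz[act, act, drop = FALSE]
        diag(M) <- diag(M) + 1 / Da
        ch <- chol(M)
        logdetM <- 2 * sum(log(diag(ch)))
        Xa <- UtZtW[act, , drop = FALSE]; ya <- UtZty[act]
        sx <- backsolve(ch, forwardsolve(t(ch), Xa))
        sy <- backsolve(ch, forwardsolve(t(ch), ya))
        a <- WtW - crossprod(Xa, sx)
        b <- Wty - as.numeric(crossprod(Xa, sy))
        cc <- yty - sum(ya * sy)
      }
      logdetH <- sum(log(Da)) + logdetM
    }
    beta <- solve(a, b)
    quad <- cc - sum(b * beta)
    s2e <- quad / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + logdetH +
                    determinant(a, logarithm = TRUE)$modulus[1L] + (n - p))
    list(ll = ll, s2e = s2e, beta = beta)
  }

  lam <- c(0.1, 0.1)
  prev <- eval_ll(lam)$ll
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    for (k in 1:2) {
      f <- function(x) { l <- lam; l[k] <- x; -eval_ll(l)$ll }
      opt <- stats::optimize(f, interval = c(0, 50), tol = 1e-7)
      # check the zero boundary explicitly; golden section cannot reach it
      lam[k] <- if (f(0) <= opt$objective) 0 else opt$minimum
    }
    cur <- eval_ll(lam)$ll
    if (abs(cur - prev) < tol) { converged <- TRUE; prev <- cur; break }
    prev <- cur
  }
  fin <- eval_ll(lam)
  s2e <- fin$s2e
  vc <- c(var_additive = lam[1L] * s2e, var_permanent = lam[2L] * s2e,
          var_residual = s2e)
  tot <- sum(vc)
  obj <- list(varcomp = vc,
              h2 = unname(vc[1L] / tot),
              repeatability = unname((vc[1L] + vc[2L]) / tot),
              loglik = fin$ll,
              beta = stats::setNames(as.numeric(fin$beta), colnames(W)),
              lambda = lam, converged = converged, iterations = iters,
              ids = ids, n_records = n,
              internals = list(U = U, Dvec = Dvec, counts = counts,
                               idx = idx, W = W, y = y, ZtW = ZtW,
                               Zty = Zty, UtZtW = UtZtW, UtZty = UtZty,
                               WtW = WtW, Wty = Wty, yty = yty,
                               equal_counts = equal_counts, Sz = Sz))
  class(obj) <- "ovipop_reml"
  obj
}

#' @export
print.ovipop_reml <- function(x, ...) {
  cat("Animal repeatability model (REML",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "sweeps)\n")
  cat(sprintf("  sigma2_a  = %.4f\n  sigma2_pe = %.4f\n  sigma2_e  = %.4f\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3]))
  cat(sprintf("  h2 = %.3f  repeatability = %.3f  logLik = %.3f\n",
              x$h2, x$repeatability, x$loglik))
  invisible(x)
}

# fixed-effects design: intercept + parity + year + season, single-level
# factors dropped
fixed_design <- function(phenotypes) {
  df <- data.frame(parity = factor(phenotypes$parity),
                   year = factor(phenotypes$year),
                   season = factor(phenotypes$season))
  keep <- vapply(df, function(f) nlevels(f) > 1L, logical(1))
  if (!any(keep)) return(matrix(1, nrow(df), 1,
                                dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., df[, keep, drop = FALSE])
}

#' Per-SNP association tests under the repeatability model
#'
#' Each SNP's dosage enters the fixed part of the null model; variance
#' components stay fixed at their null REML estimates and the SNP effect
#' and its standard error come from generalized least squares with the
#' record-level covariance V = Z G Z' sigma2_a + Z Z' sigma2_pe +
#' I sigma2_e (the usual two-stage mixed-model GWAS). Significance is a
#' 1-df Wald chi-square; the FDR flag applies [fdr_threshold()] at
#' `fdr_q`.
#'
#' @param phenotypes the `phenotype_table` used for the null fit.
#' @param panel a filled `genotype_panel` containing the phenotyped
#'   individuals.
#' @param null_fit an `ovipop_reml` object from [fit_null_repeatability()].
#' @param fdr_q FDR level for the significance flag.
#' @return data.frame: snp, chr, pos, effect, se, wald, p, passes_fdr;
#'   monomorphic SNPs are returned with NA statistics and a `skipped`
#'   reason. Attribute `fdr` holds the threshold details.
#' @export
snp_tests <- function(phenotypes, panel, null_fit, fdr_q = 0.005) {
  stopifnot(inherits(null_fit, "ovipop_reml"))
  it <- null_fit$internals
  ids <- null_fit$ids
  rows <- match(ids, panel$samples)
  if (anyNA(rows))
    stop("panel is missing phenotyped individuals: ",
         paste(utils::head(ids[is.na(rows)], 3), collapse = ", "))
  Gd <- dosage(panel)[rows, , drop = FALSE]
  if (anyNA(Gd)) stop("panel has missing genotypes; run fill_missing() first")
  m <- ncol(Gd)
  lam <- null_fit$lambda
  Delta <- lam[1L] * it$Dvec + lam[2L]
  act <- Delta > 1e-12
  p <- ncol(it$W); n <- length(it$y)
  # H^{-1} cross-products shared by all SNPs
  if (any(act)) {
    Da <- Delta[act]
    Xa <- it$UtZtW[act, , drop = FALSE]; ya <- it$UtZty[act]
    if (it$equal_counts) {
      minv <- 1 / (1 / Da + it$counts[1L])
      solveM <- function(B) minv * B
    } else {
      M <- it$Sz[act, act, drop = FALSE]
      diag(M) <- diag(M) + 1 / Da
      ch <- chol(M)
      solveM <- function(B) backsolve(ch, forwardsolve(t(ch), B))
    }
    a <- it$WtW - crossprod(Xa, solveM(Xa))
    b <- it$Wty - as.numeric(crossprod(Xa, solveM(ya)))
  } else {
    solveM <- NULL
    a <- it$WtW; b <- it$Wty
  }
  s2e <- null_fit$varcomp[3L]
  mono <- apply(Gd, 2L, function(x) length(unique(x)) == 1L)
  Ztg <- it$counts * Gd                              # q x m
  Wtg <- crossprod(it$ZtW, Gd)                       # p x m  (= W' Z g_ind)
  gty <- as.numeric(crossprod(Gd, it$Zty))
  gtg <- colSums(it$counts * Gd * Gd)
  if (any(act)) {
    UtZtg <- crossprod(it$U[, act, drop = FALSE], Ztg)  # qa x m
    Sg <- solveM(UtZtg)
    Wtg_h <- Wtg - crossprod(Xa, Sg)
    gty_h <- gty - as.numeric(crossprod(UtZtg, solveM(ya)))
    gtg_h <- gtg - colSums(UtZtg * Sg)
  } else {
    Wtg_h <- Wtg; gty_h <- gty; gtg_h <- gtg
  }
  effect <- se <- wald <- pval <- rep(NA_real_, m)
  for (jj in seq_len(m)) {
    if (mono[jj]) next
    A <- rbind(cbind(a, Wtg_h[, jj]), c(Wtg_h[, jj], gtg_h[jj]))
    rhs <- c(b, gty_h[jj])
    Ai <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ai)) { mono[jj] <- TRUE; next }
    coefs <- Ai %*% rhs
    effect[jj] <- coefs[p + 1L]
    se[jj] <- sqrt(s2e * Ai[p + 1L, p + 1L])
    wald[jj] <- (effect[jj] / se[jj])^2
    pval[jj] <- stats::pchisq(wald[jj], df = 1, lower.tail = FALSE)
  }
  out <- data.frame(snp = panel$map$snp, chr = panel$map$chr,
                    pos = panel$map$pos, effect = effect, se = se,
                    wald = wald, p = pval,
                    skipped = ifelse(mono, "monomorphic_or_collinear", ""),
                    stringsAsFactors = FALSE)
  fdr <- fdr_threshold(pval[!is.na(pval)], q = fdr_q)
  out$passes_fdr <- FALSE
  out$passes_fdr[!is.na(out$p)] <- fdr$flags
  attr(out, "fdr") <- fdr[c("threshold_p", "neg_log10_threshold", "n_discoveries")]
  out
}

#' Genomic inflation factor
#'
#' lambda_gc is the median of the 1-df chi-square quantiles of the observed
#' p-values divided by the null median 0.4549364.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return lambda_gc.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values supplied")
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg FDR threshold
#'
#' Sorts the p-values ascending, finds the largest k with
#' p_(k) <= k q / m, and flags those k tests as discoveries.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q target false discovery rate.
#' @return list: `flags` (logical, in input order), `threshold_p` (largest
#'   discovered p-value; NA if none), `neg_log10_threshold`,
#'   `n_discoveries`.
#' @export
fdr_threshold <- function(p_values, q = 0.005) {
  m <- length(p_values)
  if (!m) return(list(flags = logical(0), threshold_p = NA_real_,
                      neg_log10_threshold = NA_real_, n_discoveries = 0L))
  o <- order(p_values)
  ps <- p_values[o]
  ok <- ps <= seq_len(m) * q / m
  if (!any(ok)) {
    return(list(flags = rep(FALSE, m), threshold_p = NA_real_,
                neg_log10_threshold = NA_real_, n_discoveries = 0L))
  }
  k <- max(which(ok))
  thr <- ps[k]
  list(flags = p_values <= thr, threshold_p = thr,
       neg_log10_threshold = -log10(thr), n_discoveries = k)
}
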