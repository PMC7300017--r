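# Kinship-aware linear mixed model association scan.
#
# Model per SNP:  y = W a + x b + u + e,  u ~ N(0, s2g K), e ~ N(0, s2e I).
# With the eigendecomposition K = U D U' (done once per scan), rotating
# all quantities by U' diagonalizes the covariance: Var = s2e (l D + I)
# with variance ratio l = s2g/s2e.  The per-SNP ML over l is a bounded
# 1-D search on log(l) in [1e-5, 1e5]: a coarse log-spaced grid is
# evaluated for all SNPs at once (vectorized GLS via residualization),
# then Brent refinement runs between the flanking grid points of each
# SNP's best value (tol 1e-6).  The Wald statistic b^2/se^2 is referred
# to chi-square(1).

#' SNP quality control
#'
#' Keeps SNPs with minor allele frequency >= `maf_min` (computed on
#' non-missing genotypes) and missingness <= `miss_max`; both bounds
#' inclusive.
#'
#' @param geno Dosage matrix (individuals x SNPs).
#' @param map Matching [snp_map()].
#' @param maf_min Minimum MAF (default 0.05).
#' @param miss_max Maximum missing fraction (default 0.05).
#' @return List with filtered `genotypes` and `map`, logical `keep`, and
#'   removal counts `n_removed_maf`, `n_removed_missing` (a SNP failing
#'   both is counted in both).
#' @export
snp_qc <- function(geno, map, maf_min = 0.05, miss_max = 0.05) {
  miss <- colMeans(is.na(geno))
  af <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  fail_maf <- maf < maf_min
  fail_miss <- miss > miss_max
  keep <- !(fail_maf | fail_miss)
  list(genotypes = geno[, keep, drop = FALSE],
       map = map[keep, , drop = FALSE],
       keep = keep,
       n_removed_maf = sum(fail_maf),
       n_removed_missing = sum(fail_miss))
}

impute_mean <- function(geno) {
  mu <- colMeans(geno, na.rm = TRUE)
  nas <- which(is.na(geno), arr.ind = TRUE)
  if (nrow(nas)) geno[nas] <- mu[nas[, 2]]
  geno
}

#' Genomic relationship matrix from centered dosages
#'
#' Missing dosages are mean-imputed per SNP, columns are centered by
#' twice the sample allele frequency, and the cross-product is scaled by
#' the sum of expected per-SNP variances (`sum(2 p (1-p))`), which puts
#' entries on the standard relatedness scale (full sibs ~ 0.5,
#' self ~ 1).  The result is symmetrized and eigenvalue-clipped to be
#' positive semidefinite.
#'
#' @param geno Post-QC dosage matrix (individuals x SNPs).
#' @return Square relatedness matrix over the individuals.
#' @export
compute_grm <- function(geno) {
  G <- impute_mean(geno)
  p <- colMeans(G) / 2
  v <- apply(G, 2, var)
  if (any(v == 0)) {
    stop(sprintf("%d zero-variance SNP(s) in GRM input; run snp_qc first",
                 sum(v == 0)))
  }
  Z <- sweep(G, 2, 2 * p, `-`)
  K <- tcrossprod(Z) / sum(2 * p * (1 - p))
  (K + t(K)) / 2
}

# Eigendecompose and validate a kinship matrix.
kinship_eigen <- function(K) {
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kinship matrix must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("kinship matrix is not positive semidefinite")
  }
  e$values <- pmax(e$values, 0)
  e
}

# Profile log-likelihood (ML or REML) for one rotated design at
# log-ratio llam.  REML adds the -log|X'V^-1X| correction, which also
# removes the slow logarithmic ridge the plain ML profile develops
# toward the upper bracket when K is singular and the covariates span
# its null space (the centred GRM always has the constant vector there).
lmm_loglik <- function(llam, D, Xt, yt, reml = FALSE) {
  v <- exp(llam) * D + 1
  sw <- 1 / sqrt(v)
  Xw <- Xt * sw
  yw <- yt * sw
  fit <- lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(yt)
  if (!reml) {
    -0.5 * (n * log(2 * pi) + n * log(rss / n) + sum(log(v)) + n)
  } else {
    c <- ncol(Xt)
    nc <- n - c
    -0.5 * (nc * log(2 * pi) + nc * log(rss / nc) + sum(log(v)) +
              determinant(crossprod(Xw), logarithm = TRUE)$modulus + nc)
  }
}

#' Association scan of one gene's expression across all SNPs
#'
#' @param y Expression vector on the analysis scale, named by individual
#'   (or aligned with `geno` rows).  Individuals with missing `y` are
#'   dropped from the scan.
#' @param covariates Design matrix of fixed covariates *without*
#'   intercept columns beyond the first (pass e.g.
#'   `model.matrix(~ sex + backcross, ...)`); `NULL` gives an
#'   intercept-only design.
#' @param geno Post-QC dosage matrix (individuals x SNPs).
#' @param K Kinship matrix over the same individuals.
#' @param map Matching [snp_map()].
#' @param bracket Search bounds for the variance ratio (default
#'   `c(1e-5, 1e5)`).
#' @param grid_points Size of the coarse initialization grid.
#' @param tol Brent tolerance on the log variance ratio.
#' @param miss_max SNPs above this missing fraction at scan time are
#'   skipped with a warning (statistics set to `NA`).
#' @param likelihood `"ML"` (default) or `"REML"` for the per-SNP
#'   variance-ratio estimate; REML is the convention GEMMA uses for its
#'   Wald test and is free of the boundary ridge the ML profile shows
#'   with a singular kinship matrix (see the methods vignette).
#' @return Data frame of class `association_scan`: `snp_id`, `chr`,
#'   `pos`, `beta`, `se`, `wald_p`, `q_value` (Benjamini-Hochberg over
#'   this scan), `maf`, `n_used`, `lambda` (estimated variance ratio).
#' @export
scan_gene <- function(y, covariates, geno, K, map, bracket = c(1e-5, 1e5),
                      grid_points = 41L, tol = 1e-6, miss_max = 0.05,
                      likelihood = c("ML", "REML")) {
  reml <- match.arg(likelihood) == "REML"
  ids <- rownames(geno)
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y))) stop("y is missing some genotyped individuals")
    y <- y[ids]
  }
  if (length(y) != nrow(geno)) stop("y and genotypes are misaligned")
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  geno <- geno[keep, , drop = FALSE]
  if (is.null(covariates)) {
    W <- matrix(1, length(y), 1)
  } else {
    W <- as.matrix(covariates)[keep, , drop = FALSE]
  }
  K <- K[keep, keep, drop = FALSE]
  n <- length(y)

  miss <- colMeans(is.na(geno))
  skip <- miss > miss_max
  if (any(skip)) {
    warning(sprintf("skipping %d SNP(s) with missing rate > %.0f%% at scan time",
                    sum(skip), 100 * miss_max))
  }
  af <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  n_used <- colSums(!is.na(geno))
  X <- impute_mean(geno)

  e <- kinship_eigen(K)
  U <- e$vectors
  D <- e$values
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  Xt <- crossprod(U, X)

  lgrid <- seq(log(bracket[1]), log(bracket[2]), length.out = grid_points)
  p <- ncol(X)
  cdim <- ncol(W) + 1L
  best_ll <- rep(-Inf, p)
  best_i <- rep(1L, p)
  for (gi in seq_along(lgrid)) {
    v <- exp(lgrid[gi]) * D + 1
    sw <- 1 / sqrt(v)
    Ww <- Wt * sw
    yw <- yt * sw
    Xw <- Xt * sw
    qw <- qr(Ww)
    yr <- qr.resid(qw, yw)
    Xr <- qr.resid(qw, Xw)
    bnum <- colSums(Xr * yr)
    bden <- colSums(Xr^2)
    rss <- sum(yr^2) - ifelse(bden > 0, bnum^2 / bden, 0)
    if (!reml) {
      ll <- -0.5 * (n * log(2 * pi) + n * log(rss / n) + sum(log(v)) + n)
    } else {
      nc <- n - cdim
      # log|X'V^-1X| = log|W'V^-1W| + log of the residualized SNP norm
      ldW <- determinant(crossprod(Ww), logarithm = TRUE)$modulus
      ll <- -0.5 * (nc * log(2 * pi) + nc * log(rss / nc) + sum(log(v)) +
                      ldW + log(pmax(bden, .Machine$double.xmin)) + nc)
    }
    upd <- ll > best_ll
    best_ll[upd] <- ll[upd]
    best_i[upd] <- gi
  }

  beta <- se <- lambda <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    if (skip[j] || maf[j] == 0) next
    Xj <- cbind(Wt, Xt[, j])
    f <- function(l) lmm_loglik(l, D, Xj, yt, reml = reml)
    lo <- lgrid[max(1L, best_i[j] - 1L)]
    hi <- lgrid[min(grid_points, best_i[j] + 1L)]
    opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
    llam <- opt$maximum
    # boundary of the bracket can beat the interior optimum
    for (cand in c(lo, hi)[c(best_i[j] == 1L, best_i[j] == grid_points)]) {
      if (f(cand) > opt$objective) llam <- cand
    }
    v <- exp(llam) * D + 1
    sw <- 1 / sqrt(v)
    Xw <- Xj * sw
    yw <- yt * sw
    xtx <- crossprod(Xw)
    xty <- crossprod(Xw, yw)
    bhat <- solve(xtx, xty)
    rss <- sum((yw - Xw %*% bhat)^2)
    sigma2 <- rss / (if (reml) n - ncol(Xj) else n)
    covb <- sigma2 * solve(xtx)
    beta[j] <- bhat[ncol(Xj)]
    se[j] <- sqrt(covb[ncol(Xj), ncol(Xj)])
    lambda[j] <- exp(llam)
  }
  stat <- (beta / se)^2
  wald_p <- pchisq(stat, df = 1, lower.tail = FALSE)
  q <- rep(NA_real_, p)
  ok <- !is.na(wald_p)
  q[ok] <- bh_qvalues(wald_p[ok])
  out <- data.frame(snp_id = map$snp_id, chr = map$chr, pos = map$pos,
                    beta = beta, se = se, wald_p = wald_p, q_value = q,
                    maf = maf, n_used = n_used, lambda = lambda,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("association_scan", "data.frame")
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_qvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Storey q-values (optional alternative to Benjamini-Hochberg)
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / ((1 - lambda) m)` (capped at 1) and scales
#' the BH q-values by it.
#'
#' @param p Vector of p-values.
#' @param lambda Tuning point for the pi0 estimate (default 0.5).
#' @return Vector of q-values.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * bh_qvalues(p))
}

#' Variance in expression explained by a single SNP (partial R-squared)
#'
#' `PVE = (RSS_reduced - RSS_full) / RSS_reduced`, where the reduced
#' model holds the covariates only, so the denominator is the total
#' variation of the covariate-residualized expression.
#'
#' @param y Expression vector.
#' @param covariates Covariate design matrix (or `NULL` for intercept
#'   only).
#' @param x SNP dosage vector (missing values mean-imputed).
#' @return PVE as a fraction in `[0, 1]`.
#' @export
variance_explained <- function(y, covariates, x) {
  keep <- !is.na(y)
  y <- y[keep]
  x <- x[keep]
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  W <- if (is.null(covariates)) matrix(1, length(y), 1)
       else as.matrix(covariates)[keep, , drop = FALSE]
  if (sd(y) == 0) stop("constant expression vector")
  qw <- qr(W)
  yr <- qr.resid(qw, y)
  xr <- qr.resid(qw, x)
  rss0 <- sum(yr^2)
  den <- sum(xr^2)
  rss1 <- if (den > 0) rss0 - sum(xr * yr)^2 / den else rss0
  (rss0 - rss1) / rss0
}
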