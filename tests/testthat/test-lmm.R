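# Mixed-model scan, QC, kinship, FDR and variance explained.

test_that("SNP QC applies inclusive MAF and missingness bounds", {
  n <- 100
  G <- make_genotypes(n, 6, seed = 2, maf_range = c(0.3, 0.5))
  # column 1: MAF 0.04 (below threshold)
  G[, 1] <- 0L; G[seq_len(8), 1] <- 1L
  # column 2: exactly 5% missing (kept), column 3: 6% missing (removed)
  G[seq_len(5), 2] <- NA
  G[seq_len(6), 3] <- NA
  map <- make_map(G)
  qc <- snp_qc(G, map)
  expect_false("snp0001" %in% qc$map$snp_id)
  expect_true("snp0002" %in% qc$map$snp_id)
  expect_false("snp0003" %in% qc$map$snp_id)
  expect_gte(qc$n_removed_maf, 1)
  expect_gte(qc$n_removed_missing, 1)

  # surviving set equals a brute-force filter on a random fixture
  G2 <- make_genotypes(80, 500, seed = 5, maf_range = c(0.01, 0.99),
                       missing_rate = 0.04)
  qc2 <- snp_qc(G2, make_map(G2))
  brute <- vapply(seq_len(500), function(j) {
    x <- G2[, j]
    af <- mean(x, na.rm = TRUE) / 2
    min(af, 1 - af) >= 0.05 && mean(is.na(x)) <= 0.05
  }, logical(1))
  expect_identical(unname(qc2$keep), brute)
})

test_that("kinship matrix sits on the standard relatedness scale", {
  G <- make_genotypes(40, 800, seed = 6)
  # duplicated individual: off-diagonal equals both diagonals
  G2 <- rbind(G, dup = G[1, ])
  rownames(G2) <- c(rownames(G), "dup")
  K <- compute_grm(G2)
  expect_equal(K["ind001", "dup"], K["ind001", "ind001"], tolerance = 1e-12)
  expect_equal(K["ind001", "dup"], K["dup", "dup"], tolerance = 1e-12)
  # unrelated individuals: mean off-diagonal at the centering value
  # (-1/(n-1), since centred rows sum to ~0), i.e. near zero for large n
  off <- K[upper.tri(K)][-1]
  expect_lt(abs(mean(off) + 1 / (nrow(K) - 1)),
            3 * sd(off) / sqrt(length(off)) + 0.005)

  # full sibs ~ 0.5: draw parents, mate them, measure sib kinship
  set.seed(8)
  p <- 1500
  af <- runif(p, 0.2, 0.8)
  draw_gamete <- function(geno) rbinom(p, 1, geno / 2)
  parents <- lapply(1:40, function(i) rbinom(p, 2, af))
  kids <- matrix(0L, 40, p)
  for (fam in 1:20) {
    pa <- parents[[2 * fam - 1]]; ma <- parents[[2 * fam]]
    kids[2 * fam - 1, ] <- draw_gamete(pa) + draw_gamete(ma)
    kids[2 * fam, ] <- draw_gamete(pa) + draw_gamete(ma)
  }
  dimnames(kids) <- list(paste0("k", 1:40), paste0("s", 1:p))
  Ks <- compute_grm(kids)
  sib <- vapply(1:20, function(f) Ks[2 * f - 1, 2 * f], numeric(1))
  expect_lt(abs(mean(sib) - 0.5), 0.05)

  Gz <- G; Gz[, 1] <- 1L
  expect_error(compute_grm(Gz), "zero-variance")
})

test_that("scan matches grid-search GLS oracle and is deterministic", {
  set.seed(13)
  n <- 30; p <- 40
  fam <- rep(1:6, each = 5)
  freqs <- matrix(runif(6 * p, 0.15, 0.85), 6, p)
  G <- matrix(0L, n, p, dimnames = list(paste0("i", 1:n),
                                        sprintf("s%03d", 1:p)))
  for (i in 1:n) G[i, ] <- rbinom(p, 2, freqs[fam[i], ])
  map <- make_map(G)
  K <- compute_grm(G)
  u <- drop(t(chol(K + diag(1e-6, n))) %*% rnorm(n))
  y <- setNames(u + rnorm(n), rownames(G))
  sc <- scan_gene(y, NULL, G, K, map)
  sc2 <- scan_gene(y, NULL, G, K, map)
  expect_identical(sc, sc2)

  # independent oracle: dense grid + Brent refinement, all through
  # lm.fit GLS (handles interior variance-ratio optima exactly)
  e <- eigen(K, symmetric = TRUE)
  U <- e$vectors; D <- pmax(e$values, 0)
  yt <- drop(crossprod(U, y)); Wt <- crossprod(U, matrix(1, n, 1))
  lgrid <- seq(log(1e-5), log(1e5), length.out = 300)
  for (j in c(1, 7, 19, 33)) {
    xt <- drop(crossprod(U, G[, j]))
    ll_at <- function(llam) {
      v <- exp(llam) * D + 1
      fit <- lm.fit(cbind(Wt, xt) / sqrt(v), yt / sqrt(v))
      -0.5 * (n * log(2 * pi) + n * log(sum(fit$residuals^2) / n) +
                sum(log(v)) + n)
    }
    ll <- vapply(lgrid, ll_at, numeric(1))
    i0 <- which.max(ll)
    opt <- optimize(ll_at, interval = lgrid[c(max(1, i0 - 1),
                                              min(300, i0 + 1))],
                    maximum = TRUE, tol = 1e-9)
    llam <- if (ll[i0] > opt$objective) lgrid[i0] else opt$maximum
    v <- exp(llam) * D + 1
    X <- cbind(Wt, xt) / sqrt(v); yy <- yt / sqrt(v)
    b <- solve(crossprod(X), crossprod(X, yy))
    s2 <- sum((yy - X %*% b)^2) / n
    covb <- s2 * solve(crossprod(X))
    stat_o <- b[2]^2 / covb[2, 2]
    stat_m <- (sc$beta[j] / sc$se[j])^2
    expect_equal(stat_m, stat_o, tolerance = 1e-6)
  }
})

test_that("REML variant agrees with ML where the ratio is pinned", {
  G <- make_genotypes(80, 40, seed = 21)
  map <- make_map(G)
  K <- diag(80)
  dimnames(K) <- list(rownames(G), rownames(G))
  set.seed(22)
  y <- setNames(0.5 * G[, 5] + rnorm(80), rownames(G))
  ml <- scan_gene(y, NULL, G, K, map)
  rl <- scan_gene(y, NULL, G, K, map, likelihood = "REML")
  # with K = I the GLS fit is OLS for both; only the variance divisor
  # differs (n vs n - c), scaling every squared statistic by n/(n-c)
  expect_equal((rl$beta / rl$se)^2 * 80 / 78,
               (ml$beta / ml$se)^2, tolerance = 1e-8)
  expect_equal(rl$beta, ml$beta, tolerance = 1e-10)
})

test_that("Wald p is invariant to flipping the counted allele", {
  G <- make_genotypes(60, 30, seed = 17)
  map <- make_map(G)
  K <- compute_grm(G)
  set.seed(18)
  y <- setNames(0.4 * G[, 3] + rnorm(60), rownames(G))
  sc <- scan_gene(y, NULL, G, K, map)
  Gf <- G; Gf[, 3] <- 2L - Gf[, 3]
  scf <- scan_gene(y, NULL, Gf, K, map)
  expect_equal(scf$beta[3], -sc$beta[3], tolerance = 1e-8)
  expect_equal(scf$wald_p[3], sc$wald_p[3], tolerance = 1e-8)
})

test_that("high-missingness SNPs are skipped at scan time with a warning", {
  G <- make_genotypes(50, 10, seed = 19)
  G[1:10, 4] <- NA
  map <- make_map(G)
  K <- compute_grm(G[, -4])
  set.seed(20)
  y <- setNames(rnorm(50), rownames(G))
  expect_warning(sc <- scan_gene(y, NULL, G, K, map), "missing rate")
  expect_true(is.na(sc$wald_p[4]))
  expect_false(anyNA(sc$wald_p[-4]))
})

test_that("Benjamini-Hochberg q-values follow the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.37), 0.37)
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_qvalues(c(-0.1, 0.2)), "\\[0, 1\\]")

  # equals the reference implementation on many random vectors
  set.seed(23)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_lt(max(abs(bh_qvalues(p) - stats::p.adjust(p, "BH"))), 1e-12)
  }
  # q is monotone nondecreasing in p after sorting
  p <- runif(200)
  q <- bh_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))

  # Storey variant never exceeds BH and stays in [0, 1]
  qs <- storey_qvalues(p)
  expect_true(all(qs <= bh_qvalues(p) + 1e-12))
  expect_true(all(qs >= 0 & qs <= 1))
})

test_that("variance explained is the partial R-squared of the SNP", {
  set.seed(29)
  n <- 120
  x <- rbinom(n, 2, 0.4)
  y <- (x - mean(x)) / sd(x)
  expect_equal(variance_explained(y, NULL, x), 1.0, tolerance = 1e-12)
  expect_error(variance_explained(rep(1, n), NULL, x), "constant")

  # independent SNP: null R-squared is O(1/n)
  r2 <- replicate(200, {
    variance_explained(rnorm(n), NULL, rbinom(n, 2, 0.4))
  })
  expect_lt(mean(r2), 3 / n)

  # matches lm-based partial R2 with covariates
  W <- cbind(1, rnorm(n))
  y2 <- 0.5 * x + W[, 2] + rnorm(n)
  f0 <- lm(y2 ~ W[, 2])
  f1 <- lm(y2 ~ W[, 2] + x)
  pr2 <- (sum(f0$residuals^2) - sum(f1$residuals^2)) / sum(f0$residuals^2)
  expect_equal(variance_explained(y2, W, x), pr2, tolerance = 1e-12)
})
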