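# Shared fixture builders for the test suite.  Everything is generated
# in code under fixed seeds; no binary fixtures.

# iid dosage matrix with unstructured individuals (no families)
make_genotypes <- function(n, p, seed = 1, maf_range = c(0.1, 0.9),
                           missing_rate = 0) {
  set.seed(seed)
  af <- runif(p, maf_range[1], maf_range[2])
  G <- matrix(rbinom(n * p, 2, rep(af, each = n)), n, p,
              dimnames = list(sprintf("ind%03d", seq_len(n)),
                              sprintf("snp%04d", seq_len(p))))
  if (missing_rate > 0) {
    G[runif(n * p) < missing_rate] <- NA_integer_
  }
  storage.mode(G) <- "integer"
  G
}

make_map <- function(G, chr = "1", spacing = 1e5) {
  p <- ncol(G)
  snp_map(colnames(G), rep_len(chr, p), seq_len(p) * spacing)
}

# small desk-scale simulation config used by several tests
tiny_cfg <- function(seed = 1, ...) {
  sim_config(profile = "desk",
             n_per_backcross = c(BC1_LD = 30, BC1_DU = 30, BC1_PI = 30),
             chromosome_lengths_bp = stats::setNames(rep(100e6, 2), c("1", "2")),
             snps_per_chromosome = stats::setNames(rep(120L, 2), c("1", "2")),
             n_target_genes = 4L,
             effects = list(
               list(gene = "G01", mode = "additive_cis", pve = 0.5,
                    snp = "cis1", freq = list(sire = 0.9, dam = 0.1))),
             blocks = list(), seed = seed, ...)
}

# brute-force transitive-closure clustering of positions with gap rule:
# two eSNPs are linked iff < gap apart; clusters are the transitive
# closure of that relation (independent oracle for merge_intervals)
oracle_cluster <- function(pos, gap = 1e7) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) < gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(comp[adj[i, ]])
      if (m < comp[i]) { comp[adj[i, ] | comp == comp[i]] <-
        pmin(comp[adj[i, ] | comp == comp[i]], m); changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(pos)]))
}

# naive scalar triple-loop PCIT oracle
oracle_pcit <- function(R) {
  g <- ncol(R)
  kept <- matrix(TRUE, g, g, dimnames = dimnames(R))
  diag(kept) <- FALSE
  if (g < 3) return(kept)
  for (x in seq_len(g)) for (y in seq_len(g)) for (z in seq_len(g)) {
    if (x >= y || z == x || z == y) next
    rxy <- R[x, y]; rxz <- R[x, z]; ryz <- R[y, z]
    if (abs(rxy) >= 1 || abs(rxz) >= 1 || abs(ryz) >= 1) next
    rxy_z <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    rxz_y <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
    ryz_x <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
    eps <- (rxy_z / rxy + rxz_y / rxz + ryz_x / ryz) / 3
    if (abs(rxy) < abs(eps * rxz) && abs(rxy) < abs(eps * ryz)) {
      kept[x, y] <- kept[y, x] <- FALSE
    }
  }
  kept
}

# random correlation matrix from a random data matrix
random_corr <- function(g, n = 20, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * g), n, g)
  X <- X + rnorm(n)  # shared component so some structure exists
  colnames(X) <- paste0("g", seq_len(g))
  stats::cor(X)
}
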