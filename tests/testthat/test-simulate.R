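# Population generator: Mendelian consistency, meiosis model, planted
# parameters, phase truth and the qPCR technical layer.

test_that("per-breed allele frequencies follow the configured Beta law", {
  cfg <- sim_config(profile = "desk",
                    snps_per_chromosome = setNames(rep(667L, 3),
                                                   as.character(1:3)),
                    breed_beta = list(IB = c(2, 5), LD = c(1, 1),
                                      DU = c(1, 1), PI = c(1, 1)),
                    seed = 4)
  set.seed(cfg$seed)
  found <- simulate_founders(cfg)
  ks <- stats::ks.test(found$freq[seq_len(2000), "IB"], stats::pbeta,
                       2, 5)
  expect_gt(ks$p.value, 0.01)
  ks2 <- stats::ks.test(found$freq[seq_len(2000), "LD"], stats::punif)
  expect_gt(ks2$p.value, 0.01)
})

test_that("fixed opposite founder frequencies force heterozygous F1", {
  cfg <- tiny_cfg(seed = 8)
  cfg$effects[[1]]$freq <- list(sire = 1.0, dam = 0.0)
  pop <- simulate_population(cfg)
  snp <- Filter(function(e) e$mode == "additive_cis", pop$effects)[[1]]$snp_id
  ped <- as.data.frame(pop$pedigree)
  f1 <- ped$id[!is.na(ped$sire) & grepl("_F1_", ped$id)]
  expect_true(all(pop$genotypes[f1, snp] == 1L))
})

test_that("meiosis respects chromosome length and homozygous parents", {
  map <- snp_map(paste0("s", 1:50), rep("1", 50), seq(1e6, 50e6, length.out = 50))
  haps <- rbind(rep(1L, 50), rep(0L, 50))
  # effectively zero-length chromosome: no crossover possible
  set.seed(1)
  g <- simulate_meiosis(haps, map, c("1" = 1))
  expect_true(all(g$alleles == haps[g$origin[1], ]))
  expect_equal(length(unique(g$origin)), 1L)

  # homozygous parent: gamete identical whatever the crossovers
  hom <- rbind(rep(1L, 50), rep(1L, 50))
  g2 <- simulate_meiosis(hom, map, c("1" = 100e6))
  expect_true(all(g2$alleles == 1L))
})

test_that("crossover count on a 1-Morgan chromosome is Poisson(1)", {
  map <- snp_map(paste0("s", 1:400), rep("1", 400),
                 sort(sample.int(100e6, 400)))
  haps <- rbind(rep(1L, 400), rep(0L, 400))
  set.seed(42)
  switches <- replicate(2000, {
    g <- simulate_meiosis(haps, map, c("1" = 100e6))  # 1 Morgan at 1 cM/Mb
    sum(diff(g$origin) != 0)
  })
  # observed switches slightly undercount crossovers (double events
  # between adjacent markers cancel); 3 SE band around 1
  expect_lt(abs(mean(switches) - 1), 3 * sqrt(1 / 2000) + 0.02)
})

test_that("offspring genotypes are Mendelian-consistent and phase matches", {
  cfg <- tiny_cfg(seed = 11)
  pop <- simulate_population(cfg)
  ped <- as.data.frame(pop$pedigree)
  rownames(ped) <- ped$id
  off <- ped$id[ped$phenotyped]
  G <- pop$genotypes
  s <- G[ped[off, "sire"], , drop = FALSE]
  d <- G[ped[off, "dam"], , drop = FALSE]
  o <- G[off, , drop = FALSE]
  # a parent homozygous for one allele forces at least one copy
  expect_false(any(o == 0L & (s == 2L | d == 2L)))
  expect_false(any(o == 2L & (s == 0L | d == 0L)))
  # dosage equals paternal + maternal haplotype everywhere
  expect_identical(unname(o),
                   unname(pop$phase$pat[off, ] + pop$phase$mat[off, ]))
  # stored paternal haplotype is a gamete of the recorded sire
  sh <- pop$phase$pat[off, ]
  expect_false(any(sh == 1L & s == 0L))
  expect_false(any(sh == 0L & s == 2L))
})

test_that("BC1 sire-breed genome fraction averages 25%", {
  # default desk scale: 180 animals over three chromosomes
  pop <- simulate_population(sim_config(profile = "desk", seed = 21))
  expect_lt(abs(mean(sire_breed_fraction(pop)) - 0.25), 0.02)
})

test_that("with no planted effects log-abundance variance equals residual_sd^2", {
  cfg <- tiny_cfg(seed = 31)
  cfg$effects <- list()
  cfg$blocks <- list()
  cfg$polygenic_h2 <- 0
  cfg$sex_effect_sd <- 0
  cfg$backcross_effect_sd <- 0
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  v <- apply(log(ex$abundance[, grep("^G", colnames(ex$abundance))]), 2, var)
  expect_equal(unname(v), rep(cfg$residual_sd^2, length(v)), tolerance = 1e-8)
})

test_that("planted additive PVE is realized exactly on the adjusted scale", {
  cfg <- tiny_cfg(seed = 41)
  cfg$effects[[1]]$pve <- 0.5
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  ids <- rownames(ex$abundance)
  W <- scan_covariates(pop$pedigree, ids)
  x <- rowMeans(pop$genotypes[ids, pop$effects[[1]]$cluster, drop = FALSE])
  pve <- variance_explained(log(ex$abundance[, "G01"]), W, x)
  expect_equal(pve, 0.5, tolerance = 1e-9)
})

test_that("imprinted effect orders groups by paternal allele", {
  cfg <- tiny_cfg(seed = 51)
  cfg$effects <- list(list(gene = "G01", mode = "imprinted_paternal",
                           pve = 0.7, snp = "imp",
                           freq = list(sire = 0.9, dam = 0.1)))
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  ids <- rownames(ex$abundance)
  snp <- pop$effects[[1]]$snp_id
  patA <- pop$phase$pat[ids, snp] == 1L
  la <- log(ex$abundance[ids, "G01"])
  expect_gt(mean(la[patA]), mean(la[!patA]) + 0.5)
  # maternal allele carries no effect beyond sampling noise
  mat <- pop$phase$mat[ids, snp] == 1L
  expect_lt(abs(mean(la[patA & mat]) - mean(la[patA & !mat])), 0.5)
})

test_that("qPCR layer encodes quantities on the standard curve exactly", {
  cfg <- tiny_cfg(seed = 61)
  cfg$qpcr$efficiency_range <- c(1, 1)  # force perfect doubling
  ab <- matrix(c(1, 2, 4, 1, 1, 1), 3, 2,
               dimnames = list(paste0("s", 1:3), c("G01", "REFA")))
  qp <- simulate_qpcr(ab, cfg, noise = FALSE)
  g1 <- qp$cq[qp$cq$assay == "G01" & !qp$cq$is_standard &
              qp$cq$replicate == 1, ]
  # E = 1: doubling the quantity lowers Cq by exactly 1
  expect_equal(diff(g1$Cq), c(-1, -1), tolerance = 1e-12)
  # a quantity equal to a standard point gives that standard's Cq
  std <- qp$cq[qp$cq$assay == "G01" & qp$cq$is_standard, ]
  expect_equal(g1$Cq[1], std$Cq[std$standard_quantity == 1],
               tolerance = 1e-12)
})

test_that("quantification round-trip recovers abundance (noise off)", {
  cfg <- tiny_cfg(seed = 71)
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  qp <- simulate_qpcr(ex$abundance, cfg, noise = FALSE)
  a <- "G01"
  std <- qp$cq[qp$cq$assay == a & qp$cq$is_standard, ]
  curve <- fit_standard_curve(std$Cq, std$standard_quantity, assay = a)
  unk <- qp$cq[qp$cq$assay == a & !qp$cq$is_standard &
               qp$cq$replicate == 1, ]
  q <- quantify(unk$Cq, curve)
  expect_equal(q, unname(ex$abundance[unk$sample, a]), tolerance = 0.02)
})

test_that("truth file serializes and can embed phase", {
  cfg <- tiny_cfg(seed = 81)
  st <- simulate_study(cfg, qpcr_noise = FALSE)
  path <- file.path(withr::local_tempdir(), "truth.json")
  write_truth(st$truth, path, phase = lapply(st$population$phase,
                                             function(m) m[1:3, 1:5]))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$effects$snp_id, st$truth$effects$snp_id)
  expect_equal(obj$seed, cfg$seed)
  expect_equal(dim(obj$phase$pat$alleles), c(3L, 5L))
})
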