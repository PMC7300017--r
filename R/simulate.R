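# Simulator for pedigreed three-backcross populations with planted eQTL
# architecture, parent-of-origin effects and raw qPCR output.
#
# The emulated design: purebred sires crossed to three maternal breeds
# give F1 males; each backcross generation (BC1) is F1 male x purebred
# dam, so BC1 animals carry 25% of the sire-breed genome on average and
# the paternal haplotype is an F1 gamete (which makes paternal-origin
# deduction from trio genotypes informative).  Meiosis follows a uniform
# 1 cM/Mb map with Haldane (no-interference) crossovers.

#' Simulation configuration
#'
#' @param profile `"desk"` (3 x 60 individuals, 3 chromosomes x 500 SNPs,
#'   12 target genes; fast enough for repeated testing) or `"full"`
#'   (114/122/119 individuals, 18 autosomes, 38,426 SNPs, 45 target
#'   genes; the scale of the emulated study).
#' @param ... Named overrides for any configuration field (see Details).
#'
#' @details Fields and defaults:
#' * `n_per_backcross`: named BC1 cohort sizes.
#' * `chromosome_lengths_bp`, `snps_per_chromosome`: genome layout.
#' * `breed_beta`: per-breed `c(shape1, shape2)` of the Beta distribution
#'   allele frequencies are drawn from (default uniform, Beta(1,1), which
#'   leaves some SNPs nearly fixed in single breeds so planted effects can
#'   segregate in only a subset of backcrosses).
#' * `n_sires`: purebred sires; `n_f1_per_backcross`: F1 males per cohort.
#' * `n_target_genes`; reference assays are fixed at two stable
#'   candidates (`REFA`, `REFB`) plus one unstable pseudo-reference
#'   (`REFU`).
#' * `effects`: list of planted effects, each
#'   `list(gene=, mode=, pve=, snp=, freq=)` with mode one of
#'   `additive_cis`, `additive_trans`, `imprinted_paternal`; effects
#'   sharing a `snp` tag share one causal locus; `n_snps` widens the
#'   locus to a cluster of adjacent markers; `scope = "focal"` makes an
#'   additive effect act through the cluster-middle SNP alone (a
#'   directly genotyped causal variant) instead of the cluster-mean
#'   dosage; `freq` optionally pins per-breed allele frequencies across
#'   the cluster (`sire` / `dam` apply to the sire breed / all dam
#'   breeds).
#' * `blocks`: co-expressed gene blocks driven by a shared latent factor,
#'   each `list(genes=, pve=)`.
#' * `sex_effect_sd`, `backcross_effect_sd`: SD of per-gene mean shifts on
#'   the natural-log abundance scale.
#' * `residual_sd`, `polygenic_h2`: residual SD (log scale) and polygenic
#'   fraction of variance per gene.
#' * `qpcr`: technical layer (noise SD in Cq units, replicate count,
#'   dilution series geometry, efficiency and intercept ranges, sample
#'   loading SD, reference-gene SDs).
#' * `seed`: single seed from which all randomness flows.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(
      n_per_backcross = c(BC1_LD = 60, BC1_DU = 60, BC1_PI = 60),
      chromosome_lengths_bp = setNames(rep(150e6, 3), as.character(1:3)),
      snps_per_chromosome = setNames(rep(500L, 3), as.character(1:3)),
      n_target_genes = 12L)
  } else {
    len <- c(274, 151, 132, 130, 104, 170, 121, 138, 139,
             69, 79, 61, 208, 141, 140, 79, 63, 55) * 1e6
    names(len) <- as.character(1:18)
    nsnp <- round(38426 * len / sum(len))
    nsnp[1] <- nsnp[1] + (38426 - sum(nsnp))
    list(
      n_per_backcross = c(BC1_LD = 114, BC1_DU = 122, BC1_PI = 119),
      chromosome_lengths_bp = len,
      snps_per_chromosome = setNames(as.integer(nsnp), names(len)),
      n_target_genes = 45L)
  }
  cfg <- c(base, list(
    sire_breed = "IB",
    dam_breeds = c(BC1_LD = "LD", BC1_DU = "DU", BC1_PI = "PI"),
    breed_beta = list(IB = c(1, 1), LD = c(1, 1), DU = c(1, 1),
                      PI = c(1, 1)),
    n_sires = 3L,
    n_f1_per_backcross = 4L,
    effects = list(
      list(gene = "G01", mode = "imprinted_paternal", pve = 0.70,
           snp = "cis_imp", n_snps = 3L, freq = list(sire = 0.9, dam = 0.1)),
      # promoter variant genotyped directly: the effect acts through the
      # focal SNP; the divergent window supplies linked flanking markers
      list(gene = "G02", mode = "additive_cis", pve = 0.40,
           snp = "cis_prom", n_snps = 3L, scope = "focal",
           freq = list(sire = 0.9, dam = 0.1)),
      list(gene = "G03", mode = "additive_trans", pve = 0.30, snp = "hub",
           n_snps = 2L, freq = list(sire = 0.8, dam = 0.2)),
      list(gene = "G04", mode = "additive_trans", pve = 0.30, snp = "hub"),
      list(gene = "G05", mode = "additive_trans", pve = 0.30, snp = "hub"),
      list(gene = "G06", mode = "additive_trans", pve = 0.30, snp = "hub"),
      list(gene = "G07", mode = "additive_trans", pve = 0.25,
           snp = "private", n_snps = 2L,
           freq = list(sire = 0.5, LD = 0.5, DU = 0.0, PI = 0.0))),
    # within-block correlation ~ block pve; 0.7 emulates lipogenic gene
    # clusters whose pairwise correlations survive an |r| >= 0.6 filter
    blocks = list(list(genes = c("G08", "G09", "G10", "G11"), pve = 0.7)),
    sex_effect_sd = 0.15,
    backcross_effect_sd = 0.15,
    residual_sd = 0.3,
    polygenic_h2 = 0.10,
    qpcr = list(noise_sd = 0.15, n_replicates = 2L, dilution_points = 5L,
                dilution_factor = 4, efficiency_range = c(0.9, 1.05),
                intercept_range = c(22, 28), loading_sd = 0.3,
                ref_stable_sd = 0.05, ref_unstable_sd = 0.5),
    seed = 1L))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(all(cfg$n_per_backcross > 0),
            all(cfg$chromosome_lengths_bp > 0),
            all(cfg$snps_per_chromosome > 0),
            cfg$polygenic_h2 >= 0, cfg$polygenic_h2 < 1,
            cfg$residual_sd > 0)
  for (e in cfg$effects) {
    if (!e$mode %in% c("additive_cis", "additive_trans",
                       "imprinted_paternal")) {
      stop("unknown effect mode: ", e$mode)
    }
    if (e$pve <= 0 || e$pve >= 1) stop("effect pve must lie in (0,1)")
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Genome and founder layer

build_snp_map <- function(cfg) {
  chrs <- names(cfg$chromosome_lengths_bp)
  pos <- unlist(lapply(chrs, function(ch) {
    sort(sample.int(cfg$chromosome_lengths_bp[[ch]],
                    cfg$snps_per_chromosome[[ch]])) }))
  chr <- rep(chrs, cfg$snps_per_chromosome[chrs])
  snp_map(snp_id = sprintf("SNP%05d", seq_along(pos)), chr = chr, pos = pos)
}

#' Draw per-breed allele frequencies and founder haplotypes
#'
#' Frequencies are drawn per SNP and breed from the configured Beta
#' distributions, so breeds differ and some SNPs segregate in only a
#' subset of backcrosses.
#'
#' @param cfg A [sim_config()].
#' @param map A [snp_map()] (defaults to a fresh layout from `cfg`).
#' @return A list with `freq` (SNP x breed matrix) and `map`.
#' @export
simulate_founders <- function(cfg, map = build_snp_map(cfg)) {
  breeds <- unique(c(cfg$sire_breed, unname(cfg$dam_breeds)))
  freq <- sapply(breeds, function(b) {
    sh <- cfg$breed_beta[[b]]
    if (is.null(sh)) sh <- c(1, 1)
    rbeta(nrow(map), sh[1], sh[2])
  })
  rownames(freq) <- map$snp_id
  list(freq = freq, map = map)
}

founder_haplotypes <- function(freq_breed) {
  p <- length(freq_breed)
  matrix(rbinom(2L * p, 1L, rep(freq_breed, each = 2L)), nrow = 2L)
}

#' Simulate one meiosis (Haldane model, 1 cM/Mb)
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' chromosome length in Morgans; crossover positions are uniform
#' (no interference).  Origin labels record which parental haplotype
#' each transmitted allele came from.
#'
#' @param haps 2 x p integer matrix of the parent's haplotypes
#'   (row 1 = the parent's paternal haplotype).
#' @param map A [snp_map()] for the p loci.
#' @param lengths_bp Named chromosome lengths in bp.
#' @return List with `alleles` (length-p integer vector) and `origin`
#'   (1 = from row 1, 2 = from row 2).
#' @export
simulate_meiosis <- function(haps, map, lengths_bp) {
  p <- ncol(haps)
  origin <- integer(p)
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    len_m <- lengths_bp[[ch]] / 1e8  # 1 cM/Mb -> Morgans
    n_xo <- rpois(1L, len_m)
    start <- sample(1:2, 1L)
    if (n_xo == 0L) {
      origin[idx] <- start
    } else {
      xo <- sort(runif(n_xo, 1, lengths_bp[[ch]]))
      origin[idx] <- 1L + (start - 1L + findInterval(map$pos[idx], xo)) %% 2L
    }
  }
  list(alleles = haps[cbind(origin, seq_len(p))], origin = origin)
}

# ---------------------------------------------------------------------------
# Gene placement and effect resolution

place_genes <- function(cfg, map) {
  n <- cfg$n_target_genes
  genes <- c(sprintf("G%02d", seq_len(n)), "REFA", "REFB", "REFU")
  chrs <- names(cfg$chromosome_lengths_bp)
  chr <- sample(chrs, length(genes), replace = TRUE,
                prob = cfg$chromosome_lengths_bp / sum(cfg$chromosome_lengths_bp))
  width <- 2e4
  start <- vapply(chr, function(ch) {
    round(runif(1, 1, cfg$chromosome_lengths_bp[[ch]] - width))
  }, numeric(1))
  gene_positions(genes, chr, start, start + width)
}

# Assign causal SNPs to effect tags.  Each tag maps to a cluster of
# `n_snps` adjacent SNPs (a regulatory haplotype tagged by neighbouring
# markers; default 1); the reported causal SNP is the cluster middle.
# Cis genes are relocated next to their SNP so the planted invariant
# (causal SNP within 1 Mb of the gene) holds.
resolve_effects <- function(cfg, map, genes) {
  effects <- cfg$effects
  tags <- unique(vapply(effects, function(e) e$snp, character(1)))
  used <- character(0)
  snp_of_tag <- setNames(character(length(tags)), tags)
  cluster_of_tag <- setNames(vector("list", length(tags)), tags)
  for (tag in tags) {
    members <- Filter(function(e) e$snp == tag, effects)
    n_clu <- max(1L, unlist(lapply(members, function(e) e$n_snps)))
    cis <- any(vapply(members, function(e)
      e$mode %in% c("additive_cis", "imprinted_paternal"), logical(1)))
    cand <- setdiff(map$snp_id, used)
    if (cis) {
      j <- pick_cluster_start(map, cand, n_clu)
      g <- match(members[[1]]$gene, genes$gene)
      mid <- j + (n_clu - 1L) %/% 2L
      off <- round(runif(1, -5e5, 4.8e5))
      width <- genes$end[g] - genes$start[g]
      genes$start[g] <- max(1, map$pos[mid] + off)
      genes$end[g] <- genes$start[g] + width
      genes$chr[g] <- map$chr[mid]
    } else {
      j <- pick_cluster_start(map, cand, n_clu)
      # trans targets must not sit on the causal SNP's chromosome (keeps
      # the planted relation trans even with long-range backcross LD)
      chrs <- names(cfg$chromosome_lengths_bp)
      for (gname in vapply(members, `[[`, "", "gene")) {
        g <- match(gname, genes$gene)
        if (genes$chr[g] == map$chr[j]) {
          newchr <- sample(setdiff(chrs, map$chr[j]), 1)
          width <- genes$end[g] - genes$start[g]
          genes$chr[g] <- newchr
          genes$start[g] <- round(runif(1, 1,
            cfg$chromosome_lengths_bp[[newchr]] - width))
          genes$end[g] <- genes$start[g] + width
        }
      }
    }
    cluster <- map$snp_id[j:(j + n_clu - 1L)]
    snp_of_tag[tag] <- cluster[1L + (n_clu - 1L) %/% 2L]
    cluster_of_tag[[tag]] <- cluster
    used <- c(used, cluster)
  }
  effects <- lapply(effects, function(e) {
    e$snp_id <- unname(snp_of_tag[e$snp])
    e$cluster <- cluster_of_tag[[e$snp]]
    e
  })
  list(effects = effects, genes = genes)
}

# Start index of a run of n adjacent same-chromosome unused SNPs.
pick_cluster_start <- function(map, cand, n) {
  idx <- sort(match(cand, map$snp_id))
  ok <- idx[vapply(idx, function(i) {
    run <- i:(i + n - 1L)
    max(run) <= nrow(map) && all(map$snp_id[run] %in% cand) &&
      length(unique(map$chr[run])) == 1L
  }, logical(1))]
  if (!length(ok)) stop("no room left to place a planted SNP cluster")
  sample(ok, 1)
}

apply_freq_overrides <- function(freq, cfg, effects, map) {
  for (e in effects) {
    if (is.null(e$freq)) next
    j <- match(e$cluster, map$snp_id)
    for (b in colnames(freq)) {
      val <- e$freq[[b]]
      if (is.null(val) && b == cfg$sire_breed) val <- e$freq[["sire"]]
      if (is.null(val) && b %in% cfg$dam_breeds) val <- e$freq[["dam"]]
      if (!is.null(val)) freq[j, b] <- val
    }
  }
  freq
}

# ---------------------------------------------------------------------------
# Population assembly

#' Simulate a pedigreed multi-backcross population
#'
#' Builds founders, F1 males and BC1 cohorts with full phase tracking.
#' All randomness flows from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_population`: list with `map`, `genes`,
#'   `pedigree`, `genotypes` (dosage matrix over all animals, counted
#'   allele = allele "1"), `phase` (`pat`/`mat` haplotype matrices for
#'   BC1 animals), `pat_grand_origin` (1 = sire-breed grandparental
#'   chromosome of the paternal F1 gamete), `effects` (resolved planted
#'   effects), `freq` (per-breed allele frequencies) and `config`.
#' @export
simulate_population <- function(cfg) {
  set.seed(cfg$seed)
  found <- simulate_founders(cfg)
  map <- found$map
  placed <- resolve_effects(cfg, map, place_genes(cfg, map))
  freq <- apply_freq_overrides(found$freq, cfg, placed$effects, map)
  p <- nrow(map)
  lens <- cfg$chromosome_lengths_bp

  hap <- list()   # per-individual 2 x p haplotypes (row1 pat, row2 mat)
  ped_rows <- list()
  add_ind <- function(id, sire, dam, sex, backcross, phenotyped, haps) {
    hap[[id]] <<- haps
    ped_rows[[id]] <<- data.frame(id = id, sire = sire, dam = dam,
                                  sex = sex, backcross = backcross,
                                  phenotyped = phenotyped,
                                  stringsAsFactors = FALSE)
  }

  sires <- sprintf("%s_SIRE_%02d", cfg$sire_breed, seq_len(cfg$n_sires))
  for (s in sires) {
    add_ind(s, NA, NA, "M", NA, FALSE,
            founder_haplotypes(freq[, cfg$sire_breed]))
  }

  bc_names <- names(cfg$n_per_backcross)
  phase_pat <- NULL; phase_mat <- NULL; grand <- NULL
  bc_ids <- character(0)
  for (bc in bc_names) {
    dbreed <- cfg$dam_breeds[[bc]]
    f1 <- sprintf("%s_F1_%02d", bc, seq_len(cfg$n_f1_per_backcross))
    for (k in seq_along(f1)) {
      fdam <- sprintf("%s_F1DAM_%02d", bc, k)
      add_ind(fdam, NA, NA, "F", NA, FALSE, founder_haplotypes(freq[, dbreed]))
      boar <- sample(sires, 1)
      gp <- simulate_meiosis(hap[[boar]], map, lens)
      gm <- simulate_meiosis(hap[[fdam]], map, lens)
      add_ind(f1[k], boar, fdam, "M", NA, FALSE, rbind(gp$alleles, gm$alleles))
    }
    for (i in seq_len(cfg$n_per_backcross[[bc]])) {
      id <- sprintf("%s_%03d", bc, i)
      dam <- sprintf("%s_DAM_%03d", bc, i)
      add_ind(dam, NA, NA, "F", NA, FALSE, founder_haplotypes(freq[, dbreed]))
      sire <- sample(f1, 1)
      gp <- simulate_meiosis(hap[[sire]], map, lens)
      gm <- simulate_meiosis(hap[[dam]], map, lens)
      add_ind(id, sire, dam, sample(c("M", "F"), 1), bc, TRUE,
              rbind(gp$alleles, gm$alleles))
      phase_pat <- rbind(phase_pat, gp$alleles)
      phase_mat <- rbind(phase_mat, gm$alleles)
      grand <- rbind(grand, gp$origin)   # 1 = F1's paternal = sire breed
      bc_ids <- c(bc_ids, id)
    }
  }

  ped_df <- do.call(rbind, ped_rows)
  ped <- pedigree_table(ped_df$id, ped_df$sire, ped_df$dam, ped_df$sex,
                        ped_df$backcross, ped_df$phenotyped)
  geno <- t(vapply(hap, colSums, numeric(p)))
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(names(hap), map$snp_id)
  dimnames(phase_pat) <- list(bc_ids, map$snp_id)
  dimnames(phase_mat) <- list(bc_ids, map$snp_id)
  dimnames(grand) <- list(bc_ids, map$snp_id)

  structure(list(map = map, genes = placed$genes, pedigree = ped,
                 genotypes = geno,
                 phase = list(pat = phase_pat, mat = phase_mat),
                 pat_grand_origin = grand,
                 effects = placed$effects, freq = freq, config = cfg),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("simulated population: %d animals (%d phenotyped), %d SNPs, %d genes\n",
              nrow(x$genotypes), sum(x$pedigree$phenotyped), nrow(x$map),
              nrow(x$genes)))
  invisible(x)
}

#' Sire-breed genome fraction of each BC1 animal
#'
#' By construction of the two-generation cross the expectation is 25%
#' (the paternal F1 gamete is half sire-breed, the maternal gamete none).
#'
#' @param pop A `sim_population`.
#' @return Named numeric vector of genome fractions.
#' @export
sire_breed_fraction <- function(pop) {
  rowMeans(pop$pat_grand_origin == 1L) / 2
}

# ---------------------------------------------------------------------------
# Expression layer

#' Simulate true transcript abundances with planted effects
#'
#' Log-abundance is the sum of a gene-specific mean, sex and backcross
#' shifts, planted additive and paternal-imprinted SNP effects (betas
#' solved from the requested variance fractions given realized genotype
#' variances), block latent factors, a genotype-driven polygenic term and
#' Gaussian residual; abundance is its exponential.
#'
#' @param pop A [simulate_population()] result.
#' @param cfg The same [sim_config()] (defaults to `pop$config`).
#' @return List with `abundance` (BC1 individuals x assays, including the
#'   reference assays) and `truth` (planted-effect ground truth).
#' @export
simulate_expression <- function(pop, cfg = pop$config) {
  ids <- pop$pedigree$id[pop$pedigree$phenotyped]
  n <- length(ids)
  ped <- as.data.frame(pop$pedigree)
  rownames(ped) <- ped$id
  sex <- ped[ids, "sex"]
  bc <- ped[ids, "backcross"]
  targets <- grep("^G", pop$genes$gene, value = TRUE)

  pve_of <- setNames(rep(0, length(targets)), targets)
  block_of <- pve_of
  for (e in pop$effects) pve_of[e$gene] <- pve_of[e$gene] + e$pve
  for (b in cfg$blocks) block_of[b$genes] <- block_of[b$genes] + b$pve
  frac <- pve_of + block_of + cfg$polygenic_h2
  if (any(frac >= 1)) {
    stop("planted variance fractions sum to >= 1 for gene(s): ",
         paste(targets[frac >= 1], collapse = ", "))
  }
  sigma2P <- cfg$residual_sd^2 / (1 - frac)

  mu <- setNames(runif(length(targets), log(0.5), log(5)), targets)
  sex_eff <- setNames(rnorm(length(targets), 0, cfg$sex_effect_sd), targets)
  bc_names <- names(cfg$n_per_backcross)
  bc_eff <- matrix(rnorm(length(targets) * length(bc_names), 0,
                         cfg$backcross_effect_sd),
                   nrow = length(targets),
                   dimnames = list(targets, bc_names))
  bc_eff[, 1] <- 0

  eta <- matrix(rep(mu, each = n), n, length(targets),
                dimnames = list(ids, targets))
  eta <- eta + outer(sex == "F", sex_eff)
  eta <- eta + t(bc_eff[, bc, drop = FALSE])

  # PVE is defined on the covariate-adjusted scale (the scale on which
  # single-SNP variance explained is reported), so betas are solved
  # against the covariate-residualized predictor variance.
  Wd <- if (length(unique(bc)) > 1) {
    stats::model.matrix(~ factor(sex) + factor(bc))
  } else {
    stats::model.matrix(~ factor(sex))
  }
  truth_effects <- list()
  planted_x <- setNames(vector("list", length(targets)), targets)
  for (e in pop$effects) {
    s2 <- sigma2P[[e$gene]]
    if (e$mode == "imprinted_paternal") {
      x <- as.numeric(pop$phase$pat[ids, e$snp_id] == 1L)
    } else if (identical(e$scope, "focal")) {
      # a directly genotyped causal variant
      x <- pop$genotypes[ids, e$snp_id]
    } else {
      # default: the effect acts through the cluster-mean dosage (an
      # untyped regulator tagged equally by the cluster markers)
      x <- rowMeans(pop$genotypes[ids, e$cluster, drop = FALSE])
    }
    v <- var(qr.resid(qr(Wd), x))
    if (v == 0) {
      stop(sprintf("planted SNP %s is monomorphic among phenotyped animals",
                   e$snp_id))
    }
    beta <- sqrt(e$pve * s2 / v)
    eta[, e$gene] <- eta[, e$gene] + beta * x
    planted_x[[e$gene]] <- cbind(planted_x[[e$gene]], x)
    truth_effects[[length(truth_effects) + 1]] <-
      data.frame(gene = e$gene, snp_id = e$snp_id, mode = e$mode,
                 pve = e$pve, beta = beta, stringsAsFactors = FALSE)
  }

  # Non-SNP variance components are constructed with exact sample
  # moments: each is orthogonalized against the gene's planted
  # predictors (and against each other) and scaled to its exact target
  # SD, so the requested PVE of every planted effect is realized exactly
  # in-sample and recovery error reflects the estimator alone.
  comp <- setNames(vector("list", length(targets)), targets)

  block_f <- list()
  for (bi in seq_along(cfg$blocks)) {
    b <- cfg$blocks[[bi]]
    f <- rnorm(n)
    xs <- do.call(cbind, c(list(Wd), planted_x[b$genes]))
    f <- qr.resid(qr(xs), f)
    f <- f / sd(f)
    block_f[[bi]] <- f
    for (g in b$genes) {
      eta[, g] <- eta[, g] + sqrt(b$pve * sigma2P[[g]]) * f
      comp[[g]] <- cbind(comp[[g]], f)
    }
  }

  u <- NULL
  if (cfg$polygenic_h2 > 0) {
    Z <- scale(pop$genotypes[ids, , drop = FALSE], center = TRUE,
               scale = FALSE)
    a <- matrix(rnorm(ncol(Z) * length(targets)), ncol = length(targets))
    u <- Z %*% a
    for (gi in seq_along(targets)) {
      g <- targets[gi]
      base <- cbind(Wd, planted_x[[g]], comp[[g]])
      u[, gi] <- qr.resid(qr(base), u[, gi])
      u[, gi] <- u[, gi] / sd(u[, gi]) * sqrt(cfg$polygenic_h2 * sigma2P[[g]])
      comp[[g]] <- cbind(comp[[g]], u[, gi])
    }
    eta <- eta + u
  }

  for (gi in seq_along(targets)) {
    g <- targets[gi]
    e0 <- rnorm(n)
    base <- cbind(Wd, planted_x[[g]], comp[[g]])
    e0 <- qr.resid(qr(base), e0)
    eta[, g] <- eta[, g] + e0 / sd(e0) * cfg$residual_sd
  }

  # reference assays: two stable, one deliberately unstable (HPRT1-like)
  refs <- cbind(
    REFA = exp(rnorm(n, log(2), cfg$qpcr$ref_stable_sd)),
    REFB = exp(rnorm(n, log(1), cfg$qpcr$ref_stable_sd)),
    REFU = exp(rnorm(n, log(1.5), cfg$qpcr$ref_unstable_sd)))
  abundance <- cbind(exp(eta), refs)

  truth <- list(
    effects = do.call(rbind, truth_effects),
    blocks = cfg$blocks,
    sigma2P = sigma2P,
    mu = mu, sex_effect = sex_eff, backcross_effect = bc_eff,
    genes = pop$genes,
    reference_assays = c("REFA", "REFB"),
    unstable_reference = "REFU",
    log_scale_generative = TRUE,
    seed = cfg$seed)
  list(abundance = abundance, truth = truth)
}

# ---------------------------------------------------------------------------
# qPCR technical layer

#' Simulate qPCR Cq tables with dilution-series standards
#'
#' Per assay a PCR efficiency E and curve intercept are drawn; measured
#' Cq is `intercept - log(quantity)/log(1+E)` plus Gaussian technical
#' noise.  Each assay gets a dilution series of known relative
#' quantities.  A per-sample loading factor (shared across assays, which
#' is what reference normalization removes) multiplies all quantities.
#'
#' @param abundance Matrix of true abundances (samples x assays), e.g.
#'   from [simulate_expression()].
#' @param cfg A [sim_config()] supplying the `qpcr` block.
#' @param noise If `FALSE`, technical noise and sample loading are
#'   switched off (used by round-trip tests).
#' @return List with `cq` (long table: sample, assay, Cq, replicate,
#'   is_standard, standard_quantity), `curves` (assay, efficiency,
#'   intercept, slope) and `loading`.
#' @export
simulate_qpcr <- function(abundance, cfg, noise = TRUE) {
  q <- cfg$qpcr
  assays <- colnames(abundance)
  samples <- rownames(abundance)
  n <- nrow(abundance)
  eff <- runif(length(assays), q$efficiency_range[1], q$efficiency_range[2])
  stopifnot(all(eff > 0.8), all(eff <= 1.1))
  intercept <- runif(length(assays), q$intercept_range[1],
                     q$intercept_range[2])
  names(eff) <- names(intercept) <- assays
  loading <- if (noise) exp(rnorm(n, 0, q$loading_sd)) else rep(1, n)
  names(loading) <- samples
  noise_sd <- if (noise) q$noise_sd else 0

  std_q <- q$dilution_factor^(-(seq_len(q$dilution_points) - 1))
  out <- vector("list", length(assays))
  for (k in seq_along(assays)) {
    a <- assays[k]
    cq_fun <- function(qty) intercept[k] - log(qty) / log(1 + eff[k])
    unk <- do.call(rbind, lapply(seq_len(q$n_replicates), function(r) {
      data.frame(sample = samples, assay = a,
                 Cq = cq_fun(loading * abundance[, a]) +
                   rnorm(n, 0, noise_sd),
                 replicate = r, is_standard = FALSE,
                 standard_quantity = NA_real_, stringsAsFactors = FALSE)
    }))
    std <- data.frame(sample = sprintf("STD_%d", seq_along(std_q)),
                      assay = a, Cq = cq_fun(std_q),
                      replicate = 1L, is_standard = TRUE,
                      standard_quantity = std_q, stringsAsFactors = FALSE)
    out[[k]] <- rbind(unk, std)
  }
  list(cq = do.call(rbind, out),
       curves = data.frame(assay = assays, efficiency = unname(eff),
                           intercept = unname(intercept),
                           slope = -1 / log10(1 + unname(eff)),
                           stringsAsFactors = FALSE),
       loading = loading)
}

#' Simulate a complete study (population, expression, qPCR)
#'
#' @param cfg A [sim_config()].
#' @param qpcr_noise Passed to [simulate_qpcr()].
#' @return List with `population`, `abundance`, `qpcr`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config(), qpcr_noise = TRUE) {
  pop <- simulate_population(cfg)
  ex <- simulate_expression(pop, cfg)
  qp <- simulate_qpcr(ex$abundance, cfg, noise = qpcr_noise)
  list(population = pop, abundance = ex$abundance, qpcr = qp,
       truth = ex$truth)
}

#' Write the machine-readable truth file
#'
#' @param truth The `truth` element of [simulate_expression()] or
#'   [simulate_study()].
#' @param path Output JSON path.
#' @param phase Optional list of `pat`/`mat` haplotype matrices to embed
#'   (omitted by default; they are large).
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path, phase = NULL) {
  obj <- truth
  obj$genes <- as.data.frame(obj$genes)
  if (!is.null(phase)) {
    obj$phase <- lapply(phase, function(m) {
      list(individuals = rownames(m), snps = colnames(m),
           alleles = unname(as.matrix(m)))
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
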