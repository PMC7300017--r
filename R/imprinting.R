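# Parent-of-origin analysis at a focal biallelic SNP: deduce which
# allele each offspring inherited from its sire using trio genotypes,
# then test a paternal-expression (imprinting) model on the four
# ordered-genotype groups.

#' Deduce parental origin of alleles at a focal SNP
#'
#' Homozygous offspring are trivially resolved.  For heterozygotes the
#' paternal allele is the sire's allele when the sire is homozygous;
#' otherwise the allele the (homozygous) dam cannot have transmitted;
#' double-heterozygous trios remain ambiguous (no grandparental phasing
#' is attempted).  Offspring carrying an allele absent from both typed
#' parents are flagged as Mendelian inconsistencies and excluded from
#' grouping.
#'
#' @param offspring Named dosage vector (0/1/2 copies of the counted
#'   allele) for the focal SNP.
#' @param sire,dam Dosage of each offspring's sire/dam at the same SNP
#'   (`NA` when untyped), aligned with `offspring`.
#' @param alleles Length-2 character vector naming the counted and the
#'   other allele (default `c("A", "G")`).
#' @return Data frame: `individual`, `paternal`, `maternal` (allele
#'   letters or `NA` when unknown), `group` in
#'   `{AA, ApGm, AmGp, GG, ambiguous}` (letters follow `alleles`), and
#'   `mendelian_error`.
#' @export
deduce_parental_origin <- function(offspring, sire, dam,
                                   alleles = c("A", "G")) {
  n <- length(offspring)
  stopifnot(length(sire) == n, length(dam) == n)
  A <- alleles[1]; B <- alleles[2]
  pat <- mat <- rep(NA_character_, n)
  err <- rep(FALSE, n)
  has_a <- function(g) !is.na(g) & g >= 1   # parent can transmit counted allele
  has_b <- function(g) !is.na(g) & g <= 1
  for (i in seq_len(n)) {
    g <- offspring[i]
    if (is.na(g)) next
    s <- sire[i]; d <- dam[i]
    if (g == 2) {
      # both alleles counted; impossible if a typed parent lacks it
      if ((!is.na(s) && s == 0) || (!is.na(d) && d == 0)) { err[i] <- TRUE; next }
      pat[i] <- A; mat[i] <- A
    } else if (g == 0) {
      if ((!is.na(s) && s == 2) || (!is.na(d) && d == 2)) { err[i] <- TRUE; next }
      pat[i] <- B; mat[i] <- B
    } else {
      s_can_a <- has_a(s); s_can_b <- has_b(s)
      d_can_a <- has_a(d); d_can_b <- has_b(d)
      if ((!is.na(s) && !is.na(d)) &&
          !((s_can_a && d_can_b) || (s_can_b && d_can_a))) {
        err[i] <- TRUE; next
      }
      if (!is.na(s) && (s == 0 || s == 2)) {
        pat[i] <- if (s == 2) A else B
        mat[i] <- if (s == 2) B else A
      } else if (!is.na(d) && (d == 0 || d == 2)) {
        mat[i] <- if (d == 2) A else B
        pat[i] <- if (d == 2) B else A
      }
    }
  }
  group <- rep("ambiguous", n)
  known <- !is.na(pat) & !is.na(mat)
  group[known & pat == A & mat == A] <- paste0(A, A)
  group[known & pat == A & mat == B] <- paste0(A, "p", B, "m")
  group[known & pat == B & mat == A] <- paste0(A, "m", B, "p")
  group[known & pat == B & mat == B] <- paste0(B, B)
  group[err] <- "ambiguous"
  data.frame(individual = if (is.null(names(offspring))) as.character(seq_len(n))
                          else names(offspring),
             paternal = pat, maternal = mat, group = group,
             mendelian_error = err, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Compact letter display from a logical "differs" matrix (insert-absorb).
compact_letters <- function(differs) {
  g <- nrow(differs)
  sets <- list(seq_len(g))  # letters as index sets of non-differing groups
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (j <= i || !differs[i, j]) next
    for (k in seq_along(sets)) {
      if (i %in% sets[[k]] && j %in% sets[[k]]) {
        s1 <- setdiff(sets[[k]], j)
        s2 <- setdiff(sets[[k]], i)
        sets[[k]] <- s1
        if (!any(vapply(sets, function(s) all(s2 %in% s), logical(1)))) {
          sets[[length(sets) + 1]] <- s2
        }
      }
    }
    # absorb redundant sets
    keep <- !vapply(seq_along(sets), function(k) {
      any(vapply(seq_along(sets), function(l) {
        l != k && all(sets[[k]] %in% sets[[l]])
      }, logical(1)))
    }, logical(1))
    sets <- sets[keep]
  }
  ord <- order(vapply(sets, min, numeric(1)))
  sets <- sets[ord]
  vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Test a paternal-expression (imprinting) model
#'
#' Fits a one-way linear model on the ordered-genotype groups
#' (ambiguous individuals excluded), tests the primary contrast
#' paternal-A groups (`AA`, `ApGm`) versus paternal-G groups
#' (`AmGp`, `GG`), builds a compact letter display from pairwise Welch
#' tests at `alpha`, and compares the imprinting model against a purely
#' additive dosage model by AIC.
#'
#' @param expr Named expression vector (NQ or log2 NQ).
#' @param origin [deduce_parental_origin()] output for the same
#'   individuals.
#' @param alpha Pairwise significance level for the letter display.
#' @param alleles Allele letters, as in [deduce_parental_origin()].
#' @return List with `summary` (group, n, mean, sem, letter),
#'   `contrast_p` (paternal-A vs paternal-G), `contrast_estimate`,
#'   `model_comparison` (AIC of imprinting vs additive model) and `fit`.
#' @export
imprinting_test <- function(expr, origin, alpha = 0.05,
                            alleles = c("A", "G")) {
  A <- alleles[1]; B <- alleles[2]
  lv <- c(paste0(A, A), paste0(A, "p", B, "m"), paste0(A, "m", B, "p"),
          paste0(B, B))
  ids <- origin$individual[origin$group != "ambiguous"]
  ids <- intersect(ids, names(expr))
  grp <- setNames(origin$group, origin$individual)[ids]
  y <- expr[ids]
  keep <- !is.na(y)
  y <- y[keep]; grp <- factor(grp[keep], levels = lv)
  present <- levels(droplevels(grp))
  patA <- intersect(present, lv[1:2])
  patB <- intersect(present, lv[3:4])
  if (!length(patA) || !length(patB)) {
    stop("both paternal-allele classes must be populated")
  }
  fit <- lm(y ~ 0 + grp)
  means <- coef(fit)[paste0("grp", present)]
  covb <- stats::vcov(fit)[paste0("grp", present), paste0("grp", present)]
  cvec <- (present %in% patA) / length(patA) -
          (present %in% patB) / length(patB)
  est <- sum(cvec * means)
  se <- sqrt(drop(t(cvec) %*% covb %*% cvec))
  tval <- est / se
  dfree <- fit$df.residual
  contrast_p <- 2 * pt(-abs(tval), dfree)

  g <- length(present)
  differs <- matrix(FALSE, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (j <= i) next
    yi <- y[grp == present[i]]; yj <- y[grp == present[j]]
    if (length(yi) >= 2 && length(yj) >= 2 &&
        (sd(yi) > 0 || sd(yj) > 0)) {
      pv <- t.test(yi, yj)$p.value
      differs[i, j] <- differs[j, i] <- pv < alpha
    }
  }
  lets <- compact_letters(differs)

  smry <- data.frame(
    group = present,
    n = as.integer(table(grp)[present]),
    mean = unname(means),
    sem = vapply(present, function(l) {
      v <- y[grp == l]; sd(v) / sqrt(length(v))
    }, numeric(1)),
    letter = lets, row.names = NULL, stringsAsFactors = FALSE)

  dose <- 2 * (grp == lv[1]) + (grp %in% lv[2:3])  # copies of allele A
  pat_ind <- as.numeric(grp %in% lv[1:2])
  aic <- data.frame(
    model = c("imprinting (paternal indicator)", "additive (dosage)"),
    AIC = c(stats::AIC(lm(y ~ pat_ind)), stats::AIC(lm(y ~ dose))),
    stringsAsFactors = FALSE)

  list(summary = smry, contrast_p = contrast_p, contrast_estimate = est,
       model_comparison = aic, fit = fit)
}
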