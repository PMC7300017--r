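# Sex and genetic-background screening of per-gene expression.
#
# The screening model is the additive two-factor linear model
# value ~ sex + backcross (no interaction); each factor's p-value is the
# marginal (type-II) F test of that term.  Group summaries report
# mean +/- SEM per level with significance stars at 0.05/0.01/0.001.

fstars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))))
}

#' F-test of sex or backcross effects on each gene
#'
#' Fits `value ~ sex + backcross` per gene (or `value ~ sex` when only
#' one backcross level is present) and reports the marginal F-test of
#' the requested term.
#'
#' @param em An [expression_matrix()] (analysis scale).
#' @param ped A [pedigree_table()] covering the rows of `em`.
#' @param term `"sex"` or `"backcross"`.
#' @return Data frame `gene`, `df`, `F`, `p_value`, `stars`.
#' @export
effect_test <- function(em, ped, term = c("sex", "backcross")) {
  term <- match.arg(term)
  ped <- as.data.frame(ped)
  rownames(ped) <- ped$id
  ids <- rownames(em)
  if (!all(ids %in% ped$id)) stop("individuals missing from pedigree")
  sex <- factor(ped[ids, "sex"])
  bc <- factor(ped[ids, "backcross"])
  multi_bc <- nlevels(droplevels(bc)) > 1
  if (term == "backcross" && !multi_bc) {
    stop("backcross term requested but only one backcross present")
  }
  out <- lapply(colnames(em), function(g) {
    y <- as.numeric(em[, g])
    dat <- data.frame(y = y, sex = sex, bc = bc)
    dat <- dat[complete.cases(dat), ]
    full <- if (multi_bc) lm(y ~ sex + bc, data = dat)
            else lm(y ~ sex, data = dat)
    X <- stats::model.matrix(full)
    if (qr(X)$rank < ncol(X)) {
      stop(sprintf("rank-deficient design for gene %s (term %s confounded)",
                   g, term))
    }
    red_formula <- if (!multi_bc) y ~ 1
                   else if (term == "sex") y ~ bc else y ~ sex
    reduced <- lm(red_formula, data = dat)
    df1 <- reduced$df.residual - full$df.residual
    df2 <- full$df.residual
    rss_r <- sum(reduced$residuals^2)
    rss_f <- sum(full$residuals^2)
    Fstat <- max(0, (rss_r - rss_f) / df1 / (rss_f / df2))
    data.frame(gene = g, df = df1, F = Fstat,
               p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$stars <- fstars(out$p_value)
  out
}

#' Per-level group summaries with significance stars
#'
#' Arithmetic mean and SEM of each gene within each level of the
#' grouping factor, on the analysis scale, together with the omnibus
#' p-value of the factor from [effect_test()].
#'
#' @param em An [expression_matrix()].
#' @param ped A [pedigree_table()].
#' @param grouping `"sex"` or `"backcross"`.
#' @return Data frame `gene`, `level`, `n`, `mean`, `sem`, `p_value`,
#'   `stars`.
#' @export
group_summary <- function(em, ped, grouping = c("sex", "backcross")) {
  grouping <- match.arg(grouping)
  ped <- as.data.frame(ped)
  rownames(ped) <- ped$id
  fac <- factor(ped[rownames(em), grouping])
  if (any(is.na(fac))) stop("grouping factor has missing levels")
  tests <- effect_test(em, ped, term = grouping)
  rownames(tests) <- tests$gene
  out <- lapply(colnames(em), function(g) {
    y <- as.numeric(em[, g])
    lv <- levels(fac)
    n <- vapply(lv, function(l) sum(!is.na(y[fac == l])), numeric(1))
    if (any(n < 2)) stop(sprintf("gene %s: level with fewer than 2 observations", g))
    m <- vapply(lv, function(l) mean(y[fac == l], na.rm = TRUE), numeric(1))
    s <- vapply(lv, function(l) {
      v <- y[fac == l]; sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    }, numeric(1))
    data.frame(gene = g, level = lv, n = n, mean = m, sem = s,
               p_value = tests[g, "p_value"], stars = tests[g, "stars"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
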