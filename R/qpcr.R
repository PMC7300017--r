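# Relative standard-curve quantification and reference-gene
# normalization of qPCR data.
#
# The quantification chain reconstructs the relative standard curve
# method: a least-squares line of Cq on log10(relative quantity) per
# assay, quantities interpolated from that line, normalized quantities
# (NQ) as the ratio of the target quantity to the geometric mean of the
# selected stable reference genes.  NQ is defined up to a per-gene
# multiplicative constant, which cancels in all downstream inference.

#' Fit a relative standard curve
#'
#' @param cq Numeric vector of standard Cq values.
#' @param quantity Known relative quantities of the standards (same
#'   length, > 0); at least 3 distinct dilution points.
#' @return List of class `standard_curve`: `assay` (optional label),
#'   `slope` (Cq per log10 quantity, negative), `intercept` (Cq at
#'   quantity 1), `efficiency` (`10^(-1/slope) - 1`) and `r2`.
#' @param assay Optional assay label carried in the result.
#' @export
fit_standard_curve <- function(cq, quantity, assay = NA_character_) {
  ok <- is.finite(cq) & is.finite(quantity)
  cq <- cq[ok]; quantity <- quantity[ok]
  if (length(unique(quantity)) < 3) {
    stop("standard curve needs at least 3 dilution points")
  }
  if (any(quantity <= 0)) stop("standard quantities must be positive")
  fit <- lm(cq ~ log10(quantity))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("standard curve slope must be negative (Cq decreases with quantity)")
  }
  r2 <- 1 - sum(fit$residuals^2) / sum((cq - mean(cq))^2)
  structure(list(assay = assay, slope = slope,
                 intercept = unname(coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1, r2 = r2),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve [%s]: slope %.4f, E = %.3f, r2 = %.4f\n",
              x$assay, x$slope, x$efficiency, x$r2))
  invisible(x)
}

#' Interpolate relative quantities from Cq values
#'
#' `quantity = 10^((Cq - intercept)/slope)`; monotone decreasing in Cq.
#'
#' @param cq Numeric vector of Cq values.
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric vector of relative quantities.
#' @export
quantify <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Rank candidate reference genes by expression stability
#'
#' geNorm-style M value: for each candidate, the mean over the other
#' candidates of the sample-wise standard deviation of the pairwise
#' log2 quantity ratio.  Lower M = more stable.
#'
#' @param quantities Samples x candidate-genes matrix of relative
#'   quantities (> 0), at least 2 candidates.
#' @return Data frame (`assay`, `M`) sorted ascending by `M`.
#' @export
reference_stability <- function(quantities) {
  quantities <- as.matrix(quantities)
  if (ncol(quantities) < 2) {
    stop("reference stability needs at least 2 candidate genes")
  }
  if (any(quantities <= 0)) stop("quantities must be positive")
  lq <- log2(quantities)
  k <- ncol(lq)
  M <- vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j),
                function(l) sd(lq[, j] - lq[, l]), numeric(1)))
  }, numeric(1))
  out <- data.frame(assay = colnames(quantities), M = M,
                    stringsAsFactors = FALSE)
  out[order(out$M), , drop = FALSE]
}

#' Normalize target quantities to reference genes (NQ)
#'
#' NQ is the target quantity divided by the geometric mean of the
#' selected reference-gene quantities, per sample.
#'
#' @param target Samples x target-genes quantity matrix.
#' @param reference Samples x reference-genes quantity matrix (> 0).
#' @return An [expression_matrix()] of NQ values (untransformed).
#' @export
normalize_nq <- function(target, reference) {
  target <- as.matrix(target)
  reference <- as.matrix(reference)
  if (any(reference <= 0)) stop("reference quantities must be positive")
  gm <- exp(rowMeans(log(reference)))
  expression_matrix(sweep(target, 1, gm, `/`))
}

#' Shapiro-Wilk-driven per-gene log2 transformation
#'
#' Each gene whose NQ distribution departs from normality
#' (Shapiro-Wilk p < `alpha`) is replaced by `log2(NQ)` and flagged.
#' Constant genes, for which the test is undefined, are flagged
#' degenerate and left untransformed with a warning.
#'
#' @param em An [expression_matrix()] of raw NQ values.
#' @param alpha Significance level for the normality test (default 0.05).
#' @return The transformed [expression_matrix()] with updated `log2`
#'   flags and an attribute `"shapiro_p"` of per-gene p-values.
#' @export
normality_transform <- function(em, alpha = 0.05) {
  flags <- log2_flags(em)
  vals <- unclass(em)
  attr(vals, "log2") <- NULL
  pvals <- setNames(rep(NA_real_, ncol(vals)), colnames(vals))
  for (j in seq_len(ncol(vals))) {
    if (flags[j]) next  # already on log scale
    x <- vals[, j]
    x <- x[!is.na(x)]
    if (length(x) < 3) stop("normality test needs >= 3 observations")
    if (sd(x) == 0) {
      warning(sprintf("gene %s is constant; normality test undefined, left untransformed",
                      colnames(vals)[j]))
      next
    }
    pvals[j] <- shapiro.test(x)$p.value
    if (pvals[j] < alpha) {
      if (any(vals[, j][!is.na(vals[, j])] <= 0)) {
        stop(sprintf("gene %s has non-positive NQ; cannot log2-transform",
                     colnames(vals)[j]))
      }
      vals[, j] <- log2(vals[, j])
      flags[j] <- TRUE
    }
  }
  out <- expression_matrix(vals, log2 = flags)
  attr(out, "shapiro_p") <- pvals
  out
}

#' Run the full qPCR quantification chain on a Cq table
#'
#' Fits a standard curve per assay, interpolates unknown quantities,
#' averages technical replicates on the quantity scale, ranks the
#' candidate reference genes by stability, normalizes targets to the
#' geometric mean of the `n_refs` most stable candidates, and applies
#' the normality-driven log2 transform.
#'
#' @param cq A Cq table as read by [read_cq()] (or from
#'   [simulate_qpcr()]`$cq`).
#' @param reference_candidates Assay names of the candidate reference
#'   genes.
#' @param n_refs Number of most-stable candidates used for NQ
#'   (default 2).
#' @param alpha Passed to [normality_transform()].
#' @return List with `expression` (transformed [expression_matrix()] of
#'   the target genes), `nq` (untransformed NQ), `curves`, `stability`
#'   and `references` (the selected reference assays).
#' @export
qpcr_quantify_study <- function(cq, reference_candidates, n_refs = 2,
                                alpha = 0.05) {
  assays <- unique(cq$assay)
  curves <- lapply(setNames(assays, assays), function(a) {
    std <- cq[cq$assay == a & cq$is_standard, ]
    fit_standard_curve(std$Cq, std$standard_quantity, assay = a)
  })
  unk <- cq[!cq$is_standard, ]
  unk$quantity <- NA_real_
  for (a in assays) {
    sel <- unk$assay == a
    unk$quantity[sel] <- quantify(unk$Cq[sel], curves[[a]])
  }
  agg <- stats::aggregate(quantity ~ sample + assay, data = unk, FUN = mean)
  samples <- unique(agg$sample)
  qmat <- matrix(NA_real_, length(samples), length(assays),
                 dimnames = list(samples, assays))
  qmat[cbind(match(agg$sample, samples), match(agg$assay, assays))] <-
    agg$quantity
  refs_all <- intersect(assays, reference_candidates)
  if (length(refs_all) < 2) stop("need at least 2 candidate reference genes")
  stab <- reference_stability(qmat[, refs_all, drop = FALSE])
  chosen <- stab$assay[seq_len(min(n_refs, nrow(stab)))]
  targets <- setdiff(assays, reference_candidates)
  nq <- normalize_nq(qmat[, targets, drop = FALSE],
                     qmat[, chosen, drop = FALSE])
  list(expression = normality_transform(nq, alpha = alpha), nq = nq,
       curves = curves, stability = stab, references = chosen)
}
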