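# From significant eSNPs to eQTL intervals, cis/trans labels and
# trans-eQTL hotspots.
#
# Merge rule: eSNPs of the same gene on the same chromosome belong to
# one interval while consecutive sorted positions are < 10 Mb apart; a
# gap of exactly 10 Mb splits.  Interval size is end - start (the +1 of
# the inclusive convention is deliberately excluded, matching how such
# interval sizes are conventionally reported).  A SNP is cis when it
# lies within 1 Mb of the nearest edge of its target gene (0 bp inside
# the gene), trans otherwise or on another chromosome.

#' Call significant eSNPs from an association scan
#'
#' @param scan An [scan_gene()] result.
#' @param q_threshold Strict upper bound on the q-value (default 0.05;
#'   0.10 is the customary suggestive tier).
#' @return The rows of `scan` with `q_value < q_threshold`.
#' @export
call_esnps <- function(scan, q_threshold = 0.05) {
  scan[!is.na(scan$q_value) & scan$q_value < q_threshold, , drop = FALSE]
}

#' Merge eSNPs of one gene into eQTL intervals
#'
#' @param esnps Data frame with at least `snp_id`, `chr`, `pos` (and
#'   optionally `wald_p` used to pick the top SNP), all belonging to one
#'   gene.
#' @param gene Gene symbol recorded in the output.
#' @param gap_bp Gap at or above which an interval is split
#'   (default 10 Mb).
#' @return Data frame of intervals: `gene`, `chr`, `start_bp`, `end_bp`,
#'   `size_bp`, `n_snps`, `top_snp`, `top_p`, `snp_ids`
#'   (comma-separated members).
#' @export
merge_intervals <- function(esnps, gene = NA_character_, gap_bp = 1e7) {
  if (nrow(esnps) == 0) {
    return(data.frame(gene = character(0), chr = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      size_bp = numeric(0), n_snps = integer(0),
                      top_snp = character(0), top_p = numeric(0),
                      snp_ids = character(0), stringsAsFactors = FALSE))
  }
  out <- list()
  for (ch in unique(esnps$chr)) {
    sub <- esnps[esnps$chr == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    gaps <- diff(sub$pos)
    grp <- cumsum(c(1, as.integer(gaps >= gap_bp)))
    for (g in unique(grp)) {
      mem <- sub[grp == g, , drop = FALSE]
      top <- if ("wald_p" %in% names(mem)) which.min(mem$wald_p) else 1L
      out[[length(out) + 1]] <- data.frame(
        gene = gene, chr = ch,
        start_bp = min(mem$pos), end_bp = max(mem$pos),
        size_bp = max(mem$pos) - min(mem$pos),
        n_snps = nrow(mem),
        top_snp = mem$snp_id[top],
        top_p = if ("wald_p" %in% names(mem)) mem$wald_p[top] else NA_real_,
        snp_ids = paste(mem$snp_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Interval size from printed bounds
#'
#' The reported interval size convention: `end - start` in bp.
#' @param start_bp,end_bp Interval bounds (1-based, inclusive).
#' @return Numeric sizes.
#' @export
interval_size <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) stop("end must be >= start")
  end_bp - start_bp
}

#' Filter eQTL intervals by member SNP count
#'
#' Joint multi-backcross analyses keep intervals with >= 2 SNPs;
#' single-backcross analyses require >= 3.
#'
#' @param intervals Output of [merge_intervals()].
#' @param mode `"3BCs"` (joint) or `"single"`.
#' @return The retained intervals.
#' @export
filter_intervals <- function(intervals, mode = c("3BCs", "single")) {
  mode <- match.arg(mode)
  min_snps <- if (mode == "3BCs") 2L else 3L
  intervals[intervals$n_snps >= min_snps, , drop = FALSE]
}

#' Classify an eQTL interval as cis, trans or cis/trans
#'
#' Each member SNP is cis when it lies on the target gene's chromosome
#' within `cis_window` bp of the nearest gene edge; the interval label
#' is `cis` when all members are cis, `trans` when none are, `cis/trans`
#' when mixed.
#'
#' @param intervals Output of [merge_intervals()] (one gene).
#' @param map [snp_map()] covering all member SNPs.
#' @param genes [gene_positions()] containing the target gene.
#' @param cis_window Cis distance bound in bp (default 1 Mb).
#' @return `intervals` with added columns `label`, `n_cis`, `n_trans`.
#' @export
classify_cis_trans <- function(intervals, map, genes, cis_window = 1e6) {
  if (nrow(intervals) == 0) {
    intervals$label <- character(0)
    intervals$n_cis <- integer(0)
    intervals$n_trans <- integer(0)
    return(intervals)
  }
  rownames(map) <- map$snp_id
  lab <- character(nrow(intervals))
  ncis <- integer(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    g <- match(intervals$gene[i], genes$gene)
    if (is.na(g)) stop("no position for gene ", intervals$gene[i])
    snps <- strsplit(intervals$snp_ids[i], ",")[[1]]
    d <- bp_distance_to_gene(map[snps, "chr"], map[snps, "pos"],
                             genes$chr[g], genes$start[g], genes$end[g])
    ncis[i] <- sum(d <= cis_window)
    lab[i] <- if (ncis[i] == length(snps)) "cis"
              else if (ncis[i] == 0) "trans" else "cis/trans"
  }
  intervals$label <- lab
  intervals$n_cis <- ncis
  intervals$n_trans <- intervals$n_snps - ncis
  intervals
}

#' Annotation window around an eQTL interval
#'
#' Widens the interval by 1 Mb on each side (floored at position 1) for
#' downstream gene annotation.
#'
#' @param intervals Data frame with `start_bp`, `end_bp`.
#' @param pad_bp Padding per side (default 1 Mb).
#' @return `intervals` with `window_start`, `window_end` columns.
#' @export
annotation_window <- function(intervals, pad_bp = 1e6) {
  intervals$window_start <- pmax(1, intervals$start_bp - pad_bp)
  intervals$window_end <- intervals$end_bp + pad_bp
  intervals
}

#' Detect trans-eQTL hotspots
#'
#' Builds, per chromosome, the overlap graph of trans-labeled intervals
#' from distinct genes (overlap = at least one shared base pair, plus an
#' optional adjacency tolerance); connected components targeting >= 2
#' distinct genes are hotspots, with span equal to the component union.
#'
#' @param intervals Labeled, filtered intervals across genes
#'   ([classify_cis_trans()] output, possibly row-bound over genes).
#' @param labels Interval labels considered trans-acting (default
#'   `"trans"`; add `"cis/trans"` to include mixed intervals).
#' @param tol_bp Adjacency tolerance in bp (default 0: intervals must
#'   share a position).
#' @param min_genes Minimum distinct target genes (default 2).
#' @return Data frame: `chr`, `span_start`, `span_end`, `n_genes`,
#'   `genes` (comma-separated), `n_intervals`.
#' @export
detect_hotspots <- function(intervals, labels = "trans", tol_bp = 0,
                            min_genes = 2L) {
  tr <- intervals[intervals$label %in% labels, , drop = FALSE]
  out <- list()
  for (ch in unique(tr$chr)) {
    sub <- tr[tr$chr == ch, , drop = FALSE]
    sub <- sub[order(sub$start_bp, sub$end_bp), , drop = FALSE]
    if (nrow(sub) == 0) next
    comp <- integer(nrow(sub))
    comp[1] <- 1L
    reach <- sub$end_bp[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start_bp[i] <= reach + tol_bp) {
        comp[i] <- comp[i - 1]
      } else {
        comp[i] <- comp[i - 1] + 1L
      }
      reach <- max(reach, sub$end_bp[i])
    }
    for (cc in unique(comp)) {
      mem <- sub[comp == cc, , drop = FALSE]
      genes <- unique(mem$gene)
      if (length(genes) < min_genes) next
      out[[length(out) + 1]] <- data.frame(
        chr = ch, span_start = min(mem$start_bp),
        span_end = max(mem$end_bp), n_genes = length(genes),
        genes = paste(sort(genes), collapse = ","),
        n_intervals = nrow(mem), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chr = character(0), span_start = numeric(0),
                      span_end = numeric(0), n_genes = integer(0),
                      genes = character(0), n_intervals = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
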