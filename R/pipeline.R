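# End-to-end eQTL study driver: QC, kinship, per-gene scans, interval
# construction, cis/trans classification and hotspot detection, plus
# the tabular exports (scan TSV, Manhattan data, interval table,
# karyotype-plot data).

#' Covariate design for the association scans
#'
#' Intercept + sex, plus backcross dummies when more than one backcross
#' is present (joint mode); sex only in single-backcross mode.
#'
#' @param ped A [pedigree_table()].
#' @param ids Individuals, in scan order.
#' @return Design matrix.
#' @export
scan_covariates <- function(ped, ids) {
  ped <- as.data.frame(ped)
  rownames(ped) <- ped$id
  sex <- factor(ped[ids, "sex"])
  bc <- droplevels(factor(ped[ids, "backcross"]))
  df <- data.frame(sex = sex, bc = bc)
  W <- if (nlevels(bc) > 1) stats::model.matrix(~ sex + bc, df)
       else stats::model.matrix(~ sex, df)
  rownames(W) <- ids
  W
}

#' Run a complete eQTL mapping study
#'
#' Applies SNP QC, builds the kinship matrix, scans every gene with the
#' mixed model, calls eSNPs at `q_threshold`, merges them into
#' intervals, applies the SNP-count filter, classifies cis/trans,
#' attaches annotation windows and top-SNP variance explained, and
#' detects trans-eQTL hotspots.
#'
#' @param em [expression_matrix()] on the analysis scale (individuals x
#'   genes).
#' @param ped [pedigree_table()].
#' @param geno Dosage matrix over the phenotyped individuals.
#' @param map [snp_map()].
#' @param genes [gene_positions()] for the scanned genes.
#' @param mode `"3BCs"` (joint, interval filter >= 2 SNPs) or `"single"`
#'   (>= 3 SNPs).
#' @param q_threshold eSNP significance bound (default 0.05, strict).
#' @param hotspot_labels Interval labels treated as trans-acting for
#'   hotspot detection.
#' @return List of class `eqtl_study`: `scans` (per gene), `esnps`,
#'   `intervals`, `hotspots`, `qc`, `kinship`, `covariates`.
#' @export
eqtl_study <- function(em, ped, geno, map, genes,
                       mode = c("3BCs", "single"), q_threshold = 0.05,
                       hotspot_labels = "trans") {
  mode <- match.arg(mode)
  ids <- rownames(em)
  geno <- geno[ids, , drop = FALSE]
  qc <- snp_qc(geno, map)
  K <- compute_grm(qc$genotypes)
  W <- scan_covariates(ped, ids)

  scans <- lapply(setNames(colnames(em), colnames(em)), function(g) {
    scan_gene(setNames(as.numeric(em[, g]), ids), W, qc$genotypes, K,
              qc$map)
  })

  interval_rows <- list()
  esnp_rows <- list()
  for (g in names(scans)) {
    es <- call_esnps(scans[[g]], q_threshold)
    if (nrow(es)) esnp_rows[[g]] <- cbind(gene = g, es)
    iv <- merge_intervals(es, gene = g)
    if (nrow(iv)) interval_rows[[g]] <- iv
  }
  esnps <- if (length(esnp_rows)) do.call(rbind, c(esnp_rows, make.row.names = FALSE))
           else NULL
  intervals <- if (length(interval_rows)) do.call(rbind, c(interval_rows, make.row.names = FALSE))
               else merge_intervals(data.frame(snp_id = character(0),
                                               chr = character(0),
                                               pos = numeric(0)))
  intervals <- filter_intervals(intervals, mode)
  intervals <- classify_cis_trans(intervals, map, genes)
  intervals <- annotation_window(intervals)

  if (nrow(intervals)) {
    intervals$top_pve <- vapply(seq_len(nrow(intervals)), function(i) {
      g <- intervals$gene[i]
      x <- qc$genotypes[, intervals$top_snp[i]]
      variance_explained(setNames(as.numeric(em[, g]), ids), W, x)
    }, numeric(1))
  } else {
    intervals$top_pve <- numeric(0)
  }

  hotspots <- detect_hotspots(intervals, labels = hotspot_labels)
  structure(list(scans = scans, esnps = esnps, intervals = intervals,
                 hotspots = hotspots, qc = qc, kinship = K,
                 covariates = W, mode = mode,
                 q_threshold = q_threshold),
            class = "eqtl_study")
}

#' @export
print.eqtl_study <- function(x, ...) {
  n_es <- if (is.null(x$esnps)) 0L else nrow(x$esnps)
  cat(sprintf("eQTL study (%s mode): %d gene scans, %d eSNPs (q < %g), %d intervals, %d hotspots\n",
              x$mode, length(x$scans), n_es, x$q_threshold,
              nrow(x$intervals), nrow(x$hotspots)))
  invisible(x)
}

#' Manhattan-plot data for one gene scan
#'
#' @param scan A [scan_gene()] result.
#' @return Data frame `chr`, `pos`, `neg_log10_p`.
#' @export
manhattan_data <- function(scan) {
  data.frame(chr = scan$chr, pos = scan$pos,
             neg_log10_p = -log10(scan$wald_p), stringsAsFactors = FALSE)
}

#' Karyotype-plot (PhenoGram-style) export of eSNP positions
#'
#' @param esnps eSNP table with `gene`, `chr`, `pos`.
#' @param cohort Cohort label attached to every row.
#' @return Data frame `chr`, `pos`, `gene`, `cohort`.
#' @export
phenogram_data <- function(esnps, cohort = "3BCs") {
  data.frame(chr = esnps$chr, pos = esnps$pos, gene = esnps$gene,
             cohort = cohort, stringsAsFactors = FALSE)
}

#' Write scan results / interval tables as TSV
#'
#' @param x A data frame (scan, eSNP, interval or hotspot table).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
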