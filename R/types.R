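# Shared domain types and validators.
#
# Conventions used throughout the package:
#   * genotypes are integer dosage matrices, individuals in rows, SNPs in
#     columns, values in {0, 1, 2, NA}; the counted allele is the
#     alphabetically first allele observed at the SNP (orientation only
#     affects effect signs, never test statistics);
#   * all genomic coordinates are 1-based and inclusive; chromosome labels
#     are opaque strings ("1".."18", "X") with no numeric assumptions;
#   * expression matrices carry individuals in rows, genes in columns, with
#     a per-gene logical attribute "log2" recording whether values were
#     log2-transformed.

#' Build and validate a SNP map
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chr Chromosome labels (coerced to character, treated as opaque).
#' @param pos Base-pair positions, 1-based, strictly positive integers.
#'
#' @return A `data.frame` with columns `snp_id`, `chr`, `pos` of class
#'   `snp_map`.
#' @export
snp_map <- function(snp_id, chr, pos) {
  snp_id <- as.character(snp_id)
  chr <- as.character(chr)
  pos <- as.integer(round(pos))
  if (anyDuplicated(snp_id)) {
    stop("snp_id values must be unique")
  }
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("positions must be strictly positive integers")
  }
  if (length(snp_id) != length(chr) || length(snp_id) != length(pos)) {
    stop("snp_id, chr and pos must have equal length")
  }
  out <- data.frame(snp_id = snp_id, chr = chr, pos = pos,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_map", "data.frame")
  out
}

#' Validate a dosage matrix against a SNP map
#'
#' @param geno Integer matrix of allele dosages (individuals x SNPs),
#'   values in `{0, 1, 2, NA}`, with row and column names.
#' @param map A [snp_map()] whose `snp_id` matches `colnames(geno)`.
#' @return `geno`, invisibly, after validation.
#' @export
validate_genotypes <- function(geno, map) {
  if (!is.matrix(geno)) stop("genotypes must be a matrix")
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix must carry individual and SNP names")
  }
  if (!identical(colnames(geno), map$snp_id)) {
    stop("genotype columns do not match the SNP map")
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  invisible(geno)
}

#' Build an expression matrix with per-gene transform flags
#'
#' @param values Numeric matrix, individuals in rows, genes in columns.
#' @param log2 Logical vector, one flag per gene, `TRUE` when the column
#'   holds log2-transformed normalized quantities.  Defaults to all
#'   `FALSE` (raw NQ scale).
#' @return The matrix with a named `"log2"` attribute, class `expr_matrix`.
#' @export
expression_matrix <- function(values, log2 = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(colnames(values)) || is.null(rownames(values))) {
    stop("expression matrix must carry individual and gene names")
  }
  if (is.null(log2)) log2 <- rep(FALSE, ncol(values))
  if (is.null(names(log2))) names(log2) <- colnames(values)
  if (!identical(sort(names(log2)), sort(colnames(values)))) {
    stop("log2 flags must be named by gene")
  }
  log2 <- log2[colnames(values)]
  raw <- values[, !log2, drop = FALSE]
  if (any(raw[!is.na(raw)] <= 0)) {
    stop("NQ values must be positive before log2 transformation")
  }
  attr(values, "log2") <- log2
  class(values) <- c("expr_matrix", "matrix", "array")
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d individuals x %d genes (%d log2-transformed)\n",
              nrow(x), ncol(x), sum(attr(x, "log2"))))
  invisible(x)
}

#' Per-gene log2-transform flags of an expression matrix
#' @param x An `expr_matrix`.
#' @return Named logical vector.
#' @export
log2_flags <- function(x) attr(x, "log2")

#' Build and validate a pedigree table
#'
#' Sire/dam equal to `NA` or `"0"` mean unknown.  Sex is `"M"`/`"F"`;
#' backcross is a free label (e.g. `BC1_LD`), `NA` allowed only for
#' unphenotyped ancestors.
#'
#' @param id,sire,dam Individual and parent identifiers.
#' @param sex `"M"` or `"F"` (NA allowed for founders of unknown sex).
#' @param backcross Backcross/cohort label per individual.
#' @param phenotyped Logical; individuals entering the expression study.
#'   These must have non-missing sex and backcross.
#' @return A `data.frame` of class `pedigree_table`.
#' @export
pedigree_table <- function(id, sire = NA, dam = NA, sex = NA,
                           backcross = NA, phenotyped = TRUE) {
  id <- as.character(id)
  n <- length(id)
  norm_parent <- function(p) {
    p <- as.character(p)
    p <- rep_len(p, n)
    p[!is.na(p) & p == "0"] <- NA
    p
  }
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)
  sex <- rep_len(as.character(sex), n)
  backcross <- rep_len(as.character(backcross), n)
  phenotyped <- rep_len(as.logical(phenotyped), n)
  if (anyDuplicated(id)) stop("pedigree ids must be unique")
  if (any(!is.na(sex) & !sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'")
  }
  if (any(phenotyped & (is.na(sex) | is.na(backcross)))) {
    stop("phenotyped individuals must have sex and backcross")
  }
  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    backcross = backcross, phenotyped = phenotyped,
                    stringsAsFactors = FALSE)
  assert_no_ancestor_cycle(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# An individual may not be its own ancestor; walk sire/dam links.
assert_no_ancestor_cycle <- function(ped) {
  parent <- rbind(match(ped$sire, ped$id), match(ped$dam, ped$id))
  for (i in seq_len(nrow(ped))) {
    seen <- integer(0)
    frontier <- parent[, i]
    frontier <- frontier[!is.na(frontier)]
    while (length(frontier)) {
      if (i %in% frontier) {
        stop(sprintf("individual '%s' is its own ancestor", ped$id[i]))
      }
      seen <- union(seen, frontier)
      nxt <- unique(as.vector(parent[, frontier]))
      frontier <- setdiff(nxt[!is.na(nxt)], seen)
    }
  }
  invisible(ped)
}

#' Build and validate a gene-position table
#'
#' @param gene Gene symbols (unique).
#' @param chr Chromosome labels.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A `data.frame` of class `gene_positions`.
#' @export
gene_positions <- function(gene, chr, start, end) {
  gene <- as.character(gene)
  chr <- as.character(chr)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyDuplicated(gene)) stop("gene symbols must be unique")
  if (any(start < 1) || any(end < start)) {
    stop("gene positions require 1 <= start <= end")
  }
  out <- data.frame(gene = gene, chr = chr, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_positions", "data.frame")
  out
}

#' Base-pair distance from SNPs to a gene
#'
#' The single shared coordinate helper: distance is measured to the
#' nearest gene edge on the 1-based inclusive convention, 0 for SNPs
#' inside the gene and `Inf` across chromosomes.
#'
#' @param snp_chr,snp_pos SNP chromosome labels and positions (vectors).
#' @param gene_chr,gene_start,gene_end Scalar gene location.
#' @return Numeric vector of distances in bp.
#' @export
bp_distance_to_gene <- function(snp_chr, snp_pos, gene_chr, gene_start,
                                gene_end) {
  d <- ifelse(snp_pos < gene_start, gene_start - snp_pos,
              ifelse(snp_pos > gene_end, snp_pos - gene_end, 0))
  d[as.character(snp_chr) != as.character(gene_chr)] <- Inf
  as.numeric(d)
}
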