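# TSV readers/writers for expression, pedigree, gene positions and Cq
# tables.  All tables are tab-separated with a header row.

#' Read a long-format expression table
#'
#' Expected columns: `gene`, `individual`, `value` and optionally `log2`
#' (logical, per-gene transform flag; must be constant within gene).
#' Duplicate (gene, individual) pairs are rejected.  Raw NQ values must
#' be positive unless the gene is flagged as already log2-transformed.
#'
#' @param path Path to a TSV/CSV file (separator sniffed from the header).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  tab <- read_delim_sniff(path)
  need <- c("gene", "individual", "value")
  if (!all(need %in% names(tab))) {
    stop("expression table needs columns gene, individual, value")
  }
  key <- paste(tab$gene, tab$individual, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (gene, individual) pair in expression table")
  }
  genes <- unique(tab$gene)
  inds <- unique(tab$individual)
  m <- matrix(NA_real_, length(inds), length(genes),
              dimnames = list(inds, genes))
  m[cbind(match(tab$individual, inds), match(tab$gene, genes))] <- tab$value
  if ("log2" %in% names(tab)) {
    fl <- tapply(as.logical(tab$log2), tab$gene, unique)
    if (any(lengths(fl) != 1)) {
      stop("log2 flag must be constant within gene")
    }
    flags <- setNames(vapply(fl, identity, logical(1))[genes], genes)
  } else {
    flags <- setNames(rep(FALSE, length(genes)), genes)
  }
  expression_matrix(m, log2 = flags)
}

#' Write an expression matrix as a long TSV
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(em, path) {
  flags <- log2_flags(em)
  long <- data.frame(
    gene = rep(colnames(em), each = nrow(em)),
    individual = rep(rownames(em), ncol(em)),
    value = as.vector(unclass(em)),
    log2 = rep(flags, each = nrow(em)))
  long <- long[!is.na(long$value), ]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree TSV
#'
#' Columns: `id`, `sire`, `dam`, `sex`, `backcross` and optionally
#' `phenotyped` (defaults to `TRUE` where sex and backcross are present).
#'
#' @param path Input path.
#' @return A [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  tab <- read_delim_sniff(path, colClasses = "character")
  need <- c("id", "sire", "dam", "sex", "backcross")
  if (!all(need %in% names(tab))) {
    stop("pedigree table needs columns id, sire, dam, sex, backcross")
  }
  ph <- if ("phenotyped" %in% names(tab)) as.logical(tab$phenotyped)
        else !(is.na(tab$sex) | is.na(tab$backcross))
  pedigree_table(id = tab$id, sire = tab$sire, dam = tab$dam,
                 sex = tab$sex, backcross = tab$backcross, phenotyped = ph)
}

#' Write a pedigree table as TSV
#' @param ped A [pedigree_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "0")
  invisible(path)
}

#' Read a gene-position TSV
#'
#' Columns: `gene`, `chr`, `start`, `end` (1-based inclusive).
#' @param path Input path.
#' @return A [gene_positions()].
#' @export
read_gene_positions <- function(path) {
  tab <- read_delim_sniff(path)
  need <- c("gene", "chr", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("gene position table needs columns gene, chr, start, end")
  }
  gene_positions(tab$gene, tab$chr, tab$start, tab$end)
}

#' Write a gene-position table as TSV
#' @param gp A [gene_positions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_positions <- function(gp, path) {
  write.table(as.data.frame(gp), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Cq table
#'
#' Columns: `sample`, `assay`, `Cq`, `replicate`, `is_standard`,
#' `standard_quantity` (relative quantity for standard rows, NA
#' otherwise).
#'
#' @param path Input path.
#' @return A validated data.frame.
#' @export
read_cq <- function(path) {
  tab <- read_delim_sniff(path)
  need <- c("sample", "assay", "Cq", "replicate", "is_standard",
            "standard_quantity")
  if (!all(need %in% names(tab))) {
    stop("Cq table needs columns sample, assay, Cq, replicate, ",
         "is_standard, standard_quantity")
  }
  tab$is_standard <- as.logical(tab$is_standard)
  if (any(tab$is_standard & is.na(tab$standard_quantity))) {
    stop("standard rows must carry a standard_quantity")
  }
  tab
}

#' Write a qPCR Cq table as TSV
#' @param cq A Cq data.frame (see [read_cq()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cq <- function(cq, path) {
  write.table(cq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Sniff tab vs comma from the header line, then read with headers.
read_delim_sniff <- function(path, ...) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), ...)
}
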