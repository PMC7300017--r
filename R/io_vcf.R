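# Minimal VCF support: parsing through vcfR, writing as plain VCF 4.2
# text.  Dosage counts the ALT allele (0/0 -> 0, 0/1 -> 1, 1/1 -> 2).

#' Read genotypes from a VCF file
#'
#' Requires a GT FORMAT field.  Multiallelic records are skipped with a
#' warning; `./.` becomes a missing dosage.  Phased separators (`|`) are
#' accepted.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF 4.x file.
#' @return A list with `genotypes` (individuals x SNPs dosage matrix of
#'   ALT-allele counts) and `map` (a [snp_map()]).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  if (!"GT" %in% unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))) {
    stop("VCF has no GT field")
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multiallelic record(s)", sum(multi)))
  }
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  map <- snp_map(snp_id = ids, chr = fix[, "CHROM"],
                 pos = as.numeric(fix[, "POS"]))
  alleles <- strsplit(gsub("\\|", "/", gt), "/")
  dose <- vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  geno <- t(matrix(dose, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = list(map$snp_id, colnames(gt))))
  list(genotypes = geno, map = map)
}

#' Write a dosage matrix as a VCF 4.2 file
#'
#' Dosage is emitted as the ALT-allele count (REF=A, ALT=C by default),
#' so `read_vcf(write_vcf(x))` is an exact round-trip.
#'
#' @param geno Dosage matrix (individuals x SNPs) with dimnames.
#' @param map A [snp_map()] matching `geno` columns.
#' @param path Output file path.
#' @param ref,alt Allele letters written as REF and ALT.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(geno, map, path, ref = "A", alt = "C") {
  validate_genotypes(geno, map)
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=eqtlcross",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_len(ncol(geno)), function(j) {
    d <- geno[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(map$chr[j], map$pos[j], map$snp_id[j], ref, alt, ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
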