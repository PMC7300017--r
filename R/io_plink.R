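# PLINK text-format (.ped/.map) reader and writer.
#
# Dosages are coded against the alphabetically first allele observed at
# each SNP.  "0 0" is the missing genotype.  Only biallelic SNPs are
# accepted.  The round-trip write_plink -> read_plink is exact whenever
# the counted allele is actually observed in the written data (always the
# case for polymorphic SNPs under the writer's A/C coding).

#' Read PLINK .ped/.map files
#'
#' @param ped_path,map_path Paths to the text .ped and .map files.
#' @return A list with `genotypes` (dosage matrix, individuals x SNPs),
#'   `map` (a [snp_map()]), `fam` (data.frame of the six leading .ped
#'   columns: fid, id, sire, dam, sex, phenotype) and `alleles`
#'   (data.frame snp_id, counted, other).
#' @export
read_plink <- function(ped_path, map_path) {
  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(map_raw) < 4) stop(".map file needs 4 columns (chr, id, cM, bp)")
  map <- snp_map(snp_id = map_raw[[2]], chr = map_raw[[1]],
                 pos = as.numeric(map_raw[[4]]))
  p <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  fam <- data.frame(fid = character(n), id = character(n),
                    sire = character(n), dam = character(n),
                    sex = character(n), phenotype = character(n),
                    stringsAsFactors = FALSE)
  a1 <- matrix("", n, p)
  a2 <- matrix("", n, p)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) != 6 + 2 * p) {
      stop(sprintf(".ped line %d has %d fields, expected %d",
                   i, length(fields), 6 + 2 * p))
    }
    fam[i, ] <- as.list(fields[1:6])
    g <- fields[-(1:6)]
    a1[i, ] <- g[seq(1, 2 * p, by = 2)]
    a2[i, ] <- g[seq(2, 2 * p, by = 2)]
  }
  if (anyDuplicated(fam$id)) stop("duplicate individual ids in .ped")

  geno <- matrix(NA_integer_, n, p, dimnames = list(fam$id, map$snp_id))
  counted <- character(p)
  other <- character(p)
  for (j in seq_len(p)) {
    half <- xor(a1[, j] == "0", a2[, j] == "0")
    if (any(half)) {
      stop(sprintf(".ped line %d: half-missing genotype at SNP %s",
                   which(half)[1], map$snp_id[j]))
    }
    obs <- setdiff(unique(c(a1[, j], a2[, j])), "0")
    if (length(obs) > 2) {
      stop(sprintf("SNP %s has %d alleles; only biallelic SNPs supported",
                   map$snp_id[j], length(obs)))
    }
    obs <- sort(obs)
    counted[j] <- if (length(obs)) obs[1] else NA_character_
    other[j] <- if (length(obs) == 2) obs[2] else NA_character_
    ok <- a1[, j] != "0"
    geno[ok, j] <- (a1[ok, j] == counted[j]) + (a2[ok, j] == counted[j])
  }
  list(genotypes = geno, map = map, fam = fam,
       alleles = data.frame(snp_id = map$snp_id, counted = counted,
                            other = other, stringsAsFactors = FALSE))
}

#' Write a dosage matrix as PLINK .ped/.map
#'
#' Dosage 2 is written as the counted allele homozygote.  Default allele
#' letters are A (counted) and C (other) so that the reader's
#' alphabetically-first convention recovers the same orientation.
#'
#' @param geno Dosage matrix (individuals x SNPs) with dimnames.
#' @param map A [snp_map()] matching `geno` columns.
#' @param prefix Output path prefix; writes `<prefix>.ped`, `<prefix>.map`.
#' @param fam Optional data.frame with columns fid, id, sire, dam, sex,
#'   phenotype (defaults are synthesized from rownames).
#' @param alleles Optional data.frame (snp_id, counted, other).
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(geno, map, prefix, fam = NULL, alleles = NULL) {
  validate_genotypes(geno, map)
  n <- nrow(geno); p <- ncol(geno)
  if (is.null(fam)) {
    fam <- data.frame(fid = rownames(geno), id = rownames(geno),
                      sire = "0", dam = "0", sex = "0", phenotype = "-9",
                      stringsAsFactors = FALSE)
  }
  if (is.null(alleles)) {
    alleles <- data.frame(snp_id = map$snp_id, counted = "A", other = "C",
                          stringsAsFactors = FALSE)
  }
  ga <- matrix("0", n, 2 * p)
  for (j in seq_len(p)) {
    d <- geno[, j]
    c1 <- alleles$counted[j]; c2 <- alleles$other[j]
    if (is.na(c2)) c2 <- c1
    one <- ifelse(is.na(d), "0", ifelse(d >= 1, c1, c2))
    two <- ifelse(is.na(d), "0", ifelse(d == 2, c1, c2))
    ga[, 2 * j - 1] <- one
    ga[, 2 * j] <- two
  }
  ped <- cbind(fam$fid, fam$id, fam$sire, fam$dam, fam$sex, fam$phenotype, ga)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  write.table(data.frame(map$chr, map$snp_id, 0, map$pos), map_path,
              quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(c(ped = ped_path, map = map_path))
}
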