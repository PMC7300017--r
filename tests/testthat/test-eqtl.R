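# eSNP calling, interval merging, cis/trans classification, annotation
# windows and hotspot detection.

fake_esnps <- function(pos, chr = "1") {
  data.frame(snp_id = paste0("s", seq_along(pos)), chr = chr, pos = pos,
             wald_p = seq_along(pos) * 1e-8, stringsAsFactors = FALSE)
}

test_that("eSNP calling uses a strict q-value bound", {
  sc <- data.frame(snp_id = c("a", "b", "c"), chr = "1",
                   pos = c(1, 2, 3) * 1e6,
                   wald_p = c(1e-6, 1e-3, 0.5),
                   q_value = c(0.01, 0.05, 0.6))
  es <- call_esnps(sc, 0.05)
  expect_identical(es$snp_id, "a")   # q exactly at the bound is excluded
  expect_identical(nrow(call_esnps(sc[0, ], 0.05)), 0L)
  expect_identical(nrow(call_esnps(sc, 0.10)), 2L)
})

test_that("interval merging splits at gaps of 10 Mb or more", {
  # two eSNPs exactly 10 Mb apart start separate intervals
  iv <- merge_intervals(fake_esnps(c(5e6, 5e6 + 1e7)), gene = "g")
  expect_identical(nrow(iv), 2L)
  iv2 <- merge_intervals(fake_esnps(c(5e6, 5e6 + 1e7 - 1)), gene = "g")
  expect_identical(nrow(iv2), 1L)

  # wide chromosome-3-style span with all internal gaps < 10 Mb
  pos <- c(18557492, seq(25e6, 50e6, by = 8e6), 53699303)
  iv3 <- merge_intervals(fake_esnps(pos, chr = "3"), gene = "g")
  expect_identical(nrow(iv3), 1L)
  expect_equal(iv3$start_bp, 18557492)
  expect_equal(iv3$end_bp, 53699303)
  expect_equal(iv3$size_bp, 35141811)

  # chromosomes never merge together
  es <- rbind(fake_esnps(c(1e6, 2e6), chr = "1"),
              fake_esnps(c(1e6, 2e6), chr = "2"))
  es$snp_id <- paste0("s", 1:4)
  expect_identical(nrow(merge_intervals(es, gene = "g")), 2L)
})

test_that("merging equals brute-force transitive-closure clustering", {
  set.seed(31)
  for (trial in 1:100) {
    k <- sample(2:25, 1)
    pos <- sort(sample.int(2e8, k))
    es <- fake_esnps(pos)
    iv <- merge_intervals(es, gene = "g")
    truth <- oracle_cluster(pos)
    expect_identical(nrow(iv), length(unique(truth)))
    # every eSNP belongs to exactly one interval, bounds match clusters
    member_counts <- integer(k)
    for (i in seq_len(nrow(iv))) {
      snps <- strsplit(iv$snp_ids[i], ",")[[1]]
      member_counts[match(snps, es$snp_id)] <-
        member_counts[match(snps, es$snp_id)] + 1L
      cpos <- es$pos[match(snps, es$snp_id)]
      expect_equal(iv$start_bp[i], min(cpos))
      expect_equal(iv$end_bp[i], max(cpos))
      expect_equal(iv$size_bp[i], max(cpos) - min(cpos))
      expect_identical(length(unique(truth[match(snps, es$snp_id)])), 1L)
    }
    expect_true(all(member_counts == 1L))
    # input order invariance
    perm <- sample(k)
    ivp <- merge_intervals(es[perm, ], gene = "g")
    o <- order(ivp$start_bp)
    expect_equal(ivp$start_bp[o], iv$start_bp)
    expect_equal(ivp$n_snps[o], iv$n_snps)
  }
})

test_that("interval filters depend on analysis mode", {
  iv <- rbind(merge_intervals(fake_esnps(1e6), gene = "a"),
              merge_intervals(fake_esnps(c(2e6, 3e6)), gene = "b"),
              merge_intervals(fake_esnps(c(4e6, 5e6, 6e6)), gene = "c"))
  expect_identical(filter_intervals(iv, "3BCs")$gene, c("b", "c"))
  expect_identical(filter_intervals(iv, "single")$gene, "c")
  # co-located pair: size 0, kept in joint mode
  pair <- merge_intervals(fake_esnps(c(493510, 493510)), gene = "d")
  expect_equal(pair$size_bp, 0)
  expect_identical(nrow(filter_intervals(pair, "3BCs")), 1L)
})

test_that("cis/trans classification follows the 1 Mb edge rule", {
  genes <- gene_positions("g", "1", 10e6, 10.02e6)
  map <- snp_map(paste0("s", 1:4), c("1", "1", "1", "2"),
                 c(9.5e6, 11.02e6, 15e6, 5e6))
  # single cis SNP 0.5 Mb upstream
  iv <- merge_intervals(data.frame(snp_id = "s1", chr = "1", pos = 9.5e6),
                        gene = "g")
  expect_identical(classify_cis_trans(iv, map, genes)$label, "cis")
  # SNP exactly 1 Mb from the gene edge is still cis (inclusive)
  iv2 <- merge_intervals(data.frame(snp_id = "s2", chr = "1", pos = 11.02e6),
                         gene = "g")
  expect_identical(classify_cis_trans(iv2, map, genes)$label, "cis")
  # another chromosome: trans
  iv3 <- merge_intervals(data.frame(snp_id = "s4", chr = "2", pos = 5e6),
                         gene = "g")
  expect_identical(classify_cis_trans(iv3, map, genes)$label, "trans")
  # mixed membership: cis/trans
  iv4 <- merge_intervals(data.frame(snp_id = c("s1", "s3"), chr = "1",
                                    pos = c(9.5e6, 15e6)), gene = "g")
  out <- classify_cis_trans(iv4, map, genes)
  expect_identical(out$label, "cis/trans")
  expect_identical(out$n_cis, 1L)
  expect_identical(out$n_trans, 1L)
  expect_error(classify_cis_trans(iv4, map, gene_positions("x", "1", 1, 2)),
               "no position")
})

test_that("annotation windows add 1 Mb each side, floored at 1", {
  iv <- data.frame(start_bp = c(5e6, 0.3e6), end_bp = c(6e6, 0.4e6))
  w <- annotation_window(iv)
  expect_equal(w$window_start, c(4e6, 1))
  expect_equal(w$window_end, c(7e6, 1.4e6))
})

test_that("hotspots are overlap components of trans intervals of >= 2 genes", {
  iv <- data.frame(gene = c("a", "b", "c", "a"),
                   chr = c("1", "1", "1", "2"),
                   start_bp = c(10e6, 14e6, 40e6, 5e6),
                   end_bp = c(15e6, 20e6, 45e6, 6e6),
                   label = c("trans", "trans", "trans", "trans"),
                   stringsAsFactors = FALSE)
  hs <- detect_hotspots(iv)
  expect_identical(nrow(hs), 1L)
  expect_identical(hs$genes, "a,b")
  expect_equal(hs$span_start, 10e6)
  expect_equal(hs$span_end, 20e6)

  # same gene twice is not a hotspot
  iv2 <- iv[c(1, 2), ]; iv2$gene <- "a"
  expect_identical(nrow(detect_hotspots(iv2)), 0L)

  # cis intervals are ignored unless requested
  iv3 <- iv; iv3$label[2] <- "cis"
  expect_identical(nrow(detect_hotspots(iv3)), 0L)
  expect_identical(nrow(detect_hotspots(iv3, labels = c("trans", "cis"))), 1L)

  # chained overlap links three genes into one component
  iv4 <- data.frame(gene = c("a", "b", "c"), chr = "1",
                    start_bp = c(1e6, 4e6, 8e6),
                    end_bp = c(5e6, 9e6, 12e6), label = "trans")
  hs4 <- detect_hotspots(iv4)
  expect_identical(hs4$n_genes, 3L)
  # touching at a single shared base pair still counts as overlap
  iv5 <- data.frame(gene = c("a", "b"), chr = "1",
                    start_bp = c(1e6, 2e6), end_bp = c(2e6, 3e6),
                    label = "trans")
  expect_identical(nrow(detect_hotspots(iv5)), 1L)
  iv6 <- iv5; iv6$start_bp[2] <- 2e6 + 1
  expect_identical(nrow(detect_hotspots(iv6)), 0L)
})

test_that("interval sizes reproduce printed bounds arithmetic", {
  tab <- read.table(system.file("extdata", "muscle_eqtl_intervals.tsv",
                                package = "eqtlcross"),
                    header = TRUE, sep = "\t")
  expect_identical(nrow(tab), 10L)
  expect_equal(interval_size(tab$start_bp, tab$end_bp), tab$size_bp)
  expect_error(interval_size(10, 5), "end")
})
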