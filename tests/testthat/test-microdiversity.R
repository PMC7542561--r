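# Codon pileups, variant filters, expected-site normalization and the
# per-gene / per-genome polymorphism statistics.

test_that("expected_sites equals exhaustive 9-neighbor enumeration", {
  for (cod in sense_codons()) {
    want <- oracle_expected_sites(cod)
    got <- expected_sites(cod)
    expect_equal(got$s, unname(want["s"]), tolerance = 1e-12, label = cod)
    expect_equal(got$n, unname(want["n"]), tolerance = 1e-12, label = cod)
    expect_equal(got$s + got$n, 3, tolerance = 1e-12)
  }
  expect_equal(expected_sites("TTT")$s, 1 / 3)
  expect_equal(expected_sites("TGG")$s, 0)
  expect_error(expected_sites("TXT"), "non-ACGT")
  expect_error(expected_sites("TAA"), "stop")
})

test_that("codon pileups respect spanning, frame and strand", {
  cds <- "ATGGGCTAA"
  g <- toy_genome(list(cds, cds), strands = c("+", "-"), spacer = 12,
                  seed = 61)
  s1 <- g$genes$start[1]
  # read exactly covering the plus-strand gene
  aln <- toy_alignment_set(g, ref_start = s1,
                           aln_seq = substr(g$sequence, s1 + 1, s1 + 9))
  pil <- build_codon_pileups(aln, g)
  pil1 <- pil[pil$gene_id == "g01", ]
  expect_equal(nrow(pil1), 3)
  expect_equal(pil1$spanning_coverage, rep(1L, 3))
  expect_equal(pil1$obs_codon, pil1$ref_codon)
  expect_equal(pil1$ref_codon, c("ATG", "GGC", "TAA"))

  # read covering only 2 bases of the first codon contributes nothing there
  aln2 <- toy_alignment_set(g, ref_start = s1 + 1L,
                            aln_seq = substr(g$sequence, s1 + 2, s1 + 9))
  pil2 <- build_codon_pileups(aln2, g)
  expect_equal(pil2$codon_index[pil2$gene_id == "g01"], c(1L, 2L))

  # minus-strand gene read (matching the reference) reports gene-frame codons
  s2 <- g$genes$start[2]
  aln3 <- toy_alignment_set(g, ref_start = s2,
                            aln_seq = substr(g$sequence, s2 + 1, s2 + 9))
  pil3 <- build_codon_pileups(aln3, g)
  pil3 <- pil3[pil3$gene_id == "g02", ]
  expect_equal(pil3$ref_codon[order(pil3$codon_index)], c("ATG", "GGC", "TAA"))
  expect_equal(pil3$obs_codon, pil3$ref_codon)
})

test_that("variant filters apply all three thresholds inclusively", {
  mk <- function(count, cov) {
    data.frame(gene_id = "g", codon_index = 0L, ref_codon = "GGC",
               obs_codon = c("GGC", "GGA"),
               count = c(cov - count, count),
               spanning_coverage = cov, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(call_codon_variants(mk(3, 1000))), 0)     # count rule
  expect_equal(nrow(call_codon_variants(mk(4, 4))), 0)        # coverage rule
  v <- call_codon_variants(mk(4, 4000))                       # 0.1% boundary
  expect_equal(nrow(v), 1)
  expect_equal(v$classification, "synonymous")
  expect_equal(v$frequency, 0.001)
})

test_that("variant calling equals a brute-force triple-predicate scan", {
  set.seed(71)
  sense <- sense_codons()
  rows <- list()
  for (i in 1:2000) {
    ref <- sample(sense, 1)
    cov <- sample(c(3:8, 50, 400, 4000), 1)
    n_alt <- sample(0:2, 1)
    alts <- sample(setdiff(sense, ref), n_alt)
    counts <- if (n_alt) sample(1:8, n_alt, replace = TRUE) else integer(0)
    counts <- pmin(counts, cov)
    rows[[i]] <- data.frame(
      gene_id = sprintf("g%03d", i %% 40), codon_index = i,
      ref_codon = ref, obs_codon = c(ref, alts),
      count = c(cov - sum(counts), counts),
      spanning_coverage = cov, stringsAsFactors = FALSE)
  }
  pil <- do.call(rbind, rows)
  got <- call_codon_variants(pil, min_count = 4, min_freq = 0.001, min_cov = 5)
  want <- pil[pil$obs_codon != pil$ref_codon &
                pil$count >= 4 &
                pil$count / pil$spanning_coverage >= 0.001 &
                pil$spanning_coverage >= 5, ]
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$gene_id, got$codon_index, got$alt_codon),
                  paste(want$gene_id, want$codon_index, want$obs_codon))
  # classification via the genetic-code oracle
  expect_equal(got$classification == "synonymous",
               unname(GC_MAP[got$alt_codon] == GC_MAP[got$ref_codon]))
})

test_that("gene statistics match hand computations on toy pileups", {
  cds <- random_cds(100, seed = 72)
  g <- toy_genome(list(cds), seed = 72)
  s1 <- g$genes$start[1]
  # 10 identical perfect reads covering the whole gene
  aln <- toy_alignment_set(g, ref_start = rep(s1, 10),
                           aln_seq = rep(substr(g$sequence, s1 + 1, s1 + 300), 10))
  pil <- build_codon_pileups(aln, g)
  gs0 <- gene_stats(call_codon_variants(pil), pil)
  expect_equal(gs0$pn, 0)
  expect_equal(gs0$ps, 0)
  expect_equal(gs0$pps, 0)
  expect_true(is.na(gs0$pnps))
  expect_equal(gs0$covered_codons, 99L)  # terminal stop excluded

  # inject one synonymous variant passing all filters (5 of 10 reads)
  done <- FALSE
  for (ci in 2:99) {
    cod <- substr(cds, 3 * ci - 2, 3 * ci)
    for (pos in 1:3) {
      for (b in setdiff(ORACLE_BASES, substr(cod, pos, pos))) {
        alt <- cod; substr(alt, pos, pos) <- b
        if (GC_MAP[alt] == GC_MAP[cod]) { done <- TRUE; break }
      }
      if (done) break
    }
    if (done) break
  }
  mut <- substr(g$sequence, s1 + 1, s1 + 300)
  substr(mut, 3 * ci - 3 + pos, 3 * ci - 3 + pos) <- b
  aln2 <- toy_alignment_set(g, ref_start = rep(s1, 10),
                            aln_seq = c(rep(substr(g$sequence, s1 + 1, s1 + 300), 5),
                                        rep(mut, 5)))
  pil2 <- build_codon_pileups(aln2, g)
  gs <- gene_stats(call_codon_variants(pil2), pil2)
  s_exp <- sum(vapply(substring(cds, seq(1, 297, 3), seq(3, 299, 3)),
                      function(cd) oracle_expected_sites(cd)["s"], 0))
  expect_equal(gs$s_exp, s_exp, tolerance = 1e-12)
  expect_equal(gs$s_exp + gs$n_exp, 3 * 99)
  expect_equal(gs$ps, 100 / s_exp, tolerance = 1e-12)
  expect_equal(gs$pn, 0)
  expect_equal(gs$pps, 100 / (3 * 99))
  expect_true(is.na(gs$pnps) || gs$pnps == 0)
})

test_that("an alt codon differing at two positions marks two polymorphic sites", {
  g <- toy_genome(list("ATGCTGGGATAA"), seed = 73)
  s1 <- g$genes$start[1]
  ref_read <- substr(g$sequence, s1 + 1, s1 + 12)
  mut <- ref_read
  substr(mut, 7, 8) <- "TC"   # GGA -> TCA (two positions changed)
  aln <- toy_alignment_set(g, ref_start = rep(s1, 10),
                           aln_seq = c(rep(ref_read, 5), rep(mut, 5)))
  pil <- build_codon_pileups(aln, g)
  v <- call_codon_variants(pil)
  expect_equal(v$alt_codon, "TCA")
  expect_equal(v$classification, "nonsynonymous")
  gs <- gene_stats(v, pil)
  expect_equal(gs$pps, 100 * 2 / (3 * 3))
})

test_that("genome aggregation matches its definition and a re-summation oracle", {
  gsx <- data.frame(gene_id = c("a", "b", "c"), covered_codons = c(10L, 10L, 10L),
                    s_exp = 8, n_exp = 22, n_syn_variant_positions = 1L,
                    n_nonsyn_variant_positions = 1L,
                    pn = c(1, 2, 3), ps = c(2, 4, 6),
                    pnps = c(0.5, 1.5, NA), pps = c(10, 20, 30),
                    flagged = FALSE, stringsAsFactors = FALSE)
  agg <- aggregate_genome(gsx, rpkg = 12, anir = 95)
  expect_equal(agg$median_pnps, 1.0)
  expect_equal(agg$fraction_pnps_gt1, 0.5)
  expect_equal(agg$mean_pps, 20)
  expect_equal(agg$rpkg, 12)

  expect_equal(aggregate_genome(gsx[1, ])$median_pnps, gsx$pnps[1])

  set.seed(74)
  rnd <- gsx[sample.int(3, 40, replace = TRUE), ]
  rnd$pnps <- runif(40); rnd$pnps[sample.int(40, 5)] <- NA
  rnd$pps <- runif(40, 0, 50)
  agg2 <- aggregate_genome(rnd)
  expect_equal(agg2$median_pnps, median(rnd$pnps, na.rm = TRUE))
  expect_equal(agg2$mean_pps, mean(rnd$pps))
  expect_equal(agg2$fraction_pnps_gt1,
               sum(rnd$pnps > 1, na.rm = TRUE) / sum(!is.na(rnd$pnps)))
})
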