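# Read placement, identity/length filtering, RPKG and ANIr.

test_that("exact and near-exact reads are placed with correct identity", {
  g <- generate_genome(20000, 15, seed = 51)
  r_exact <- substr(g$sequence, 101, 200)         # positions [100, 200)
  r_mm <- r_exact
  substr(r_mm, 50, 50) <- setdiff(ORACLE_BASES, substr(r_mm, 50, 50))[1]
  aln <- align_reads(data.frame(read_id = c("e", "m"),
                                sequence = c(r_exact, r_mm)), g)
  expect_equal(aln$records$ref_start, c(100L, 100L))
  expect_equal(aln$records$identity, c(100, 99))
  expect_equal(aln$records$matches, c(100L, 99L))

  expect_error(align_reads(data.frame(sequence = strrep("A", 30000)), g),
               "shorter")
  empty <- align_reads(data.frame(read_id = character(0),
                                  sequence = character(0)), g)
  expect_s3_class(empty, "alignment_set")
  expect_equal(nrow(empty$records), 0)
})

test_that("alignment filtering keeps inclusive boundaries and matches brute force", {
  g <- generate_genome(20000, 15, seed = 52)
  rec <- data.frame(read_id = c("a", "b", "c"),
                    ref_start = c(0L, 0L, 0L),
                    aligned_len = c(50L, 200L, 49L),
                    matches = c(49L, 195L, 49L),
                    identity = c(98.0, 97.5, 100),
                    aln_seq = strrep("A", c(50, 200, 49)),
                    truth_lineage = NA, stringsAsFactors = FALSE)
  aln <- alignment_set(g$id, rec, 1e6, 1e4, 100)
  kept <- filter_alignments(aln, 98, 50)
  expect_equal(kept$records$read_id, "a")          # 98.0/50 inclusive
  expect_equal(kept$metagenome_bases, 1e6)         # denominators untouched

  pop <- evolve_population(g, n_lineages = 5, theta = 0.02, omega = 1, seed = 1)
  reads <- simulate_reads(pop, 5000, read_len = 100, seed = 2)
  aln2 <- align_reads(reads, g)
  for (co in list(c(98, 50), c(99, 100), c(80, 50))) {
    got <- filter_alignments(aln2, co[1], co[2])$records$read_id
    want <- aln2$records$read_id[aln2$records$identity >= co[1] &
                                   aln2$records$aligned_len >= co[2]]
    expect_equal(got, want)
  }
})

test_that("RPKG follows its unit definition in both normalization modes", {
  rec <- data.frame(read_id = sprintf("r%d", 1:1000), ref_start = 0L,
                    aligned_len = 100L, matches = 100L, identity = 100,
                    aln_seq = strrep("A", 100), truth_lineage = NA)
  aln <- alignment_set("g", rec, metagenome_bases = 1e9,
                       metagenome_reads = 1e7, mean_read_len = 100)
  expect_equal(as.numeric(compute_rpkg(aln, 1e6)), 1.0)
  aln2 <- aln; aln2$metagenome_bases <- 2e9
  expect_identical(as.numeric(compute_rpkg(aln2, 1e6)),
                   as.numeric(compute_rpkg(aln, 1e6)) / 2)
  expect_equal(as.numeric(compute_rpkg(aln, 1e6, "read_adjusted")), 100.0)
  expect_error(compute_rpkg(aln, 0), "genome")
  aln3 <- aln; aln3$metagenome_bases <- 0
  expect_error(compute_rpkg(aln3, 1e6), "metagenome")
})

test_that("ANIr summarizes per-read identities with histogram", {
  rec <- data.frame(read_id = c("a", "b"), ref_start = 0L,
                    aligned_len = 100L, matches = c(90L, 100L),
                    identity = c(90, 100), aln_seq = strrep("A", 100),
                    truth_lineage = NA)
  an <- compute_anir(alignment_set("g", rec, 200, 2, 100))
  expect_equal(an$anir_mean, 95.0)
  expect_equal(an$anir_median, 95.0)
  expect_equal(an$histogram$count[an$histogram$bin_low == 90], 1L)
  expect_equal(an$histogram$count[an$histogram$bin_low == 99], 1L)
  expect_equal(sum(an$histogram$count), 2L)

  empty <- alignment_set("g", rec[0, ], 200, 2, 100)
  expect_warning(an0 <- compute_anir(empty), "undefined")
  expect_true(is.na(an0$anir_median))

  # identity floor: after a 98% cutoff ANIr cannot drop below 98
  g <- generate_genome(20000, 15, seed = 53)
  pop <- evolve_population(g, n_lineages = 5, theta = 0.02, omega = 1, seed = 3)
  reads <- simulate_reads(pop, 5000, read_len = 100, err_rate = 0.01, seed = 4)
  a98 <- filter_alignments(align_reads(reads, g), 98, 50)
  expect_gte(compute_anir(a98)$anir_median, 98)
})

test_that("subsampling is deterministic, warns on shortfall, keeps composition", {
  g <- generate_genome(20000, 15, seed = 54)
  pop <- toy_population(g, c(a = g$sequence, b = g$sequence), c(0.7, 0.3))
  reads <- simulate_reads(pop, 20000, read_len = 50, seed = 5)
  aln <- align_reads(reads, g)
  s1 <- subsample_alignments(aln, 2000, seed = 9)
  s2 <- subsample_alignments(aln, 2000, seed = 9)
  expect_identical(s1$records, s2$records)
  expect_equal(nrow(s1$records), 2000)
  expect_equal(s1$metagenome_bases, aln$metagenome_bases)
  expect_warning(sall <- subsample_alignments(aln, 1e7, seed = 9), "available")
  expect_equal(nrow(sall$records), nrow(aln$records))

  # composition within 3 hypergeometric SD of the source
  p <- mean(aln$records$truth_lineage == "lin_01")
  n <- 2000; N <- nrow(aln$records)
  sd_h <- sqrt(n * p * (1 - p) * (N - n) / (N - 1))
  expect_lt(abs(sum(s1$records$truth_lineage == "lin_01") - n * p), 3 * sd_h)
})

test_that("reads mostly inside masked regions are not recruited", {
  g <- generate_genome(20000, 15, seed = 55)
  gm <- mask_regions(g, data.frame(start = 1000, end = 1500))
  inside <- substr(g$sequence, 1101, 1200)      # fully masked span
  outside <- substr(g$sequence, 5001, 5100)
  aln <- align_reads(data.frame(read_id = c("in", "out"),
                                sequence = c(inside, outside)), gm)
  expect_equal(aln$records$read_id, "out")
  # denominators still count the dropped read
  expect_equal(aln$metagenome_reads, 2)
})

test_that("recruited identities recover the simulated divergence", {
  g <- generate_genome(30000, 25, seed = 56)
  pop <- evolve_population(g, n_lineages = 10, theta = 0.05, omega = 1,
                           seed = 6, lineage_freqs = rep(1, 10))
  reads <- simulate_reads(pop, 20000, read_len = 100, err_rate = 0, seed = 7)
  aln <- filter_alignments(align_reads(reads, g), 80, 50)
  # mean divergence realized by the simulator, measured independently
  truth_id <- 100 * (1 - mean(vapply(pop$lineages$sequence, function(s)
    oracle_hamming(s, g$sequence), 0) / nchar(g$sequence)))
  expect_lt(abs(compute_anir(aln)$anir_mean - truth_id), 0.2)
})
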