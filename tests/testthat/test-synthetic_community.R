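# The population simulator: genome generation, codon-aware evolution with a
# selection knob (omega), recombination bookkeeping and read simulation.

test_that("generated genomes are deterministic with valid gene models", {
  g1 <- generate_genome(60000, 50, gc = 0.45, seed = 7)
  g2 <- generate_genome(60000, 50, gc = 0.45, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1$sequence, generate_genome(60000, 50, 0.45, 8)$sequence))

  ge <- g1$genes
  expect_true(all((ge$end - ge$start) %% 3 == 0))
  expect_true(all(ge$end - ge$start >= 300))
  expect_true(all(ge$start[-1] >= ge$end[-nrow(ge)]))  # non-overlapping
  for (i in seq_len(nrow(ge))) {
    cds <- popmicrodiv:::gene_sequence(g1, ge$gene_id[i])
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds))), "")[[1]]
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))  # no in-frame stop
  }
})

test_that("genome GC content tracks the requested fraction", {
  for (gc in c(0.30, 0.50, 0.65)) {
    g <- generate_genome(100000, 80, gc = gc, seed = 3)
    obs <- mean(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
    expect_true(abs(obs - gc) <= 0.02)
  }
})

test_that("infeasible gene packings are refused with a capacity message", {
  expect_error(generate_genome(30000, 50), "at most")
})

test_that("selection and recombination knobs shape the truth as stated", {
  g <- generate_genome(50000, 40, seed = 11)
  pop0 <- evolve_population(g, n_lineages = 6, theta = 0.02, omega = 0, seed = 1)
  expect_false(any(pop0$true_variants$class == "nonsynonymous"))
  expect_equal(nrow(pop0$recomb_events), 0)           # rho_over_theta = 0
  expect_error(evolve_population(g, theta = 0.3), "0.25")

  # conservation at rho = 0: every accepted substitution is a logged allele
  expect_equal(sum(pop0$true_variants$n_lineages),
               pop0$params$n_accepted_mutations)

  # determinism
  pop0b <- evolve_population(g, n_lineages = 6, theta = 0.02, omega = 0, seed = 1)
  expect_identical(pop0$lineages, pop0b$lineages)
})

test_that("truth classifications agree with re-translation of mutated codons", {
  g <- generate_genome(40000, 35, seed = 13)
  pop <- evolve_population(g, n_lineages = 5, theta = 0.03, omega = 0.5, seed = 2)
  tv <- pop$true_variants
  coding <- tv[!is.na(tv$gene_id), ]
  coding <- coding[sample.int(nrow(coding), 200), ]
  for (i in seq_len(nrow(coding))) {
    k <- match(coding$gene_id[i], g$genes$gene_id)
    mutated <- g$sequence
    substr(mutated, coding$pos[i] + 1, coding$pos[i] + 1) <- coding$alt_base[i]
    cds_ref <- popmicrodiv:::gene_sequence(g, coding$gene_id[i])
    cds_mut <- substr(mutated, g$genes$start[k] + 1, g$genes$end[k])
    if (g$genes$strand[k] == "-") {
      cds_mut <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_mut)))
    }
    same_aa <- identical(
      as.character(Biostrings::translate(Biostrings::DNAString(cds_ref),
                                         no.init.codon = TRUE)),
      as.character(Biostrings::translate(Biostrings::DNAString(cds_mut),
                                         no.init.codon = TRUE)))
    expect_equal(coding$class[i] == "synonymous", same_aa,
                 label = sprintf("variant at %d", coding$pos[i]))
  }
})

test_that("ground-truth pN/pS is nondecreasing in omega", {
  g <- generate_genome(50000, 40, seed = 17)
  ratio <- vapply(c(0, 0.3, 1), function(om) {
    pop <- evolve_population(g, n_lineages = 8, theta = 0.02, omega = om,
                             seed = 5)
    ts <- true_summary(pop)
    ts$genome$mean_pn / ts$genome$mean_ps
  }, 0)
  expect_true(all(diff(ratio) > 0))
  expect_equal(ratio[1], 0)  # omega = 0: no nonsynonymous variation at all
})

test_that("reads mirror lineage content, coverage and composition", {
  g <- generate_genome(20000, 15, seed = 21)
  # single lineage identical to the reference: every read matches exactly
  pop1 <- toy_population(g, c(a = g$sequence))
  r1 <- simulate_reads(pop1, 500, read_len = 80, err_rate = 0, seed = 1)
  expect_true(all(substring(g$sequence, r1$truth_start + 1,
                            r1$truth_start + 80) == r1$sequence))

  expect_error(simulate_reads(pop1, 0), "positive")
  expect_error(simulate_reads(pop1, 10, read_len = 30000), "shortest")
  expect_error(simulate_reads(pop1, 10, err_rate = 0.2), "err_rate")

  # realized mean depth within 5% of n * read_len / L at 1e5 reads
  r2 <- simulate_reads(pop1, 1e5, read_len = 50, err_rate = 0, seed = 2)
  depth <- numeric(nchar(g$sequence))
  add <- tabulate(r2$truth_start + 1, nbins = length(depth))
  rem <- tabulate(r2$truth_start + 51, nbins = length(depth))
  depth <- cumsum(add - rem)
  expect_lt(abs(mean(depth) - 1e5 * 50 / 20000) / (1e5 * 50 / 20000), 0.05)

  # 50/50 lineage mixture: counts within 3 binomial SD of half
  pop2 <- toy_population(g, c(a = g$sequence, b = g$sequence), c(0.5, 0.5))
  r3 <- simulate_reads(pop2, 1e5, read_len = 50, seed = 3)
  n_a <- sum(r3$truth_lineage == "lin_01")
  expect_lt(abs(n_a - 50000), 3 * sqrt(1e5 * 0.25))

  # per-base errors appear at the requested rate with matching Phreds
  r4 <- simulate_reads(pop1, 2000, read_len = 100, err_rate = 0.02, seed = 4)
  nmm <- vapply(seq_len(2000), function(i) {
    oracle_hamming(r4$sequence[i],
                   substr(g$sequence, r4$truth_start[i] + 1,
                          r4$truth_start[i] + 100))
  }, 0)
  expect_lt(abs(sum(nmm) - 2000 * 100 * 0.02), 4 * sqrt(2000 * 100 * 0.02))
  expect_equal(unique(r4$qualities), strrep(rawToChar(as.raw(17 + 33)), 100))
})

test_that("true_summary matches hand-counted statistics on toy populations", {
  cds <- random_cds(100, seed = 31)                 # 300 bp gene
  g <- toy_genome(list(cds), seed = 31)
  # single lineage: no polymorphism at all
  ts1 <- true_summary(toy_population(g, c(a = g$sequence)))
  expect_equal(ts1$gene_table$pps, 0)
  expect_equal(ts1$gene_table$pn, 0)
  expect_equal(ts1$gene_table$ps, 0)

  # one synonymous difference in lineage 2: pS = 100 / S_exp, pN = 0
  es <- sum(vapply(substring(cds, seq(1, 297, 3), seq(3, 299, 3)),
                   function(cd) oracle_expected_sites(cd)["s"], 0))
  # find a codon with a synonymous neighbor and apply it
  hap2 <- g$sequence
  done <- FALSE
  for (ci in 2:99) {
    cod <- substr(cds, 3 * ci - 2, 3 * ci)
    for (pos in 1:3) {
      for (b in setdiff(ORACLE_BASES, substr(cod, pos, pos))) {
        alt <- cod; substr(alt, pos, pos) <- b
        if (GC_MAP[alt] == GC_MAP[cod]) {
          gp <- g$genes$start[1] + 3 * (ci - 1) + pos  # 1-based genome pos
          substr(hap2, gp, gp) <- b
          done <- TRUE; break
        }
      }
      if (done) break
    }
    if (done) break
  }
  expect_true(done)
  ts2 <- true_summary(toy_population(g, c(a = g$sequence, b = hap2)))
  expect_equal(ts2$gene_table$ps, 100 / es, tolerance = 1e-12)
  expect_equal(ts2$gene_table$pn, 0)
  expect_equal(ts2$gene_table$pps, 100 / (3 * 99))  # stop codon excluded
})

test_that("mean lineage identity tracks theta and a direct Hamming check", {
  g <- generate_genome(50000, 40, seed = 41)
  pop <- evolve_population(g, n_lineages = 6, theta = 0.02, omega = 1,
                           seed = 6, lineage_freqs = rep(1, 6))
  ts <- true_summary(pop)
  direct <- mean(vapply(pop$lineages$sequence, function(s) {
    100 * (1 - oracle_hamming(s, g$sequence) / nchar(g$sequence))
  }, 0))
  expect_equal(ts$genome$mean_identity_to_ref, direct, tolerance = 1e-9)
  expect_lt(abs(ts$genome$mean_identity_to_ref - 98), 0.3)
})
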