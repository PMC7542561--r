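# Independent oracles and small fixture builders. These deliberately avoid
# the package's own lookup tables and compiled paths: expected values come
# from direct enumeration, brute-force scans or string arithmetic.

GC_MAP <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")

# expected synonymous sites of a codon by exhaustive 9-neighbor enumeration
oracle_expected_sites <- function(codon) {
  aa <- unname(GC_MAP[codon])
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in setdiff(ORACLE_BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      aa2 <- unname(GC_MAP[alt])
      if (aa2 != "*" && aa2 == aa) syn <- syn + 1
    }
    s <- s + syn / 3
  }
  c(s = s, n = 3 - s)
}

sense_codons <- function() {
  cods <- apply(expand.grid(ORACLE_BASES, ORACLE_BASES, ORACLE_BASES), 1,
                paste0, collapse = "")
  sort(cods[GC_MAP[cods] != "*"])
}

# brute-force union length of 0-based half-open intervals
oracle_union_length <- function(iv, L) {
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) {
      covered[(iv$start[i] + 1):iv$end[i]] <- TRUE
    }
  }
  sum(covered)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# build an annotated genome directly from gene coding sequences: genes are
# placed left to right with `spacer` random intergenic bases; minus-strand
# genes are reverse-complemented into the genome
toy_genome <- function(cds_list, strands = NULL, spacer = 10, seed = 99,
                       id = "toy") {
  set.seed(seed)
  if (is.null(strands)) strands <- rep("+", length(cds_list))
  seqs <- character(0)
  starts <- integer(length(cds_list))
  pos <- 0L
  for (i in seq_along(cds_list)) {
    sp <- paste0(sample(ORACLE_BASES, spacer, replace = TRUE), collapse = "")
    cds <- cds_list[[i]]
    g <- if (strands[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    } else cds
    seqs <- c(seqs, sp, g)
    starts[i] <- pos + spacer
    pos <- pos + spacer + nchar(cds)
  }
  tail_sp <- paste0(sample(ORACLE_BASES, spacer, replace = TRUE), collapse = "")
  genes <- data.frame(gene_id = sprintf("g%02d", seq_along(cds_list)),
                      start = starts,
                      end = starts + vapply(cds_list, nchar, 0L),
                      strand = strands, stringsAsFactors = FALSE)
  annotated_genome(id, paste0(c(seqs, tail_sp), collapse = ""), genes)
}

# hand-made population_truth around explicit haplotypes
toy_population <- function(genome, haplotypes, freqs = NULL) {
  n <- length(haplotypes)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  pop <- list(reference = genome,
              lineages = data.frame(
                lineage_id = sprintf("lin_%02d", seq_len(n)),
                sequence = unname(haplotypes), freq = freqs / sum(freqs),
                divergence = NA_real_, stringsAsFactors = FALSE),
              true_variants = data.frame(),
              recomb_events = data.frame(),
              params = list())
  class(pop) <- "population_truth"
  pop
}

# alignment set built directly from (ref_start, aln_seq) pairs against a
# genome, identities recomputed by string comparison
toy_alignment_set <- function(genome, ref_start, aln_seq,
                              read_id = sprintf("r%04d", seq_along(ref_start))) {
  ref <- genome$sequence
  matches <- mapply(function(s, st) {
    w <- substr(ref, st + 1, st + nchar(s))
    sum(strsplit(s, "")[[1]] == strsplit(w, "")[[1]])
  }, aln_seq, ref_start)
  alen <- nchar(aln_seq)
  rec <- data.frame(read_id = read_id, ref_start = ref_start,
                    aligned_len = alen, matches = as.integer(unname(matches)),
                    identity = unname(100 * matches / alen),
                    aln_seq = unname(aln_seq),
                    truth_lineage = NA_character_, stringsAsFactors = FALSE,
                    row.names = NULL)
  alignment_set(genome$id, rec, metagenome_bases = sum(alen),
                metagenome_reads = length(aln_seq),
                mean_read_len = mean(alen))
}

# brute-force correlation profile: double loop over reads and masked-site
# pairs, mirroring the definition rather than the implementation
oracle_corr_profile <- function(aln, mask, genome, max_l) {
  ref <- strsplit(genome$sequence, "")[[1]]
  pair_n <- numeric(max_l)
  pair_sum <- numeric(max_l)
  site_n <- 0
  site_mm <- 0
  for (i in seq_len(nrow(aln$records))) {
    st <- aln$records$ref_start[i]
    s <- strsplit(aln$records$aln_seq[i], "")[[1]]
    in_read <- mask[mask >= st & mask < st + length(s)]
    if (!length(in_read)) next
    x <- integer(length(in_read))
    keep <- logical(length(in_read))
    for (k in seq_along(in_read)) {
      ch <- s[in_read[k] - st + 1]
      keep[k] <- ch %in% ORACLE_BASES
      x[k] <- as.integer(ch != ref[in_read[k] + 1])
    }
    in_read <- in_read[keep]; x <- x[keep]
    site_n <- site_n + length(in_read)
    site_mm <- site_mm + sum(x)
    if (length(in_read) >= 2) {
      for (a in 1:(length(in_read) - 1)) {
        for (b in (a + 1):length(in_read)) {
          l <- in_read[b] - in_read[a]
          if (l <= max_l) {
            pair_n[l] <- pair_n[l] + 1
            pair_sum[l] <- pair_sum[l] + x[a] * x[b]
          }
        }
      }
    }
  }
  list(l = which(pair_n > 0),
       d = pair_sum[pair_n > 0] / pair_n[pair_n > 0],
       n_pairs = pair_n[pair_n > 0],
       d_sample = site_mm / site_n)
}

# connected components of the pairwise identity threshold graph
oracle_cluster_components <- function(seqs, id_threshold, len_threshold) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      lo <- min(nchar(seqs[i]), nchar(seqs[j]))
      hi <- max(nchar(seqs[i]), nchar(seqs[j]))
      if (lo / hi < len_threshold) next
      mm <- oracle_hamming(substr(seqs[i], 1, lo), substr(seqs[j], 1, lo))
      if ((lo - mm) / lo >= id_threshold) adj[i, j] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# random sense-codon CDS of n codons (ATG ... stop)
random_cds <- function(n_codons, seed = 1) {
  set.seed(seed)
  sense <- sense_codons()
  mid <- sample(setdiff(sense, "ATG"), n_codons - 2, replace = TRUE)
  paste0(c("ATG", mid, sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}
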