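# Codon-level polymorphism statistics from recruited alignments: pileups,
# variant calling under count/frequency/coverage filters, expected-site
# normalization, and per-gene / per-genome summaries.

#' Build per-codon pileups from an alignment set
#'
#' One pileup per (gene, codon): counts of observed codons over reads that
#' span all three codon positions (partial overlaps contribute nothing).
#' Minus-strand genes are reported in gene reading frame: observed codons
#' are reverse-complemented and codon indices count from the gene's 5' end.
#'
#' @param aln an [alignment_set], already identity-filtered (and typically
#'   depth-subsampled).
#' @param genome the reference [annotated_genome].
#' @return data.frame with `gene_id`, `codon_index` (0-based, gene frame),
#'   `ref_codon`, `obs_codon`, `count`, `spanning_coverage`.
#' @export
build_codon_pileups <- function(aln, genome) {
  stopifnot(inherits(aln, "alignment_set"), inherits(genome, "annotated_genome"))
  ge <- genome$genes
  if (nrow(ge) && any((ge$end - ge$start) %% 3L != 0L)) {
    bad <- ge$gene_id[(ge$end - ge$start) %% 3L != 0L][1]
    stop("gene frame inconsistency (length not divisible by 3): ", bad)
  }
  L <- nchar(genome$sequence)
  codon_first <- rep(-1L, L)
  # global codon id registry, genome orientation
  n_cod <- sum((ge$end - ge$start) %/% 3L)
  map_gene <- integer(n_cod)
  map_slot <- integer(n_cod)   # genome-orientation slot within gene
  cid <- 0L
  for (i in seq_len(nrow(ge))) {
    nc <- (ge$end[i] - ge$start[i]) %/% 3L
    slots <- seq_len(nc) - 1L
    codon_first[ge$start[i] + 3L * slots + 1L] <- cid + slots
    map_gene[cid + slots + 1L] <- i
    map_slot[cid + slots + 1L] <- slots
    cid <- cid + nc
  }
  if (nrow(aln$records) == 0 || n_cod == 0) {
    return(data.frame(gene_id = character(0), codon_index = integer(0),
                      ref_codon = character(0), obs_codon = character(0),
                      count = integer(0), spanning_coverage = integer(0),
                      stringsAsFactors = FALSE))
  }
  acc <- cpp_codon_pileup(as.integer(aln$records$ref_start),
                          aln$records$aln_seq, codon_first)
  gi <- map_gene[acc$codon_id + 1L]
  slot <- map_slot[acc$codon_id + 1L]
  nc_g <- (ge$end[gi] - ge$start[gi]) %/% 3L
  minus <- ge$strand[gi] == "-"
  codon_index <- ifelse(minus, nc_g - 1L - slot, slot)
  code <- acc$codon_code
  code[minus] <- revcomp_codon_code(code[minus])
  tab <- codon_tables()
  obs <- tab$codons[code + 1L]
  # reference codon in gene frame
  ref_code_genome <- ref_codon_codes(genome, ge, gi, slot)
  ref_code <- ifelse(minus, revcomp_codon_code(ref_code_genome), ref_code_genome)
  out <- data.frame(gene_id = ge$gene_id[gi], codon_index = codon_index,
                    ref_codon = tab$codons[ref_code + 1L], obs_codon = obs,
                    count = acc$count, stringsAsFactors = FALSE)
  key <- paste(out$gene_id, out$codon_index)
  cov <- tapply(out$count, key, sum)
  out$spanning_coverage <- as.integer(cov[key])
  out <- out[order(out$gene_id, out$codon_index, out$obs_codon), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# genome-orientation codon codes of reference codon slots
ref_codon_codes <- function(genome, ge, gi, slot) {
  p <- ge$start[gi] + 3L * slot
  b <- encode_bases(genome$sequence)
  b[p + 1L] * 16L + b[p + 2L] * 4L + b[p + 3L]
}

#' Call codon variants from pileups
#'
#' Emits every alternative codon observed at least `min_count` times, at
#' frequency (relative to codon-spanning reads) at least `min_freq`, at
#' codons with spanning coverage at least `min_cov` — the three validity
#' filters for codon mutations (defaults: 4 observations, 0.1%, 5x; all
#' boundaries inclusive). Several alternative codons at one codon slot may
#' each be emitted. Codons whose reference codon is a stop are skipped.
#'
#' @param pileups output of [build_codon_pileups].
#' @param min_count minimum observation count (default 4).
#' @param min_freq minimum frequency among spanning reads (default 0.001).
#' @param min_cov minimum spanning coverage (default 5).
#' @return data.frame with `gene_id`, `codon_index`, `ref_codon`,
#'   `alt_codon`, `count`, `frequency`, `classification`.
#' @export
call_codon_variants <- function(pileups, min_count = 4, min_freq = 0.001,
                                min_cov = 5) {
  stopifnot(min_count >= 0, min_freq >= 0, min_cov >= 0)
  tab <- codon_tables()
  ref_stop <- tab$is_stop[match(pileups$ref_codon, tab$codons)]
  freq <- pileups$count / pileups$spanning_coverage
  keep <- !ref_stop &
    pileups$obs_codon != pileups$ref_codon &
    pileups$count >= min_count &
    freq >= min_freq &
    pileups$spanning_coverage >= min_cov
  v <- pileups[keep, , drop = FALSE]
  aa_ref <- tab$aa[match(v$ref_codon, tab$codons)]
  aa_alt <- tab$aa[match(v$obs_codon, tab$codons)]
  data.frame(gene_id = v$gene_id, codon_index = v$codon_index,
             ref_codon = v$ref_codon, alt_codon = v$obs_codon,
             count = v$count, frequency = v$count / v$spanning_coverage,
             classification = ifelse(aa_alt == aa_ref, "synonymous",
                                     "nonsynonymous"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene polymorphism statistics
#'
#' For each gene: covered codons (spanning coverage >= `min_cov`, stop
#' reference codons excluded), expected synonymous/nonsynonymous site sums
#' over covered codons, the number of codons with at least one passing
#' synonymous (resp. nonsynonymous) variant — a codon counts once per
#' classification however many alternative codons pass — and the percent of
#' covered nucleotide positions that are polymorphic (any non-reference
#' base passing the count and frequency filters at that position).
#'
#' `pN = 100 * n_nonsyn / N_exp`, `pS = 100 * n_syn / S_exp`,
#' `pnps = pN / pS` (NA when `pS = 0`).
#'
#' @param variants output of [call_codon_variants].
#' @param pileups output of [build_codon_pileups] for the same genes.
#' @param min_cov minimum spanning coverage (default 5).
#' @param min_count,min_freq filters applied at nucleotide level for the
#'   percent-polymorphic-sites computation (defaults as in
#'   [call_codon_variants]).
#' @return data.frame, one row per gene present in `pileups`.
#' @export
gene_stats <- function(variants, pileups, min_cov = 5, min_count = 4,
                       min_freq = 0.001) {
  tab <- codon_tables()
  pil <- pileups[!tab$is_stop[match(pileups$ref_codon, tab$codons)], ,
                 drop = FALSE]
  genes <- unique(pileups$gene_id)
  # one row per codon slot
  ck <- !duplicated(paste(pil$gene_id, pil$codon_index))
  cod <- pil[ck, c("gene_id", "codon_index", "ref_codon", "spanning_coverage")]
  cod$covered <- cod$spanning_coverage >= min_cov
  es <- expected_sites(cod$ref_codon)
  cod$s <- es$s
  cod$n <- es$n

  vkey <- character(0)
  if (nrow(variants)) {
    vc <- variants[variants$classification == "synonymous", ]
    vn <- variants[variants$classification == "nonsynonymous", ]
    syn_codons <- unique(paste(vc$gene_id, vc$codon_index))
    nonsyn_codons <- unique(paste(vn$gene_id, vn$codon_index))
  } else {
    syn_codons <- nonsyn_codons <- character(0)
  }
  codkey <- paste(cod$gene_id, cod$codon_index)
  cod$has_syn <- cod$covered & codkey %in% syn_codons
  cod$has_nonsyn <- cod$covered & codkey %in% nonsyn_codons

  poly_by_gene <- polymorphic_positions(pil, min_cov, min_count, min_freq)

  rows <- lapply(genes, function(g) {
    cg <- cod[cod$gene_id == g, , drop = FALSE]
    ncov <- sum(cg$covered)
    if (ncov == 0) {
      return(data.frame(gene_id = g, covered_codons = 0L,
                        s_exp = NA_real_, n_exp = NA_real_,
                        n_syn_variant_positions = NA_integer_,
                        n_nonsyn_variant_positions = NA_integer_,
                        pn = NA_real_, ps = NA_real_, pnps = NA_real_,
                        pps = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    s_exp <- sum(cg$s[cg$covered])
    n_exp <- sum(cg$n[cg$covered])
    nsv <- sum(cg$has_syn)
    nnv <- sum(cg$has_nonsyn)
    pn <- 100 * nnv / n_exp
    ps <- 100 * nsv / s_exp
    npoly <- if (g %in% names(poly_by_gene)) poly_by_gene[[g]] else 0L
    data.frame(gene_id = g, covered_codons = ncov, s_exp = s_exp,
               n_exp = n_exp, n_syn_variant_positions = nsv,
               n_nonsyn_variant_positions = nnv, pn = pn, ps = ps,
               pnps = if (nsv > 0) pn / ps else NA_real_,
               pps = 100 * npoly / (3 * ncov), flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

# count polymorphic nucleotide positions per gene: a covered position is
# polymorphic if any non-reference base passes the count/frequency filters
polymorphic_positions <- function(pil, min_cov, min_count, min_freq) {
  pil <- pil[pil$spanning_coverage >= min_cov, , drop = FALSE]
  if (nrow(pil) == 0) return(list())
  # explode codons into 3 positions
  long <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(gene_id = pil$gene_id,
               posn = 3L * pil$codon_index + (k - 1L),
               base = substr(pil$obs_codon, k, k),
               ref = substr(pil$ref_codon, k, k),
               count = pil$count,
               cov = pil$spanning_coverage,
               stringsAsFactors = FALSE)
  }))
  alt <- long[long$base != long$ref, , drop = FALSE]
  if (nrow(alt) == 0) return(list())
  key <- paste(alt$gene_id, alt$posn, alt$base)
  cnt <- tapply(alt$count, key, sum)
  cov <- tapply(alt$cov, key, max)
  pass <- cnt >= min_count & cnt / cov >= min_freq
  if (!any(pass)) return(list())
  gp <- unique(do.call(rbind, strsplit(names(cnt)[pass], " "))[, 1:2, drop = FALSE])
  tapply(gp[, 2], gp[, 1], function(x) length(unique(x)))
}

#' Aggregate per-gene statistics to a genome summary
#'
#' Mean percent polymorphic sites over genes, median pN/pS over genes where
#' it is defined, the fraction of genes with pN/pS > 1, mean pN and pS, and
#' the recruitment metrics carried through.
#'
#' @param gene_stats output of [gene_stats].
#' @param rpkg,anir recruitment metrics to carry into the summary row.
#' @param genome_id,sample_id identifiers for the summary row.
#' @return one-row data.frame.
#' @export
aggregate_genome <- function(gene_stats, rpkg = NA_real_, anir = NA_real_,
                             genome_id = NA_character_,
                             sample_id = NA_character_) {
  ok <- !gene_stats$flagged
  if (!any(ok)) stop("no gene with defined statistics")
  g <- gene_stats[ok, , drop = FALSE]
  def <- !is.na(g$pnps)
  data.frame(genome_id = genome_id, sample_id = sample_id,
             n_genes = nrow(g),
             mean_pps = mean(g$pps),
             median_pnps = if (any(def)) median(g$pnps[def]) else NA_real_,
             mean_pn = mean(g$pn), mean_ps = mean(g$ps),
             fraction_pnps_gt1 = if (any(def)) mean(g$pnps[def] > 1) else NA_real_,
             rpkg = as.double(rpkg), anir = as.double(anir),
             stringsAsFactors = FALSE)
}
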