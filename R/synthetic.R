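# Synthetic population generator: an annotated reference, a lineage-structured
# population evolved from it with controlled mutation, selection balance
# (omega) and homologous recombination, and shotgun reads with ground truth.
# All randomness is drawn from R's RNG under the caller-supplied seed; the
# compiled helpers only apply pre-drawn events, so identical seeds give
# identical output at every stage.

#' Generate a synthetic annotated genome
#'
#' Genes are tiled left to right with intergenic spacers: lengths are drawn
#' uniformly from 300--900 bp (multiples of 3), spacers from 50--150 bp.
#' Every gene starts with ATG, contains no in-frame stop and ends with a
#' stop codon; strands are random. Base composition follows `gc`.
#'
#' @param length genome length in bp.
#' @param n_genes number of protein-coding genes.
#' @param gc target GC fraction (default 0.5).
#' @param seed RNG seed; output is byte-identical for identical seeds.
#' @return an [annotated_genome].
#' @export
generate_genome <- function(length, n_genes, gc = 0.5, seed = 1) {
  stopifnot(length > 0, n_genes >= 1, gc > 0, gc < 1)
  # expected footprint ~700 bp per gene (mean gene 600 + mean spacer 100)
  if (n_genes * 700 > length) {
    stop(sprintf(paste0("cannot pack %d genes into %d bp: expected footprint ",
                        "~700 bp/gene allows at most %d genes"),
                 n_genes, length, length %/% 700))
  }
  set.seed(seed)
  glen <- 3L * sample(100:300, n_genes, replace = TRUE)
  spacer <- sample(50:150, n_genes + 1L, replace = TRUE)
  over <- sum(glen) + sum(spacer) - length
  if (over > 0) {  # rare under the capacity rule; shrink genes toward 300 bp
    shrinkable <- glen - 300L
    if (sum(shrinkable) < over) stop("cannot pack genes: capacity exceeded")
    cut <- 3L * (ceiling(over / 3) %/% n_genes + 1L)
    glen <- pmax(300L, glen - cut)
    if (sum(glen) + sum(spacer) > length) stop("cannot pack genes: capacity exceeded")
  }
  pbase <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  tab <- codon_tables()
  sense <- which(!tab$is_stop)  # 1-based indices into 0..63
  codon_p <- vapply(sense, function(i) {
    b <- c((i - 1L) %/% 16L, ((i - 1L) %/% 4L) %% 4L, (i - 1L) %% 4L)
    prod(pbase[b + 1L])
  }, 0)
  codon_p <- codon_p / sum(codon_p)
  stops <- c("TAA", "TAG", "TGA")
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)

  seq_parts <- character(2L * n_genes + 2L)
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    sp <- paste0(BASES[sample.int(4L, spacer[i], replace = TRUE, prob = pbase)],
                 collapse = "")
    n_mid <- glen[i] %/% 3L - 2L
    mid <- paste0(tab$codons[sense[sample.int(length(sense), n_mid,
                                              replace = TRUE, prob = codon_p)]],
                  collapse = "")
    cds <- paste0("ATG", mid, sample(stops, 1L))
    if (strands[i] == "-") cds <- reverse_complement(cds)
    seq_parts[2L * i - 1L] <- sp
    seq_parts[2L * i] <- cds
    starts[i] <- pos + spacer[i]
    pos <- pos + spacer[i] + glen[i]
  }
  sp_last <- paste0(BASES[sample.int(4L, spacer[n_genes + 1L], replace = TRUE,
                                     prob = pbase)], collapse = "")
  tail_len <- length - pos - spacer[n_genes + 1L]
  tail_seq <- if (tail_len > 0) {
    paste0(BASES[sample.int(4L, tail_len, replace = TRUE, prob = pbase)],
           collapse = "")
  } else ""
  seq_parts[2L * n_genes + 1L] <- sp_last
  seq_parts[2L * n_genes + 2L] <- tail_seq
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
                      start = starts, end = starts + glen, strand = strands,
                      stringsAsFactors = FALSE)
  annotated_genome(id = sprintf("synth_g%d", seed),
                   sequence = paste0(seq_parts, collapse = ""), genes = genes)
}

# Per-position codon bookkeeping in gene frame. Returns integer vectors of
# genome length: gene index (0 = intergenic), gene-frame codon code (-1),
# 1-based position within codon, codon index within gene, and a logical for
# minus strand. Later genes win on (malformed) overlaps.
build_codon_maps <- function(genome) {
  L <- nchar(genome$sequence)
  gene_idx <- integer(L)
  codon_code <- rep(-1L, L)
  pos_in_codon <- integer(L)
  codon_index <- rep(-1L, L)
  minus <- logical(L)
  ge <- genome$genes
  for (i in seq_len(nrow(ge))) {
    s <- ge$start[i]; e <- ge$end[i]
    p <- (s + 1L):e                      # 1-based genome positions
    q <- if (ge$strand[i] == "+") (p - 1L) - s else (e - 1L) - (p - 1L)
    cds <- gene_sequence(genome, ge$gene_id[i])
    b <- encode_bases(cds)
    ncod <- length(b) %/% 3L
    codes <- b[seq(1L, by = 3L, length.out = ncod)] * 16L +
      b[seq(2L, by = 3L, length.out = ncod)] * 4L +
      b[seq(3L, by = 3L, length.out = ncod)]
    gene_idx[p] <- i
    codon_index[p] <- q %/% 3L
    pos_in_codon[p] <- q %% 3L + 1L
    codon_code[p] <- codes[q %/% 3L + 1L]
    minus[p] <- ge$strand[i] == "-"
  }
  list(gene_idx = gene_idx, codon_code = codon_code,
       pos_in_codon = pos_in_codon, codon_index = codon_index, minus = minus)
}

# padded lookup of synonymous alternatives: SA[code+1, pos, k], SC[code+1, pos]
syn_alt_matrix <- function() {
  if (!is.null(.codon_env$sa)) return(.codon_env$sa)
  tab <- codon_tables()
  SA <- array(NA_integer_, dim = c(64L, 3L, 3L))
  SC <- matrix(0L, 64L, 3L)
  for (i in 1:64) {
    for (pos in 1:3) {
      alts <- tab$syn_alt[[i]][[pos]]
      SC[i, pos] <- length(alts)
      if (length(alts)) SA[i, pos, seq_along(alts)] <- alts
    }
  }
  .codon_env$sa <- list(SA = SA, SC = SC)
  .codon_env$sa
}

# Draw and classify substitution attempts for one branch (vectorized).
# Returns accepted events: genome position (1-based), new genome-frame base
# code, classification. Attempts on stop reference codons are discarded.
# When `positions` is supplied (1-based), attempts are made exactly there
# (no dedup, the caller owns ordering) and a `keep` index into the input is
# returned alongside.
draw_substitutions <- function(n_attempt, L, maps, omega, ref_int,
                               positions = NULL) {
  explicit <- !is.null(positions)
  if (explicit) {
    pos <- as.integer(positions)
  } else {
    if (n_attempt == 0) {
      return(data.frame(pos = integer(0), new_base = integer(0),
                        class = character(0), stringsAsFactors = FALSE))
    }
    pos <- sample.int(L, n_attempt, replace = TRUE)
    # resolve duplicate positions within the branch: keep the last attempt
    pos <- pos[!duplicated(pos, fromLast = TRUE)]
  }
  tab <- codon_tables()
  sa <- syn_alt_matrix()
  n <- length(pos)
  if (n == 0) {
    if (explicit) {
      return(list(pos = integer(0), new_base = integer(0),
                  class = character(0), keep = integer(0)))
    }
    return(data.frame(pos = integer(0), new_base = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  gidx <- maps$gene_idx[pos]
  coding <- gidx > 0L
  code <- maps$codon_code[pos]
  pic <- maps$pos_in_codon[pos]
  new_base <- integer(n)
  class <- character(n)
  accept <- logical(n)

  # gene-frame reference base at each coding position
  ref_gene_base <- integer(n)
  ref_gene_base[coding] <- extract_codon_base(code[coding], pic[coding])
  d <- sample.int(3L, n, replace = TRUE)  # offset 1..3 among alternatives
  # intergenic: any of the 3 alternatives of the reference base, always kept
  ig <- which(!coding)
  if (length(ig)) {
    new_base[ig] <- (ref_int[pos[ig]] + d[ig]) %% 4L
    class[ig] <- "intergenic"
    accept[ig] <- TRUE
  }
  cd <- which(coding)
  if (length(cd)) {
    stop_ref <- tab$is_stop[code[cd] + 1L]
    alt_gene <- (ref_gene_base[cd] + d[cd]) %% 4L
    syn <- tab$syn_change[cbind(code[cd] + 1L, pic[cd], alt_gene + 1L)]
    u <- runif(length(cd))
    take_nonsyn <- !syn & u < omega
    # rejected nonsynonymous attempts are resampled among synonymous
    # alternatives of the same site (discarded when none exist)
    n_syn_alt <- sa$SC[cbind(code[cd] + 1L, pic[cd])]
    resample <- !syn & !take_nonsyn & n_syn_alt > 0L
    if (any(resample)) {
      k <- 1L + floor(runif(sum(resample)) * n_syn_alt[resample])
      alt_gene[resample] <- sa$SA[cbind(code[cd][resample] + 1L,
                                        pic[cd][resample], k)]
      syn[resample] <- TRUE
    }
    ok <- !stop_ref & (syn | take_nonsyn)
    accept[cd] <- ok
    class[cd] <- ifelse(syn, "synonymous", "nonsynonymous")
    # back to genome frame: complement on the minus strand
    gb <- ifelse(maps$minus[pos[cd]], 3L - alt_gene, alt_gene)
    new_base[cd] <- gb
  }
  if (explicit) {
    return(list(pos = pos[accept], new_base = new_base[accept],
                class = class[accept], keep = which(accept)))
  }
  out <- data.frame(pos = pos[accept], new_base = new_base[accept],
                    class = class[accept], stringsAsFactors = FALSE)
  enforce_codon_chain(out, maps, omega)
}

# Codons hit more than once in one branch: two individually synonymous
# substitutions can combine into a codon encoding a different amino acid
# (e.g. CGA -> AGA -> AGC, Arg -> Ser). Selection sees the protein, so the
# changes are re-examined in order against the evolving codon: a change
# that breaks the whole-codon amino acid is kept with probability omega,
# otherwise dropped. Single-hit codons (the vast majority) are untouched,
# and omega = 1 keeps everything, so this is a no-op there.
enforce_codon_chain <- function(ev, maps, omega) {
  if (omega >= 1 || nrow(ev) < 2) return(ev)
  tab <- codon_tables()
  gidx <- maps$gene_idx[ev$pos]
  coding <- which(gidx > 0L)
  if (length(coding) < 2) return(ev)
  codon_key <- paste(gidx[coding], maps$codon_index[ev$pos[coding]])
  dup_keys <- unique(codon_key[duplicated(codon_key)])
  if (!length(dup_keys)) return(ev)
  drop <- logical(nrow(ev))
  for (k in dup_keys) {
    rows <- coding[codon_key == k]
    p1 <- ev$pos[rows[1]]
    code <- maps$codon_code[p1]
    ref_aa <- tab$aa[code + 1L]
    b <- c(code %/% 16L, (code %/% 4L) %% 4L, code %% 4L)
    for (r in rows) {
      pic <- maps$pos_in_codon[ev$pos[r]]
      alt_gene <- if (maps$minus[ev$pos[r]]) 3L - ev$new_base[r] else ev$new_base[r]
      b2 <- b
      b2[pic] <- alt_gene
      new_aa <- tab$aa[b2[1] * 16L + b2[2] * 4L + b2[3] + 1L]
      if (new_aa != ref_aa && runif(1) >= omega) {
        drop[r] <- TRUE
      } else {
        b <- b2
      }
    }
  }
  ev[!drop, , drop = FALSE]
}

extract_codon_base <- function(code, pic) {
  out <- integer(length(code))
  out[pic == 1L] <- code[pic == 1L] %/% 16L
  out[pic == 2L] <- (code[pic == 2L] %/% 4L) %% 4L
  out[pic == 3L] <- code[pic == 3L] %% 4L
  out
}

#' Evolve a lineage-structured population from a reference genome
#'
#' Each lineage diverges from the reference by point substitutions and,
#' optionally, homologous recombination. An attempted coding substitution
#' that is nonsynonymous is accepted with probability `omega`; otherwise it
#' is resampled among the synonymous alternatives of that site (discarded if
#' none exist). Recombination draws `Poisson(rho_over_theta * mutations)`
#' events per lineage, each copying a geometric fragment (mean `fbar`) from
#' a random donor lineage, applied sequentially in random order.
#'
#' `divergence = "fixed"` gives every lineage `Poisson(theta * L)` attempted
#' substitutions. `divergence = "exponential"` draws a per-lineage branch
#' length from `Exp(mean = theta)` first, emulating the branch-length
#' heterogeneity of a coalescent sample (required for linkage-based
#' recombination inference; see the methods vignette).
#'
#' Alternatively, `phylogeny` (an `ape` "phylo" with branch lengths in
#' substitutions/site) evolves lineages down a fixed tree; recombination is
#' not available in tree mode.
#'
#' @param genome reference [annotated_genome].
#' @param n_lineages number of haplotypes (ignored when `phylogeny` given).
#' @param theta per-site mutational divergence in (0, 0.25].
#' @param omega probability a nonsynonymous attempt is accepted, in `[0,1]`.
#' @param rho_over_theta attempted recombination events per mutation event.
#' @param fbar mean recombined fragment length (bp, >= 100).
#' @param seed RNG seed.
#' @param divergence `"fixed"` or `"exponential"` (see above).
#' @param donor_model `"population"` (default): fragments are copied from a
#'   random co-sampled donor lineage (current state, events applied
#'   sequentially); `"pool"`: each fragment is drawn fresh from an external
#'   gene pool at the same divergence distribution — the regime assumed by
#'   correlation-profile recombination inference (see the methods
#'   vignette).
#' @param lineage_freqs relative lineage frequencies (default: geometric,
#'   `0.8^i`, normalized — uneven strain abundances as seen in situ).
#' @param phylogeny optional `ape` "phylo"; overrides the star model.
#' @return object of class `population_truth`: reference, lineages (with
#'   haplotype sequences and frequencies), `true_variants`, `recomb_events`
#'   and the generating parameters.
#' @export
evolve_population <- function(genome, n_lineages = 10, theta = 0.02,
                              omega = 0.1, rho_over_theta = 0, fbar = 1000,
                              seed = 1, divergence = c("fixed", "exponential"),
                              donor_model = c("population", "pool"),
                              lineage_freqs = NULL, phylogeny = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (theta <= 0 || theta > 0.25) {
    stop("theta must be in (0, 0.25]: beyond that, divergence leaves the ",
         "sequence-discrete regime")
  }
  stopifnot(omega >= 0, omega <= 1, rho_over_theta >= 0, fbar >= 100)
  divergence <- match.arg(divergence)
  donor_model <- match.arg(donor_model)
  set.seed(seed)
  L <- nchar(genome$sequence)
  ref_int <- encode_bases(genome$sequence)
  maps <- build_codon_maps(genome)

  if (!is.null(phylogeny)) {
    if (rho_over_theta > 0) stop("recombination is not available in tree mode")
    res <- evolve_on_tree(phylogeny, ref_int, maps, omega)
    hap <- res$hap
    n_lineages <- ncol(hap)
    lineage_ids <- colnames(hap)
    t_i <- res$depths
    n_mut <- res$n_mut
    if (is.null(lineage_freqs)) lineage_freqs <- rep(1 / n_lineages, n_lineages)
  } else {
    t_i <- switch(divergence,
                  fixed = rep(theta, n_lineages),
                  exponential = rexp(n_lineages, rate = 1 / theta))
    lineage_ids <- sprintf("lineage_%03d", seq_len(n_lineages))
    hap <- matrix(rep(ref_int, n_lineages), ncol = n_lineages,
                  dimnames = list(NULL, lineage_ids))
    n_mut <- integer(n_lineages)
    for (i in seq_len(n_lineages)) {
      ev <- draw_substitutions(rpois(1L, t_i[i] * L), L, maps, omega, ref_int)
      n_mut[i] <- nrow(ev)
      if (nrow(ev)) hap[ev$pos, i] <- ev$new_base
    }
    if (is.null(lineage_freqs)) {
      lineage_freqs <- 0.8^(seq_len(n_lineages) - 1L)
    }
  }
  lineage_freqs <- lineage_freqs / sum(lineage_freqs)
  if (length(lineage_freqs) != n_lineages) {
    stop("lineage_freqs length must equal n_lineages")
  }

  # recombination: draw all events, shuffle globally, apply sequentially.
  # Receipt rate uses the expected mutation count (theta * L) so that
  # receiving recombination is independent of a lineage's own divergence
  # (recombination homogenizes; it must not systematically purge the most
  # divergent content).
  ev_tab <- data.frame(donor = character(0), recipient = integer(0),
                       start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
  if (rho_over_theta > 0 && (n_lineages > 1 || donor_model == "pool")) {
    n_ev <- rpois(n_lineages, rho_over_theta * theta * L)
    recipient <- rep(seq_len(n_lineages), n_ev)
    m <- length(recipient)
    if (m > 0) {
      start <- sample.int(L, m, replace = TRUE)           # 1-based
      len <- rgeom(m, prob = 1 / fbar) + 1L
      end <- pmin(L, start + len - 1L)
      ord <- sample.int(m)
      recipient <- recipient[ord]; start <- start[ord]; end <- end[ord]
      if (donor_model == "population") {
        donor <- sample.int(n_lineages - 1L, m, replace = TRUE)
        donor <- ifelse(donor >= recipient, donor + 1L, donor)
        hap <- cpp_apply_recomb(hap, donor, recipient, start, end)
        donor_lab <- lineage_ids[donor]
      } else {
        # external gene pool: each fragment is the reference plus fresh
        # substitutions at a per-event divergence drawn like a lineage's
        t_ev <- switch(divergence,
                       fixed = rep(theta, m),
                       exponential = rexp(m, rate = 1 / theta))
        flen <- end - start + 1L
        n_sub <- rpois(m, t_ev * flen)
        ev_of_mut <- rep(seq_len(m), n_sub)
        rel <- floor(runif(length(ev_of_mut)) * flen[ev_of_mut])
        mpos <- start[ev_of_mut] + as.integer(rel)        # 1-based position
        sub <- draw_substitutions(0L, L, maps, omega, ref_int,
                                  positions = mpos)
        keep <- sub$keep
        hap <- cpp_apply_pool_recomb(hap, recipient, start, end,
                                     ev_of_mut[keep], sub$pos, sub$new_base,
                                     ref_int)
        donor_lab <- rep("pool", m)
      }
      colnames(hap) <- lineage_ids
      ev_tab <- data.frame(donor = donor_lab, recipient = recipient,
                           start = start, end = end,
                           stringsAsFactors = FALSE)
    }
  }

  truth <- variants_from_haplotypes(hap, ref_int, maps, lineage_ids, genome)
  lineages <- data.frame(lineage_id = lineage_ids,
                         sequence = apply(hap, 2L, decode_bases),
                         freq = lineage_freqs, divergence = t_i,
                         stringsAsFactors = FALSE, row.names = NULL)
  ev_out <- ev_tab
  if (nrow(ev_out)) {
    ev_out$recipient <- lineage_ids[ev_out$recipient]
    ev_out$start <- ev_out$start - 1L   # 0-based half-open in the truth log
  }
  pop <- list(reference = genome, lineages = lineages,
              true_variants = truth,
              recomb_events = ev_out,
              params = list(theta = theta, omega = omega,
                            rho_over_theta = rho_over_theta, fbar = fbar,
                            seed = seed, divergence = divergence,
                            n_accepted_mutations = sum(n_mut)))
  class(pop) <- "population_truth"
  pop
}

# evolve integer haplotypes down an ape tree; tips become lineages
evolve_on_tree <- function(tree, ref_int, maps, omega) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  L <- length(ref_int)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- ref_int
  n_mut <- setNames(integer(n_tip), tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # preorder: parents before children
  edges <- tr$edge
  elen <- tr$edge.length
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    s <- seqs[[par]]
    ev <- draw_substitutions(rpois(1L, elen[k] * L), L, maps, omega, ref_int)
    if (nrow(ev)) s[ev$pos] <- ev$new_base
    seqs[[child]] <- s
    if (child <= n_tip) n_mut[child] <- sum(s != ref_int)
  }
  hap <- do.call(cbind, seqs[seq_len(n_tip)])
  colnames(hap) <- tree$tip.label
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  list(hap = hap, depths = depths, n_mut = n_mut)
}

# final truth table: one row per (position, alt base), with the set of
# lineages carrying it; classification against the reference codon context
variants_from_haplotypes <- function(hap, ref_int, maps, lineage_ids, genome) {
  tab <- codon_tables()
  diffs <- which(hap != ref_int, arr.ind = TRUE)
  if (nrow(diffs) == 0) {
    return(data.frame(pos = integer(0), ref_base = character(0),
                      alt_base = character(0), lineages = character(0),
                      n_lineages = integer(0), class = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  pos <- diffs[, 1]
  lin <- diffs[, 2]
  alt <- hap[diffs]
  key <- paste(pos, alt, sep = ":")
  lin_by_key <- split(lineage_ids[lin], key)
  u <- !duplicated(key)
  pos_u <- pos[u]; alt_u <- alt[u]; key_u <- key[u]
  ord <- order(pos_u, alt_u)
  pos_u <- pos_u[ord]; alt_u <- alt_u[ord]; key_u <- key_u[ord]
  gidx <- maps$gene_idx[pos_u]
  cls <- rep("intergenic", length(pos_u))
  cd <- which(gidx > 0L)
  if (length(cd)) {
    code <- maps$codon_code[pos_u[cd]]
    pic <- maps$pos_in_codon[pos_u[cd]]
    alt_gene <- ifelse(maps$minus[pos_u[cd]], 3L - alt_u[cd], alt_u[cd])
    syn <- tab$syn_change[cbind(code + 1L, pic, alt_gene + 1L)]
    cls[cd] <- ifelse(is.na(syn), "nonsynonymous",
                      ifelse(syn, "synonymous", "nonsynonymous"))
  }
  gene_id <- rep(NA_character_, length(pos_u))
  gene_id[gidx > 0L] <- genome$genes$gene_id[gidx[gidx > 0L]]
  data.frame(pos = pos_u - 1L,
             ref_base = BASES[ref_int[pos_u] + 1L],
             alt_base = BASES[alt_u + 1L],
             lineages = vapply(lin_by_key[key_u],
                               function(x) paste(sort(x), collapse = ","), ""),
             n_lineages = vapply(lin_by_key[key_u], length, 0L),
             class = cls,
             gene_id = gene_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.population_truth <- function(x, ...) {
  cat(sprintf(paste0("<population_truth> %d lineages on %s (%d bp); ",
                     "%d variant alleles, %d recombination events\n"),
              nrow(x$lineages), x$reference$id, nchar(x$reference$sequence),
              nrow(x$true_variants), nrow(x$recomb_events)))
  invisible(x)
}

#' Transfer whole genes between lineages
#'
#' Copies the sequence of each listed gene from a donor lineage into a
#' recipient lineage — the whole-gene homologous transfer used to create
#' known phylogenetic conflicts for congruence analysis.
#'
#' @param pop a `population_truth`.
#' @param gene_ids genes to transfer.
#' @param donor,recipient lineage ids.
#' @return the modified `population_truth`.
#' @export
transfer_genes <- function(pop, gene_ids, donor, recipient) {
  stopifnot(inherits(pop, "population_truth"))
  li <- pop$lineages
  di <- match(donor, li$lineage_id)
  ri <- match(recipient, li$lineage_id)
  if (is.na(di) || is.na(ri)) stop("unknown donor or recipient lineage")
  ge <- pop$reference$genes
  for (g in gene_ids) {
    k <- match(g, ge$gene_id)
    if (is.na(k)) stop("unknown gene: ", g)
    frag <- substr(li$sequence[di], ge$start[k] + 1L, ge$end[k])
    substr(li$sequence[ri], ge$start[k] + 1L, ge$end[k]) <- frag
    pop$recomb_events <- rbind(
      pop$recomb_events,
      data.frame(donor = donor, recipient = recipient,
                 start = ge$start[k], end = ge$end[k]))
  }
  pop$lineages <- li
  # truth table is stale after manual transfer; recompute
  ref_int <- encode_bases(pop$reference$sequence)
  hap <- vapply(li$sequence, encode_bases, integer(nchar(pop$reference$sequence)))
  colnames(hap) <- li$lineage_id
  maps <- build_codon_maps(pop$reference)
  pop$true_variants <- variants_from_haplotypes(hap, ref_int, maps,
                                                li$lineage_id, pop$reference)
  pop
}

#' Simulate shotgun reads from a population
#'
#' Reads are drawn from lineages proportionally to their frequencies, with
#' uniform start positions, optional uniform per-base substitution error and
#' flat Phred qualities consistent with the error rate. The generating
#' lineage and 0-based start are recorded for validation.
#'
#' @param pop a `population_truth`.
#' @param n_reads number of reads (> 0).
#' @param read_len read length in bp.
#' @param err_rate per-base error rate in `[0, 0.05]`.
#' @param seed RNG seed.
#' @return data.frame with `read_id`, `sequence`, `qualities`,
#'   `truth_lineage`, `truth_start`.
#' @export
simulate_reads <- function(pop, n_reads, read_len = 100, err_rate = 0, seed = 1) {
  stopifnot(inherits(pop, "population_truth"))
  if (n_reads <= 0) stop("n_reads must be positive")
  if (err_rate < 0 || err_rate > 0.05) stop("err_rate must be in [0, 0.05]")
  L <- min(nchar(pop$lineages$sequence))
  if (read_len > L) stop("read_len exceeds the shortest haplotype")
  set.seed(seed)
  n_lin <- nrow(pop$lineages)
  lidx <- sample.int(n_lin, n_reads, replace = TRUE, prob = pop$lineages$freq)
  starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
  seqs <- substring(pop$lineages$sequence[lidx], starts, starts + read_len - 1L)
  if (err_rate > 0) {
    nerr <- rbinom(n_reads, read_len, err_rate)
    kmax <- max(nerr)
    k <- 0L
    while (k < kmax) {            # k-th error of each affected read, vectorized
      k <- k + 1L
      idx <- which(nerr >= k)
      p <- sample.int(read_len, length(idx), replace = TRUE)
      cur <- encode_bases(paste0(substr(seqs[idx], p, p), collapse = ""))
      new <- (cur + sample.int(3L, length(idx), replace = TRUE)) %% 4L
      ss <- seqs[idx]
      substr(ss, p, p) <- strsplit(decode_bases(new), "")[[1]]
      seqs[idx] <- ss
    }
  }
  q <- if (err_rate == 0) 40L else max(2L, min(41L, round(-10 * log10(err_rate))))
  qual <- strrep(intToUtf8(q + 33L), read_len)
  data.frame(read_id = sprintf("read_%07d", seq_len(n_reads)),
             sequence = seqs,
             qualities = qual,
             truth_lineage = pop$lineages$lineage_id[lidx],
             truth_start = starts - 1L,
             stringsAsFactors = FALSE)
}

#' Ground-truth summary statistics of a population
#'
#' Computes, directly from the haplotypes (no reads), the same per-gene
#' statistics the read-based pipeline estimates — pN, pS, pN/pS, percent
#' polymorphic sites — plus the identity targets for ANIr: the
#' frequency-weighted mean lineage identity to the reference and the mean
#' pairwise lineage identity.
#'
#' @param pop a `population_truth`.
#' @return list with `gene_table` (per-gene data.frame) and `genome`
#'   (named list of genome-level values).
#' @export
true_summary <- function(pop) {
  stopifnot(inherits(pop, "population_truth"))
  genome <- pop$reference
  tab <- codon_tables()
  ge <- genome$genes
  n_lin <- nrow(pop$lineages)
  rows <- vector("list", nrow(ge))
  for (i in seq_len(nrow(ge))) {
    s <- ge$start[i]; e <- ge$end[i]
    cds <- lapply(pop$lineages$sequence, function(x) {
      g <- substr(x, s + 1L, e)
      if (ge$strand[i] == "-") g <- reverse_complement(g)
      g
    })
    refcds <- gene_sequence(genome, ge$gene_id[i])
    ncod <- nchar(refcds) %/% 3L
    st <- 3L * (seq_len(ncod) - 1L) + 1L
    ref_cod <- substring(refcds, st, st + 2L)
    lin_cod <- vapply(cds, function(x) substring(x, st, st + 2L),
                      character(ncod))
    if (ncod == 1L) lin_cod <- matrix(lin_cod, nrow = 1L)
    sense <- !tab$is_stop[match(ref_cod, tab$codons)]
    es <- expected_sites(ref_cod[sense])
    s_exp <- sum(es$s); n_exp <- sum(es$n)
    ref_aa <- tab$aa[match(ref_cod, tab$codons)]
    n_syn <- 0L; n_nonsyn <- 0L
    for (j in which(sense)) {
      alts <- setdiff(unique(lin_cod[j, ]), ref_cod[j])
      if (!length(alts)) next
      aa <- tab$aa[match(alts, tab$codons)]
      if (any(aa == ref_aa[j])) n_syn <- n_syn + 1L
      if (any(aa != ref_aa[j])) n_nonsyn <- n_nonsyn + 1L
    }
    # nucleotide-level percent polymorphic sites over the sense codons
    glen <- 3L * sum(sense)
    poly <- 0L
    for (j in which(sense)) {
      for (k in 1:3) {
        if (any(substr(lin_cod[j, ], k, k) != substr(ref_cod[j], k, k))) {
          poly <- poly + 1L
        }
      }
    }
    rows[[i]] <- data.frame(
      gene_id = ge$gene_id[i], s_exp = s_exp, n_exp = n_exp,
      n_syn_codons = n_syn, n_nonsyn_codons = n_nonsyn,
      pn = 100 * n_nonsyn / n_exp, ps = 100 * n_syn / s_exp,
      pnps = if (n_syn > 0) (n_nonsyn / n_exp) / (n_syn / s_exp) else NA_real_,
      pps = 100 * poly / glen, stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, rows)
  mm <- cpp_pairwise_mismatch(pop$lineages$sequence, pop$reference$sequence)
  L <- nchar(pop$reference$sequence)
  f <- pop$lineages$freq
  id_ref <- 1 - mm$to_ref / L
  pw <- 1 - mm$pairwise / L
  w <- outer(f, f)
  diag(w) <- 0
  list(gene_table = gt,
       genome = list(
         mean_pps = mean(gt$pps),
         median_pnps = median(gt$pnps, na.rm = TRUE),
         mean_pn = mean(gt$pn), mean_ps = mean(gt$ps),
         mean_identity_to_ref = 100 * sum(f * id_ref),
         mean_pairwise_identity = 100 * sum(w * pw) / sum(w)))
}
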