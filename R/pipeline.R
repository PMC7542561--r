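# End-to-end convenience wrappers: simulate a study, run recruitment,
# microdiversity and recombination on it, and write every result as TSV
# (commented header) plus FASTA/FASTQ/BED/SAM sidecars. All outputs are
# deterministic functions of the parameter list and seed.

#' Simulate a complete synthetic study to disk
#'
#' @param out_dir output directory (created if needed).
#' @param length,n_genes,gc see [generate_genome].
#' @param n_lineages,theta,omega,rho_over_theta,fbar,divergence see
#'   [evolve_population].
#' @param n_reads,read_len,err_rate see [simulate_reads].
#' @param seed RNG seed for all stages.
#' @return invisibly, list with `genome`, `pop`, `reads` and file paths.
#' @export
simulate_study <- function(out_dir, length = 50000, n_genes = 60, gc = 0.45,
                           n_lineages = 10, theta = 0.02, omega = 0.1,
                           rho_over_theta = 0, fbar = 1000,
                           divergence = "fixed", n_reads = 20000,
                           read_len = 100, err_rate = 0, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(length, n_genes, gc, seed = seed)
  pop <- evolve_population(genome, n_lineages = n_lineages, theta = theta,
                           omega = omega, rho_over_theta = rho_over_theta,
                           fbar = fbar, seed = seed + 1L,
                           divergence = divergence)
  reads <- simulate_reads(pop, n_reads = n_reads, read_len = read_len,
                          err_rate = err_rate, seed = seed + 2L)
  write_fasta(data.frame(id = genome$id, sequence = genome$sequence),
              file.path(out_dir, "reference.fasta"))
  write_genes_bed(genome$genes, genome$id, file.path(out_dir, "genes.bed"))
  write_fastq(reads, file.path(out_dir, "reads.fastq"))
  write_tsv_commented(pop$true_variants, file.path(out_dir, "truth.tsv"),
                      "ground-truth variant alleles (0-based positions)")
  write_tsv_commented(pop$recomb_events, file.path(out_dir, "truth_events.tsv"),
                      "ground-truth recombination events (0-based half-open)")
  par <- c(length = length, n_genes = n_genes, gc = gc,
           n_lineages = n_lineages, theta = theta, omega = omega,
           rho_over_theta = rho_over_theta, fbar = fbar,
           n_reads = n_reads, read_len = read_len, err_rate = err_rate,
           seed = seed)
  writeLines(sprintf("%s: %s", names(par), as.character(par)),
             file.path(out_dir, "params.txt"))
  invisible(list(genome = genome, pop = pop, reads = reads, dir = out_dir))
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulates a study (see [simulate_study]), then runs QC, alignment,
#' recruitment metrics (RPKG at the 98%/50 bp cutoff, ANIr at 80%/50 bp),
#' depth subsampling, codon-level microdiversity and correlation-profile
#' recombination inference, writing each stage's tables to `out_dir`.
#'
#' @param out_dir output directory.
#' @param sim named list of arguments for [simulate_study].
#' @param subsample alignment records kept for microdiversity (default 1e6).
#' @param min_identity,min_alen recruitment cutoffs (defaults 98, 50).
#' @param anir_min_identity ANIr recruitment cutoff (default 80).
#' @param min_count,min_freq,min_cov variant filters (defaults 4, 0.001, 5).
#' @param max_l largest correlation-profile distance (default read length - 1).
#' @param seed RNG seed.
#' @return invisibly, list with every intermediate result.
#' @export
run_pipeline <- function(out_dir, sim = list(), subsample = 1e6,
                         min_identity = 98, min_alen = 50,
                         anir_min_identity = 80, min_count = 4,
                         min_freq = 0.001, min_cov = 5, max_l = NULL,
                         seed = 1) {
  sim$out_dir <- out_dir
  sim$seed <- seed
  st <- do.call(simulate_study, sim)
  genome <- st$genome
  reads <- qc_filter_reads(st$reads)
  aln <- align_reads(reads, genome)
  write_sam(aln, genome, file.path(out_dir, "alignments.sam"))

  aln98 <- filter_alignments(aln, min_identity, min_alen)
  aln80 <- filter_alignments(aln, anir_min_identity, min_alen)
  rpkg <- compute_rpkg(aln98, effective_length(genome))
  anir <- compute_anir(aln80)
  write_tsv_commented(
    data.frame(metric = c("rpkg", "anir_median", "anir_mean", "n_recruited_98",
                          "n_recruited_80"),
               value = c(rpkg, anir$anir_median, anir$anir_mean,
                         nrow(aln98$records), nrow(aln80$records))),
    file.path(out_dir, "recruitment.tsv"), "recruitment metrics")
  write_tsv_commented(anir$histogram, file.path(out_dir, "identity_hist.tsv"),
                      "recruited-read identity histogram (1% bins)")

  sub <- suppressWarnings(subsample_alignments(aln98, subsample,
                                               seed = seed + 3L))
  pil <- build_codon_pileups(sub, genome)
  var <- call_codon_variants(pil, min_count, min_freq, min_cov)
  gs <- gene_stats(var, pil, min_cov, min_count, min_freq)
  summ <- aggregate_genome(gs, rpkg = rpkg, anir = anir$anir_median,
                           genome_id = genome$id, sample_id = "sim")
  write_tsv_commented(var, file.path(out_dir, "variants.tsv"),
                      "codon variants passing all filters")
  write_tsv_commented(gs, file.path(out_dir, "gene_stats.tsv"),
                      "per-gene polymorphism statistics")
  write_tsv_commented(summ, file.path(out_dir, "genome_summary.tsv"),
                      "genome-level summary")

  mask <- synonymous_site_mask(genome)
  prof <- correlation_profile(sub, mask, genome, max_l = max_l)
  est <- fit_recombination(prof)
  write_tsv_commented(prof$profile, file.path(out_dir, "profile.tsv"),
                      sprintf("correlation profile; d_sample = %.8g",
                              prof$d_sample))
  write_tsv_commented(
    data.frame(parameter = c("gamma_over_mu", "c", "thetas", "phis",
                             "fbar_hat", "fit_residual", "converged"),
               value = c(est$gamma_over_mu, est$c, est$thetas, est$phis,
                         est$fbar_hat, est$fit_residual,
                         as.numeric(est$converged))),
    file.path(out_dir, "recomb_fit.tsv"), "correlation-profile fit")
  invisible(list(study = st, aln = aln, aln98 = aln98, rpkg = rpkg,
                 anir = anir, pileups = pil, variants = var,
                 gene_stats = gs, summary = summ, profile = prof,
                 recomb = est))
}
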