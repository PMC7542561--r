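# Read recruitment: place reads on a reference, apply identity/length
# cutoffs, and compute the normalized abundance (RPKG) and read-based
# average nucleotide identity (ANIr).

#' Construct an alignment set
#'
#' The shared substrate of recruitment, microdiversity and recombination
#' analyses: reads placed on one reference with per-column base calls.
#' `metagenome_bases`/`metagenome_reads` describe the *source* read set
#' before recruitment — the RPKG denominator — and are deliberately carried
#' unchanged through filtering and subsampling.
#'
#' @param ref_id reference id.
#' @param records data.frame with `read_id`, `ref_start` (0-based),
#'   `aligned_len`, `matches`, `identity`, `aln_seq` (read bases projected
#'   on reference columns; `-` marks a deletion column).
#' @param metagenome_bases total bases in the source read set.
#' @param metagenome_reads total reads in the source read set.
#' @param mean_read_len mean source read length.
#' @return object of class `alignment_set`.
#' @export
alignment_set <- function(ref_id, records, metagenome_bases,
                          metagenome_reads, mean_read_len) {
  stopifnot(is.data.frame(records))
  if (nrow(records) && (any(records$identity < 0) || any(records$identity > 100))) {
    stop("identity outside [0, 100]")
  }
  x <- list(ref_id = ref_id, records = records,
            metagenome_bases = as.double(metagenome_bases),
            metagenome_reads = as.double(metagenome_reads),
            mean_read_len = mean_read_len)
  class(x) <- "alignment_set"
  x
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d records on %s (source: %.0f reads, %.0f bases)\n",
              nrow(x$records), x$ref_id, x$metagenome_reads, x$metagenome_bases))
  invisible(x)
}

#' Align reads to a reference genome
#'
#' Ungapped seed-and-extend placement: exact k-mer seeds vote for a diagonal
#' and the best full-length Hamming placement wins (most matches, ties to
#' the leftmost position, then read order). Masked reference columns are
#' excluded from scoring, and reads whose span is more than half masked are
#' dropped. Each read receives at most one (best) alignment.
#'
#' @param reads data.frame with `sequence` (and optionally `read_id`,
#'   `truth_lineage`); QC is expected to have been applied.
#' @param genome reference [annotated_genome] (mask already set).
#' @param k seed length (default 13).
#' @param step seed spacing along the read (default `k`).
#' @return an [alignment_set]; unalignable reads are absent from `records`
#'   but still counted in the metagenome denominators.
#' @export
align_reads <- function(reads, genome, k = 13, step = k) {
  stopifnot(inherits(genome, "annotated_genome"))
  L <- nchar(genome$sequence)
  empty <- data.frame(read_id = character(0), ref_start = integer(0),
                      aligned_len = integer(0), matches = integer(0),
                      identity = numeric(0), aln_seq = character(0),
                      truth_lineage = character(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0) {
    return(alignment_set(genome$id, empty, 0, 0, NA_real_))
  }
  if (any(nchar(reads$sequence) > L)) stop("genome shorter than a read")
  mk <- reduce_intervals(genome$masked)
  hits <- cpp_align_reads(reads$sequence, genome$sequence, as.integer(k),
                          as.integer(step), as.integer(mk$start),
                          as.integer(mk$end), 0.5)
  idx <- hits$read_idx
  rec <- data.frame(
    read_id = if (!is.null(reads$read_id)) reads$read_id[idx] else
      sprintf("read_%07d", idx),
    ref_start = hits$ref_start,
    aligned_len = hits$aligned_len,
    matches = hits$matches,
    identity = ifelse(hits$aligned_len > 0,
                      100 * hits$matches / hits$aligned_len, NA_real_),
    aln_seq = reads$sequence[idx],
    truth_lineage = if (!is.null(reads$truth_lineage))
      reads$truth_lineage[idx] else NA_character_,
    stringsAsFactors = FALSE)
  alignment_set(genome$id, rec,
                metagenome_bases = sum(nchar(reads$sequence)),
                metagenome_reads = nrow(reads),
                mean_read_len = mean(nchar(reads$sequence)))
}

#' Filter alignments by identity and aligned length
#'
#' Keeps records with `identity >= min_identity` and
#' `aligned_len >= min_alen` (both inclusive, matching the recruitment
#' cutoffs of 98%/50 bp for abundance and microdiversity and 80%/50 bp for
#' ANIr). The metagenome denominators are left unchanged.
#'
#' @param aln an [alignment_set].
#' @param min_identity percent identity cutoff.
#' @param min_alen minimum aligned length (bp).
#' @return the filtered [alignment_set].
#' @export
filter_alignments <- function(aln, min_identity = 98, min_alen = 50) {
  stopifnot(inherits(aln, "alignment_set"))
  keep <- aln$records$identity >= min_identity &
    aln$records$aligned_len >= min_alen
  aln$records <- aln$records[keep, , drop = FALSE]
  row.names(aln$records) <- NULL
  aln
}

#' Subsample alignments to a fixed depth
#'
#' Uniform without-replacement sample of records, deterministic per seed,
#' used to decouple the polymorphism statistics from genome coverage. If
#' `n` exceeds the number of records all are returned with a warning. The
#' metagenome denominators are unchanged.
#'
#' @param aln an [alignment_set].
#' @param n target number of records (>= 1).
#' @param seed RNG seed.
#' @return the subsampled [alignment_set].
#' @export
subsample_alignments <- function(aln, n, seed = 1) {
  stopifnot(inherits(aln, "alignment_set"), n >= 1)
  nr <- nrow(aln$records)
  if (n >= nr) {
    if (n > nr) {
      warning(sprintf("requested %d records but only %d available; returning all",
                      n, nr))
    }
    return(aln)
  }
  set.seed(seed)
  keep <- sort(sample.int(nr, n))
  aln$records <- aln$records[keep, , drop = FALSE]
  row.names(aln$records) <- NULL
  aln
}

#' Reads recruited per kilobase of genome per gigabase of metagenome
#'
#' `norm_mode = "bases"` (the strict definition):
#' `RPKG = n / ((G/1e3) * (B/1e9))` with `G` the unmasked genome length and
#' `B` the total source metagenome bases. `norm_mode = "read_adjusted"`
#' replaces the metagenome term by read count normalized by mean read
#' length, `(B / mean_read_len) / 1e9`, the alternative reading of
#' normalizing a database by its average read size.
#'
#' @param aln a filtered [alignment_set] (98%/50 bp cutoffs applied).
#' @param genome_effective_len unmasked genome length in bp
#'   (see [effective_length]).
#' @param norm_mode `"bases"` (default) or `"read_adjusted"`.
#' @return RPKG value with the mode recorded in attribute `norm_mode`.
#' @export
compute_rpkg <- function(aln, genome_effective_len,
                         norm_mode = c("bases", "read_adjusted")) {
  stopifnot(inherits(aln, "alignment_set"))
  norm_mode <- match.arg(norm_mode)
  if (genome_effective_len <= 0) stop("zero genome length")
  if (aln$metagenome_bases <= 0) stop("zero metagenome size")
  meta_term <- switch(norm_mode,
                      bases = aln$metagenome_bases / 1e9,
                      read_adjusted = (aln$metagenome_bases / aln$mean_read_len) / 1e9)
  rpkg <- nrow(aln$records) / ((genome_effective_len / 1e3) * meta_term)
  attr(rpkg, "norm_mode") <- norm_mode
  rpkg
}

#' Read-based average nucleotide identity (ANIr)
#'
#' Median and mean of per-read percent identities of recruited reads,
#' conventionally after an 80%/50 bp recruitment cutoff, plus an identity
#' histogram in 1% bins over `[80, 100]`.
#'
#' @param aln a filtered [alignment_set].
#' @return list with `anir_median`, `anir_mean`, `n_recruited` and
#'   `histogram` (data.frame `bin_low`, `bin_high`, `count`).
#' @export
compute_anir <- function(aln) {
  stopifnot(inherits(aln, "alignment_set"))
  ids <- aln$records$identity
  if (length(ids) == 0) {
    warning("no recruited reads: ANIr is undefined")
    return(list(anir_median = NA_real_, anir_mean = NA_real_,
                n_recruited = 0L, histogram = anir_hist(numeric(0))))
  }
  list(anir_median = median(ids), anir_mean = mean(ids),
       n_recruited = length(ids), histogram = anir_hist(ids))
}

anir_hist <- function(ids) {
  lows <- 80:99
  counts <- vapply(lows, function(lo) {
    hi <- lo + 1L
    sum(ids >= lo & (ids < hi | (hi == 100 & ids <= 100)))
  }, 0L)
  data.frame(bin_low = lows, bin_high = lows + 1L, count = counts)
}
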