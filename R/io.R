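# Readers and writers for the standard formats the pipeline touches.
# FASTA/FASTQ go through Biostrings, BED/GFF3 through rtracklayer; the
# minimal SAM subset (header + aligned segments, CIGAR M/I/D/S, NM tag) is
# parsed directly since it is part of the package's exchange surface.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return data.frame with columns `id` and `sequence` (uppercased).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("FASTA format error at line 1: empty file")
  if (!startsWith(first, ">")) {
    stop("FASTA format error at line 1: expected '>' header, got: ", first)
  }
  x <- Biostrings::readBStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = toupper(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write records to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(setNames(toupper(records$sequence), records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame with columns `read_id`, `sequence`, `qualities`
#'   (Phred+33 encoded string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `sequence`, `qualities`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$qualities)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Quality-filter reads
#'
#' Keeps reads whose mean Phred score, length and ambiguous-base content pass
#' the thresholds used throughout the package: mean Phred >= 30, length
#' >= 50 bp and no N bases by default. Thresholds are inclusive. The Phred
#' criterion is applied to the mean base quality of the read (a single
#' interpretable scalar; sliding-window trimming is out of scope).
#'
#' @param reads data.frame with `sequence` and (if `min_phred > 0`)
#'   `qualities` columns.
#' @param min_phred minimum mean Phred score (default 30).
#' @param min_len minimum read length in bp (default 50).
#' @param forbid_n drop reads containing any `N` (default TRUE).
#' @return the passing subset of `reads`, input order preserved.
#' @export
qc_filter_reads <- function(reads, min_phred = 30, min_len = 50, forbid_n = TRUE) {
  n0 <- nrow(reads)
  keep <- nchar(reads$sequence) >= min_len
  if (min_phred > 0) {
    if (is.null(reads$qualities) || anyNA(reads$qualities)) {
      stop("reads carry no qualities but min_phred > 0; refusing to pass them silently")
    }
    keep <- keep & cpp_mean_phred(reads$qualities) >= min_phred
  }
  if (forbid_n) keep <- keep & !grepl("N", reads$sequence, fixed = TRUE)
  out <- reads[keep, , drop = FALSE]
  row.names(out) <- NULL
  message(sprintf("qc_filter_reads: kept %d of %d reads (discarded %d)",
                  nrow(out), n0, n0 - nrow(out)))
  out
}

#' Read gene coordinates from BED
#'
#' BED is natively 0-based half-open; columns used are chrom, start, end,
#' name and strand.
#'
#' @param path BED file.
#' @return data.frame with `gene_id`, `start`, `end`, `strand`.
#' @export
read_genes_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = g$name,
             start = BiocGenerics::start(g) - 1L,
             end = BiocGenerics::end(g),
             strand = as.character(BiocGenerics::strand(g)),
             stringsAsFactors = FALSE)
}

#' Write gene coordinates to BED
#'
#' @param genes data.frame with `gene_id`, `start`, `end`, `strand`.
#' @param ref_id reference sequence name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, ref_id, path) {
  df <- data.frame(chrom = ref_id, start = genes$start, end = genes$end,
                   name = genes$gene_id, score = 0L, strand = genes$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene coordinates from GFF3 (CDS features)
#'
#' GFF3 is 1-based closed; coordinates are converted to the package's
#' 0-based half-open convention on read.
#'
#' @param path GFF3 file.
#' @return data.frame with `gene_id`, `start`, `end`, `strand`.
#' @export
read_genes_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "GFF3")
  g <- g[g$type == "CDS"]
  ids <- if (!is.null(g$ID)) as.character(g$ID) else as.character(seq_along(g))
  data.frame(gene_id = ids,
             start = BiocGenerics::start(g) - 1L,
             end = BiocGenerics::end(g),
             strand = as.character(BiocGenerics::strand(g)),
             stringsAsFactors = FALSE)
}

# ---- minimal SAM subset ----------------------------------------------------

#' Write an alignment set to SAM
#'
#' Emits the minimal SAM subset used for interchange: header (`@HD`, `@SQ`)
#' plus one aligned segment per record with an all-`M` CIGAR (the internal
#' aligner is ungapped) and an `NM` tag.
#'
#' @param aln an [alignment_set].
#' @param genome the reference [annotated_genome].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$id, nchar(genome$sequence))),
             con)
  r <- aln$records
  if (nrow(r)) {
    nm <- r$aligned_len - r$matches
    lines <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                     r$read_id, aln$ref_id, r$ref_start + 1L,
                     nchar(r$aln_seq), gsub("-", "N", r$aln_seq), nm)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Import alignments from a minimal SAM file
#'
#' Parses header plus aligned segments with CIGAR operations `M`, `I`, `D`
#' and `S`. Each record is projected onto reference columns: `M` consumes
#' read and reference, `D` inserts a gap column (`-`, scored as mismatch),
#' `I` and `S` consume read bases only. Matches are recomputed against the
#' reference (masked columns excluded from scoring), so `NM` tags are not
#' trusted.
#'
#' @param path SAM file.
#' @param genome reference [annotated_genome]; records on other references
#'   are dropped.
#' @param metagenome_bases,metagenome_reads size of the source read set
#'   before recruitment (the RPKG denominator). If `NULL`, totals are taken
#'   from the imported records themselves, which undercounts the true
#'   metagenome; a warning is issued.
#' @return an [alignment_set].
#' @export
read_sam <- function(path, genome, metagenome_bases = NULL,
                     metagenome_reads = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  recs <- list()
  read_lens <- integer(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM line: ", ln)
    read_lens <- c(read_lens, nchar(f[10]))
    if (f[3] != genome$id || f[6] == "*") next
    proj <- project_cigar(f[10], f[6])
    recs[[length(recs) + 1L]] <- list(read_id = f[1],
                                      ref_start = as.integer(f[4]) - 1L,
                                      aln_seq = proj)
  }
  if (length(recs)) {
    df <- data.frame(read_id = vapply(recs, `[[`, "", "read_id"),
                     ref_start = vapply(recs, `[[`, 0L, "ref_start"),
                     aln_seq = vapply(recs, `[[`, "", "aln_seq"),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(read_id = character(0), ref_start = integer(0),
                     aln_seq = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(metagenome_bases)) {
    warning("metagenome size not supplied; using total imported read bases ",
            "as the RPKG denominator")
    metagenome_bases <- sum(read_lens)
  }
  if (is.null(metagenome_reads)) metagenome_reads <- length(read_lens)
  score <- score_alignments(df$aln_seq, df$ref_start, genome)
  df$aligned_len <- score$aligned_len
  df$matches <- score$matches
  df$identity <- ifelse(df$aligned_len > 0, 100 * df$matches / df$aligned_len, NA_real_)
  alignment_set(ref_id = genome$id, records = df,
                metagenome_bases = metagenome_bases,
                metagenome_reads = metagenome_reads,
                mean_read_len = if (length(read_lens)) mean(read_lens) else NA_real_)
}

# expand CIGAR onto reference columns
project_cigar <- function(seq, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDS]", cigar))[[1]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    stop("unsupported CIGAR (only M/I/D/S): ", cigar)
  }
  out <- character(0)
  rp <- 1L
  for (op in ops) {
    n <- as.integer(sub("[MIDS]", "", op))
    type <- substr(op, nchar(op), nchar(op))
    if (type == "M") {
      out <- c(out, substr(seq, rp, rp + n - 1L))
      rp <- rp + n
    } else if (type == "D") {
      out <- c(out, strrep("-", n))
    } else {  # I or S consume read only
      rp <- rp + n
    }
  }
  paste0(out, collapse = "")
}

# recompute matches / aligned_len for projected alignment strings,
# excluding masked reference columns from both counts
score_alignments <- function(aln_seq, ref_start, genome) {
  if (!length(aln_seq)) return(list(aligned_len = integer(0), matches = integer(0)))
  mk <- reduce_intervals(genome$masked)
  cpp_score_alignments(aln_seq, ref_start, genome$sequence,
                       as.integer(mk$start), as.integer(mk$end))
}

# TSV with a commented header line describing columns
write_tsv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("# columns: ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
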