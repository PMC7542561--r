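# Phylogenetic view of recombination: per-gene neighbor-joining trees
# versus a concatenated reference topology; genes whose tree contains a
# focal bipartition "rescue" it, the rest conflict.

#' Single-copy ortholog selection by greedy identity clustering
#'
#' Greedy clustering in the style of cd-hit: sequences are sorted by
#' decreasing length; each unassigned sequence joins the first cluster
#' whose seed it matches at `>= id_threshold` identity over
#' `>= len_threshold` of the shorter length (anchored, ungapped
#' comparison), otherwise it seeds a new cluster. Only clusters with
#' exactly one member from every genome are returned.
#'
#' @param gene_seqs data.frame with columns `genome`, `gene_id`,
#'   `sequence`.
#' @param id_threshold identity fraction (default 0.70).
#' @param len_threshold length-coverage fraction (default 0.80).
#' @return list of ortholog sets; each is a list with `cluster_id`,
#'   `members` (data.frame) and `alignment_length`.
#' @export
select_single_copy <- function(gene_seqs, id_threshold = 0.70,
                               len_threshold = 0.80) {
  stopifnot(all(c("genome", "gene_id", "sequence") %in% names(gene_seqs)))
  genomes <- sort(unique(gene_seqs$genome))
  if (length(genomes) < 3) stop("need at least 3 genomes")
  gs <- gene_seqs[order(-nchar(gene_seqs$sequence), gene_seqs$genome,
                        gene_seqs$gene_id), , drop = FALSE]
  n <- nrow(gs)
  cluster <- rep(NA_integer_, n)
  seeds <- integer(0)
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    for (ci in seq_along(seeds)) {
      if (pair_identity_ok(gs$sequence[seeds[ci]], gs$sequence[i],
                           id_threshold, len_threshold)) {
        cluster[i] <- ci
        break
      }
    }
    if (is.na(cluster[i])) {
      seeds <- c(seeds, i)
      cluster[i] <- length(seeds)
    }
  }
  out <- list()
  for (ci in seq_along(seeds)) {
    m <- gs[cluster == ci, , drop = FALSE]
    if (nrow(m) != length(genomes)) next
    if (!setequal(m$genome, genomes) || anyDuplicated(m$genome)) next
    m <- m[order(m$genome), , drop = FALSE]
    row.names(m) <- NULL
    out[[length(out) + 1L]] <- list(cluster_id = sprintf("cluster_%03d",
                                                         length(out) + 1L),
                                    members = m,
                                    alignment_length = min(nchar(m$sequence)))
  }
  out
}

# anchored ungapped identity over the shorter sequence; coverage =
# shorter/longer length
pair_identity_ok <- function(a, b, id_threshold, len_threshold) {
  la <- nchar(a); lb <- nchar(b)
  lo <- min(la, lb); hi <- max(la, lb)
  if (lo / hi < len_threshold) return(FALSE)
  mm <- cpp_pairwise_mismatch(c(substr(a, 1, lo)), substr(b, 1, lo))$to_ref[1]
  (lo - mm) / lo >= id_threshold
}

#' Neighbor-joining tree from an alignment
#'
#' Alignment columns with less than `min_site_coverage` non-gap characters
#' are removed, pairwise raw (p) distances are computed and a
#' neighbor-joining tree is built; negative branch lengths are clamped
#' to 0.
#'
#' @param alignment named character vector (one equal-length sequence per
#'   genome).
#' @param min_site_coverage minimum fraction of non-gap characters per
#'   retained column (default 0.8).
#' @return an `ape` "phylo" tree.
#' @export
nj_tree <- function(alignment, min_site_coverage = 0.8) {
  if (length(alignment) < 3) stop("need at least 3 leaves")
  if (length(unique(nchar(alignment))) != 1) {
    stop("alignment sequences must have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  okbase <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  keep <- colMeans(okbase) >= min_site_coverage
  if (!any(keep)) stop("no alignment columns pass the site-coverage filter")
  mat <- mat[, keep, drop = FALSE]
  dn <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(dn, model = "raw", pairwise.deletion = TRUE)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree from concatenated alignments
#'
#' Concatenates alignment columns across gene alignments sharing the same
#' genome names, then calls [nj_tree].
#'
#' @param alignments list of named character vectors.
#' @param min_site_coverage see [nj_tree].
#' @return an `ape` "phylo" tree.
#' @export
concat_tree <- function(alignments, min_site_coverage = 0.8) {
  stopifnot(length(alignments) >= 1)
  nms <- sort(names(alignments[[1]]))
  cat_seq <- setNames(rep("", length(nms)), nms)
  for (al in alignments) {
    if (!setequal(names(al), nms)) stop("alignments must share genome names")
    cat_seq <- paste0(cat_seq, al[nms])
  }
  nj_tree(setNames(cat_seq, nms), min_site_coverage)
}

# non-trivial bipartitions of an unrooted tree as canonical strings: the
# side containing the alphabetically first leaf, sorted and comma-joined
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  first <- min(tips)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- tips[cl]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (!(first %in% side)) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

split_key <- function(side, tips) {
  first <- min(tips)
  if (!(first %in% side)) side <- setdiff(tips, side)
  paste(sort(side), collapse = ",")
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets.
#'
#' @param t1,t2 `ape` "phylo" trees on the same leaf set.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Count gene trees that rescue or conflict with reference branches
#'
#' For each focal bipartition of the reference tree, a gene tree supports
#' ("rescues") it iff the bipartition occurs in the gene tree's bipartition
#' set, and conflicts otherwise. Also reports the Robinson-Foulds distance
#' of each gene tree to the reference.
#'
#' @param gene_trees list of `ape` "phylo" trees.
#' @param reference_tree the reference (e.g. concatenated) tree.
#' @param focal_branches list of leaf-name vectors, one side of each focal
#'   bipartition; `NULL` (default) uses every non-trivial bipartition of
#'   the reference tree.
#' @return object of class `congruence_report`: `branches` (data.frame
#'   `branch`, `n_support`, `n_conflict`) and `per_gene` (data.frame
#'   `tree`, `rf`).
#' @export
congruence_counts <- function(gene_trees, reference_tree,
                              focal_branches = NULL) {
  tips <- sort(reference_tree$tip.label)
  for (i in seq_along(gene_trees)) {
    missing <- setdiff(tips, gene_trees[[i]]$tip.label)
    extra <- setdiff(gene_trees[[i]]$tip.label, tips)
    if (length(missing) || length(extra)) {
      stop("gene tree ", i, " leaf set mismatch; missing: ",
           paste(missing, collapse = ","), "; extra: ",
           paste(extra, collapse = ","))
    }
  }
  ref_bip <- tree_bipartitions(reference_tree)
  focal <- if (is.null(focal_branches)) {
    ref_bip
  } else {
    vapply(focal_branches, split_key, "", tips = tips)
  }
  gene_bips <- lapply(gene_trees, tree_bipartitions)
  support <- vapply(focal, function(b) {
    sum(vapply(gene_bips, function(g) b %in% g, TRUE))
  }, 0L)
  nm <- names(gene_trees)
  if (is.null(nm)) nm <- sprintf("gene_tree_%03d", seq_along(gene_trees))
  out <- list(
    branches = data.frame(branch = unname(focal),
                          n_support = unname(support),
                          n_conflict = length(gene_trees) - unname(support),
                          stringsAsFactors = FALSE),
    per_gene = data.frame(tree = nm,
                          rf = vapply(gene_trees, rf_distance, 0L,
                                      t2 = reference_tree),
                          stringsAsFactors = FALSE))
  class(out) <- "congruence_report"
  out
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("<congruence_report> %d focal branches, %d gene trees\n",
              nrow(x$branches), nrow(x$per_gene)))
  print(x$branches)
  invisible(x)
}
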