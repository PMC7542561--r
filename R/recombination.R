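# Correlation-profile inference of homologous recombination: the
# recombination-to-mutation ratio (gamma/mu) and the recombination coverage
# c (0 = clonal history, 1 = the whole genome has recombined), estimated
# from the joint mismatch structure of synonymous site pairs within reads.

#' Fourfold-degenerate (strictly synonymous) site mask
#'
#' Returns all coding genome positions whose every single-base change is
#' synonymous: the third positions of fourfold-degenerate codons. This is
#' the cleanest site class for recombination inference, since substitutions
#' there carry no selection signal.
#'
#' @param genome an [annotated_genome].
#' @return sorted integer vector of 0-based genome positions.
#' @export
synonymous_site_mask <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  maps <- build_codon_maps(genome)
  sa <- syn_alt_matrix()
  coding <- which(maps$gene_idx > 0L & maps$pos_in_codon == 3L)
  four <- coding[sa$SC[cbind(maps$codon_code[coding] + 1L, 3L)] == 3L]
  sort(four) - 1L
}

#' Correlation profile of synonymous-site mismatches
#'
#' For every distance `l = 1..max_l`, `d(l)` is the mean over reads and
#' masked-site pairs `(i, i + l)` jointly covered by one read of the product
#' of mismatch indicators against the reference; `d_sample` is the mean
#' single-site mismatch over the mask. Linkage between sites appears as an
#' excess of `d(l)` over `d_sample^2` that decays with distance when
#' recombination shuffles fragments.
#'
#' @param aln an [alignment_set] (typically identity-filtered and
#'   subsampled).
#' @param mask positions from [synonymous_site_mask].
#' @param genome the reference [annotated_genome].
#' @param max_l largest within-read distance (default: longest read - 1).
#' @return object of class `correlation_profile`: data.frame `profile`
#'   (`l`, `d`, `n_pairs`) restricted to distances with pairs, plus
#'   `d_sample` and `n_sites`.
#' @export
correlation_profile <- function(aln, mask, genome, max_l = NULL) {
  stopifnot(inherits(aln, "alignment_set"))
  if (length(mask) == 0) stop("empty synonymous-site mask")
  rl <- max(nchar(aln$records$aln_seq), 0L)
  if (is.null(max_l)) max_l <- rl - 1L
  if (max_l >= rl) stop("max_l must be smaller than the read length")
  if (max_l < 1L) stop("max_l must be >= 1")
  res <- cpp_corr_profile(as.integer(aln$records$ref_start),
                          aln$records$aln_seq, genome$sequence,
                          as.integer(mask), as.integer(max_l))
  l <- seq_len(max_l)
  n <- res$pair_n[l + 1L]
  d <- ifelse(n > 0, res$pair_sum[l + 1L] / n, NA_real_)
  out <- list(profile = data.frame(l = l[n > 0], d = d[n > 0],
                                   n_pairs = n[n > 0]),
              d_sample = if (res$site_n > 0) res$site_mm / res$site_n else NA_real_,
              n_sites = res$site_n)
  class(out) <- "correlation_profile"
  out
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile> %d distances, d_sample = %.4g (%.0f site obs)\n",
              nrow(x$profile), x$d_sample, x$n_sites))
  invisible(x)
}

#' Fit recombination parameters to a correlation profile
#'
#' Fits the gene-pool block model of the excess correlation
#' `d(l) = d_sample^2 + V * S(l)` by weighted least squares over a
#' deterministic grid (weights = pair counts; the amplitude `V >= 0`, the
#' between-lineage divergence variance, has a closed form). `S(l)` is the
#' probability that two sites at distance `l` on one read share their
#' ancestral origin when recombination from an external gene pool covers
#' each site at rate `R` with geometric fragments of mean `fbar_hat`
#' (latest event wins); writing `u = exp(-l / fbar_hat)`,
#' `S(l) = exp(-R (2 - u)) + u / (2 - u) * (1 - exp(-R (2 - u)))` — the
#' first term is a pair that fully escaped recombination, the second a
#' pair acquired by one and the same event. The recombination coverage is
#' `c = 1 - exp(-R)` and the recombination-to-mutation ratio is derived as
#' `gamma/mu = R / (d_sample * fbar_hat)`: the per-site event rate per
#' unit of mutational diversity per correlation block. A nonzero `R` is
#' retained only when it improves on the flat (clonal) model by an F
#' ratio of at least 8, which controls false recombination calls on
#' sparse-pair noise; a clonal profile therefore yields
#' `(gamma/mu, c) = (0, 0)`, and a fully recombined one drives `c`
#' toward 1. See the methods vignette for the derivation and the model's
#' assumptions.
#'
#' @param profile a [correlation_profile].
#' @param n_boot optional number of bootstrap resamples of profile rows for
#'   confidence intervals (default 0).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `recombination_estimate` with fields
#'   `gamma_over_mu`, `c`, `thetas` (synonymous diversity), `phis`
#'   (recombinational share of diversity), `fbar_hat`, `fit_residual`,
#'   `converged`, and bootstrap CIs when requested.
#' @export
fit_recombination <- function(profile, n_boot = 0, seed = 1) {
  stopifnot(inherits(profile, "correlation_profile"))
  pr <- profile$profile
  if (nrow(pr) < 10) stop("profile has fewer than 10 distance points")
  est <- fit_profile_model(pr$l, pr$d, pr$n_pairs, profile$d_sample)
  est$n_points <- nrow(pr)
  if (n_boot > 0) {
    set.seed(seed)
    bs <- replicate(n_boot, {
      i <- sample.int(nrow(pr), replace = TRUE)
      e <- fit_profile_model(pr$l[i], pr$d[i], pr$n_pairs[i],
                             profile$d_sample)
      c(gamma_over_mu = e$gamma_over_mu, c = e$c)
    })
    est$ci <- apply(bs, 1L, stats::quantile, probs = c(0.025, 0.975),
                    na.rm = TRUE)
  }
  class(est) <- "recombination_estimate"
  est
}

# Constrained pool-model fit. Excess correlation y(l) = d(l) - d_sample^2
# follows y = V * S(l) where V is the between-lineage divergence variance
# and S(l) the probability two sites at distance l share their ancestral
# origin. Under gene-pool recombination at rate R events covering a site
# (geometric fragments, mean f, latest event wins) this has the closed
# form, writing u = exp(-l/f):
#
#   S(l) = exp(-R (2 - u)) + u / (2 - u) * (1 - exp(-R (2 - u)))
#
# First term: neither site recombined (both keep the lineage's clonal
# history); second: both sites acquired by the same (latest) event. Pairs
# with different origins are uncorrelated and contribute nothing. (R, f)
# are grid-searched deterministically; V >= 0 solves in closed form. The
# recombination coverage is c = 1 - exp(-R). The R = 0 boundary is the
# flat (clonal) model; a nonzero R is retained only when it beats flat by
# an F ratio >= f_gate, which controls false recombination calls on
# sparse-pair noise.
fit_profile_model <- function(l, d, w, d_sample, f_gate = 8) {
  y <- d - d_sample^2
  W <- sum(w)
  v_flat <- max(sum(w * y) / W, 0)
  sse_flat <- sum(w * (y - v_flat)^2)
  rgrid <- exp(seq(log(0.02), log(12), length.out = 60))
  fgrid <- exp(seq(log(5), log(max(l) * 1.5), length.out = 40))
  best <- list(R = 0, f = fgrid[1], V = v_flat, sse = sse_flat)
  for (f in fgrid) {
    u <- exp(-l / f)
    for (R in rgrid) {
      eu <- exp(-R * (2 - u))
      g <- eu + u / (2 - u) * (1 - eu)
      den <- sum(w * g^2)
      V <- if (den > 0) max(sum(w * g * y) / den, 0) else 0
      sse <- sum(w * (y - V * g)^2)
      if (sse < best$sse) best <- list(R = R, f = f, V = V, sse = sse)
    }
  }
  n <- length(l)
  fr <- if (best$sse > 0) {
    ((sse_flat - best$sse) / 2) / (best$sse / max(n - 3, 1))
  } else Inf
  if (fr < f_gate) best <- list(R = 0, f = best$f, V = v_flat,
                                sse = sse_flat)
  c_hat <- 1 - exp(-best$R)
  gamma <- if (best$R > 0 && d_sample > 0) {
    best$R / (d_sample * best$f)
  } else 0
  list(gamma_over_mu = gamma, c = c_hat, thetas = d_sample,
       phis = c_hat * d_sample, fbar_hat = best$f,
       fit_residual = sqrt(best$sse / W), f_ratio = fr,
       lineage_var = best$V, event_rate = best$R,
       converged = is.finite(best$sse))
}

#' @export
print.recombination_estimate <- function(x, ...) {
  cat(sprintf(paste0("<recombination_estimate> gamma/mu = %.3g, c = %.3f, ",
                     "fbar_hat = %.1f bp, residual = %.3g%s\n"),
              x$gamma_over_mu, x$c, x$fbar_hat, x$fit_residual,
              if (!x$converged) " [flagged: no excess correlation]" else ""))
  invisible(x)
}
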