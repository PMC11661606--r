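# Self-contained calibration experiments used by the acceptance checks.
# Each fixes its study conditions (sample sizes, panel design, effect
# sizes) as documented defaults and takes only a seed.

#' Effective-trait-count calibration experiment
#'
#' Runs the permutation estimator on two reference families whose true
#' effective size is known: (a) `k` i.i.d. standard-normal traits, for
#' which the minimum of `k` independent uniform p-values gives the closed
#' form `Meff = 0.05 / (1 - 0.95^(1/k))` (about 9.77 for k = 10), and (b)
#' `k` mutually uncorrelated principal-component scores, for which the
#' effective count is the trait count.
#'
#' @param k traits per family.
#' @param n individuals.
#' @param m null SNPs (the permutation substrate).
#' @param seed RNG seed.
#' @return list with `meff_iid`, `meff_pca`, `closed_form`, `k`, `m`.
#' @export
experiment_meff_calibration <- function(k = 10L, n = 1000L, m = 10000L,
                                        seed = 1L) {
  panel <- simulate_genotypes(n, m, block_size = 25L, seed = seed)
  with_seed(seed + 1L, {
    Y_iid <- matrix(rnorm(n * k), n, k)
    Y_base <- matrix(rnorm(n * 4L * k), n, 4L * k)
  })
  meff_iid <- as.numeric(effective_trait_count(Y_iid, panel, seed = seed + 2L))
  scores <- fit_pca(Y_base)$scores[, seq_len(k), drop = FALSE]
  meff_pca <- as.numeric(effective_trait_count(scores, panel, seed = seed + 3L))
  list(meff_iid = meff_iid, meff_pca = meff_pca,
       closed_form = 0.05 / (1 - 0.95^(1 / k)), k = k, m = m)
}

#' Family-wise error calibration of the group-wide threshold
#'
#' The group-wide threshold `base_alpha / Meff` equals, by construction,
#' the 5th percentile of the per-SNP null distribution of min-p across the
#' trait family (at `base_alpha = 0.05`), so for any null SNP the
#' probability that some trait in the family reaches it is `base_alpha`.
#' The experiment fixes a correlated trait family, estimates `Meff` from a
#' permuted panel, then draws `n_reps` fresh null SNPs and records how
#' often the family's min-p beats the threshold.
#'
#' @param n individuals.
#' @param k traits; generated from `n_factors` shared latent factors plus
#'   noise so the family is genuinely correlated (`Meff < k`).
#' @param n_factors shared factors.
#' @param m_null SNPs used for the Meff permutation null.
#' @param n_reps fresh null SNP replicates.
#' @param base_alpha nominal family-wise level.
#' @param seed RNG seed.
#' @return list with `fwer`, `meff`, `threshold`, `n_reps`, `hits`.
#' @export
experiment_fwer_calibration <- function(n = 1000L, k = 10L, n_factors = 5L,
                                        m_null = 5000L, n_reps = 400L,
                                        base_alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    Z <- matrix(rnorm(n * n_factors), n, n_factors)
    Y <- Z %*% matrix(rnorm(n_factors * k), n_factors, k) +
      matrix(rnorm(n * k), n, k)
  })
  panel <- simulate_genotypes(n, m_null, block_size = 25L, seed = seed + 1L)
  meff <- as.numeric(effective_trait_count(Y, panel, seed = seed + 2L))
  thr <- group_threshold(meff, base_alpha)
  hits <- with_seed(seed + 3L, {
    sum(vapply(seq_len(n_reps), function(r) {
      g <- rbinom(n, 2L, runif(1, 0.1, 0.5))
      if (var(g) == 0) g[1L] <- if (g[1L] > 0L) g[1L] - 1L else 1L
      fit <- gwas_matrix(Y, matrix(g, ncol = 1L), NULL)
      min(fit$p) < thr
    }, logical(1)))
  })
  list(fwer = hits / n_reps, meff = meff, threshold = thr,
       n_reps = n_reps, hits = hits)
}

#' Planted-locus recovery experiment
#'
#' Plants `n_loci` well-separated large-effect causal SNPs (each
#' explaining `effect_var` of the trait variance) on a strong-LD panel,
#' runs the univariate GWAS, calls peaks at the genome-wide threshold, and
#' counts loci whose lead lands within 250 kb of a causal SNP.
#'
#' @param n individuals per replicate.
#' @param m SNPs (5 kb spacing: a 50 Mb chromosome at the defaults).
#' @param n_loci planted causal loci.
#' @param effect_var trait-variance fraction per causal SNP.
#' @param n_seeds replicate count.
#' @param threshold significance threshold for the peak caller.
#' @param seed RNG seed.
#' @return list with `recovered` (per replicate), `n_loci_called`,
#'   `median_recovered`, `n_planted`.
#' @export
experiment_locus_recovery <- function(n = 2000L, m = 10000L, n_loci = 5L,
                                      effect_var = 0.05, n_seeds = 10L,
                                      threshold = 5e-8, seed = 1L) {
  recovered <- integer(n_seeds); called <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    panel <- simulate_genotypes(n, m, block_size = 25L, pool_size = 8L,
                                seed = seed + 31L * s)
    region <- floor(m / n_loci)
    causal <- with_seed(seed + 57L * s, {
      vapply(seq_len(n_loci) - 1L, function(kk) {
        lo <- kk * region + floor(region / 4)
        sample(lo:(lo + floor(region / 2)), 1L)
      }, integer(1))
    })
    y <- with_seed(seed + 77L * s, {
      G <- scale(panel$genotypes[, causal, drop = FALSE])
      as.vector(G %*% rep(sqrt(effect_var), n_loci)) +
        rnorm(n, 0, sqrt(max(1 - n_loci * effect_var, 0.1)))
    })
    fit <- gwas_matrix(matrix(y, ncol = 1L), panel$genotypes)
    peaks <- call_peaks(fit$p[, 1L], panel, threshold)
    called[s] <- nrow(peaks)
    recovered[s] <- sum(vapply(causal, function(cs) {
      any(peaks$chrom == panel$chrom[cs] &
            abs(peaks$lead_pos - panel$pos_bp[cs]) <= 250e3)
    }, logical(1)))
  }
  list(recovered = recovered, n_loci_called = called,
       median_recovered = median(recovered), n_planted = n_loci)
}

#' Heritability-recovery experiment for the LD-score regression estimator
#'
#' Simulates polygenic traits of known SNP heritability on panels with
#' heterogeneous LD (mixed block lengths and founder-pool sizes, so the LD
#' score distribution is dispersed enough to identify the regression
#' slope), runs the GWAS, and regresses the chi-square statistics on
#' in-sample LD scores.
#'
#' @param h2_values true heritabilities to plant.
#' @param n individuals.
#' @param m SNPs.
#' @param n_causal causal SNPs per trait.
#' @param n_seeds replicates (panel + trait redrawn each time).
#' @param window_bp LD-score window.
#' @param seed RNG seed.
#' @return `data.table` with one row per (seed, h2): `h2_true`, `h2_est`,
#'   `intercept`; attribute `"medians"` holds the per-h2 medians.
#' @export
experiment_h2_recovery <- function(h2_values = c(0, 0.3, 0.5), n = 2000L,
                                   m = 20000L, n_causal = 2000L,
                                   n_seeds = 10L, window_bp = 500e3,
                                   seed = 1L) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    panel <- simulate_genotypes(n, m, block_size = c(5L, 50L),
                                pool_size = c(4L, 30L), seed = seed + 101L * s)
    ld <- ld_scores(panel, window_bp = window_bp)
    gsc <- with_seed(seed + 131L * s, {
      causal <- sample.int(m, n_causal)
      G <- scale(panel$genotypes[, causal, drop = FALSE])
      v <- as.vector(G %*% rnorm(n_causal))
      v / sd(v)
    })
    for (h2 in h2_values) {
      y <- with_seed(seed + 151L * s + round(1000 * h2), {
        if (h2 > 0) sqrt(h2) * gsc + rnorm(n, 0, sqrt(1 - h2)) else rnorm(n)
      })
      fit <- gwas_matrix(matrix(y, ncol = 1L), panel$genotypes)
      est <- ldsc_regress((fit$beta / fit$se)[, 1L]^2, ld, N = n, M = m)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        seed = s, h2_true = h2, h2_est = est$h2, intercept = est$intercept)
    }
  }
  out <- data.table::rbindlist(rows)
  med <- out[, list(h2_est = median(h2_est), intercept = median(intercept)),
             by = "h2_true"]
  data.table::setattr(out, "medians", med)
  out
}
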