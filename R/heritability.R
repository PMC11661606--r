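#' Per-SNP LD scores
#'
#' For every SNP `j`, `l_j = sum_k r^2_jk` over all SNPs `k` (including `j`
#' itself) whose position lies within `window_bp` on the same chromosome,
#' with `r^2` the squared sample correlation of allele counts.  Since the
#' self term is exactly 1, `l_j >= 1`.  Computation is chunked so large
#' panels never materialize the full correlation matrix.
#'
#' @param panel a genotype panel.
#' @param window_bp window half-width in bp.
#' @param chunk SNP columns per block of the chunked cross-product.
#' @return a `data.table` with `snp_id`, `chrom`, `pos`, `ld`.
#' @export
ld_scores <- function(panel, window_bp = 1e6, chunk = 512L) {
  G <- panel$genotypes
  n <- nrow(G); m <- ncol(G)
  Xs <- scale(G)
  ld <- numeric(m)
  for (chr in unique(panel$chrom)) {
    cols <- which(panel$chrom == chr)
    pos <- panel$pos_bp[cols]
    for (start in seq(1L, length(cols), by = chunk)) {
      idx <- start:min(start + chunk - 1L, length(cols))
      lo <- findInterval(pos[idx[1]] - window_bp - 1L, pos) + 1L
      hi <- findInterval(pos[idx[length(idx)]] + window_bp, pos)
      nb <- lo:hi
      r <- crossprod(Xs[, cols[idx], drop = FALSE],
                     Xs[, cols[nb], drop = FALSE]) / (n - 1)
      mask <- abs(outer(pos[idx], pos[nb], `-`)) <= window_bp
      ld[cols[idx]] <- rowSums((r^2) * mask)
    }
  }
  data.table::data.table(snp_id = panel$snp_id, chrom = panel$chrom,
                         pos = panel$pos_bp, ld = ld)
}

#' LD-score regression heritability estimate
#'
#' Regresses per-SNP GWAS chi-square statistics on LD scores:
#' under a polygenic additive model `E[chi2_j] = 1 + N h2 l_j / M`, so the
#' weighted least-squares slope times `M / N` estimates the SNP
#' heritability and the intercept (estimated freely, not constrained to 1)
#' exposes confounding.  Weights are `1 / l_j`; standard errors come from a
#' delete-one block jackknife over contiguous SNP blocks.
#'
#' @param chi2 per-SNP chi-square statistics, `(beta/se)^2` from a (meta)
#'   scan.
#' @param ld matching LD scores (vector or [ld_scores()] table).
#' @param N GWAS sample size.
#' @param M number of SNPs the heritability is spread over (defaults to
#'   `length(chi2)`).
#' @param n_blocks jackknife blocks (>= 20).
#' @param trait_id,category labels carried into the result.
#' @return an object of class `h2_estimate`: list with `h2`, `h2_se`,
#'   `intercept`, `intercept_se`, `n_blocks`, `trait_id`, `category`.
#' @export
ldsc_regress <- function(chi2, ld, N, M = length(chi2), n_blocks = 20L,
                         trait_id = "trait", category = NA_character_) {
  if (inherits(ld, "data.frame")) ld <- ld$ld
  stopifnot(length(chi2) == length(ld), N > 0, M > 0)
  if (n_blocks < 20L) stop_arg("`n_blocks` must be >= 20")
  ok <- is.finite(chi2) & is.finite(ld)
  chi2 <- chi2[ok]; ld <- ld[ok]
  m <- length(chi2)
  if (m <= n_blocks) stop_arg("too few SNPs for the jackknife")
  if (var(ld) < .Machine$double.eps) stop_arg("degenerate LD scores: no variance")
  w <- 1 / pmax(ld, 1)
  wls <- function(keep) {
    x <- ld[keep]; y <- chi2[keep]; ww <- w[keep]
    sw <- sum(ww); mx <- sum(ww * x) / sw; my <- sum(ww * y) / sw
    slope <- sum(ww * (x - mx) * (y - my)) / sum(ww * (x - mx)^2)
    c(slope = slope, intercept = my - slope * mx)
  }
  full <- wls(rep(TRUE, m))
  blk <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  jk <- t(vapply(seq_len(n_blocks), function(b) wls(blk != b), numeric(2)))
  jk_se <- sqrt((n_blocks - 1) / n_blocks * colSums(sweep(jk, 2L, colMeans(jk))^2))
  scale_h2 <- M / N
  structure(list(h2 = unname(full["slope"]) * scale_h2,
                 h2_se = unname(jk_se[1]) * scale_h2,
                 intercept = unname(full["intercept"]),
                 intercept_se = unname(jk_se[2]),
                 n_blocks = n_blocks, n_snps = m, N = N, M = M,
                 trait_id = trait_id, category = category),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2_estimate [%s]: h2 = %.3f (SE %.3f), intercept = %.3f (SE %.3f)\n",
              x$trait_id, x$h2, x$h2_se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Heritability of every trait in a family
#'
#' Convenience wrapper: computes `chi2 = (beta/se)^2` per trait from a
#' [family_gwas()] fit and runs [ldsc_regress()] per trait.
#'
#' @param scan a [family_gwas()] result.
#' @param ld [ld_scores()] of the same panel.
#' @param traits the [trait_set()] the scan came from.
#' @param N GWAS sample size (default: median per-SNP meta sample size).
#' @param ... passed to [ldsc_regress()].
#' @return a `data.table` with `trait_id`, `category`, `h2`, `h2_se`,
#'   `intercept`, `intercept_se`.
#' @export
h2_by_trait <- function(scan, ld, traits, N = NULL, ...) {
  N <- N %||% stats::median(scan$n)
  chi2 <- (scan$beta / scan$se)^2
  data.table::rbindlist(lapply(seq_len(ncol(chi2)), function(t) {
    est <- ldsc_regress(chi2[, t], ld, N = N,
                        trait_id = traits$trait_ids[t],
                        category = traits$category, ...)
    data.table::data.table(trait_id = est$trait_id, category = est$category,
                           h2 = est$h2, h2_se = est$h2_se,
                           intercept = est$intercept,
                           intercept_se = est$intercept_se)
  }))
}

#' Compare mean heritability across phenotyping categories
#'
#' All pairwise two-tailed t-tests of mean SNP heritability between
#' categories, Benjamini-Hochberg adjusted across the pairwise family.
#' Categories with fewer than 2 estimates are excluded with a warning.
#'
#' @param estimates data.frame with columns `h2` and `category` (e.g. from
#'   [h2_by_trait()], possibly row-bound across families).
#' @return a `data.table` with one row per category pair: group means, the
#'   t statistic, raw and BH-adjusted p-values.
#' @export
compare_h2_groups <- function(estimates) {
  est <- as.data.frame(estimates)
  stopifnot(all(c("h2", "category") %in% names(est)))
  sizes <- table(est$category)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding singleton group(s): ", paste(small, collapse = ", "))
    est <- est[!est$category %in% small, , drop = FALSE]
  }
  groups <- sort(unique(est$category))
  if (length(groups) < 2L) stop_arg("need at least 2 groups with >= 2 estimates")
  pairs <- combn(groups, 2L)
  out <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(i) {
    a <- est$h2[est$category == pairs[1, i]]
    b <- est$h2[est$category == pairs[2, i]]
    tt <- t.test(a, b)
    data.table::data.table(group_a = pairs[1, i], group_b = pairs[2, i],
                           mean_a = mean(a), mean_b = mean(b),
                           diff = mean(a) - mean(b),
                           t = unname(tt$statistic), p = tt$p.value)
  }))
  out[, p_adj := p.adjust(p, method = "BH")][]
}
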