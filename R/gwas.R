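#' Residualize a genotype vector on covariates
#'
#' Returns the genotype minus its least-squares projection onto the
#' intercept plus covariates; the residual is orthogonal to every covariate
#' column.  With no covariates this is plain mean-centring.
#'
#' @param genotype numeric allele-count vector.
#' @param covariates optional covariate table/matrix (constant columns are
#'   dropped).
#' @return residual vector with attribute `"monomorphic"` set to `TRUE`
#'   when the residual carries (numerically) no variance, flagging the SNP
#'   for downstream skipping.
#' @export
residualize_genotype <- function(genotype, covariates = NULL) {
  n <- length(genotype)
  X <- if (is.null(covariates)) matrix(1, n, 1L)
       else cbind(1, covariate_matrix(covariates))
  r <- qr.resid(qr(X), genotype)
  structure(r, monomorphic = sum(r^2) < n * 1e-12)
}

# Vectorized association core: regress every trait column of Y on every
# covariate-residualized genotype column of G.  Traits are assumed
# covariate-adjusted upstream and are only centred here; SE uses df = n - 2
# (intercept + genotype), matching the two-stage adjust-then-regress design.
gwas_matrix <- function(Y, G, covariates = NULL) {
  Y <- as.matrix(Y); G <- as.matrix(G)
  n <- nrow(G)
  stopifnot(nrow(Y) == n)
  X <- if (is.null(covariates)) matrix(1, n, 1L)
       else cbind(1, covariate_matrix(covariates))
  qx <- qr(X)
  Gr <- G - qr.fitted(qx, G)
  Yc <- scale(Y, scale = FALSE)
  sg <- colSums(Gr^2)
  keep <- sg > n * 1e-12
  sg[!keep] <- NA_real_
  beta <- crossprod(Gr, Yc) / sg                      # M x T
  ssy <- colSums(Yc^2)
  ssr <- pmax(outer(rep(1, length(sg)), ssy) - beta^2 * sg, 0)
  df <- n - 2L
  se <- sqrt(ssr / df / sg)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  p[se == 0] <- NA_real_
  beta[!keep, ] <- NA_real_; se[!keep, ] <- NA_real_; p[!keep, ] <- NA_real_
  list(beta = beta, se = se, p = p, n = n, keep = keep)
}

#' Univariate GWAS of one trait
#'
#' Per SNP: simple linear regression of the (upstream covariate-adjusted)
#' trait on the covariate-residualized additive genotype (0/1/2).  Effect,
#' standard error, and a two-tailed p-value from the t statistic with
#' `n - 2` degrees of freedom.  SNPs whose residual genotype is
#' (numerically) constant are reported as missing records, never silent
#' zeros.
#'
#' @param trait numeric phenotype vector (length = panel individuals).
#' @param panel a [simulate_genotypes()] panel (or any list with a
#'   `genotypes` matrix plus `snp_id`, `chrom`, `pos_bp`).
#' @param covariates optional covariates to residualize the genotypes on.
#' @param trait_id,cohort labels copied into the scan.
#' @return a `data.table` (class `association_scan`) with columns `snp_id`,
#'   `chrom`, `pos`, `beta`, `se`, `p`, `n`, `trait_id`, `cohort`.
#' @export
linear_gwas <- function(trait, panel, covariates = NULL,
                        trait_id = "trait", cohort = "all") {
  if (length(trait) != nrow(panel$genotypes))
    stop_arg("trait length must match the panel")
  fit <- gwas_matrix(matrix(trait, ncol = 1L), panel$genotypes, covariates)
  out <- data.table::data.table(
    snp_id = panel$snp_id, chrom = panel$chrom, pos = panel$pos_bp,
    beta = fit$beta[, 1L], se = fit$se[, 1L], p = fit$p[, 1L],
    n = fit$n, trait_id = trait_id, cohort = cohort)
  data.table::setattr(out, "class", c("association_scan", class(out)))
  out[]
}

#' Inverse-variance-weighted meta-analysis
#'
#' Fixed-effects IVW combination of per-cohort scans: weights `w = 1/se^2`,
#' `beta_meta = sum(w * beta) / sum(w)`, `se_meta = 1 / sqrt(sum(w))`, and a
#' two-tailed normal p-value.  A SNP present (non-missing) in only one
#' cohort passes through unchanged.
#'
#' @param scans list of [linear_gwas()] scans sharing a SNP set.
#' @return a `data.table` (class `meta_scan`) with `snp_id`, `chrom`,
#'   `pos`, `beta`, `se`, `p`, `n`, `n_cohorts`.
#' @export
ivw_meta <- function(scans) {
  if (length(scans) < 1L) stop_arg("need at least one scan")
  ids <- scans[[1]]$snp_id
  for (s in scans[-1]) if (!identical(s$snp_id, ids))
    stop_arg("scans must share an identical SNP set")
  B <- sapply(scans, `[[`, "beta")
  S <- sapply(scans, `[[`, "se")
  N <- sapply(scans, `[[`, "n")
  if (is.null(dim(B))) { B <- matrix(B, ncol = 1); S <- matrix(S, ncol = 1); N <- matrix(N, ncol = 1) }
  W <- 1 / S^2
  W[is.na(W)] <- 0
  B0 <- B; B0[is.na(B0)] <- 0
  sw <- rowSums(W)
  beta <- rowSums(W * B0) / sw
  se <- 1 / sqrt(sw)
  beta[sw == 0] <- NA_real_; se[sw == 0] <- NA_real_
  p <- 2 * pnorm(-abs(beta / se))
  out <- data.table::data.table(
    snp_id = ids, chrom = scans[[1]]$chrom, pos = scans[[1]]$pos,
    beta = beta, se = se, p = p,
    n = rowSums(N * (W > 0)), n_cohorts = rowSums(W > 0))
  data.table::setattr(out, "class", c("meta_scan", class(out)))
  out[]
}

#' Per-cohort GWAS plus meta-analysis for a whole trait family
#'
#' Splits the panel by cohort, runs the vectorized association scan of all
#' traits in each cohort, and IVW-combines cohorts per trait.
#'
#' @param traits a [trait_set()].
#' @param panel genotype panel with a `cohort` field.
#' @param covariates cohort-level covariate table (rows = individuals),
#'   subset per cohort for genotype residualization.
#' @return list with matrices `beta`, `se`, `p` (`M x T`, meta-analysed),
#'   `n` (per-SNP meta sample size) and `per_cohort` fits.
#' @export
family_gwas <- function(traits, panel, covariates = NULL) {
  Y <- traits$values
  stopifnot(nrow(Y) == nrow(panel$genotypes))
  cohorts <- unique(panel$cohort)
  fits <- lapply(cohorts, function(ch) {
    rows <- panel$cohort == ch
    cv <- if (is.null(covariates)) NULL else covariates[rows, , drop = FALSE]
    gwas_matrix(Y[rows, , drop = FALSE], panel$genotypes[rows, , drop = FALSE], cv)
  })
  names(fits) <- cohorts
  W <- lapply(fits, function(f) { w <- 1 / f$se^2; w[is.na(w)] <- 0; w })
  sw <- Reduce(`+`, W)
  bw <- Reduce(`+`, Map(function(f, w) { b <- f$beta; b[is.na(b)] <- 0; b * w }, fits, W))
  beta <- bw / sw
  se <- 1 / sqrt(sw)
  beta[sw == 0] <- NA_real_; se[sw == 0] <- NA_real_
  p <- 2 * pnorm(-abs(beta / se))
  dimnames(p) <- list(panel$snp_id, traits$trait_ids)
  list(beta = beta, se = se, p = p,
       n = rowSums(sapply(fits, function(f) rep(f$n, nrow(beta))) *
                   sapply(W, function(w) (rowSums(w) > 0))),
       per_cohort = fits)
}
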