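#' Min-p aggregation of a trait family's scans
#'
#' Tippett combination: the per-SNP minimum p-value across all univariate
#' traits of one family.
#'
#' @param p a numeric `M x T` matrix of per-SNP p-values (e.g. the `p`
#'   element of [family_gwas()]), or a list of scans with a `p` column
#'   sharing one SNP set.
#' @return numeric vector of per-SNP minimum p-values (NA rows where every
#'   trait is missing).
#' @export
minp_aggregate <- function(p) {
  if (is.list(p) && !is.matrix(p)) {
    if (length(p) == 0L) stop_arg("empty trait family")
    p <- sapply(p, `[[`, "p")
    if (is.null(dim(p))) p <- matrix(p, ncol = 1L)
  }
  if (is.null(dim(p)) || ncol(p) < 1L) stop_arg("empty trait family")
  out <- suppressWarnings(apply(p, 1L, min, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Permutation-based effective number of traits
#'
#' Estimates the number of independent traits in a correlated family: every
#' SNP's genotype vector is independently permuted once (breaking
#' genotype-phenotype association while preserving the trait correlation
#' structure), the family's GWAS is re-run on the permuted panel, and the
#' per-SNP minimum p-values across traits form a null sample.  The
#' effective trait count is `0.05 / quantile(null min-p, 0.05)`; for
#' independent traits this approaches the trait count, and for perfectly
#' duplicated traits it stays near 1.
#'
#' @param traits a [trait_set()] (or numeric `N x T` matrix).
#' @param panel genotype panel supplying the null-scan substrate.
#' @param covariates optional covariates for genotype residualization.
#' @param seed RNG seed for the genotype permutations.
#' @return effective trait count (numeric scalar, >= values near 1) with
#'   attribute `"null_minp"`.
#' @export
effective_trait_count <- function(traits, panel, covariates = NULL, seed = NULL) {
  Y <- if (inherits(traits, "trait_set")) traits$values else as.matrix(traits)
  G <- panel$genotypes
  if (ncol(G) < 100L)
    warning("fewer than 100 SNPs: the 5th-percentile estimate is unstable")
  with_seed(seed, {
    n <- nrow(G)
    Gp <- apply(G, 2L, function(g) g[sample.int(n)])
    fit <- gwas_matrix(Y, Gp, covariates)
    null_minp <- minp_aggregate(fit$p)
    q5 <- quantile(null_minp, 0.05, na.rm = TRUE, names = FALSE)
    structure(0.05 / q5, null_minp = null_minp)
  })
}

#' Group-wide significance threshold
#'
#' Divides the genome-wide significance level by the effective number of
#' traits in the family: `threshold = base_alpha / meff`.
#'
#' @param meff effective trait count (values below 1 are clamped to 1 with
#'   a warning).
#' @param base_alpha genome-wide significance level (default `5e-8`).
#' @return the group-wide threshold.
#' @export
group_threshold <- function(meff, base_alpha = 5e-8) {
  if (meff < 1) {
    warning("effective trait count below 1; clamping to 1")
    meff <- 1
  }
  base_alpha / meff
}

# r^2 between one SNP and a set of SNPs, from panel allele counts.
snp_r2 <- function(panel, lead, others) {
  if (length(others) == 0L) return(numeric(0))
  g <- panel$genotypes
  as.vector(cor(g[, lead], g[, others, drop = FALSE]))^2
}

#' Three-step peak calling
#'
#' Calls loci from a per-SNP p-value vector at a significance threshold:
#'
#' 1. Iteratively take the most significant unassigned significant SNP as
#'    lead and clump with it every significant SNP within +/- `clump_bp` of
#'    the lead, plus those within `ld_bp` whose `r^2` with the lead exceeds
#'    `r2`; repeat until all significant SNPs are assigned.
#' 2. Merge loci whose lead SNPs are within `merge_bp` and in LD
#'    (`r^2 > r2`); the merged locus is led by its lowest-p SNP.
#' 3. Discard loci containing exactly one SNP.
#'
#' Only SNPs below the threshold participate.  Windows are closed intervals
#' in base pairs on the same chromosome; LD is computed from the panel's
#' allele-count correlations.
#'
#' @param p per-SNP p-values (e.g. from [minp_aggregate()]), aligned with
#'   the panel's SNPs.
#' @param panel genotype panel providing positions and the LD reference.
#' @param threshold significance threshold (see [group_threshold()]).
#' @param clump_bp,ld_bp,merge_bp window sizes in bp for steps 1-2.
#' @param r2 LD threshold for clumping and merging.
#' @return a `data.table` of loci: `locus_id`, `chrom`, `lead_snp`,
#'   `lead_pos`, `lead_p`, `n_snps`, `start`, `end`, and a list column
#'   `members` of member SNP ids.  Zero rows when nothing is significant.
#' @export
call_peaks <- function(p, panel, threshold,
                       clump_bp = 250e3, ld_bp = 1e6, merge_bp = 10e6,
                       r2 = 0.01) {
  stopifnot(length(p) == length(panel$pos_bp))
  sig <- which(!is.na(p) & p < threshold)
  empty <- data.table::data.table(
    locus_id = integer(0), chrom = character(0), lead_snp = character(0),
    lead_pos = integer(0), lead_p = numeric(0), n_snps = integer(0),
    start = integer(0), end = integer(0), members = list())
  if (length(sig) == 0L) return(empty)
  # order significant SNPs by (p, position index) for deterministic leads
  remaining <- sig[order(p[sig], sig)]
  loci <- list()
  while (length(remaining) > 0L) {
    lead <- remaining[1L]
    same_chr <- remaining[panel$chrom[remaining] == panel$chrom[lead]]
    dist <- abs(panel$pos_bp[same_chr] - panel$pos_bp[lead])
    near <- same_chr[dist <= clump_bp]
    ldwin <- same_chr[dist > clump_bp & dist <= ld_bp]
    inld <- ldwin[snp_r2(panel, lead, ldwin) > r2]
    members <- sort(unique(c(lead, near, inld)))
    loci[[length(loci) + 1L]] <- list(lead = lead, members = members)
    remaining <- setdiff(remaining, members)
  }
  # step 2: merge leads within merge_bp and in LD (iterate to closure)
  repeat {
    merged <- FALSE
    if (length(loci) >= 2L) {
      for (i in seq_along(loci)) {
        for (j in seq_along(loci)) {
          if (j <= i) next
          li <- loci[[i]]$lead; lj <- loci[[j]]$lead
          if (panel$chrom[li] != panel$chrom[lj]) next
          if (abs(panel$pos_bp[li] - panel$pos_bp[lj]) > merge_bp) next
          if (snp_r2(panel, li, lj) <= r2) next
          mem <- sort(unique(c(loci[[i]]$members, loci[[j]]$members)))
          lead <- mem[which.min(p[mem])]
          loci[[i]] <- list(lead = lead, members = mem)
          loci[[j]] <- NULL
          merged <- TRUE
          break
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  # step 3: single-SNP peaks are disregarded
  loci <- Filter(function(l) length(l$members) > 1L, loci)
  if (length(loci) == 0L) return(empty)
  out <- data.table::rbindlist(lapply(seq_along(loci), function(i) {
    l <- loci[[i]]
    data.table::data.table(
      locus_id = i, chrom = panel$chrom[l$lead],
      lead_snp = panel$snp_id[l$lead], lead_pos = panel$pos_bp[l$lead],
      lead_p = p[l$lead], n_snps = length(l$members),
      start = min(panel$pos_bp[l$members]), end = max(panel$pos_bp[l$members]),
      members = list(panel$snp_id[l$members]))
  }))
  out[order(out$lead_p)][, locus_id := .I][]
}

#' Locus overlap between two phenotyping strategies
#'
#' A locus of one list is shared when some lead SNP of the other list lies
#' within `window` bp on the same chromosome.  Matching is greedy by
#' ascending lead p-value with each lead matched at most once (nearest
#' unmatched candidate wins), and
#' `IoU = shared / (|A| + |B| - shared)`.
#'
#' @param loci_a,loci_b [call_peaks()] locus tables.
#' @param window matching window in bp (default 250 kb).
#' @return list with `n_shared`, `n_union`, `iou`, and the matched `pairs`
#'   table.
#' @export
locus_overlap <- function(loci_a, loci_b, window = 250e3) {
  na <- nrow(loci_a); nb <- nrow(loci_b)
  pairs <- data.table::data.table(lead_a = character(0), lead_b = character(0),
                                  dist = numeric(0))
  if (na > 0L && nb > 0L) {
    used_b <- rep(FALSE, nb)
    ord <- order(loci_a$lead_p)
    for (i in ord) {
      cand <- which(!used_b & loci_b$chrom == loci_a$chrom[i] &
                    abs(loci_b$lead_pos - loci_a$lead_pos[i]) <= window)
      if (length(cand) == 0L) next
      j <- cand[which.min(abs(loci_b$lead_pos[cand] - loci_a$lead_pos[i]))]
      used_b[j] <- TRUE
      pairs <- rbind(pairs, data.table::data.table(
        lead_a = loci_a$lead_snp[i], lead_b = loci_b$lead_snp[j],
        dist = abs(loci_b$lead_pos[j] - loci_a$lead_pos[i])))
    }
  }
  shared <- nrow(pairs)
  n_union <- na + nb - shared
  list(n_shared = shared, n_union = n_union,
       iou = if (n_union == 0L) 1 else shared / n_union,
       pairs = pairs)
}

#' Discovery-rate curve for one trait family
#'
#' Re-runs the aggregation pipeline over increasing trait-subset sizes: for
#' each size, traits are selected per the family's convention (ordered
#' families - `PCA` in component order, `EXTREME` in extremeness rank -
#' take the first `k`; unordered families draw a random subset per
#' replicate), the effective trait count and group-wide threshold are
#' recomputed, peaks are called on the min-p scan, and the locus count is
#' recorded.  For the `PCA` family the effective trait count is the trait
#' count itself, since the scores are mutually uncorrelated.
#'
#' @param traits a [trait_set()] for the family.
#' @param panel genotype panel.
#' @param covariates covariates for genotype residualization.
#' @param trait_counts increasing subset sizes (each <= number of traits).
#' @param n_replicates random-subset replicates for unordered families
#'   (forced to 1 for ordered ones).
#' @param base_alpha genome-wide significance level.
#' @param seed RNG seed.
#' @param scan optional precomputed [family_gwas()] result for all traits
#'   (avoids refitting).
#' @param ... window/LD settings passed to [call_peaks()].
#' @return a `data.table` with one row per (size, replicate):
#'   `n_traits`, `replicate`, `meff`, `threshold`, `n_loci`.
#' @export
discovery_curve <- function(traits, panel, covariates = NULL, trait_counts,
                            n_replicates = 1L, base_alpha = 5e-8, seed = NULL,
                            scan = NULL, ...) {
  T_all <- n_traits(traits)
  if (any(trait_counts > T_all)) stop_arg("`trait_counts` exceed available traits")
  ordered_family <- traits$category %in% c("PCA", "EXTREME")
  if (ordered_family) n_replicates <- 1L
  scan <- scan %||% family_gwas(traits, panel, covariates)
  rows <- list()
  with_seed(seed, {
    for (k in trait_counts) {
      for (rep_i in seq_len(n_replicates)) {
        cols <- if (ordered_family) seq_len(k) else sample.int(T_all, k)
        sub <- subset_traits(traits, cols)
        meff <- if (traits$category == "PCA") as.numeric(k)
                else as.numeric(effective_trait_count(sub, panel, covariates))
        thr <- group_threshold(meff, base_alpha)
        minp <- minp_aggregate(scan$p[, cols, drop = FALSE])
        peaks <- call_peaks(minp, panel, thr, ...)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          n_traits = k, replicate = rep_i, meff = meff,
          threshold = thr, n_loci = nrow(peaks))
      }
    }
  })
  data.table::rbindlist(rows)
}

#' Phenotypic variance explained by a trait family
#'
#' Partial least-squares regression of the flattened shape coordinates on
#' the family's trait matrix; the cumulative variance of all PLS components
#' is the fraction of total shape variance the traits explain.
#'
#' @param traits a [trait_set()] (or numeric matrix).
#' @param meshes a [mesh_config] of the same individuals.
#' @param n_components number of PLS components; default
#'   `min(T, N - 1)`.
#' @return scalar fraction in `[0, 1]`.
#' @export
variance_explained <- function(traits, meshes, n_components = NULL) {
  X <- if (inherits(traits, "trait_set")) traits$values else as.matrix(traits)
  Y <- if (inherits(meshes, "mesh_config")) flatten_coords(meshes$coords) else as.matrix(meshes)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  ncomp <- n_components %||% min(ncol(X), n - 1L)
  ncomp <- min(ncomp, ncol(X), n - 1L)
  fit <- simpls_fit(X, Y, ncomp)
  Yc <- scale(Y, scale = FALSE)
  1 - sum((Yc - scale(fit$fitted, scale = FALSE))^2) / sum(Yc^2)
}
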