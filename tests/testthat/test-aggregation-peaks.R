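test_that("min-p aggregation is the elementwise minimum", {
  p <- rbind(c(0.3, 0.01, 0.2), c(0.5, 0.9, 0.04))
  expect_equal(minp_aggregate(p), c(0.01, 0.04))
  expect_equal(minp_aggregate(p[, 1, drop = FALSE]), p[, 1])
  expect_equal(minp_aggregate(cbind(p, p[, 2])), minp_aggregate(p))
  expect_error(minp_aggregate(matrix(0, 2, 0)), "empty")
})

test_that("effective trait count is ~1 for a single or duplicated trait", {
  set.seed(1)
  panel <- simulate_genotypes(400, 4000, block_size = 10, seed = 2)
  y <- rnorm(400)
  m1 <- as.numeric(effective_trait_count(matrix(y, ncol = 1), panel, seed = 3))
  expect_lt(abs(m1 - 1), 0.2)
  md <- as.numeric(effective_trait_count(matrix(rep(y, 8), ncol = 8), panel, seed = 4))
  expect_lt(abs(md - 1), 0.2)
  expect_warning(effective_trait_count(matrix(rnorm(50), ncol = 1),
                                       simulate_genotypes(50, 60, seed = 5), seed = 6),
                 "100 SNPs")
})

test_that("effective trait count grows with independent traits", {
  set.seed(7)
  panel <- simulate_genotypes(400, 4000, block_size = 10, seed = 8)
  Y2 <- matrix(rnorm(400 * 2), ncol = 2)
  Y6 <- cbind(Y2, matrix(rnorm(400 * 4), ncol = 4))
  m2 <- as.numeric(effective_trait_count(Y2, panel, seed = 9))
  m6 <- as.numeric(effective_trait_count(Y6, panel, seed = 9))
  expect_gt(m6, m2)
})

test_that("group-wide threshold is base alpha over Meff", {
  expect_equal(group_threshold(10, 5e-8), 5e-9)
  expect_equal(group_threshold(1), 5e-8)
  expect_equal(group_threshold(5, 0.05), 0.01)
  expect_warning(thr <- group_threshold(0.7, 0.05), "clamp")
  expect_equal(thr, 0.05)
})

# A panel with hand-controlled positions and LD for exercising the peak
# caller: column j of `geno` at position pos[j]; duplicated columns give
# r^2 = 1, independent draws give r^2 ~ 0.
toy_panel <- function(pos, geno, chrom = rep("chr1", length(pos))) {
  structure(list(genotypes = geno, snp_id = sprintf("s%02d", seq_along(pos)),
                 chrom = chrom, pos_bp = as.integer(pos),
                 maf = rep(0.3, length(pos)), block = NULL,
                 cohort = rep("US", nrow(geno))),
            class = "genotype_panel")
}

test_that("peak calling follows the three-step rules on constructed scans", {
  set.seed(10)
  n <- 200
  g <- function() rbinom(n, 2, 0.3)
  # two clusters 5 Mb apart (3 SNPs each, within 250 kb), one isolated SNP
  pos <- c(1e6, 1.1e6, 1.2e6, 6e6, 6.1e6, 6.2e6, 20e6)
  geno <- cbind(g(), g(), g(), g(), g(), g(), g())
  pan <- toy_panel(pos, geno)
  p <- c(1e-10, 1e-9, 1e-8, 1e-12, 1e-7, 1e-9, 1e-15)
  pk <- call_peaks(p, pan, threshold = 1e-6)
  expect_equal(nrow(pk), 2L)                      # isolated SNP dropped (step 3)
  expect_setequal(pk$lead_snp, c("s01", "s04"))
  expect_equal(sort(unlist(pk$members)), sort(pan$snp_id[1:6]))

  # brute-force re-application of the clumping rule
  sig <- which(p < 1e-6)
  oracle_members <- lapply(c(4, 1), function(lead) {
    sig[abs(pos[sig] - pos[lead]) <= 250e3 |
        (abs(pos[sig] - pos[lead]) <= 1e6 &
           cor(geno[, lead], geno[, sig])^2 > 0.01)]
  })
  expect_equal(sort(unlist(pk$members)),
               sort(pan$snp_id[unique(unlist(oracle_members))]))

  # no significant SNP: empty result, not an error
  expect_equal(nrow(call_peaks(p, pan, threshold = 1e-20)), 0L)
  # one isolated significant SNP: zero loci after step 3
  expect_equal(nrow(call_peaks(c(1, 1, 1, 1, 1, 1, 1e-15), pan, 1e-6)), 0L)
})

test_that("LD pulls distant significant SNPs into the lead's locus and merges loci", {
  set.seed(11)
  n <- 300
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  # s1 lead; s2 at 800 kb in perfect LD (within 1 Mb, r2 = 1); s3 at 800 kb
  # independent; s4/s5 a second locus 8 Mb away in perfect LD with s1
  pos <- c(1e6, 1.8e6, 0.2e6, 9e6, 9.05e6)
  geno <- cbind(g1, g1, g2, g1, g1)
  pan <- toy_panel(pos, geno)
  p <- c(1e-12, 1e-8, 1e-8, 1e-10, 1e-9)
  pk <- call_peaks(p, pan, threshold = 1e-6)
  # step 2 merges the two LD-linked loci into one led by s1; s3 falls
  # outside 250 kb? (no: 0.8 Mb away, independent) -> own single-SNP locus
  # dropped by step 3
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$lead_snp, "s01")
  expect_setequal(unlist(pk$members), c("s01", "s02", "s04", "s05"))
})

test_that("peak calling is invariant to SNP input order", {
  set.seed(12)
  n <- 150
  m <- 40
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m)
  pos <- sort(sample.int(30e6, m))
  p <- runif(m); p[c(5, 6, 20, 21)] <- 1e-12
  pan <- toy_panel(pos, geno)
  pk1 <- call_peaks(p, pan, 1e-6)
  ord <- sample.int(m)
  pan2 <- toy_panel(pos[ord], geno[, ord])
  pan2$snp_id <- pan$snp_id[ord]
  pk2 <- call_peaks(p[ord], pan2, 1e-6)
  expect_setequal(pk1$lead_snp, pk2$lead_snp)
  expect_equal(sort(unlist(pk1$members)), sort(unlist(pk2$members)))
})

test_that("locus overlap counts shared leads within the window", {
  mk <- function(chrom, pos, p) data.table::data.table(
    locus_id = seq_along(pos), chrom = chrom, lead_snp = sprintf("L%d", seq_along(pos)),
    lead_pos = pos, lead_p = p, n_snps = 2L, start = pos - 1, end = pos + 1)
  a <- mk("chr1", c(1.0e6, 5.0e6), c(1e-10, 1e-9))
  b <- mk("chr1", c(1.2e6, 9.0e6), c(1e-8, 1e-12))
  ov <- locus_overlap(a, b)
  expect_equal(ov$n_shared, 1L)
  expect_equal(ov$n_union, 3L)
  expect_equal(ov$iou, 1 / 3)

  expect_equal(locus_overlap(a, a)$iou, 1)
  b2 <- mk("chr2", c(1.0e6, 5.0e6), c(1e-8, 1e-8))
  expect_equal(locus_overlap(a, b2)$iou, 0)
})

test_that("discovery curve: degenerate grid equals the direct pipeline run and PCA Meff is exact", {
  fx <- tiny_cohort(n = 200, m = 300, seed = 30, h2 = 0.8)
  traits <- pca_traits(fit_pca(fx$cohort$meshes), k = 4)
  scan <- family_gwas(traits, fx$panel, fx$covars)
  dc <- discovery_curve(traits, fx$panel, fx$covars, trait_counts = c(2, 4),
                        base_alpha = 1e-4, seed = 31, scan = scan)
  expect_equal(dc$meff, c(2, 4))
  direct <- call_peaks(minp_aggregate(scan$p), fx$panel, group_threshold(4, 1e-4))
  expect_equal(dc$n_loci[dc$n_traits == 4], nrow(direct))

  # a fully null family at a stringent threshold finds nothing
  set.seed(32)
  null_traits <- trait_set(matrix(rnorm(200 * 3), 200, 3), "RANDOM")
  dcn <- discovery_curve(null_traits, fx$panel, fx$covars, trait_counts = 3,
                         base_alpha = 5e-8, seed = 33)
  expect_equal(dcn$n_loci, 0L)
})

test_that("variance explained by trait families matches its PCA oracle limits", {
  set.seed(34)
  n <- 200; L <- 6
  X <- matrix(rnorm(n * 3 * L), n, 3 * L) %*% diag(rep(c(3, 1), each = 9))
  meshes <- mesh_config(unflatten_coords(X, L))
  sp <- fit_pca(X)
  full <- variance_explained(sp$scores, meshes)
  expect_gt(full, 0.999)
  # traits spanning exactly the top-2 PCs explain the top-2 variance share
  top2 <- variance_explained(sp$scores[, 1:2], meshes)
  expect_equal(top2, sum(sp$axis_variance[1:2]) / sum(sp$axis_variance),
               tolerance = 1e-6)
  # fresh noise traits explain (almost) nothing at large N
  set.seed(35)
  Xn <- matrix(rnorm(2000 * 9), 2000, 9)
  noise <- matrix(rnorm(2000 * 5), 2000, 5)
  expect_lt(variance_explained(noise, mesh_config(unflatten_coords(Xn, 3))), 0.05)
})
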