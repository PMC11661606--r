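#' Simulate a diploid genotype panel with block LD
#'
#' Genotypes are additive allele counts in \{0, 1, 2\}.  Linkage
#' disequilibrium is generated by haplotype copying: SNPs are grouped into
#' blocks of `block_size`, each block carries a small pool of founder
#' haplotypes, and every individual draws two haplotypes per block, so SNPs
#' within a block are correlated while blocks are mutually independent.
#' Monomorphic columns are redrawn, so no monomorphic SNP is emitted.
#'
#' @param n number of individuals (>= 2).
#' @param m number of SNPs (>= 1).
#' @param block_size SNPs per LD block; either a scalar (uniform blocks) or
#'   a length-2 range from which each block's length is drawn, producing
#'   heterogeneous LD.
#' @param maf_range interval for the generating minor-allele frequency; the
#'   `maf` field records this generating frequency, which lies inside the
#'   interval by construction.
#' @param n_chrom number of synthetic chromosomes; SNPs are split evenly.
#' @param spacing_bp base-pair spacing between adjacent SNPs (1-based
#'   positions, strictly increasing within a chromosome).
#' @param pool_size founder haplotypes per block; smaller pools give
#'   stronger within-block LD.  A length-2 range draws a pool size per
#'   block, spreading the per-SNP LD score distribution the way real
#'   genomes mix strong- and weak-LD regions.
#' @param cohorts character vector of cohort labels; individuals are split
#'   evenly across them in order.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return an object of class `genotype_panel` with fields `genotypes`
#'   (`n x m` integer matrix), `snp_id`, `chrom`, `pos_bp`, `maf`, `block`,
#'   and `cohort` (per individual).
#' @export
simulate_genotypes <- function(n, m, block_size = 25L,
                               maf_range = c(0.05, 0.5),
                               n_chrom = 1L, spacing_bp = 5000L,
                               pool_size = 20L,
                               cohorts = c("US", "UK"), seed = NULL) {
  if (n < 2L) stop_arg("`n` must be >= 2")
  if (m < 1L) stop_arg("`m` must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_arg("`maf_range` must satisfy 0 < low <= high <= 0.5")
  with_seed(seed, {
    if (length(block_size) == 1L) {
      block <- ceiling(seq_len(m) / block_size)
    } else {
      lens <- integer(0)
      while (sum(lens) < m)
        lens <- c(lens, sample(block_size[1]:block_size[2], 1L))
      block <- rep(seq_along(lens), lens)[seq_len(m)]
    }
    geno <- matrix(0L, n, m)
    maf <- numeric(m)
    for (b in unique(block)) {
      cols <- which(block == b)
      pool <- if (length(pool_size) == 1L) pool_size
              else sample(pool_size[1]:pool_size[2], 1L)
      h1 <- sample.int(pool, n, replace = TRUE)
      h2 <- sample.int(pool, n, replace = TRUE)
      for (j in cols) {
        p <- runif(1, maf_range[1], maf_range[2])
        for (try in 1:100) {
          hap <- rbinom(pool, 1L, p)
          g <- hap[h1] + hap[h2]
          if (var(g) > 0) break
        }
        if (var(g) == 0) {        # force one heterozygote as a last resort
          g[1L] <- if (g[1L] > 0L) g[1L] - 1L else 1L
        }
        geno[, j] <- g
        maf[j] <- p
      }
    }
    chrom_of <- rep(sprintf("chr%d", seq_len(n_chrom)), length.out = n_chrom)
    chrom_idx <- sort(rep_len(seq_len(n_chrom), m))
    pos <- integer(m)
    for (cidx in seq_len(n_chrom)) {
      sel <- which(chrom_idx == cidx)
      pos[sel] <- (seq_along(sel) - 1L) * as.integer(spacing_bp) + 1L
    }
    structure(list(
      genotypes = geno,
      snp_id = sprintf("snp%05d", seq_len(m)),
      chrom = chrom_of[chrom_idx],
      pos_bp = pos,
      maf = maf,
      block = block,
      cohort = rep_len(rep(cohorts, each = ceiling(n / length(cohorts))), n)
    ), class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs on %d chromosome(s); cohorts: %s\n",
              nrow(x$genotypes), ncol(x$genotypes), length(unique(x$chrom)),
              paste(unique(x$cohort), collapse = ", ")))
  invisible(x)
}

#' Additive genetic architecture for shape simulation
#'
#' Describes how planted causal SNPs, covariates and noise drive latent
#' shape scores.  Per latent axis, the genetic component is rescaled so that
#' it contributes a fraction `h2_target` of that axis's variance
#' (`latent_sd^2`); the residual fraction is filled with Gaussian noise of
#' standard deviation `sqrt(1 - h2_target) * latent_sd` unless `noise_sd`
#' overrides it.
#'
#' @param effects data.frame with columns `snp` (index into the panel),
#'   `axis` (latent axis index) and `beta` (relative per-allele weight);
#'   `NULL` for no genetic effects.
#' @param h2_target fraction of latent variance of genetic origin on axes
#'   that carry causal SNPs, in `[0, 1]`.
#' @param latent_sd per-axis latent standard deviation (recycled), in the
#'   shape units of the basis (mm for the default template).
#' @param noise_sd optional override of the residual noise SD.
#' @param covariate_effects data.frame with columns `covariate` (name),
#'   `axis`, `slope` (latent units per covariate unit); `NULL` for none.
#' @param seed RNG seed used when simulating the cohort.
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(effects = NULL, h2_target = 0.5, latent_sd = 3,
                              noise_sd = NULL, covariate_effects = NULL,
                              seed = NULL) {
  check_scalar_in(h2_target, 0, 1, "h2_target")
  if (!is.null(effects)) {
    stopifnot(all(c("snp", "axis", "beta") %in% names(effects)))
  }
  if (!is.null(covariate_effects)) {
    stopifnot(all(c("covariate", "axis", "slope") %in% names(covariate_effects)))
  }
  structure(list(effects = effects, h2_target = h2_target,
                 latent_sd = latent_sd, noise_sd = noise_sd,
                 covariate_effects = covariate_effects, seed = seed),
            class = "architecture_spec")
}

#' Simulate cohort covariates
#'
#' Generates the covariate table used for shape adjustment: sex, age,
#' age-squared, height, weight, four genomic-ancestry axes, and the camera
#' system (one camera per cohort, mirroring a two-site study).  Facial size
#' is appended by [simulate_cohort()] as the centroid size of each generated
#' shape.
#'
#' @param n number of individuals.
#' @param cohort per-individual cohort labels.
#' @param seed RNG seed.
#' @return data.frame with one row per individual.
#' @export
make_covariates <- function(n, cohort = rep("US", n), seed = NULL) {
  with_seed(seed, {
    sex <- rbinom(n, 1L, 0.5)
    age <- runif(n, 18, 40)
    height <- 165 + 10 * sex + rnorm(n, 0, 6)
    weight <- -50 + 0.7 * height + rnorm(n, 0, 8)
    anc <- matrix(rnorm(4L * n), n, 4L)
    data.frame(sex = sex, age = age, age2 = age^2,
               height = height, weight = weight,
               anc1 = anc[, 1], anc2 = anc[, 2],
               anc3 = anc[, 3], anc4 = anc[, 4],
               camera = factor(cohort))
  })
}

#' Simulate a genotype-shape cohort with known architecture
#'
#' Each shape is the template displaced along orthonormal latent basis
#' directions: `mesh_i = template + sum_k score_ik * basis_k`, where the
#' latent score on axis `k` is the sum of a genetic component (additive in
#' the planted causal allele counts, scaled to the target heritability), a
#' covariate component, and Gaussian noise.  The returned truth table
#' records the causal SNPs, their latent effect vectors, and the realized
#' per-axis heritability.
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param arch an [architecture_spec()].
#' @param template a [face_template] or 1-shape [mesh_config].
#' @param basis `3L x K` orthonormal basis, e.g. from [make_shape_basis()].
#' @param covariates optional covariate table; defaults to
#'   [make_covariates()] on the panel's cohort labels.
#' @return a list of class `synthetic_cohort` with `meshes`
#'   ([mesh_config]), `genotypes`, `covariates` (with `size` appended),
#'   `latent` (`N x K` scores) and `truth`.
#' @export
simulate_cohort <- function(panel, arch, template, basis, covariates = NULL) {
  mesh <- if (inherits(template, "face_template")) template$mesh else template
  L <- n_vertices(mesh)
  K <- ncol(basis)
  if (nrow(basis) != 3L * L) stop_arg("basis rows must equal 3L of the template")
  if (max(abs(crossprod(basis) - diag(K))) > 1e-6)
    stop_arg("basis columns must be orthonormal")
  n <- nrow(panel$genotypes)
  with_seed(arch$seed, {
    covariates <- covariates %||% make_covariates(n, panel$cohort)
    latent_sd <- rep_len(arch$latent_sd, K)
    latent <- matrix(0, n, K)
    gvar <- rep(0, K); evar <- rep(0, K)
    # genetic component, scaled per axis to h2_target of latent variance
    if (!is.null(arch$effects) && nrow(arch$effects) > 0 && arch$h2_target > 0) {
      for (k in unique(arch$effects$axis)) {
        rows <- arch$effects[arch$effects$axis == k, , drop = FALSE]
        g <- panel$genotypes[, rows$snp, drop = FALSE]
        score <- as.vector(scale(g, center = TRUE, scale = FALSE) %*% rows$beta)
        s <- sd(score)
        if (s > 0) {
          latent[, k] <- latent[, k] +
            score / s * sqrt(arch$h2_target) * latent_sd[k]
          gvar[k] <- arch$h2_target * latent_sd[k]^2
        }
      }
    }
    # covariate component
    if (!is.null(arch$covariate_effects) && nrow(arch$covariate_effects) > 0) {
      for (r in seq_len(nrow(arch$covariate_effects))) {
        ce <- arch$covariate_effects[r, ]
        x <- covariates[[ce$covariate]]
        if (is.null(x)) stop_arg("unknown covariate in architecture: ", ce$covariate)
        x <- if (is.factor(x)) as.numeric(x) - 1 else as.numeric(x)
        latent[, ce$axis] <- latent[, ce$axis] + ce$slope * (x - mean(x))
      }
    }
    # residual noise
    for (k in seq_len(K)) {
      ns <- if (!is.null(arch$noise_sd)) rep_len(arch$noise_sd, K)[k]
            else if (gvar[k] > 0) sqrt(1 - arch$h2_target) * latent_sd[k]
            else latent_sd[k]
      if (ns > 0) {
        e <- rnorm(n, 0, ns)
        latent[, k] <- latent[, k] + e
        evar[k] <- ns^2
      }
    }
    tmpl_flat <- flatten_coords(mesh$coords)[1L, ]
    flat <- matrix(tmpl_flat, n, 3L * L, byrow = TRUE) + latent %*% t(basis)
    meshes <- mesh_config(unflatten_coords(flat, L),
                          mirror_map = mesh$mirror_map,
                          vertex_ids = mesh$vertex_ids)
    covariates$size <- apply(meshes$coords, 1L, centroid_size)
    realized_h2 <- ifelse(gvar + evar > 0, gvar / apply(latent, 2L, var), 0)
    truth <- list(effects = arch$effects,
                  causal_snp_ids = if (is.null(arch$effects)) character(0)
                                   else panel$snp_id[arch$effects$snp],
                  h2_target = arch$h2_target,
                  realized_h2 = realized_h2,
                  basis = basis)
    structure(list(meshes = meshes, genotypes = panel,
                   covariates = covariates, latent = latent, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d individuals, %d vertices, %d SNPs, %d latent axes\n",
              n_shapes(x$meshes), n_vertices(x$meshes),
              ncol(x$genotypes$genotypes), ncol(x$latent)))
  invisible(x)
}

#' Simulate syndromic shape groups plus controls
#'
#' Group `g` shapes scatter around `template + shift_g * basis[, g]`
#' (cycling through basis columns); controls scatter around the template.
#' Scatter is isotropic Gaussian across all basis axes with SD
#' `scatter_sd`, expressed in latent units.
#'
#' @param template a [face_template] or 1-shape [mesh_config].
#' @param basis orthonormal latent basis (`3L x K`).
#' @param k_groups number of syndromic groups (>= 1).
#' @param shift_magnitudes length-`k_groups` mean shifts in latent units.
#' @param n_per_group individuals per group (recycled).
#' @param n_controls number of control individuals.
#' @param scatter_sd within-group latent SD.
#' @param seed RNG seed.
#' @return list with `meshes` ([mesh_config] of all groups then controls),
#'   `labels` (factor, `"syndrome<g>"`/`"control"`), and `truth` (per-group
#'   shift vectors in latent space).
#' @export
simulate_syndromic_groups <- function(template, basis, k_groups,
                                      shift_magnitudes, n_per_group = 30L,
                                      n_controls = 54L, scatter_sd = 1,
                                      seed = NULL) {
  if (k_groups < 1L) stop_arg("`k_groups` must be >= 1")
  if (length(shift_magnitudes) != k_groups)
    stop_arg("`shift_magnitudes` must have length `k_groups`")
  mesh <- if (inherits(template, "face_template")) template$mesh else template
  L <- n_vertices(mesh); K <- ncol(basis)
  n_per_group <- rep_len(as.integer(n_per_group), k_groups)
  with_seed(seed, {
    n_tot <- sum(n_per_group) + n_controls
    latent <- matrix(rnorm(n_tot * K, 0, scatter_sd), n_tot, K)
    labels <- character(n_tot)
    shifts <- matrix(0, k_groups, K)
    at <- 0L
    for (g in seq_len(k_groups)) {
      ax <- ((g - 1L) %% K) + 1L
      rows <- at + seq_len(n_per_group[g])
      latent[rows, ax] <- latent[rows, ax] + shift_magnitudes[g]
      labels[rows] <- sprintf("syndrome%d", g)
      shifts[g, ax] <- shift_magnitudes[g]
      at <- at + n_per_group[g]
    }
    labels[(at + 1L):n_tot] <- "control"
    tmpl_flat <- flatten_coords(mesh$coords)[1L, ]
    flat <- matrix(tmpl_flat, n_tot, 3L * L, byrow = TRUE) + latent %*% t(basis)
    list(meshes = mesh_config(unflatten_coords(flat, L),
                              mirror_map = mesh$mirror_map,
                              vertex_ids = mesh$vertex_ids),
         labels = factor(labels, levels = c(sprintf("syndrome%d", seq_len(k_groups)),
                                            "control")),
         truth = list(shifts = shifts, scatter_sd = scatter_sd))
  })
}
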