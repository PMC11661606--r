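#' Pipeline run configuration
#'
#' All knobs of the end-to-end comparison in one serializable list: cohort
#' and panel sizes, architecture, template resolution, trait-family sizes,
#' significance level, and the window/LD settings of the peak caller.
#' Every stochastic stage has an explicit seed derived from `seed`, so two
#' runs with the same configuration are identical.
#'
#' @param n individuals; `m` SNPs; remaining arguments as documented
#'   inline.
#' @param m number of SNPs.
#' @param block_size SNPs per LD block.
#' @param maf_range generating minor-allele-frequency interval.
#' @param spacing_bp SNP spacing in bp.
#' @param n_polar,n_lateral template grid resolution.
#' @param k_latent latent shape axes.
#' @param n_causal planted causal SNPs.
#' @param h2_target latent heritability of axes carrying causal SNPs.
#' @param latent_sd latent axis SD (mm).
#' @param n_random,n_extreme random/extreme gestalt counts.
#' @param k_syndromes,syndrome_shift,n_per_syndrome,n_syndrome_controls
#'   syndromic-cohort settings.
#' @param ae_latent,ae_hidden,ae_epochs auto-encoder settings.
#' @param base_alpha genome-wide significance level.
#' @param clump_bp,ld_bp,merge_bp,r2 peak-caller windows and LD threshold.
#' @param ld_window_bp LD-score window.
#' @param distinctness_perm permutations of the archetype test.
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 400L, m = 1000L, block_size = 20L,
                            maf_range = c(0.1, 0.5), spacing_bp = 5000L,
                            n_polar = 10L, n_lateral = 9L,
                            k_latent = 12L, n_causal = 8L, h2_target = 0.6,
                            latent_sd = 3,
                            n_random = 8L, n_extreme = 8L,
                            k_syndromes = 3L, syndrome_shift = 4,
                            n_per_syndrome = 30L, n_syndrome_controls = 40L,
                            ae_latent = 6L, ae_hidden = c(32L, 16L),
                            ae_epochs = 60L,
                            base_alpha = 5e-8,
                            clump_bp = 250e3, ld_bp = 1e6, merge_bp = 10e6,
                            r2 = 0.01, ld_window_bp = 1e6,
                            distinctness_perm = 199L, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full phenotyping-comparison pipeline
#'
#' Simulate, preprocess, phenotype, scan, aggregate, call loci, compare:
#'
#' 1. simulate a genotype panel, covariates and shape cohort with planted
#'    causal SNPs, plus a syndromic cohort;
#' 2. GPA-align, symmetrize and PLS-adjust the shapes;
#' 3. derive the six trait families (DISTANCE, PCA, AE, RANDOM, EXTREME,
#'    SYNDROME), with the resemblance families built in the
#'    parallel-analysis-retained face space;
#' 4. per family: per-cohort GWAS, IVW meta, min-p aggregation, effective
#'    trait count, group-wide threshold, 3-step peak calling;
#' 5. pairwise locus overlap (250 kb window, IoU);
#' 6. LD-score-regression heritability per trait and category comparison.
#'
#' @param config a [pipeline_config()].
#' @param families subset of families to run.
#' @param outdir optional directory; when given, stage outputs are written
#'   (genotypes, traits, summary stats, loci, config).
#' @return a list of class `pipeline_report`: `traits`, `scans`,
#'   `aggregation` (per-family meff/threshold/loci), `overlap` (pairwise
#'   IoU table), `h2` (per-trait estimates), `h2_comparison`, plus the
#'   simulated `cohort` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         families = c("DISTANCE", "PCA", "AE", "RANDOM",
                                      "EXTREME", "SYNDROME"),
                         outdir = NULL) {
  cfg <- config
  seeds <- cfg$seed + 0:19                       # one sub-seed per stage
  tmpl <- face_template(cfg$n_polar, cfg$n_lateral)
  basis <- make_shape_basis(tmpl, cfg$k_latent, seed = seeds[1])
  panel <- simulate_genotypes(cfg$n, cfg$m, block_size = cfg$block_size,
                              maf_range = cfg$maf_range,
                              spacing_bp = cfg$spacing_bp, seed = seeds[2])
  covars <- make_covariates(cfg$n, panel$cohort, seed = seeds[3])
  arch <- plant_architecture(cfg, panel, seed = seeds[4])
  cohort <- simulate_cohort(panel, arch, tmpl, basis, covariates = covars)

  # preprocessing: align, symmetrize, covariate-adjust
  gpa <- gpa_align(cohort$meshes)
  sym <- symmetrize(gpa$meshes)
  covars$size <- gpa$centroid_size
  adj <- adjust_covariates_pls(sym, covars, keep_mean = TRUE)
  covmat <- covariate_matrix(covars)

  # face space
  space <- fit_pca(adj)
  k_pa <- max(2L, parallel_analysis(adj, n_perm = 20L, seed = seeds[5]))
  k_pa <- min(k_pa, ncol(space$basis))
  space_k <- space
  space_k$basis <- space$basis[, seq_len(k_pa), drop = FALSE]
  space_k$axis_variance <- space$axis_variance[seq_len(k_pa)]
  space_k$scores <- space$scores[, seq_len(k_pa), drop = FALSE]
  scores <- space_k$scores

  traits <- list()
  if ("DISTANCE" %in% families)
    traits$DISTANCE <- interlandmark_distances(adj, which = tmpl$landmarks)
  if ("PCA" %in% families)
    traits$PCA <- pca_traits(space, k = k_pa)
  if ("AE" %in% families) {
    ae <- train_autoencoder(adj, latent_dim = cfg$ae_latent,
                            hidden = cfg$ae_hidden, epochs = cfg$ae_epochs,
                            seed = seeds[6])
    traits$AE <- encode_latents(ae, adj)
  }
  if ("RANDOM" %in% families)
    traits$RANDOM <- random_gestalt_traits(scores, cfg$n_random,
                                           space_k$axis_variance, seed = seeds[7])
  if ("EXTREME" %in% families)
    traits$EXTREME <- extreme_gestalt_traits(scores, cfg$n_extreme,
                                             space_k$axis_variance)
  if ("SYNDROME" %in% families) {
    synd <- simulate_syndromic_groups(tmpl, basis, cfg$k_syndromes,
                                      rep(cfg$syndrome_shift, cfg$k_syndromes),
                                      n_per_group = cfg$n_per_syndrome,
                                      n_controls = cfg$n_syndrome_controls,
                                      seed = seeds[8])
    synd_proc <- symmetrize(gpa_newdata(synd$meshes, gpa$consensus))
    traits$SYNDROME <- syndrome_gestalt_traits(scores,
                                               list(meshes = synd_proc,
                                                    labels = synd$labels),
                                               space_k,
                                               n_perm = cfg$distinctness_perm,
                                               seed = seeds[9])
  }

  scans <- lapply(traits, family_gwas, panel = panel, covariates = covars)
  ldt <- ld_scores(panel, window_bp = cfg$ld_window_bp)

  aggregation <- list(); loci <- list(); h2 <- list()
  for (fam in names(traits)) {
    meff <- if (fam == "PCA") as.numeric(n_traits(traits[[fam]]))
            else as.numeric(effective_trait_count(traits[[fam]], panel, covars,
                                                  seed = seeds[10] + match(fam, names(traits))))
    thr <- group_threshold(meff, cfg$base_alpha)
    minp <- minp_aggregate(scans[[fam]]$p)
    pk <- call_peaks(minp, panel, thr, clump_bp = cfg$clump_bp,
                     ld_bp = cfg$ld_bp, merge_bp = cfg$merge_bp, r2 = cfg$r2)
    loci[[fam]] <- pk
    aggregation[[fam]] <- data.table::data.table(
      family = fam, n_traits = n_traits(traits[[fam]]),
      meff = meff, threshold = thr, n_loci = nrow(pk))
    h2[[fam]] <- h2_by_trait(scans[[fam]], ldt, traits[[fam]], M = cfg$m)
  }
  aggregation <- data.table::rbindlist(aggregation)
  h2 <- data.table::rbindlist(h2)

  overlap <- NULL
  if (length(loci) >= 2L) {
    prs <- combn(names(loci), 2L)
    overlap <- data.table::rbindlist(lapply(seq_len(ncol(prs)), function(i) {
      ov <- locus_overlap(loci[[prs[1, i]]], loci[[prs[2, i]]],
                          window = cfg$clump_bp)
      data.table::data.table(family_a = prs[1, i], family_b = prs[2, i],
                             n_a = nrow(loci[[prs[1, i]]]),
                             n_b = nrow(loci[[prs[2, i]]]),
                             n_shared = ov$n_shared, n_union = ov$n_union,
                             iou = ov$iou)
    }))
  }
  h2_cmp <- suppressWarnings(tryCatch(compare_h2_groups(h2),
                                      error = function(e) NULL))

  report <- structure(list(config = cfg, cohort = cohort, traits = traits,
                           scans = scans, aggregation = aggregation,
                           loci = loci, overlap = overlap, h2 = h2,
                           h2_comparison = h2_cmp, face_space = space_k,
                           ld = ldt),
                      class = "pipeline_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Rigidly align new shapes to an existing GPA consensus (no reflection).
gpa_newdata <- function(meshes, consensus) {
  x <- meshes$coords
  for (i in seq_len(dim(x)[1])) {
    xi <- sweep(x[i, , ], 2L, colMeans(x[i, , ]))
    x[i, , ] <- xi %*% rotation_to(xi, consensus)
  }
  mesh_config(x, mirror_map = meshes$mirror_map, vertex_ids = meshes$vertex_ids)
}

plant_architecture <- function(cfg, panel, seed = NULL) {
  with_seed(seed, {
    if (cfg$n_causal > 0L) {
      causal <- sort(sample.int(cfg$m, cfg$n_causal))
      effects <- data.frame(snp = causal,
                            axis = rep_len(seq_len(cfg$k_latent), cfg$n_causal),
                            beta = 1)
    } else effects <- NULL
    architecture_spec(effects = effects, h2_target = cfg$h2_target,
                      latent_sd = cfg$latent_sd, seed = seed)
  })
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_config(report$config, file.path(outdir, "config.yaml"))
  write_genotypes(report$cohort$genotypes, file.path(outdir, "genotypes.tsv.gz"))
  for (fam in names(report$traits)) {
    write_traits(report$traits[[fam]],
                 file.path(outdir, sprintf("traits_%s.tsv", fam)))
    if (nrow(report$loci[[fam]]) > 0L)
      write_loci(report$loci[[fam]], file.path(outdir, sprintf("loci_%s.bed", fam)))
  }
  write.table(report$aggregation, file.path(outdir, "aggregation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$overlap))
    write.table(report$overlap, file.path(outdir, "overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$h2, file.path(outdir, "h2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  cohort: %d individuals, %d SNPs\n",
              n_shapes(x$cohort$meshes), ncol(x$cohort$genotypes$genotypes)))
  cat("  aggregation:\n")
  print(x$aggregation)
  if (!is.null(x$overlap)) {
    cat(sprintf("  median pairwise IoU: %.2f\n", stats::median(x$overlap$iou)))
  }
  invisible(x)
}
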