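# Readers/writers for the stage-boundary formats: gzip TSV for genotypes,
# summary statistics and traits; OBJ for meshes; BED + TSV for loci; YAML
# for run configuration.

#' Write / read a genotype panel as gzip TSV
#'
#' Layout: columns `snp_id`, `chrom`, `pos`, `maf`, then one column of
#' allele counts per individual (`ind0001`, ...).  Cohort labels travel in
#' a `#cohort:` header line.
#'
#' @param panel a genotype panel.
#' @param path output path (".tsv.gz" recommended).
#' @return `path`, invisibly (writer); a `genotype_panel` (reader).
#' @export
write_genotypes <- function(panel, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#cohort: ", paste(panel$cohort, collapse = ",")), con)
  df <- data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                   pos = panel$pos_bp, maf = panel$maf,
                   t(panel$genotypes))
  colnames(df)[-(1:4)] <- sprintf("ind%04d", seq_len(nrow(panel$genotypes)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  cohort <- strsplit(sub("^#cohort: ", "", header), ",")[[1]]
  df <- read.table(con, header = TRUE, sep = "\t", check.names = FALSE)
  geno <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  dimnames(geno) <- NULL
  storage.mode(geno) <- "integer"
  structure(list(genotypes = geno, snp_id = df$snp_id, chrom = as.character(df$chrom),
                 pos_bp = as.integer(df$pos), maf = df$maf,
                 block = NULL, cohort = cohort),
            class = "genotype_panel")
}

#' Write a (meta) association scan as gzip TSV summary statistics
#'
#' Conventional layout: `snp_id`, `chrom`, `pos`, `beta`, `se`, `p`, `n`.
#'
#' @param scan a [linear_gwas()] or [ivw_meta()] table.
#' @param path output path.
#' @export
write_sumstats <- function(scan, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  cols <- intersect(c("snp_id", "chrom", "pos", "beta", "se", "p", "n"), names(scan))
  write.table(as.data.frame(scan)[, cols], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  data.table::as.data.table(read.table(gzfile(path), header = TRUE, sep = "\t"))
}

#' Write a trait set as TSV with a JSON sidecar
#'
#' The TSV holds the `N x T` value matrix (individuals in rows); the
#' sidecar `<path>.json` records category, trait ids, provenance and seed.
#'
#' @param traits a [trait_set()].
#' @param path output TSV path.
#' @export
write_traits <- function(traits, path) {
  df <- data.frame(individual = sprintf("ind%04d", seq_len(nrow(traits$values))),
                   traits$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(category = traits$category, trait_ids = traits$trait_ids,
               seed = traits$seed,
               provenance = traits$provenance)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Write loci as BED plus a lead-SNP TSV
#'
#' The BED file uses 0-based half-open intervals spanning each locus's
#' member SNPs; the companion TSV (`<path>.tsv`) lists lead SNP, lead
#' p-value and member count.
#'
#' @param loci a [call_peaks()] table.
#' @param path output BED path.
#' @export
write_loci <- function(loci, path) {
  bed <- data.frame(chrom = loci$chrom, start = loci$start - 1L, end = loci$end,
                    name = loci$lead_snp, score = 0L, strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv <- data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
                    lead_snp = loci$lead_snp, lead_pos = loci$lead_pos,
                    lead_p = loci$lead_p, n_snps = loci$n_snps)
  write.table(tsv, paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read one shape as a Wavefront OBJ
#'
#' Vertex-only OBJ (`v x y z` lines) — quasi-landmark configurations carry
#' no face connectivity.
#'
#' @param mesh a 1-shape [mesh_config] or `L x 3` matrix.
#' @param path file path.
#' @export
write_mesh_obj <- function(mesh, path) {
  x <- if (inherits(mesh, "mesh_config")) mesh$coords[1L, , ] else as.matrix(mesh)
  writeLines(c("# morphogwas quasi-landmark configuration",
               sprintf("v %.8g %.8g %.8g", x[, 1], x[, 2], x[, 3])), path)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  v <- lines[startsWith(lines, "v ")]
  coords <- do.call(rbind, lapply(strsplit(v, "\\s+"), function(f) as.numeric(f[2:4])))
  mesh_config(array(coords, dim = c(1L, nrow(coords), 3L)))
}

#' Write vertex segment labels as TSV
#'
#' @param labels a [segment_hierarchical()] label matrix.
#' @param vertex_ids vertex labels.
#' @param path output path.
#' @export
write_segments <- function(labels, vertex_ids, path) {
  df <- data.frame(vertex_id = vertex_ids, labels, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' Round trips exactly: `read_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param config a [pipeline_config()] list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
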