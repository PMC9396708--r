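#' Construct a genotype matrix
#'
#' The central container for biallelic diploid SNP genotypes: a sites x
#' samples matrix of alternate-allele counts (0, 1, 2 or `NA` for missing),
#' with per-genotype total read depth and per-allele read depths, and a
#' per-site table carrying the RAD-locus identifier, the position of the SNP
#' within the locus, the two alleles and a multi-allelic flag.
#'
#' @param genotypes integer matrix, sites x samples, values in {0,1,2,NA}.
#' @param samples character vector of unique sample identifiers (columns).
#' @param loci data.frame with one row per site: columns `locus` (RAD-locus
#'   id), `pos` (site position within locus), `ref`, `alt` (alleles) and
#'   optionally `multiallelic` (logical; defaults to `FALSE`).
#' @param depth optional sites x samples matrix of total read depth (`NA`
#'   where unknown).
#' @param ad_ref,ad_alt optional sites x samples matrices of reference- and
#'   alternate-allele read depths.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, samples, loci,
                            depth = NULL, ad_ref = NULL, ad_alt = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (ncol(genotypes) != length(samples))
    stop("ncol(genotypes) must equal length(samples)")
  if (nrow(genotypes) != nrow(loci))
    stop("nrow(genotypes) must equal nrow(loci)")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(loci$multiallelic)) loci$multiallelic <- FALSE
  loci <- as.data.frame(loci)
  rownames(loci) <- NULL
  chk_dim <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(genotypes)))
      stop(what, " must have the same dimensions as genotypes")
    m
  }
  depth <- chk_dim(depth, "depth")
  ad_ref <- chk_dim(ad_ref, "ad_ref")
  ad_alt <- chk_dim(ad_alt, "ad_alt")
  if (!is.null(depth) && any(depth < 0, na.rm = TRUE))
    stop("depth must be non-negative")
  if (!is.null(ad_ref) && !is.null(ad_alt) && !is.null(depth)) {
    s <- ad_ref + ad_alt
    if (any(s > depth, na.rm = TRUE))
      stop("allele depths must not sum to more than total depth")
  }
  colnames(genotypes) <- samples
  structure(
    list(genotypes = genotypes, samples = as.character(samples), loci = loci,
         depth = depth, ad_ref = ad_ref, ad_alt = ad_alt,
         ploidy_assumption = 2L),
    class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d RAD loci)\n",
              nrow(x$genotypes), length(x$samples),
              length(unique(x$loci$locus))))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.1f%%; depth %s; allele depth %s\n",
              100 * miss,
              if (is.null(x$depth)) "absent" else "present",
              if (is.null(x$ad_ref)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Subset a genotype matrix by site and/or sample
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer or logical index over sites (rows).
#' @param samples integer, logical or character index over samples (columns).
#' @return a `genotype_matrix` restricted to the requested sites and samples.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(gm$genotypes))
  if (is.null(samples)) samples <- seq_along(gm$samples)
  if (is.character(samples)) samples <- match(samples, gm$samples)
  sub <- function(m) if (is.null(m)) NULL else m[sites, samples, drop = FALSE]
  genotype_matrix(
    genotypes = gm$genotypes[sites, samples, drop = FALSE],
    samples = gm$samples[samples],
    loci = gm$loci[sites, , drop = FALSE],
    depth = sub(gm$depth), ad_ref = sub(gm$ad_ref), ad_alt = sub(gm$ad_alt))
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated text (sample id, population label), no header.
#' An optional third column assigns each population to a region group; if it
#' is absent each population is its own group.
#'
#' @param path path to the popmap file.
#' @return a `population_map`: data.frame with columns `sample`, `pop`,
#'   `group`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("popmap must have at least 2 tab-separated columns")
  population_map(df[[1]], df[[2]], if (ncol(df) >= 3) df[[3]] else NULL)
}

#' Construct a sample-to-population map
#'
#' @param sample character vector of sample ids.
#' @param pop population label per sample.
#' @param group optional region-group label per sample (e.g. the native-range
#'   and introduced-range genetic groups); defaults to `pop`.
#' @return data.frame of class `population_map`.
#' @export
population_map <- function(sample, pop, group = NULL) {
  if (is.null(group)) group <- pop
  if (anyDuplicated(sample)) stop("duplicated sample ids in popmap")
  pg <- unique(data.frame(pop = pop, group = group))
  if (anyDuplicated(pg$pop))
    stop("groups must partition populations: a population maps to 2+ groups")
  structure(data.frame(sample = as.character(sample), pop = as.character(pop),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

#' Write a popmap to tab-separated text
#' @param popmap a [population_map()].
#' @param path output path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap[, c("sample", "pop", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Group index per sample of gm, in a stable group order. Errors on samples
# missing from the map.
gm_groups <- function(gm, popmap) {
  idx <- match(gm$samples, popmap$sample)
  if (anyNA(idx))
    stop("samples absent from popmap: ",
         paste(gm$samples[is.na(idx)], collapse = ", "))
  grp <- popmap$group[idx]
  levels <- unique(popmap$group)
  levels <- levels[levels %in% grp]
  factor(grp, levels = levels)
}
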