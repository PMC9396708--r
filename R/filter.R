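#' Per-site minor allele frequency over non-missing genotypes
#'
#' @param gm a [genotype_matrix()].
#' @return numeric vector, one MAF per site (`NaN` where all genotypes are
#'   missing).
#' @export
site_maf <- function(gm) {
  g <- gm$genotypes
  n_called <- rowSums(!is.na(g))
  p_alt <- rowSums(g, na.rm = TRUE) / (2 * n_called)
  pmin(p_alt, 1 - p_alt)
}

#' Post-calling SNP filter cascade
#'
#' Applies, in order: (1) remove samples with more than `sample_miss_pre`
#' missing genotypes; (2) set genotype calls with depth below `min_depth` to
#' missing; (3) retain biallelic sites with less than `site_miss` missing
#' genotypes and minor allele frequency greater than `maf`; (4) thin to one
#' randomly chosen SNP per RAD locus; (5) remove samples with more than
#' `sample_miss_post` missing genotypes. All inequalities are strict.
#' Genotypes with unrecorded depth are left untouched by stage 2.
#'
#' Stage 5 can in principle re-raise per-site missingness above the stage-3
#' bound; the report notes when that happens rather than re-running stage 3,
#' mirroring the stated stage order.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_miss_pre,sample_miss_post strict sample-missingness bounds
#'   before and after site filtering (defaults 0.9 and 0.5).
#' @param min_depth genotypes with depth strictly below this are masked
#'   (default 5).
#' @param site_miss strict per-site missingness bound (default 0.2).
#' @param maf strict minor-allele-frequency lower bound (default 0.05).
#' @param seed integer seed for the per-locus thinning draw (default 1).
#' @return list with elements `gm` (the filtered [genotype_matrix()]) and
#'   `report` (a `filter_report`: per-stage data.frame of counts plus the
#'   parameters and seed used).
#' @export
filter_cascade <- function(gm, sample_miss_pre = 0.9, min_depth = 5,
                           site_miss = 0.2, maf = 0.05,
                           sample_miss_post = 0.5, seed = 1L) {
  stages <- list()
  note <- character()
  log_stage <- function(name, gm_in, gm_out, detail = "") {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name,
      sites_in = nrow(gm_in$genotypes), sites_out = nrow(gm_out$genotypes),
      samples_in = length(gm_in$samples), samples_out = length(gm_out$samples),
      detail = detail, stringsAsFactors = FALSE)
    if (nrow(gm_out$genotypes) == 0 || length(gm_out$samples) == 0)
      stop("empty after stage ", length(stages), " (", name, ")")
    gm_out
  }

  # stage 1: drop samples with > sample_miss_pre missing
  miss_s <- colMeans(is.na(gm$genotypes))
  keep <- miss_s <= sample_miss_pre
  out <- log_stage("sample_missingness_pre", gm,
                   gm_subset(gm, samples = which(keep)),
                   sprintf("> %g removed", sample_miss_pre))
  # stage 2: mask genotype calls with depth < min_depth
  masked <- 0L
  if (!is.null(out$depth)) {
    low <- !is.na(out$depth) & out$depth < min_depth & !is.na(out$genotypes)
    masked <- sum(low)
    out$genotypes[low] <- NA_integer_
  }
  out <- log_stage("depth_mask", out, out,
                   sprintf("depth < %g: %d calls masked", min_depth, masked))
  # stage 3: biallelic, site missingness, MAF
  miss_site <- rowMeans(is.na(out$genotypes))
  mafs <- site_maf(out)
  keep_site <- !out$loci$multiallelic & miss_site < site_miss &
    !is.na(mafs) & mafs > maf
  out <- log_stage("biallelic_missingness_maf", out,
                   gm_subset(out, sites = which(keep_site)),
                   sprintf("multiallelic or missing >= %g or MAF <= %g",
                           site_miss, maf))
  # stage 4: one SNP per RAD locus
  thin <- thin_one_per_locus(out, seed = seed)
  out <- log_stage("thin_one_per_locus", out, thin,
                   sprintf("seed %d", as.integer(seed)))
  # stage 5: drop samples with > sample_miss_post missing
  miss_s2 <- colMeans(is.na(out$genotypes))
  keep2 <- miss_s2 <= sample_miss_post
  out <- log_stage("sample_missingness_post", out,
                   gm_subset(out, samples = which(keep2)),
                   sprintf("> %g removed", sample_miss_post))
  if (any(rowMeans(is.na(out$genotypes)) >= site_miss))
    note <- c(note, "stage 5 re-raised some per-site missingness above the stage-3 bound")

  report <- structure(
    list(stages = do.call(rbind, stages),
         params = list(sample_miss_pre = sample_miss_pre,
                       min_depth = min_depth, site_miss = site_miss,
                       maf = maf, sample_miss_post = sample_miss_post),
         seed = as.integer(seed), notes = note),
    class = "filter_report")
  list(gm = out, report = report)
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("SNP filter cascade report (thinning seed", x$seed, ")\n")
  print(x$stages, row.names = FALSE)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report` from [filter_cascade()].
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Thin to one SNP per RAD locus
#'
#' Keeps exactly one site per RAD locus, selected uniformly at random among
#' the locus's sites under the given seed. Site order of the survivors is
#' preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param seed integer seed for the selection (default 1).
#' @return a [genotype_matrix()] with one site per locus.
#' @export
thin_one_per_locus <- function(gm, seed = 1L) {
  loc <- gm$loci$locus
  if (is.null(loc) || all(is.na(loc)))
    stop("RAD-locus ids are absent; re-read the VCF with a locus_id_rule")
  keep <- withr::with_seed(as.integer(seed), {
    idx <- split(seq_along(loc), loc)
    vapply(idx, function(i) if (length(i) == 1L) i else sample(i, 1L),
           integer(1))
  })
  gm_subset(gm, sites = sort(unname(keep)))
}
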