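#' Read a VCF file into a genotype matrix
#'
#' Parses GT (required) plus DP and AD (optional) from a VCF 4.x file.
#' Genotype separators "/" and "|" are both accepted; any genotype with a
#' missing allele ("./.", ".") becomes the missing code. AD is assumed to be
#' ordered ref,alt; when DP is absent but AD present, DP is taken as the sum
#' of AD. Multi-allelic records are retained but flagged, so that the filter
#' cascade can remove them at the biallelic stage.
#'
#' RAD-locus identifiers are recovered according to `locus_id_rule`:
#' \describe{
#'   \item{"id"}{the ID column holds `locus_site` (e.g. `12_7`: locus 12,
#'     site 7 within the locus).}
#'   \item{"chrom"}{the CHROM column names the locus (position = POS).}
#'   \item{"info:KEY"}{the INFO field `KEY` holds the locus id.}
#' }
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param locus_id_rule one of `"id"`, `"chrom"` or `"info:KEY"`.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, locus_id_rule = "chrom") {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- v@fix
  n_site <- nrow(fix)
  if (n_site == 0) stop("VCF contains no records: ", path)
  samples <- colnames(v@gt)[-1]

  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  geno <- matrix(NA_integer_, n_site, length(samples))
  clean <- gsub("\\|", "/", gt)
  geno[clean %in% c("0/0")] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean %in% c("1/1")] <- 2L
  # alleles beyond the first alternate stay NA on the 0/1/2 scale; the
  # record itself is flagged multiallelic

  has_el <- function(el) any(grepl(el, v@gt[, "FORMAT"]))
  dp <- if (has_el("DP")) {
    m <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    m
  } else NULL
  ad_ref <- ad_alt <- NULL
  if (has_el("AD")) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ad_ref <- suppressWarnings(as.numeric(sub(",.*", "", ad)))
    ad_alt <- suppressWarnings(as.numeric(vapply(strsplit(ad, ","), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1))))
    ad_ref <- matrix(ad_ref, n_site, length(samples))
    ad_alt <- matrix(ad_alt, n_site, length(samples))
    if (is.null(dp)) dp <- ad_ref + ad_alt
  }

  loc <- switch(
    sub(":.*", "", locus_id_rule),
    id = {
      id <- fix[, "ID"]
      parts <- strsplit(id, "_")
      data.frame(locus = vapply(parts, `[`, character(1), 1),
                 pos = suppressWarnings(as.integer(
                   vapply(parts, function(x) if (length(x) >= 2) x[2] else NA_character_,
                          character(1)))))
    },
    chrom = data.frame(locus = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"])),
    info = {
      key <- sub("^info:", "", locus_id_rule)
      info <- fix[, "INFO"]
      pat <- paste0("(^|;)", key, "=([^;]*)")
      m <- regmatches(info, regexpr(pat, info))
      if (length(m) != n_site) stop("INFO key '", key, "' missing from some records")
      data.frame(locus = sub(pat, "\\2", m),
                 pos = as.integer(fix[, "POS"]))
    },
    stop("unknown locus_id_rule: ", locus_id_rule,
         " (use \"id\", \"chrom\" or \"info:KEY\")"))

  loci <- data.frame(locus = loc$locus, pos = loc$pos,
                     ref = fix[, "REF"], alt = alt,
                     multiallelic = multi, stringsAsFactors = FALSE)
  genotype_matrix(geno, samples, loci, depth = dp,
                  ad_ref = ad_ref, ad_alt = ad_alt)
}

#' Write a genotype matrix as plain-text VCF 4.2
#'
#' Emits GT:DP:AD records (DP/AD only where present). The RAD-locus id is
#' written as CHROM and the site position within the locus as POS, so the
#' file round-trips under `locus_id_rule = "chrom"`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- nrow(gm$genotypes)
  has_dp <- !is.null(gm$depth)
  has_ad <- !is.null(gm$ad_ref) && !is.null(gm$ad_alt)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_ad) "AD"), collapse = ":")
  gt_str <- matrix("./.", n, length(gm$samples))
  gt_str[gm$genotypes == 0L] <- "0/0"
  gt_str[gm$genotypes == 1L] <- "0/1"
  gt_str[gm$genotypes == 2L] <- "1/1"
  cells <- gt_str
  if (has_dp) {
    dp <- ifelse(is.na(gm$depth), ".", as.character(gm$depth))
    cells <- matrix(paste(cells, dp, sep = ":"), n)
  }
  if (has_ad) {
    ad <- ifelse(is.na(gm$ad_ref) | is.na(gm$ad_alt), ".",
                 paste0(gm$ad_ref, ",", gm$ad_alt))
    cells <- matrix(paste(cells, ad, sep = ":"), n)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=invadeR",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if (has_ad) '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  pos <- gm$loci$pos
  if (is.null(pos) || anyNA(pos)) pos <- seq_len(n)
  body <- paste(gm$loci$locus, pos,
                paste0(gm$loci$locus, "_", pos),
                gm$loci$ref, gm$loci$alt, ".", "PASS", ".", fmt,
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
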