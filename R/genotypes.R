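#' Marker matrix of biallelic SNP dosages
#'
#' Container for an individuals x markers table of allele dosages. Dosages are
#' counts of the alternate allele, 0/1/2 for called genotypes (real-valued
#' dosages in \[0, 2\] are accepted for bulked-DNA profiles) and `NA` for
#' missing calls. Row names are individual ids, column names marker ids; both
#' must be unique. An optional marker map carries chromosome and genetic
#' position (Morgans).
#'
#' @param geno numeric matrix, individuals in rows, markers in columns, with
#'   unique dimnames.
#' @param map optional `data.frame` with columns `marker`, `chrom`, `pos`
#'   (position in Morgans), one row per marker, in column order of `geno`.
#' @return An object of class `marker_matrix`: a list with elements `geno`
#'   and `map`.
#' @export
marker_matrix <- function(geno, map = NULL) {
  if (!is.matrix(geno) || !is.numeric(geno))
    stop_arg("`geno` must be a numeric matrix")
  if (is.null(rownames(geno)) ||
      (ncol(geno) > 0L && is.null(colnames(geno))))
    stop_arg("`geno` must have individual ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(geno))) stop_arg("duplicate individual ids")
  if (anyDuplicated(colnames(geno))) stop_arg("duplicate marker ids")
  if (any(!is.na(geno) & !is.finite(geno)))
    stop_arg("non-finite dosages")
  if (any(!is.na(geno) & (geno < 0 | geno > 2)))
    stop_arg("dosages must lie in [0, 2] (or NA)")
  storage.mode(geno) <- "double"
  if (!is.null(map)) {
    if (!is.data.frame(map) || !all(c("marker", "chrom", "pos") %in% names(map)))
      stop_arg("`map` needs columns marker, chrom, pos")
    if (nrow(map) != ncol(geno) || !identical(as.character(map$marker), colnames(geno)))
      stop_arg("`map` must match the marker columns of `geno` in order")
  }
  structure(list(geno = geno, map = map), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$geno))
  cat(sprintf("marker_matrix: %d individuals x %d markers (%d missing calls)\n",
              nrow(x$geno), ncol(x$geno), nmiss))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$geno)

#' Per-marker alternate-allele frequencies
#'
#' Frequency of the counted allele per marker, `mean(dosage) / 2` over
#' non-missing calls.
#'
#' @param mm a [marker_matrix()].
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
allele_freq <- function(mm) {
  colMeans(mm$geno, na.rm = TRUE) / 2
}

# --- file I/O ----------------------------------------------------------------

#' Read and write marker matrices
#'
#' The delimited dialect is a rectangular table: header row of marker ids,
#' first column the individual id, remaining cells dosages 0/1/2 with `NA`
#' for missing, tab- or comma-separated (sniffed on read, tab on write).
#' VCF import uses `vcfR` and maps diploid GT codes `0/0`, `0/1`, `1/1`,
#' `./.` (phased or unphased) to dosages 0, 1, 2, `NA`; any record whose GT
#' references an allele beyond 1 is rejected as multi-allelic. VCF export
#' writes a minimal VCF 4.2 body with one pseudo-sample per individual and
#' phased GT; it requires integer dosages.
#'
#' @param path file path.
#' @param format `"delimited"` or `"vcf"`.
#' @return `read_genotypes()` returns a [marker_matrix()];
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(tab) < 2L) stop_arg("genotype table needs an id column and >= 1 marker")
  ids <- tab[[1L]]
  g <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(g) <- "numeric")
  bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)) & (g < 0 | g > 2))
  raw <- toupper(as.matrix(tab[, -1L, drop = FALSE]))
  unparsed <- which(is.na(g) & !is.na(raw) & !(raw %in% c("NA", ".", "")))
  if (length(unparsed))
    stop_arg(sprintf("unparseable dosage at line %d of %s",
                     (unparsed[1L] - 1L) %% nrow(g) + 2L, path))
  if (length(bad))
    stop_arg(sprintf("dosage outside [0,2] at line %d of %s",
                     (bad[1L] - 1L) %% nrow(g) + 2L, path))
  rownames(g) <- ids
  marker_matrix(g)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[/|]", "", gt)
  if (any(grepl("[2-9]", alleles), na.rm = TRUE))
    stop_arg("multi-allelic GT encountered; only biallelic records are supported")
  d <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  d[known] <- vapply(strsplit(gt[known], "[/|]"),
                     function(a) sum(as.integer(a)), numeric(1L))
  marker_matrix(t(d))
}

#' @rdname read_genotypes
#' @param mm a [marker_matrix()].
#' @export
write_genotypes <- function(mm, path, format = c("delimited", "vcf")) {
  format <- match.arg(format)
  if (format == "delimited") {
    tab <- data.frame(id = rownames(mm$geno), mm$geno, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- mm$geno
    if (any(!is.na(g) & g != round(g)))
      stop_arg("VCF export requires integer dosages (0/1/2)")
    chrom <- if (!is.null(mm$map)) as.character(mm$map$chrom) else rep("1", ncol(g))
    pos <- if (!is.null(mm$map)) as.integer(round(mm$map$pos * 1e6)) + 1L else seq_len(ncol(g))
    gt_codes <- c(`0` = "0|0", `1` = "0|1", `2` = "1|1")
    body <- vapply(seq_len(ncol(g)), function(j) {
      calls <- ifelse(is.na(g[, j]), ".|.", gt_codes[as.character(g[, j])])
      paste(c(chrom[j], pos[j], colnames(g)[j], "A", "T", ".", "PASS", ".", "GT",
              calls), collapse = "\t")
    }, character(1L))
    header <- c("##fileformat=VCFv4.2",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(g)), collapse = "\t"))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

# --- platform intersection, imputation, QC ----------------------------------

#' Restrict two marker matrices to their common markers
#'
#' Both outputs contain exactly the markers present on both platforms, in
#' sorted marker-id order.
#'
#' @param mm_a,mm_b [marker_matrix()] objects.
#' @return List with elements `a` and `b`.
#' @export
intersect_platforms <- function(mm_a, mm_b) {
  common <- sort(intersect(colnames(mm_a$geno), colnames(mm_b$geno)))
  sub <- function(mm) {
    map <- mm$map
    if (!is.null(map)) map <- map[match(common, map$marker), , drop = FALSE]
    marker_matrix(mm$geno[, common, drop = FALSE], map)
  }
  list(a = sub(mm_a), b = sub(mm_b))
}

#' Random imputation of missing genotypes from allele frequencies
#'
#' Each missing call is replaced by a genotype drawn from the
#' Hardy-Weinberg proportions \eqn{\{(1-f)^2, 2f(1-f), f^2\}} at the marker's
#' observed alternate-allele frequency `f` (mode `"hwe"`, default), or by the
#' sum of two independent Bernoulli(`f`) allele draws (mode `"allele"`).
#' Both modes preserve the expected allele frequency. Non-missing calls are
#' untouched.
#'
#' @param mm a [marker_matrix()]; every marker must have at least one
#'   non-missing call.
#' @param seed optional integer seed.
#' @param mode `"hwe"` or `"allele"`.
#' @return A [marker_matrix()] without missing entries.
#' @export
impute_random <- function(mm, seed = NULL, mode = c("hwe", "allele")) {
  mode <- match.arg(mode)
  set_seed_if(seed)
  g <- mm$geno
  nobs <- colSums(!is.na(g))
  if (any(nobs == 0L))
    stop_arg(sprintf("marker %s has no observed calls; cannot impute",
                     colnames(g)[which(nobs == 0L)[1L]]))
  f <- allele_freq(mm)
  for (j in which(colSums(is.na(g)) > 0L)) {
    miss <- which(is.na(g[, j]))
    if (mode == "hwe") {
      p <- c((1 - f[j])^2, 2 * f[j] * (1 - f[j]), f[j]^2)
      g[miss, j] <- sample(0:2, length(miss), replace = TRUE, prob = p)
    } else {
      g[miss, j] <- stats::rbinom(length(miss), 2L, f[j])
    }
  }
  marker_matrix(g, mm$map)
}

#' Monomorphic and minor-allele-frequency marker filter
#'
#' Removes markers whose minor allele frequency (MAF, `min(f, 1-f)`) is zero
#' (monomorphic) and markers with `0 < MAF < maf_threshold`. The inequality
#' is strict: a marker at exactly the threshold is retained.
#'
#' @param mm a [marker_matrix()] with no missing calls (impute first).
#' @param maf_threshold minimum MAF retained (default 0.05).
#' @return List with the filtered `marker_matrix` (`mm`) and a `qc_report`
#'   list of counts (`n_input`, `n_removed_monomorphic`, `n_removed_maf`,
#'   `n_retained`, `maf_threshold`).
#' @export
filter_markers <- function(mm, maf_threshold = 0.05) {
  if (anyNA(mm$geno)) stop_arg("missing calls present; run impute_random() first")
  maf_threshold <- check_prob(maf_threshold, "maf_threshold")
  f <- allele_freq(mm)
  maf <- pmin(f, 1 - f)
  mono <- maf == 0
  low <- !mono & maf < maf_threshold
  keep <- !(mono | low)
  map <- mm$map
  if (!is.null(map)) map <- map[keep, , drop = FALSE]
  report <- list(n_input = ncol(mm$geno),
                 n_removed_monomorphic = sum(mono),
                 n_removed_maf = sum(low),
                 n_retained = sum(keep),
                 maf_threshold = maf_threshold)
  class(report) <- "qc_report"
  list(mm = marker_matrix(mm$geno[, keep, drop = FALSE], map), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("marker QC: %d input, %d monomorphic removed, ",
                     "%d below MAF %.3g removed, %d retained\n"),
              x$n_input, x$n_removed_monomorphic, x$n_removed_maf,
              x$maf_threshold, x$n_retained))
  invisible(x)
}
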