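#' Pedigree records
#'
#' Three-column pedigree (id, parent1, parent2) with an optional per-record
#' count of extra selfing generations. Unknown parents are `NA` (the value
#' `"0"` read from file is treated as unknown). Records are checked for
#' duplicate ids and for cycles; rows may be given in any order.
#'
#' The `selfing` column supports derived inbred lines: a record with parents
#' (p1, p2) and `selfing = g` denotes a line obtained from a (p1 x p2)
#' offspring by `g` further generations of self-fertilization.
#'
#' @param id,parent1,parent2 character vectors.
#' @param selfing integer vector of extra selfing generations (default 0).
#' @return A `data.frame` of class `rcgs_pedigree`, sorted so parents
#'   precede offspring.
#' @export
pedigree <- function(id, parent1, parent2, selfing = 0L) {
  id <- as.character(id)
  p1 <- as.character(parent1); p2 <- as.character(parent2)
  p1[p1 %in% c("0", "")] <- NA; p2[p2 %in% c("0", "")] <- NA
  if (anyDuplicated(id)) stop_arg("duplicate ids in pedigree")
  if (any(id == p1 | id == p2, na.rm = TRUE))
    stop_arg("individual listed as its own parent")
  known <- unique(c(p1, p2)); known <- known[!is.na(known)]
  miss <- setdiff(known, id)
  if (length(miss))
    stop_arg("parents not present as records: ", paste(miss, collapse = ", "))
  ped <- data.frame(id = id, parent1 = p1, parent2 = p2,
                    selfing = rep_len(as.integer(selfing), length(id)))
  # Kahn topological sort; failure to exhaust the records means a cycle
  order <- integer(0)
  placed <- character(0)
  remaining <- seq_len(nrow(ped))
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      ps <- c(ped$parent1[i], ped$parent2[i])
      all(is.na(ps) | ps %in% placed)
    }, logical(1L))]
    if (!length(ready)) stop_arg("cycle detected in pedigree")
    order <- c(order, ready)
    placed <- c(placed, ped$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  ped <- ped[order, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("rcgs_pedigree", "data.frame")
  ped
}

#' Read / write 3-column pedigree files
#'
#' Whitespace- or tab-separated text with columns id, parent1, parent2 and an
#' optional fourth selfing-generation column; `0` marks an unknown parent.
#'
#' @param path file path.
#' @return [pedigree()] object; the writer returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE, colClasses = "character")
  selfing <- if (ncol(tab) >= 4L) as.integer(tab[[4L]]) else 0L
  pedigree(tab[[1L]], tab[[2L]], tab[[3L]], selfing)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$parent1[is.na(out$parent1)] <- "0"
  out$parent2[is.na(out$parent2)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relationship matrix container
#'
#' @param mat symmetric numeric matrix with id dimnames.
#' @param kind `"genomic"`, `"pedigree"` or `"kernel"`.
#' @param bandwidth kernel bandwidth (kernel matrices only).
#' @return The matrix with class `relationship_matrix` and attributes
#'   `kind` / `bandwidth`.
#' @export
relationship_matrix <- function(mat, kind = c("genomic", "pedigree", "kernel"),
                                bandwidth = NULL) {
  kind <- match.arg(kind)
  if (!isSymmetric(unname(mat), tol = 1e-10))
    stop_arg("relationship matrix must be symmetric")
  structure(mat, kind = kind, bandwidth = bandwidth,
            class = c("relationship_matrix", "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d x %d\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  if (!is.null(attr(x, "bandwidth")))
    cat(sprintf("  bandwidth h = %.6g\n", attr(x, "bandwidth")))
  invisible(x)
}

# center to mean 0 and scale to unit SD by marker column, optionally reusing
# reference moments (e.g. training-set moments for selection candidates)
standardize_markers <- function(geno, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(geno)
  if (is.null(scale)) scale <- apply(geno, 2L, stats::sd)
  if (any(scale == 0))
    stop_arg("zero-variance marker column; run filter_markers() first")
  M <- sweep(sweep(geno, 2L, center), 2L, scale, "/")
  attr(M, "center") <- center
  attr(M, "scale") <- scale
  M
}

#' Genomic relationship matrix K = MM'/p
#'
#' Marker columns are centered to mean 0 and scaled to unit standard
#' deviation; `K = M M' / p` with `p` the number of markers. For a large
#' random population the mean diagonal is close to 1. `center`/`scale` allow
#' standardizing selection candidates with training-set moments.
#'
#' @param mm a [marker_matrix()] or dosage matrix without missing values;
#'   all markers must be polymorphic.
#' @param center,scale optional reference column moments.
#' @return A [relationship_matrix()] of kind `"genomic"`.
#' @export
genomic_matrix <- function(mm, center = NULL, scale = NULL) {
  geno <- if (inherits(mm, "marker_matrix")) mm$geno else mm
  if (anyNA(geno)) stop_arg("missing dosages; impute first")
  if (nrow(geno) < 2L) stop_arg("need at least 2 individuals")
  M <- standardize_markers(geno, center, scale)
  K <- tcrossprod(M) / ncol(M)
  relationship_matrix((K + t(K)) / 2, kind = "genomic")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Implements the standard recurrences: `A_ii = 1 + F_i` with
#' `F_i = A_{p1,p2} / 2`, and `A_ij = (A_{j,p1} + A_{j,p2}) / 2` for `j`
#' earlier than `i`; unknown parents are treated as unrelated and
#' non-inbred. A record with `selfing = g` has its diagonal advanced through
#' `g` generations of selfing via `A' = 1 + A/2` applied `g` times
#' (equivalently `A' = 2 - (2 - A)/2^g`); relationships to other records are
#' unchanged, as selfing does not alter expected kinship with relatives.
#' `A` equals twice the coefficient-of-parentage (kinship) matrix; use
#' [cop_matrix()] for the COP view.
#'
#' @param ped a [pedigree()].
#' @return A [relationship_matrix()] of kind `"pedigree"` in pedigree order.
#' @export
pedigree_matrix <- function(ped) {
  n <- nrow(ped)
  idx1 <- match(ped$parent1, ped$id)
  idx2 <- match(ped$parent2, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    p1 <- idx1[i]; p2 <- idx2[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      a1 <- if (is.na(p1)) rep(0, length(j)) else A[j, p1]
      a2 <- if (is.na(p2)) rep(0, length(j)) else A[j, p2]
      A[j, i] <- A[i, j] <- (a1 + a2) / 2
    }
    Fi <- if (is.na(p1) || is.na(p2)) 0 else A[p1, p2] / 2
    A[i, i] <- 1 + Fi
    g <- ped$selfing[i]
    if (g > 0L) A[i, i] <- 2 - (2 - A[i, i]) / 2^g
  }
  relationship_matrix(A, kind = "pedigree")
}

#' Coefficient-of-parentage view of a pedigree matrix
#'
#' COP (kinship) is half the numerator relationship: `A / 2`.
#'
#' @param ped a [pedigree()] or a pedigree [relationship_matrix()].
#' @return Numeric matrix of kinship coefficients.
#' @export
cop_matrix <- function(ped) {
  A <- if (inherits(ped, "relationship_matrix")) ped else pedigree_matrix(ped)
  unclass(A) / 2
}

#' Squared Euclidean distances and their off-diagonal median
#'
#' Distances are computed on the same centered and standardized marker
#' matrix that [genomic_matrix()] uses, so the genomic matrix and the
#' Gaussian kernels share one preprocessing path. `m` is the median of the
#' strictly off-diagonal squared distances, each unordered pair counted
#' once.
#'
#' @inheritParams genomic_matrix
#' @return List of class `distance_summary`: `d2` (squared-distance matrix)
#'   and `m` (off-diagonal median).
#' @export
distance_summary <- function(mm, center = NULL, scale = NULL) {
  geno <- if (inherits(mm, "marker_matrix")) mm$geno else mm
  M <- standardize_markers(geno, center, scale)
  d2 <- as.matrix(stats::dist(M))^2
  m <- stats::median(d2[upper.tri(d2)])
  structure(list(d2 = d2, m = m), class = "distance_summary")
}

#' Gaussian kernels with averaged bandwidths
#'
#' For each multiplier `c` the bandwidth is `h = c / m`, with `m` the median
#' off-diagonal squared distance, and the kernel is
#' \eqn{K(x_i, x_{i'}) = \exp(-h\, d^2_{ii'})}. Scaling `h` by `1/m` makes
#' `h d^2` scale-free. The default multipliers (1/5, 1, 5) give one kernel
#' flatter and one sharper than the median-calibrated one; larger `c` means
#' smaller off-diagonal entries. Diagonals are exactly 1.
#'
#' @param ds a [distance_summary()].
#' @param multipliers numeric vector of bandwidth multipliers.
#' @return List of kernel [relationship_matrix()] objects, one per
#'   multiplier, named `K1`, `K2`, ...
#' @export
gaussian_kernels <- function(ds, multipliers = c(1 / 5, 1, 5)) {
  if (!inherits(ds, "distance_summary")) stop_arg("`ds` must be a distance_summary")
  if (ds$m <= 0) stop_arg("median squared distance must be > 0")
  ks <- lapply(multipliers, function(cc) {
    h <- cc / ds$m
    K <- exp(-h * ds$d2)
    diag(K) <- 1
    relationship_matrix(K, kind = "kernel", bandwidth = h)
  })
  names(ks) <- paste0("K", seq_along(ks))
  ks
}

#' Nei's standard genetic distance
#'
#' For biallelic loci with frequency vectors `x` and `y` of the same allele:
#' `Jx = mean(x^2 + (1-x)^2)`, `Jy` likewise,
#' `Jxy = mean(x y + (1-x)(1-y))`, and `D = -log(Jxy / sqrt(Jx Jy))`.
#' `D` is 0 for identical profiles and `Inf` when the normalized identity is
#' zero (alleles alternately fixed at every locus). An individual inbred
#' line can be treated as a one-line population with frequency
#' `dosage / 2`.
#'
#' @param freq_a,freq_b numeric vectors of per-locus allele frequencies in
#'   \[0, 1\], equal length.
#' @return Non-negative numeric scalar (possibly `Inf`).
#' @export
nei_distance <- function(freq_a, freq_b) {
  if (length(freq_a) != length(freq_b)) stop_arg("frequency vectors differ in length")
  if (any(freq_a < 0 | freq_a > 1 | freq_b < 0 | freq_b > 1, na.rm = TRUE))
    stop_arg("frequencies must lie in [0, 1]")
  jx <- mean(freq_a^2 + (1 - freq_a)^2)
  jy <- mean(freq_b^2 + (1 - freq_b)^2)
  jxy <- mean(freq_a * freq_b + (1 - freq_a) * (1 - freq_b))
  if (jxy == 0) return(Inf)
  -log(jxy / sqrt(jx * jy))
}

#' Pairwise Nei distance matrix
#'
#' Rows of `freq` are allele-frequency profiles (lines at `dosage / 2`, or
#' group frequencies); all pairwise distances are returned.
#'
#' @param freq numeric matrix, profiles x loci.
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
nei_distance_matrix <- function(freq) {
  D <- nei_cross(freq, freq)
  diag(D) <- 0
  D
}

# all Nei distances between rows of freq_a and rows of freq_b, by blocked
# identity sums: J(X, Y) = (XY' + (1-X)(1-Y)') / L
nei_cross <- function(freq_a, freq_b) {
  L <- ncol(freq_a)
  if (ncol(freq_b) != L) stop_arg("frequency matrices differ in locus count")
  jxy <- (tcrossprod(freq_a, freq_b) +
            tcrossprod(1 - freq_a, 1 - freq_b)) / L
  ja <- rowMeans(freq_a^2 + (1 - freq_a)^2)
  jb <- rowMeans(freq_b^2 + (1 - freq_b)^2)
  D <- -log(jxy / sqrt(outer(ja, jb)))
  D[jxy == 0] <- Inf
  D
}

#' Principal component scores of a marker matrix
#'
#' Eigen-decomposition of the covariance of centered dosages via
#' [stats::prcomp()]. The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param mm a [marker_matrix()] or dosage matrix.
#' @param n_components number of components returned.
#' @return List with `scores` (individuals x components) and
#'   `explained` (fraction of variance per component).
#' @export
pca_scores <- function(mm, n_components = 2L) {
  geno <- if (inherits(mm, "marker_matrix")) mm$geno else mm
  n_components <- check_count(n_components, "n_components")
  pc <- stats::prcomp(geno, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1L))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  list(scores = scores,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
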