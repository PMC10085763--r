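#' Specify a Bayesian genomic prediction model
#'
#' A model is "intercept + sum of covariance-structured random effects +
#' error": `y = mu 1 + sum_k u_k + e`, with `u_k ~ N(0, sigma2_k K_k)` and
#' `e ~ N(0, sigma2_e I)`. The four standard presets expand to
#' \describe{
#'   \item{GBLUP}{one genomic term `K`.}
#'   \item{P+GBLUP}{pedigree term `A` plus genomic `K`.}
#'   \item{RKHS-KA}{three Gaussian kernels `K1`, `K2`, `K3` (kernel
#'     averaging).}
#'   \item{P+RKHS-KA}{`A` plus the three kernels.}
#' }
#' Alternatively pass an explicit named list of relationship matrices as
#' `terms`. All matrices must be square, symmetric and share one id
#' ordering.
#'
#' @param preset one of `"GBLUP"`, `"P+GBLUP"`, `"RKHS-KA"`, `"P+RKHS-KA"`,
#'   or `NULL` when `terms` is given directly.
#' @param G genomic [relationship_matrix()] (presets with K).
#' @param A pedigree [relationship_matrix()] (presets with P).
#' @param kernels list of kernel matrices from [gaussian_kernels()].
#' @param terms explicit named list of matrices (overrides `preset`).
#' @param niter,burnin,thin Gibbs chain settings.
#' @param df0 prior degrees of freedom of every scaled-inverse-chi-squared
#'   variance prior.
#' @param R2 prior share of phenotypic variance attributed to the genetic
#'   terms jointly (split equally among them); the error prior gets
#'   `1 - R2`.
#' @param seed optional integer seed for the chain.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(preset = c("GBLUP", "P+GBLUP", "RKHS-KA", "P+RKHS-KA"),
                       G = NULL, A = NULL, kernels = NULL, terms = NULL,
                       niter = 12000L, burnin = 2000L, thin = 5L,
                       df0 = 5, R2 = 0.5, seed = NULL) {
  if (is.null(terms)) {
    preset <- match.arg(preset)
    need <- function(x, what) if (is.null(x))
      stop_arg(sprintf("preset %s needs `%s`", preset, what)) else x
    terms <- switch(preset,
      "GBLUP" = list(K = need(G, "G")),
      "P+GBLUP" = list(A = need(A, "A"), K = need(G, "G")),
      "RKHS-KA" = need(kernels, "kernels"),
      "P+RKHS-KA" = c(list(A = need(A, "A")), need(kernels, "kernels")))
  } else {
    preset <- "custom"
    if (is.null(names(terms)) || any(names(terms) == ""))
      stop_arg("`terms` must be a named list")
  }
  if (!length(terms)) stop_arg("model needs at least one random term")
  ids <- rownames(terms[[1L]])
  for (K in terms) {
    if (nrow(K) != ncol(K)) stop_arg("term matrices must be square")
    if (!identical(rownames(K), ids))
      stop_arg("all term matrices must share one id ordering")
  }
  niter <- check_count(niter, "niter"); burnin <- check_count(burnin, "burnin", 0L)
  thin <- check_count(thin, "thin")
  if (burnin >= niter) stop_arg("burnin must be smaller than niter")
  structure(list(preset = preset, terms = terms, ids = ids, niter = niter,
                 burnin = burnin, thin = thin, df0 = df0, R2 = R2,
                 seed = seed),
            class = "model_spec")
}

#' Fit a multi-kernel Bayesian mixed model by Gibbs sampling
#'
#' Each random term is sampled on the eigenbasis of its covariance matrix:
#' with `K = U diag(d) U'` and `u = U b`, the prior is
#' `b_j ~ N(0, sigma2_k d_j)` and, because `U` is orthonormal, the full
#' conditional of `b` factorizes into independent normals. Eigenvalues below
#' `1e-8 * max(d)` are dropped, restricting each effect to the numerically
#' non-null eigenspace. Variance components have scaled-inverse-chi-squared
#' full conditionals; the prior scale of each genetic term corresponds to an
#' equal share of `R2` of the phenotypic variance (error prior: `1 - R2`).
#' The intercept has a flat prior. Missing phenotypes are treated as latent
#' variables and redrawn from their conditional normal each sweep, so
#' unphenotyped individuals (e.g. selection candidates) are predicted
#' jointly with model fitting.
#'
#' @param y numeric phenotype vector aligned with the spec's ids; `NA`
#'   marks unphenotyped individuals (at least 10 observed values required).
#' @param spec a [model_spec()].
#' @param fixed_var optional named numeric vector clamping variance
#'   components instead of sampling them; names are the term names plus
#'   `"error"`. Used for validation against closed-form BLUP.
#' @return An object of class `gs_fit`: posterior means and SDs of the
#'   intercept and variance components, per-term posterior-mean genetic
#'   values, total genetic values (`gebv = mu + sum of terms`), thinned
#'   scalar samples, effective sample sizes, and the chain settings.
#' @export
fit_gs <- function(y, spec, fixed_var = NULL) {
  if (!inherits(spec, "model_spec")) stop_arg("`spec` must be a model_spec")
  n <- length(spec$ids)
  if (length(y) != n) stop_arg("length(y) must match the spec's ids")
  if (!is.null(names(y)) && !identical(names(y), spec$ids))
    stop_arg("names(y) must match the spec's ids")
  obs <- which(!is.na(y))
  if (length(obs) < 10L) stop_arg("need at least 10 non-missing phenotypes")
  set_seed_if(spec$seed)

  nt <- length(spec$terms)
  tn <- names(spec$terms)
  eig <- lapply(spec$terms, function(K) {
    e <- eigen(unclass(K), symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(e$values))
      stop_arg("term matrix is not positive semi-definite")
    keep <- e$values > 1e-8 * max(e$values)
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })

  vy <- stats::var(y[obs])
  df0 <- spec$df0
  S_g <- vy * spec$R2 / nt * (df0 + 2) / df0
  S_e <- vy * (1 - spec$R2) * (df0 + 2) / df0

  mu <- mean(y[obs])
  sigma2 <- stats::setNames(c(rep(vy * spec$R2 / nt, nt), vy * (1 - spec$R2)),
                            c(tn, "error"))
  if (!is.null(fixed_var)) {
    if (!all(names(sigma2) %in% names(fixed_var)))
      stop_arg("fixed_var must name every term and 'error'")
    sigma2 <- fixed_var[names(sigma2)]
  }
  u <- matrix(0, n, nt)
  utot <- numeric(n)
  ystar <- y
  ystar[-obs] <- mu

  nsave <- (spec$niter - spec$burnin) %/% spec$thin
  scal <- matrix(NA_real_, nsave, nt + 2L,
                 dimnames = list(NULL, c("mu", tn, "error")))
  usum <- matrix(0, n, nt)
  gsum <- numeric(n); gsumsq <- numeric(n)
  saved <- 0L

  for (it in seq_len(spec$niter)) {
    # intercept (flat prior)
    mu <- stats::rnorm(1L, mean(ystar - utot), sqrt(sigma2[["error"]] / n))
    # random terms on their eigenbases
    for (k in seq_len(nt)) {
      U <- eig[[k]]$U; d <- eig[[k]]$d
      res_k <- ystar - mu - utot + u[, k]
      rhs <- crossprod(U, res_k)
      prec <- 1 / sigma2[["error"]] + 1 / (sigma2[[k]] * d)
      b <- stats::rnorm(length(d), (rhs / sigma2[["error"]]) / prec,
                        sqrt(1 / prec))
      unew <- drop(U %*% b)
      utot <- utot - u[, k] + unew
      u[, k] <- unew
      if (is.null(fixed_var)) {
        ss <- sum(b^2 / d)
        sigma2[k] <- (ss + df0 * S_g) / stats::rchisq(1L, df0 + length(d))
      }
    }
    # error variance and latent phenotypes
    e <- ystar - mu - utot
    if (is.null(fixed_var))
      sigma2["error"] <- (sum(e^2) + df0 * S_e) / stats::rchisq(1L, df0 + n)
    if (length(obs) < n)
      ystar[-obs] <- mu + utot[-obs] +
        stats::rnorm(n - length(obs), 0, sqrt(sigma2[["error"]]))
    if (!all(is.finite(sigma2)) || !all(is.finite(utot)))
      stop_arg(sprintf("divergent chain at iteration %d (non-finite draw)", it))
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
      saved <- saved + 1L
      scal[saved, ] <- c(mu, sigma2)
      usum <- usum + u
      g <- mu + utot
      gsum <- gsum + g
      gsumsq <- gsumsq + g^2
    }
  }

  post_mean <- colMeans(scal)
  post_sd <- apply(scal, 2L, stats::sd)
  gebv <- gsum / saved
  gebv_sd <- sqrt(pmax(gsumsq / saved - gebv^2, 0))
  structure(list(
    ids = spec$ids, preset = spec$preset,
    mu = post_mean[["mu"]],
    var_components = post_mean[c(tn, "error")],
    var_sd = post_sd[c(tn, "error")],
    u = stats::setNames(as.data.frame(usum / saved), tn),
    gebv = stats::setNames(gebv, spec$ids),
    gebv_sd = stats::setNames(gebv_sd, spec$ids),
    phenotyped = stats::setNames(!is.na(y), spec$ids),
    samples = scal,
    ess = apply(scal, 2L, ess),
    n_saved = saved,
    settings = spec[c("niter", "burnin", "thin", "df0", "R2")]),
    class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit (%s): %d individuals (%d phenotyped), %d saved samples\n",
              x$preset, length(x$ids), sum(x$phenotyped), x$n_saved))
  cat("posterior mean variance components:\n")
  print(round(x$var_components, 4))
  invisible(x)
}

#' Extract predicted genetic values (GEBVs)
#'
#' The GEBV of an individual is the posterior mean of `mu + sum of its
#' random-term effects`, available for phenotyped and unphenotyped
#' individuals alike.
#'
#' @param object a [fit_gs()] result.
#' @param ids individuals to extract (default all).
#' @param ... unused.
#' @return `data.frame` with columns `id`, `gebv`, `sd`, `phenotyped`.
#' @export
predict.gs_fit <- function(object, ids = NULL, ...) {
  if (is.null(ids)) ids <- object$ids
  miss <- setdiff(ids, object$ids)
  if (length(miss)) stop_arg("ids not in fit: ", paste(miss, collapse = ", "))
  data.frame(id = ids,
             gebv = unname(object$gebv[ids]),
             sd = unname(object$gebv_sd[ids]),
             phenotyped = unname(object$phenotyped[ids]))
}

#' Truncation selection on a GEBV table
#'
#' Returns the ids of the `n_select` largest predicted values; ties are
#' broken by lexicographic id order for reproducibility.
#'
#' @param gebvs `data.frame` with columns `id` and `gebv` (as returned by
#'   [predict.gs_fit()]), or a named numeric vector.
#' @param n_select number of individuals to keep.
#' @return Character vector of selected ids, in decreasing GEBV order.
#' @export
rank_and_select <- function(gebvs, n_select) {
  if (is.numeric(gebvs)) gebvs <- data.frame(id = names(gebvs), gebv = unname(gebvs))
  n_select <- check_count(n_select, "n_select")
  if (n_select > nrow(gebvs)) stop_arg("n_select exceeds the table size")
  ord <- order(-gebvs$gebv, gebvs$id)
  gebvs$id[ord][seq_len(n_select)]
}

#' Per-cycle GEBV means and average increment
#'
#' @param gebvs_by_cycle named list (in cycle order) of numeric GEBV
#'   vectors or GEBV tables.
#' @return List with `means` (named per-cycle means) and `increment`,
#'   the mean per-cycle change `(last - first) / n_intervals`.
#' @export
gebv_cycle_summary <- function(gebvs_by_cycle) {
  vals <- lapply(gebvs_by_cycle, function(x) if (is.data.frame(x)) x$gebv else x)
  means <- vapply(vals, mean, numeric(1L))
  k <- length(means)
  if (k < 2L) stop_arg("need at least two cycles")
  list(means = means, increment = (means[[k]] - means[[1L]]) / (k - 1L))
}
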