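#' Line-mean heritability from variance components
#'
#' Evaluates
#' \deqn{h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/e +
#'   \sigma^2_e/(r e)}}
#' with `r` replications and `e` environments (years). With `r = e = 1` this
#' is the line-mean heritability on a single-trial basis.
#'
#' @param sigma_g genotypic variance.
#' @param sigma_e residual (error) variance.
#' @param sigma_ge genotype-by-environment variance (default 0).
#' @param r number of replications.
#' @param e number of environments.
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(sigma_g, sigma_e, sigma_ge = 0, r = 1, e = 1) {
  if (any(c(sigma_g, sigma_e, sigma_ge) < 0)) stop_arg("variances must be >= 0")
  r <- check_count(r, "r"); e <- check_count(e, "e")
  denom <- sigma_g + sigma_ge / e + sigma_e / (r * e)
  if (denom <= 0) stop_arg("denominator must be > 0")
  sigma_g / denom
}

#' Within- and between-family cross-validation of prediction ability
#'
#' Prediction ability is the Pearson correlation between predicted and
#' observed values in held-out data. Two schemes:
#' \describe{
#'   \item{within}{k-fold cross-validation repeated `repeats` times inside
#'     each family; by default the training set is the remainder of that
#'     family only (`train_within_only = FALSE` adds all other families).}
#'   \item{between}{leave-one-family-out: train on all other families,
#'     predict the left-out family.}
#' }
#' Held-out phenotypes are set missing and predicted jointly by the Gibbs
#' engine. Relationship structures for each split are taken as sub-blocks of
#' the full-data matrices in `structures`, so marker standardization and
#' kernel bandwidths come from the full data (one preprocessing path).
#' Folds whose observed values have zero variance are skipped.
#'
#' @param y named numeric vector of line values (e.g. BLUEs).
#' @param family named character vector, line id -> family.
#' @param structures named list of full relationship matrices (ids covering
#'   all lines), e.g. `list(A = ..., K1 = ..., ...)`.
#' @param mode `"within"`, `"between"` or both.
#' @param k folds for the within scheme.
#' @param repeats repeats of the within scheme.
#' @param train_within_only logical; see above.
#' @param niter,burnin,thin chain settings for the per-fold fits.
#' @param seed optional integer seed.
#' @return `data.frame` of class `cv_result` with columns `family`, `mode`,
#'   `fold`, `repeat.`, `ability`, plus a per-family mean ability summary in
#'   attribute `"summary"`.
#' @export
cross_validate <- function(y, family, structures, mode = c("within", "between"),
                           k = 5L, repeats = 10L, train_within_only = TRUE,
                           niter = 3000L, burnin = 500L, thin = 5L,
                           seed = NULL) {
  mode <- match.arg(mode, several.ok = TRUE)
  set_seed_if(seed)
  ids <- names(y)
  if (is.null(ids)) stop_arg("`y` must be named by line id")
  fams <- unique(unname(family[ids]))
  if ("between" %in% mode && length(fams) < 2L)
    stop_arg("between-family mode needs >= 2 families")
  rows <- list()
  fit_split <- function(train_ids, test_ids) {
    all_ids <- c(train_ids, test_ids)
    terms <- lapply(structures, function(S)
      S[all_ids, all_ids, drop = FALSE])
    yy <- stats::setNames(c(y[train_ids], rep(NA_real_, length(test_ids))),
                          all_ids)
    sp <- model_spec(terms = terms, niter = niter, burnin = burnin, thin = thin)
    fit <- fit_gs(yy, sp)
    unname(fit$gebv[test_ids])
  }
  if ("within" %in% mode) {
    for (fm in fams) {
      fids <- ids[family[ids] == fm]
      if (length(fids) < k) next
      for (rp in seq_len(repeats)) {
        fold <- sample(rep_len(seq_len(k), length(fids)))
        for (fd in seq_len(k)) {
          test <- fids[fold == fd]
          if (length(test) < 2L || stats::sd(y[test]) == 0) next
          train <- setdiff(fids, test)
          if (!train_within_only) train <- c(train, setdiff(ids, fids))
          pred <- fit_split(train, test)
          rows[[length(rows) + 1L]] <- data.frame(
            family = fm, mode = "within", fold = fd, `repeat.` = rp,
            ability = stats::cor(pred, y[test]))
        }
      }
    }
  }
  if ("between" %in% mode) {
    for (fm in fams) {
      test <- ids[family[ids] == fm]
      if (length(test) < 2L || stats::sd(y[test]) == 0) next
      train <- setdiff(ids, test)
      pred <- fit_split(train, test)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fm, mode = "between", fold = 1L, `repeat.` = 1L,
        ability = stats::cor(pred, y[test]))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_arg("no usable folds")
  summ <- stats::aggregate(ability ~ family + mode, out, mean)
  attr(out, "summary") <- summ
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Per-cycle, per-year and combined phenotype means
#'
#' The combined mean of a cycle is the average of its per-year means
#' (balanced-design convention), not the grand plot mean.
#'
#' @param pheno `data.frame` with columns `cycle`, `year`, `value`.
#' @return `data.frame` with one row per cycle: `n_lines` (per year,
#'   maximum across years of distinct lines if a `line` column is present,
#'   otherwise observations per year), one column per year, and `combined`.
#' @export
cycle_means <- function(pheno) {
  stopifnot(all(c("cycle", "year", "value") %in% names(pheno)))
  yrs <- sort(unique(pheno$year))
  cyc <- sort(unique(pheno$cycle))
  tab <- data.frame(cycle = cyc)
  for (yr in yrs)
    tab[[paste0("year_", yr)]] <- vapply(cyc, function(cc)
      mean(pheno$value[pheno$cycle == cc & pheno$year == yr]), numeric(1L))
  tab$combined <- rowMeans(tab[, paste0("year_", yrs), drop = FALSE])
  if ("line" %in% names(pheno)) {
    tab$n_lines <- vapply(cyc, function(cc)
      length(unique(pheno$line[pheno$cycle == cc])), integer(1L))
  }
  tab
}

#' Realized genetic gain between first and last cycle
#'
#' @param first_mean,last_mean cycle means on the trait scale.
#' @param n_cycles number of selection cycles between them (>= 1).
#' @return List with `per_cycle` = `(last - first) / n_cycles` and
#'   `percent` = `100 (last - first) / first`.
#' @export
realized_gain <- function(first_mean, last_mean, n_cycles) {
  n_cycles <- check_count(n_cycles, "n_cycles")
  if (first_mean <= 0) stop_arg("first_mean must be > 0 for a percent gain")
  list(per_cycle = (last_mean - first_mean) / n_cycles,
       percent = 100 * (last_mean - first_mean) / first_mean)
}

#' Genetic gain per year
#'
#' `(n_cycles * per_cycle_gain) / elapsed_years`.
#'
#' @param per_cycle_gain gain per selection cycle (trait units).
#' @param n_cycles number of cycles achieved.
#' @param elapsed_years elapsed time in years.
#' @return Gain per year in trait units.
#' @export
gain_per_year <- function(per_cycle_gain, n_cycles, elapsed_years) {
  if (elapsed_years <= 0) stop_arg("elapsed_years must be > 0")
  (n_cycles * per_cycle_gain) / elapsed_years
}

#' Least significant difference
#'
#' `t(1 - alpha/2, df) * sqrt(2 * mse / r)` for comparing two means
#' estimated from `r` replicates with error mean square `mse`.
#'
#' @param mse error mean square.
#' @param df_error error degrees of freedom.
#' @param r replicates per mean.
#' @param alpha significance level (default 0.05).
#' @return The LSD on the trait scale.
#' @export
lsd <- function(mse, df_error, r, alpha = 0.05) {
  if (mse < 0) stop_arg("mse must be >= 0")
  stats::qt(1 - alpha / 2, df_error) * sqrt(2 * mse / r)
}

#' Within- and between-cycle diversity from Nei's distance
#'
#' Treats each line as an allele-frequency profile (`dosage / 2`) and
#' summarizes pairwise Nei standard distances within each cycle and across
#' each cycle pair (mean and SD). Infinite distances (disjoint fixation)
#' propagate to the summaries.
#'
#' @param mm_by_cycle named list (cycle order) of dosage matrices or
#'   [marker_matrix()] objects on a common marker set.
#' @return List with `within` (`data.frame`: cycle, n_lines, mean, sd) and
#'   `between` (`data.frame`: cycle_a, cycle_b, mean, sd).
#' @export
diversity_summary <- function(mm_by_cycle) {
  mats <- lapply(mm_by_cycle, function(m)
    (if (inherits(m, "marker_matrix")) m$geno else m) / 2)
  cycles <- names(mats)
  within <- do.call(rbind, lapply(cycles, function(cc) {
    Dm <- nei_distance_matrix(mats[[cc]])
    v <- Dm[upper.tri(Dm)]
    data.frame(cycle = cc, n_lines = nrow(mats[[cc]]),
               mean = mean(v), sd = stats::sd(v))
  }))
  between <- NULL
  if (length(cycles) > 1L) {
    combs <- utils::combn(cycles, 2L)
    between <- do.call(rbind, apply(combs, 2L, function(pr) {
      v <- as.vector(nei_cross(mats[[pr[1L]]], mats[[pr[2L]]]))
      data.frame(cycle_a = pr[1L], cycle_b = pr[2L],
                 mean = mean(v), sd = stats::sd(v))
    }))
  }
  list(within = within, between = between)
}
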