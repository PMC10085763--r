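# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: BLUP via a direct generalized
# least-squares solve of the mixed model, pedigree expectations via
# gene-dropping Monte Carlo, counting rules via brute-force enumeration.

# Closed-form BLUP for y = mu 1 + sum_k u_k + e with known variances.
# Returns mu, per-term effects at all individuals, and the total prediction.
# `obs` indexes the phenotyped individuals; effects for the others are the
# conditional means given the observed records.
blup_oracle <- function(y, terms, sigma2, sigma2_e, obs = seq_along(y)) {
  n <- length(y)
  V <- diag(sigma2_e, length(obs))
  for (k in seq_along(terms))
    V <- V + sigma2[k] * unclass(terms[[k]])[obs, obs]
  Vi <- solve(V)
  one <- rep(1, length(obs))
  mu <- drop(crossprod(one, Vi %*% y[obs]) / crossprod(one, Vi %*% one))
  r <- Vi %*% (y[obs] - mu)
  u <- lapply(seq_along(terms), function(k)
    drop(sigma2[k] * unclass(terms[[k]])[, obs] %*% r))
  total <- mu + Reduce(`+`, u)
  list(mu = mu, u = u, total = total)
}

# Gene-dropping estimate of the numerator relationship matrix: unique
# founder alleles are dropped through the pedigree nrep times; kinship is
# the identity probability of random alleles, A = 2 * kinship off-diagonal
# and 1 + P(self-identity) on the diagonal. Also returns per-entry Monte
# Carlo standard errors.
gene_drop_A <- function(ped, nrep = 1e5) {
  n <- nrow(ped)
  A1 <- matrix(0L, nrep, n)
  A2 <- matrix(0L, nrep, n)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(p1[i])) {
      a1 <- rep.int(lab + 1L, nrep); lab <- lab + 1L
    } else {
      pick <- stats::runif(nrep) < 0.5
      a1 <- ifelse(pick, A1[, p1[i]], A2[, p1[i]])
    }
    if (is.na(p2[i])) {
      a2 <- rep.int(lab + 1L, nrep); lab <- lab + 1L
    } else {
      pick <- stats::runif(nrep) < 0.5
      a2 <- ifelse(pick, A1[, p2[i]], A2[, p2[i]])
    }
    for (g in seq_len(ped$selfing[i])) {
      n1 <- ifelse(stats::runif(nrep) < 0.5, a1, a2)
      n2 <- ifelse(stats::runif(nrep) < 0.5, a1, a2)
      a1 <- n1; a2 <- n2
    }
    A1[, i] <- a1; A2[, i] <- a2
  }
  Ahat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  Ase <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      z <- 1 + (A1[, i] == A2[, i])
    } else {
      z <- 2 * ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                  (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 4
    }
    Ahat[i, j] <- Ahat[j, i] <- mean(z)
    Ase[i, j] <- Ase[j, i] <- stats::sd(z) / sqrt(nrep)
  }
  list(A = Ahat, se = Ase)
}

# random pedigree: nf unrelated founders, then descendants of earlier
# records with random extra selfing generations
random_pedigree <- function(n, nf = 8L, max_selfing = 2L) {
  id <- sprintf("I%02d", seq_len(n))
  par1 <- par2 <- rep(NA_character_, n)
  selfing <- integer(n)
  for (i in (nf + 1L):n) {
    pick <- sample.int(i - 1L, 2L)
    par1[i] <- id[pick[1L]]
    par2[i] <- id[pick[2L]]
    selfing[i] <- sample.int(max_selfing + 1L, 1L) - 1L
  }
  pedigree(id, par1, par2, selfing)
}

# small random marker matrix with all markers polymorphic
random_dosages <- function(n, p, f = NULL) {
  if (is.null(f)) f <- stats::runif(p, 0.15, 0.85)
  repeat {
    g <- matrix(as.double(stats::rbinom(n * p, 2L, rep(f, each = n))), n, p,
                dimnames = list(sprintf("I%03d", seq_len(n)),
                                sprintf("M%03d", seq_len(p))))
    if (all(apply(g, 2L, stats::var) > 0)) return(g)
  }
}

# simulated GBLUP data set: genetic values from a marker architecture with
# heritability h2 at the line level
sim_gblup_data <- function(n, p, h2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- random_dosages(n, p)
  eff <- stats::rnorm(p) / sqrt(p)
  tbv <- drop(g %*% eff)
  tbv <- (tbv - mean(tbv)) / stats::sd(tbv)
  y <- tbv + stats::rnorm(n, 0, sqrt((1 - h2) / h2))
  list(geno = g, tbv = tbv, y = stats::setNames(y, rownames(g)),
       var_g = 1, var_e = (1 - h2) / h2)
}
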