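test_that("model presets expand to their term lists and validate alignment", {
  g <- random_dosages(15, 40)
  K <- genomic_matrix(g)
  ds <- distance_summary(g)
  ks <- gaussian_kernels(ds)
  ped <- pedigree(rownames(g), rep(NA, 15), rep(NA, 15))
  A <- pedigree_matrix(ped)

  expect_named(model_spec("GBLUP", G = K)$terms, "K")
  expect_named(model_spec("P+GBLUP", G = K, A = A)$terms, c("A", "K"))
  expect_named(model_spec("RKHS-KA", kernels = ks)$terms, c("K1", "K2", "K3"))
  expect_named(model_spec("P+RKHS-KA", A = A, kernels = ks)$terms,
               c("A", "K1", "K2", "K3"))

  Abad <- A[15:1, 15:1]
  expect_error(model_spec("P+GBLUP", G = K, A = Abad), "ordering")
  expect_error(model_spec("GBLUP", G = K, niter = 100, burnin = 100),
               "burnin")
  expect_error(model_spec("GBLUP"), "needs")
})

test_that("fixed-variance Gibbs agrees with the closed-form BLUP solve", {
  set.seed(101)
  dat <- sim_gblup_data(80, 120, h2 = 0.5)
  K <- genomic_matrix(dat$geno)
  sp <- model_spec("GBLUP", G = K, niter = 8000, burnin = 1000, thin = 2,
                   seed = 7)
  fit <- fit_gs(dat$y, sp, fixed_var = c(K = 1, error = 1))
  or <- blup_oracle(dat$y, list(K), sigma2 = 1, sigma2_e = 1)
  expect_lt(sqrt(mean((fit$gebv - or$total)^2)), 0.02)
})

test_that("an identity covariance reduces to exchangeable shrinkage", {
  set.seed(102)
  n <- 40
  ids <- sprintf("I%02d", 1:n)
  I <- diag(n); dimnames(I) <- list(ids, ids)
  y <- stats::setNames(stats::rnorm(n, 10, 1), ids)
  sp <- model_spec(terms = list(K = I), niter = 4000, burnin = 500, thin = 2,
                   seed = 8)
  fit <- fit_gs(y, sp)
  expect_lt(abs(fit$mu - mean(y)), 3 * stats::sd(y) / sqrt(n))
  expect_true(all(fit$samples[, c("K", "error")] > 0))
})

test_that("an RKHS fit on a linear kernel reproduces GBLUP predictions", {
  set.seed(103)
  dat <- sim_gblup_data(70, 100, h2 = 0.5)
  K <- genomic_matrix(dat$geno)
  y <- dat$y
  fit_g <- fit_gs(y, model_spec("GBLUP", G = K, niter = 6000, burnin = 1000,
                                thin = 2, seed = 9))
  fit_r <- fit_gs(y, model_spec(terms = list(K1 = K), niter = 6000,
                                burnin = 1000, thin = 2, seed = 10))
  expect_gt(stats::cor(fit_g$gebv, fit_r$gebv), 0.99)
  expect_lt(sqrt(mean((fit_g$gebv - fit_r$gebv)^2)), 0.05)
})

test_that("missing phenotypes are predicted as the conditional mean extension", {
  set.seed(104)
  dat <- sim_gblup_data(60, 90, h2 = 0.6)
  K <- genomic_matrix(dat$geno)
  y <- dat$y
  miss <- 1:15
  y[miss] <- NA
  sp <- model_spec("GBLUP", G = K, niter = 8000, burnin = 1000, thin = 2,
                   seed = 11)
  fit <- fit_gs(y, sp, fixed_var = c(K = 1, error = 0.8))
  or <- blup_oracle(y, list(K), sigma2 = 1, sigma2_e = 0.8,
                    obs = setdiff(seq_along(y), miss))
  expect_lt(sqrt(mean((fit$gebv[miss] - or$total[miss])^2)), 0.03)
  expect_false(any(fit$phenotyped[miss]))
})

test_that("the sampler is deterministic given a seed and flags bad input", {
  set.seed(105)
  dat <- sim_gblup_data(30, 40, h2 = 0.5)
  K <- genomic_matrix(dat$geno)
  sp <- model_spec("GBLUP", G = K, niter = 600, burnin = 100, thin = 2,
                   seed = 12)
  f1 <- fit_gs(dat$y, sp)
  f2 <- fit_gs(dat$y, sp)
  expect_identical(f1$gebv, f2$gebv)
  expect_identical(f1$samples, f2$samples)

  yna <- dat$y; yna[1:25] <- NA
  expect_error(fit_gs(yna, sp), "at least 10")
  notpsd <- K; notpsd[1, 2] <- notpsd[2, 1] <- 25
  expect_error(fit_gs(dat$y, model_spec(terms = list(K = notpsd),
                                        niter = 600, burnin = 100)),
               "positive semi-definite")
})

test_that("GEBV extraction, ranking and selection follow the documented rules", {
  tab <- data.frame(id = c("e", "a", "c", "b", "d"),
                    gebv = c(3, 5, 4, 5, 1))
  expect_identical(rank_and_select(tab, 2), c("a", "b"))  # tie: id order
  expect_identical(rank_and_select(tab, 5), c("a", "b", "c", "e", "d"))
  expect_error(rank_and_select(tab, 6), "exceeds")
  # brute-force comparison on random tables
  set.seed(106)
  for (i in 1:10) {
    v <- stats::setNames(stats::rnorm(20), sample(sprintf("x%02d", 1:20)))
    got <- rank_and_select(v, 7)
    brute <- names(sort(v, decreasing = TRUE))[1:7]
    expect_setequal(got, brute)
  }
})

test_that("cycle GEBV summaries report means and the average increment", {
  expect_equal(gebv_cycle_summary(list(C0 = 6.71, C1 = 6.9, C2 = 7.1,
                                       C3 = 7.20))$increment,
               0.1633333, tolerance = 1e-6)
  s <- gebv_cycle_summary(list(C0 = c(6.5, 6.92), C1 = 7, C2 = 7, C3 = 7.2))
  expect_equal(unname(s$means[1]), 6.71)
  expect_equal(s$increment, (7.2 - 6.71) / 3)
  expect_equal(gebv_cycle_summary(list(a = 1, b = 2, c = 4))$increment, 1.5)
  expect_equal(gebv_cycle_summary(list(a = 5, b = 5, c = 5))$increment, 0)
})

test_that("doubling the chain barely perturbs the top of the GEBV ranking", {
  set.seed(107)
  dat <- sim_gblup_data(80, 120, h2 = 0.5)
  K <- genomic_matrix(dat$geno)
  top <- function(niter) {
    fit <- fit_gs(dat$y, model_spec("GBLUP", G = K, niter = niter,
                                    burnin = niter %/% 4, thin = 2,
                                    seed = 14))
    rank_and_select(predict(fit), 16)  # top 20%
  }
  t1 <- top(2000)
  t2 <- top(4000)
  expect_lte(length(setdiff(t1, t2)), 2)
})

test_that("adding an informative pedigree term does not hurt in-sample fit", {
  # data with strong family structure: the pedigree matrix carries real
  # signal, so P+GBLUP should track the phenotypes at least as closely at
  # the posterior mean as GBLUP alone
  set.seed(108)
  tp <- make_training_population(
    training_pop_config("desk", family_sizes = rep(15L, 4L),
                        family_h2 = rep(0.6, 4L), n_markers = 84L),
    seed = 109)
  flt <- filter_markers(tp$mm)
  blues <- tapply(tp$pheno$value, tp$pheno$line, mean)[rownames(flt$mm$geno)]
  y <- stats::setNames(as.numeric(blues), names(blues))
  G <- genomic_matrix(flt$mm)
  A <- pedigree_matrix(tp$pedigree)[names(y), names(y)]
  msr <- function(spec) {
    fit <- fit_gs(y, spec)
    mean((y - fit$gebv)^2)
  }
  m_g <- msr(model_spec("GBLUP", G = G, niter = 2000, burnin = 500,
                        thin = 2, seed = 15))
  m_pg <- msr(model_spec("P+GBLUP", G = G, A = A, niter = 2000, burnin = 500,
                         thin = 2, seed = 16))
  expect_lte(m_pg, m_g * 1.1)
})
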