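# brute-force verifier for crossing plans
check_plan <- function(plan, parents_by_family, n_within, n_pairs, n_per_pair,
                       min_uses) {
  expect_false(any(plan$parent1 == plan$parent2))
  w <- plan[plan$type == "within", ]
  b <- plan[plan$type == "between", ]
  expect_equal(nrow(w), n_within * length(parents_by_family))
  expect_equal(nrow(b), n_pairs * n_per_pair)
  expect_true(all(w$family1 == w$family2))
  expect_true(all(b$family1 != b$family2))
  # within pairs are distinct inside each family
  for (fm in names(parents_by_family)) {
    wf <- w[w$family1 == fm, ]
    key <- apply(cbind(pmin(wf$parent1, wf$parent2),
                       pmax(wf$parent1, wf$parent2)), 1, paste, collapse = "|")
    expect_equal(length(unique(key)), nrow(wf))
    expect_true(all(c(wf$parent1, wf$parent2) %in% parents_by_family[[fm]]))
  }
  # each family appears in >= min_uses chosen family pairs
  pair_key <- unique(paste(pmin(b$family1, b$family2),
                           pmax(b$family1, b$family2)))
  uses <- table(unlist(strsplit(pair_key, " ")))
  expect_true(all(uses[names(parents_by_family)] >= min_uses))
}

test_that("the C1 crossing plan reproduces the 36 + 110 cross structure", {
  pf <- split(sprintf("L%03d", 1:60), rep(paste0("F", 1:6), each = 10))
  plan <- make_cross_plan(pf, n_within_per_family = 6, n_between_pairs = 11,
                          n_between_per_pair = 10, min_family_intercross = 3,
                          seed = 31)
  expect_equal(nrow(plan), 146L)
  check_plan(plan, pf, 6, 11, 10, 3)
  # deterministic under a fixed seed
  plan2 <- make_cross_plan(pf, 6, 11, 10, 3, seed = 31)
  expect_identical(as.data.frame(plan), as.data.frame(plan2))
  # scores steer the chosen family pairs
  sc <- stats::setNames(c(5, 4, 3, 2, 1, 0), names(pf))
  plan3 <- make_cross_plan(pf, 2, 11, 4, 3, between_scores = sc, seed = 32)
  check_plan(plan3, pf, 2, 11, 4, 3)
})

test_that("infeasible crossing requests raise explicit errors", {
  one <- list(F1 = c("a", "b", "c"))
  expect_error(make_cross_plan(one, 2, 1, 5), ">= 2 families")
  few <- list(F1 = c("a"), F2 = c("x", "y"))
  expect_error(make_cross_plan(few, 1, 1, 2), "within-crosses infeasible")
  two <- list(F1 = c("a", "b"), F2 = c("x", "y"))
  expect_error(make_cross_plan(two, 2, 1, 2), "distinct pairs")
  expect_error(make_cross_plan(two, 1, 5, 2), "family pairs exist")
  # coverage quota larger than the pair budget allows
  six <- split(letters[1:12], rep(paste0("F", 1:6), each = 2))
  expect_error(make_cross_plan(six, 1, 4, 2, min_family_intercross = 3),
               "intercross uses")
})

test_that("rank-sum family selection matches brute-force enumeration", {
  summ <- data.frame(family = c("F1", "F2", "F3", "F4"),
                     mean_gy = c(7, 6, 5, 4), h2 = c(0.7, 0.5, 0.3, 0.1),
                     within = c(0.5, 0.4, 0.3, 0.2),
                     between = c(0.3, 0.2, 0.1, 0.0))
  expect_identical(select_families(summ, 2), c("F1", "F2"))
  # equal criteria everywhere: ties broken by family id
  tied <- data.frame(family = c("Fb", "Fa", "Fc"), x = 1, y = 1)
  expect_identical(select_families(tied, 2), c("Fa", "Fb"))
  # random tables against an explicit rank-sum enumeration
  set.seed(33)
  for (i in 1:10) {
    tab <- data.frame(family = sprintf("F%02d", 1:8),
                      a = stats::rnorm(8), b = stats::rnorm(8),
                      c = stats::rnorm(8))
    rs <- rank(-tab$a) + rank(-tab$b) + rank(-tab$c)
    brute <- tab$family[order(rs, tab$family)][1:3]
    expect_identical(select_families(tab, 3), brute)
  }
})

test_that("C0 parents are the highest-value lines of each chosen family", {
  blues <- stats::setNames(c(5, 9, 7, 3, 8, 6, 2, 4),
                           sprintf("L%d", 1:8))
  fam <- stats::setNames(rep(c("A", "B"), each = 4), names(blues))
  got <- select_c0_parents(blues, fam, c("A", "B"), 2)
  expect_identical(got, c("L2", "L3", "L5", "L6"))
  expect_error(select_c0_parents(blues, fam, "A", 5), "fewer than")
})

test_that("bulked F1 genotypes average sibling dosages", {
  f <- make_founders(2, 40, 2, seed = 34)
  # inbred x inbred: every F1 identical, bulk is the deterministic dosage
  off <- cross(f[1], f[2], 6, seed = 35)
  bulk <- bulk_f1_genotype(off)
  expect_equal(bulk, (dosage(f)[1, ] + dosage(f)[2, ]) / 2)
  expect_true(all(bulk %in% c(0, 1, 2)))
  # n_plants = 1 is an ordinary individual genotype
  b1 <- bulk_f1_genotype(off, n_plants = 1, seed = 36)
  expect_true(all(b1 %in% 0:2))
  # heterozygous parent: large bulks approach the expected dosage
  het <- cross(f[1], f[2], 1, seed = 37)
  off2 <- cross(het, f[2], 500, seed = 38)
  exp_dos <- (dosage(het)[1, ] + dosage(f)[2, ]) / 2
  dev <- bulk_f1_genotype(off2) - exp_dos
  expect_lt(max(abs(dev)), 4 * sqrt(0.5 / 500) + 1e-12)
})

test_that("cycle intermating plans respect origin families and rebalance", {
  entries <- data.frame(id = sprintf("E%02d", 1:10),
                        family = rep(c("X1", "X2", "X3", "X4", "X5"), 2))
  plan <- rcgs:::make_cycle_plan(entries, n_within = 3, n_between = 5,
                                 seed = 39)
  expect_equal(nrow(plan), 8L)
  w <- plan[plan$type == "within", ]
  expect_true(all(w$family1 == w$family2))
  b <- plan[plan$type == "between", ]
  expect_true(all(b$family1 != b$family2))
  # all entries singletons: every within cross is rebalanced to between
  solo <- data.frame(id = sprintf("S%02d", 1:6), family = sprintf("C%d", 1:6))
  plan2 <- rcgs:::make_cycle_plan(solo, n_within = 4, n_between = 2, seed = 40)
  expect_equal(attr(plan2, "n_within_realized"), 0L)
  expect_equal(nrow(plan2), 6L)
  expect_true(all(plan2$type == "between"))
})

test_that("a desk-scale scheme run is deterministic and selection-consistent", {
  cfg <- scheme_config("desk",
                       training = training_pop_config(
                         "desk", family_sizes = rep(16L, 8L),
                         family_h2 = rep(c(0.4, 0.6), 4L), n_markers = 105L),
                       n_families_select = 4L,
                       c1_between_pairs = 6L,
                       c1_between_per_pair = 3L,
                       n_f1_planted = c(40L, 40L),
                       n_select = c(10L, 10L),
                       cycle_within = 4L,
                       cycle_between = 16L,
                       n_advance = c(6L, 6L),
                       advance_rank_band = 15L,
                       n_c0_eval = 5L,
                       chain = list(niter = 600L, burnin = 150L, thin = 3L),
                       cv = list(k = 3L, repeats = 1L, niter = 400L,
                                 burnin = 100L, thin = 2L),
                       compute_diversity = FALSE)
  sc <- run_scheme(cfg, seed = 41)
  # structural invariants
  expect_equal(length(sc$selected_families), 4L)
  for (lab in names(sc$cycles)) {
    cy <- sc$cycles[[lab]]
    expect_true(all(cy$selected %in% cy$entries$id))
    expect_true(all(cy$advance %in% cy$entries$id))
    # selection differential: selected mean GEBV above candidate mean
    expect_gt(mean(cy$gebv$gebv[cy$gebv$id %in% cy$selected]),
              mean(cy$gebv$gebv))
  }
  expect_equal(nrow(sc$cycles$C1$entries), 40L)
  expect_s3_class(sc$cycle_means, "data.frame")
  # determinism: identical config and seed give identical reports
  sc2 <- run_scheme(cfg, seed = 41)
  expect_identical(sc$gain, sc2$gain)
  expect_identical(sc$tbv_cycle_means, sc2$tbv_cycle_means)
  expect_identical(sc$cycles$C2$selected, sc2$cycles$C2$selected)
})
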