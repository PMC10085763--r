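#' Recurrent-selection scheme configuration
#'
#' Defaults reproduce the study structure: a 1,609-line training population
#' (cycle C0), 6 of 14 families selected, 10 top lines per family (60 C0
#' parents), a C1 crossing plan of 6 within-family crosses per family (36)
#' plus 10 crosses in each of 11 family pairs (110) with every family in at
#' least 3 intercross pairs, 136 C1 F1 entries planted, truncation selection
#' of the top 26 (C1) and 29 (C2) entries, within/between intermating plans
#' of 19 + 69 crosses for the later cycles, advancement of 32-35 entries per
#' cycle (sampled from GEBV ranks 1-58) to F6 lines by selfing, and a final
#' 2-year x 2-replicate evaluation. `scale = "desk"` keeps the same
#' structure at example/test size.
#'
#' @param scale `"study"` or `"desk"`.
#' @param ... named overrides of any configuration element.
#' @return A list of class `scheme_config`.
#' @export
scheme_config <- function(scale = c("study", "desk"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    training = training_pop_config("study"),
    n_families_select = 6L,
    n_top_per_family = 10L,
    c1_within_per_family = 6L,
    c1_between_pairs = 11L,
    c1_between_per_pair = 10L,
    min_family_intercross = 3L,
    n_f1_planted = c(136L, 88L, 88L),
    n_select = c(26L, 29L),
    cycle_within = c(19L, 19L),
    cycle_between = c(69L, 69L),
    n_advance = c(32L, 34L, 35L),
    advance_rank_band = 58L,
    n_c0_eval = 17L,
    n_bulk_plants = 4L,
    selfing_to_line = 5L,  # F1 -> F6
    preset = "P+RKHS-KA",
    chain = list(niter = 12000L, burnin = 2000L, thin = 5L),
    cv = list(k = 5L, repeats = 10L, niter = 3000L, burnin = 500L, thin = 5L),
    eval_years = 2L,
    eval_reps = 2L,
    eval_env_var = 0.35,
    year_sd = 0.2,
    compute_diversity = TRUE)
  if (scale == "desk") {
    cfg$training <- training_pop_config("desk")
    cfg$n_top_per_family <- 5L
    cfg$c1_within_per_family <- 3L
    cfg$c1_between_pairs <- 9L
    cfg$c1_between_per_pair <- 4L
    cfg$n_f1_planted <- c(120L, 120L, 120L)
    cfg$n_select <- c(24L, 24L)
    cfg$cycle_within <- c(12L, 12L)
    cfg$cycle_between <- c(48L, 48L)
    cfg$n_advance <- c(10L, 10L, 10L)
    cfg$advance_rank_band <- 36L
    cfg$n_c0_eval <- 8L
    cfg$chain <- list(niter = 1200L, burnin = 300L, thin = 3L)
    cfg$cv <- list(k = 3L, repeats = 1L, niter = 500L, burnin = 125L, thin = 3L)
  }
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop_arg("unknown config fields: ",
                                  paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = c("scheme_config", "list"))
}

#' Composite family selection by rank sum
#'
#' Families are ranked on each criterion (larger better) and the
#' `n_select` smallest rank sums are chosen; ties are broken by family id.
#' This realizes "rank in yield, heritability and prediction ability within
#' and between families" as an unweighted composite, the rule being
#' pluggable via the columns supplied.
#'
#' @param summary `data.frame` with a `family` column and one numeric
#'   column per criterion (e.g. `mean_gy`, `h2`, `within`, `between`).
#' @param n_select number of families to choose.
#' @return Character vector of selected family ids.
#' @export
select_families <- function(summary, n_select) {
  n_select <- check_count(n_select, "n_select")
  crit <- setdiff(names(summary), "family")
  if (!length(crit)) stop_arg("no criterion columns")
  if (n_select > nrow(summary)) stop_arg("n_select exceeds the number of families")
  ranks <- vapply(crit, function(cl) rank(-summary[[cl]], ties.method = "average"),
                  numeric(nrow(summary)))
  rs <- rowSums(ranks)
  ord <- order(rs, as.character(summary$family))
  as.character(summary$family)[ord][seq_len(n_select)]
}

#' Select the top-yielding lines within chosen families
#'
#' @param blues named numeric vector of line values (BLUEs).
#' @param family named character vector, line -> family.
#' @param families families to draw from.
#' @param n_per_family lines per family.
#' @return Character vector of parent ids.
#' @export
select_c0_parents <- function(blues, family, families, n_per_family) {
  n_per_family <- check_count(n_per_family, "n_per_family")
  unlist(lapply(families, function(fm) {
    ids <- names(blues)[family[names(blues)] == fm]
    if (length(ids) < n_per_family)
      stop_arg(sprintf("family %s has fewer than %d lines", fm, n_per_family))
    ids[order(-blues[ids], ids)][seq_len(n_per_family)]
  }), use.names = FALSE)
}

#' Crossing plan within and between families
#'
#' Produces `n_within_per_family` distinct random non-self pairs inside each
#' family and `n_between_per_pair` crosses in each of `n_between_pairs`
#' family pairs. Family pairs are chosen by decreasing `between_scores`
#' (mean of the two families' scores; random when no scores are given),
#' then greedily repaired so that every family appears in at least
#' `min_family_intercross` of the chosen pairs. Infeasible requests (too
#' few parents, too few realizable pairs) raise an error naming the
#' constraint.
#'
#' @param parents_by_family named list, family -> character vector of
#'   parent ids.
#' @param n_within_per_family within-family crosses per family.
#' @param n_between_pairs number of family pairs intercrossed.
#' @param n_between_per_pair crosses per chosen family pair.
#' @param min_family_intercross minimum pair memberships per family.
#' @param between_scores optional named numeric vector, family -> score.
#' @param seed optional integer seed.
#' @return `data.frame` of class `cross_plan`: `cross_id`, `type`
#'   (`within`/`between`), `family1`, `family2`, `parent1`, `parent2`.
#' @export
make_cross_plan <- function(parents_by_family, n_within_per_family,
                            n_between_pairs, n_between_per_pair,
                            min_family_intercross = 3L,
                            between_scores = NULL, seed = NULL) {
  set_seed_if(seed)
  fams <- names(parents_by_family)
  nf <- length(fams)
  rows <- list()
  # within-family crosses
  for (fm in fams) {
    par <- parents_by_family[[fm]]
    if (length(par) < 2L)
      stop_arg(sprintf("family %s has < 2 parents; within-crosses infeasible", fm))
    allp <- utils::combn(par, 2L)
    if (ncol(allp) < n_within_per_family)
      stop_arg(sprintf("family %s: only %d distinct pairs for %d within-crosses",
                       fm, ncol(allp), n_within_per_family))
    take <- allp[, sample.int(ncol(allp), n_within_per_family), drop = FALSE]
    for (cc in seq_len(ncol(take)))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "within", family1 = fm, family2 = fm,
        parent1 = take[1L, cc], parent2 = take[2L, cc])
  }
  # between-family pairs
  if (n_between_pairs > 0L) {
    if (nf < 2L) stop_arg("between-family crosses need >= 2 families")
    pairs <- utils::combn(fams, 2L)
    if (ncol(pairs) < n_between_pairs)
      stop_arg(sprintf("only %d family pairs exist, %d requested",
                       ncol(pairs), n_between_pairs))
    if (n_between_pairs * 2L < nf * min_family_intercross)
      stop_arg(sprintf(
        "%d pairs cannot give every one of %d families %d intercross uses",
        n_between_pairs, nf, min_family_intercross))
    score <- if (is.null(between_scores)) stats::runif(ncol(pairs)) else
      (between_scores[pairs[1L, ]] + between_scores[pairs[2L, ]]) / 2
    # coverage-first greedy: while some family is below its quota, add the
    # unchosen pair that reduces the largest shortfall (preferring pairs
    # joining two deficient families, then higher score); then fill the
    # remaining slots purely by score
    chosen <- integer(0)
    uses <- stats::setNames(rep(0L, nf), fams)
    repeat {
      shortfall <- pmax(min_family_intercross - uses, 0L)
      if (!any(shortfall > 0L)) break
      if (length(chosen) >= n_between_pairs)
        stop_arg("intercross coverage constraint could not be satisfied")
      open <- setdiff(seq_len(ncol(pairs)), chosen)
      gain <- shortfall[pairs[1L, open]] + shortfall[pairs[2L, open]]
      covers_worst <- (pairs[1L, open] %in% fams[shortfall == max(shortfall)]) |
        (pairs[2L, open] %in% fams[shortfall == max(shortfall)])
      if (!any(gain > 0L & covers_worst))
        stop_arg("intercross coverage constraint could not be satisfied")
      pick <- open[order(-(gain > 0L & covers_worst), -gain, -score[open])][1L]
      chosen <- c(chosen, pick)
      uses[pairs[1L, pick]] <- uses[pairs[1L, pick]] + 1L
      uses[pairs[2L, pick]] <- uses[pairs[2L, pick]] + 1L
    }
    open <- setdiff(seq_len(ncol(pairs)), chosen)
    n_fill <- n_between_pairs - length(chosen)
    if (n_fill > 0L)
      chosen <- c(chosen, open[order(-score[open])][seq_len(n_fill)])
    for (j in chosen) {
      f1 <- pairs[1L, j]; f2 <- pairs[2L, j]
      p1 <- sample(rep_len(sample(parents_by_family[[f1]]), n_between_per_pair))
      p2 <- sample(rep_len(sample(parents_by_family[[f2]]), n_between_per_pair))
      for (cc in seq_len(n_between_per_pair))
        rows[[length(rows) + 1L]] <- data.frame(
          type = "between", family1 = f1, family2 = f2,
          parent1 = p1[cc], parent2 = p2[cc])
    }
  }
  plan <- do.call(rbind, rows)
  plan <- cbind(cross_id = sprintf("X%03d", seq_len(nrow(plan))), plan)
  if (any(plan$parent1 == plan$parent2)) stop_arg("self cross in plan")
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

# intermating plan for cycle candidates: "family" of a candidate is its
# cross of origin; a within cross pairs two sibling entries of one cross.
# If the requested within count is not realizable among the selected
# entries, the shortfall moves to between-crosses (recorded in attributes).
make_cycle_plan <- function(entries, n_within, n_between, seed = NULL) {
  set_seed_if(seed)
  if (nrow(entries) < 2L) stop_arg("need >= 2 selected entries to intermate")
  fam <- split(entries$id, entries$family)
  within_pairs <- do.call(cbind, c(list(matrix(character(0), 2L)),
                                   lapply(fam[lengths(fam) >= 2L],
                                          function(v) utils::combn(v, 2L))))
  nw <- min(n_within, ncol(within_pairs))
  rows <- list()
  if (nw > 0L) {
    take <- within_pairs[, sample.int(ncol(within_pairs), nw), drop = FALSE]
    for (cc in seq_len(nw))
      rows[[length(rows) + 1L]] <- data.frame(type = "within",
                                              parent1 = take[1L, cc],
                                              parent2 = take[2L, cc])
  }
  nb <- n_between + (n_within - nw)
  famof <- stats::setNames(entries$family, entries$id)
  for (cc in seq_len(nb)) {
    for (try in 1:100) {
      pr <- sample(entries$id, 2L)
      if (famof[pr[1L]] != famof[pr[2L]]) break
    }
    rows[[length(rows) + 1L]] <- data.frame(type = "between",
                                            parent1 = pr[1L], parent2 = pr[2L])
  }
  plan <- do.call(rbind, rows)
  plan$family1 <- famof[plan$parent1]
  plan$family2 <- famof[plan$parent2]
  plan <- cbind(cross_id = sprintf("X%03d", seq_len(nrow(plan))), plan)
  attr(plan, "n_within_realized") <- nw
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

#' Bulk F1 genotype of one cross
#'
#' Mean allele dosage over `n_plants` sampled sibling F1 individuals,
#' emulating genotyping of pooled (bulked) seedling DNA. For a cross of two
#' fully inbred parents every F1 is identical and the bulk equals the
#' deterministic F1 dosage.
#'
#' @param offspring a [sim_pop()] of sibling F1 individuals of one cross.
#' @param n_plants number of plants contributing to the bulk (default all).
#' @param seed optional integer seed.
#' @return Numeric dosage vector in \[0, 2\], one entry per marker.
#' @export
bulk_f1_genotype <- function(offspring, n_plants = length(offspring),
                             seed = NULL) {
  n_plants <- check_count(n_plants, "n_plants")
  set_seed_if(seed)
  n <- length(offspring)
  take <- if (n_plants >= n) seq_len(n) else sample.int(n, n_plants)
  colMeans(dosage(offspring)[take, , drop = FALSE])
}

# realize the F1 entries of a plan: distribute `n_planted` entries over the
# crosses, grow `n_plants` sibling plants per entry, record bulk genotypes,
# true values and pedigree rows
execute_plan <- function(plan, get_parent, n_planted, n_plants, arch,
                         cycle_label, map) {
  ncross <- nrow(plan)
  per <- rep(n_planted %/% ncross, ncross)
  extra <- n_planted - sum(per)
  if (extra > 0L) {
    idx <- sample.int(ncross, extra)
    per[idx] <- per[idx] + 1L
  }
  entries <- list(); plants <- list()
  eid <- 0L
  for (cc in seq_len(ncross)) {
    if (per[cc] == 0L) next
    p1 <- get_parent(plan$parent1[cc])
    p2 <- get_parent(plan$parent2[cc])
    for (k in seq_len(per[cc])) {
      eid <- eid + 1L
      id <- sprintf("%s_%03d", cycle_label, eid)
      off <- cross(p1, p2, n_offspring = n_plants, ids =
                     sprintf("%s.p%d", id, seq_len(n_plants)),
                   generation = cycle_label)
      plants[[id]] <- off
      entries[[length(entries) + 1L]] <- data.frame(
        id = id, cross_id = plan$cross_id[cc], family = plan$cross_id[cc],
        parent1 = plan$parent1[cc], parent2 = plan$parent2[cc],
        tbv = mean(true_values(off, arch)) )
    }
  }
  entries <- do.call(rbind, entries)
  bulk <- t(vapply(entries$id, function(id) bulk_f1_genotype(plants[[id]]),
                   numeric(length(map_markers(map)))))
  colnames(bulk) <- map_markers(map)
  list(entries = entries, plants = plants, bulk = bulk)
}

map_markers <- function(map) as.character(map$marker)

# relationship structures for a preset over a joint genotype matrix; marker
# standardization and kernel bandwidth come from the training block
build_structures <- function(preset, geno, train_rows, A = NULL) {
  ctr <- colMeans(geno[train_rows, , drop = FALSE])
  scl <- apply(geno[train_rows, , drop = FALSE], 2L, stats::sd)
  out <- list()
  if (preset %in% c("P+GBLUP", "P+RKHS-KA")) {
    if (is.null(A)) stop_arg("preset needs a pedigree matrix")
    out$A <- A
  }
  if (preset %in% c("GBLUP", "P+GBLUP")) {
    out$K <- genomic_matrix(geno, center = ctr, scale = scl)
  } else {
    ds_train <- distance_summary(geno[train_rows, , drop = FALSE],
                                 center = ctr, scale = scl)
    ds_joint <- distance_summary(geno, center = ctr, scale = scl)
    ds_joint$m <- ds_train$m
    out <- c(out, gaussian_kernels(ds_joint))
  }
  out
}

#' Predict, select and intermate one recurrent-selection cycle
#'
#' Extends the relationship structures of the configured model preset to the
#' cycle's F1 candidates (genomic/kernel structures from bulk dosages
#' standardized with training-set moments; pedigree block from the growing
#' pedigree), fits the model with all candidate phenotypes missing (the
#' training set is never updated across cycles), truncation-selects the top
#' `n_select` candidates and returns their intermating plan.
#'
#' @param candidates list from `execute_plan` (entries/plants/bulk).
#' @param training list with elements `geno` (QC'd training dosages),
#'   `blues` (named vector), `ped` (full [pedigree()]).
#' @param cfg a [scheme_config()].
#' @param n_select number of entries selected as parents.
#' @param n_within,n_between intermating plan sizes for the next cycle
#'   (`NULL` for the final cycle: prediction and selection only).
#' @param n_advance entries sampled (from the GEBV rank band) for line
#'   advancement.
#' @return List: `gebv` (candidate GEBV table), `selected`, `advance`,
#'   `plan` (or `NULL`), `var_components`.
#' @export
run_cycle <- function(candidates, training, cfg, n_select, n_within = NULL,
                      n_between = NULL, n_advance = 0L) {
  geno_joint <- rbind(training$geno,
                      candidates$bulk[, colnames(training$geno), drop = FALSE])
  train_rows <- seq_len(nrow(training$geno))
  Afull <- NULL
  if (cfg$preset %in% c("P+GBLUP", "P+RKHS-KA")) {
    Aped <- pedigree_matrix(training$ped)
    Afull <- Aped[rownames(geno_joint), rownames(geno_joint)]
  }
  structures <- build_structures(cfg$preset, geno_joint, train_rows, Afull)
  y <- stats::setNames(c(training$blues[rownames(training$geno)],
                         rep(NA_real_, nrow(candidates$entries))),
                       rownames(geno_joint))
  sp <- model_spec(terms = structures, niter = cfg$chain$niter,
                   burnin = cfg$chain$burnin, thin = cfg$chain$thin)
  fit <- fit_gs(y, sp)
  gebv <- predict(fit, candidates$entries$id)
  selected <- rank_and_select(gebv, n_select)
  advance <- character(0)
  if (n_advance > 0L) {
    band <- rank_and_select(gebv, min(cfg$advance_rank_band, nrow(gebv)))
    advance <- sample(band, min(n_advance, length(band)))
  }
  plan <- NULL
  if (!is.null(n_within)) {
    sel_entries <- candidates$entries[candidates$entries$id %in% selected, ]
    plan <- make_cycle_plan(sel_entries, n_within, n_between)
  }
  list(gebv = gebv, selected = selected, advance = advance, plan = plan,
       var_components = fit$var_components)
}

#' Run the full rapid-cycle recurrent genomic selection scheme in silico
#'
#' End-to-end forward simulation of the breeding scheme: training-population
#' simulation and QC, per-family summary (yield, heritability, within- and
#' between-family cross-validated prediction ability), composite family and
#' parent selection, the C1 crossing plan, three recurrent cycles of
#' bulk-genotyping, joint prediction, truncation selection and intermating,
#' advancement of sampled entries to inbred lines by selfing, a simulated
#' multi-year replicated yield trial of the advanced lines, and gain and
#' diversity summaries on both phenotypic and true genetic values.
#'
#' @param cfg a [scheme_config()].
#' @param seed integer seed governing the whole run.
#' @return A list of class `rcgs_scheme`; see the elements returned.
#' @export
run_scheme <- function(cfg = scheme_config("desk"), seed = NULL) {
  set_seed_if(seed)
  tp <- make_training_population(cfg$training)
  flt <- filter_markers(tp$mm, cfg$training$maf_threshold)
  geno <- flt$mm$geno
  blues <- tapply(tp$pheno$value, tp$pheno$line, mean)[rownames(geno)]
  fams <- sort(unique(unname(tp$family)))

  # per-family summary: mean yield, heritability from the replicated trial,
  # and cross-validated prediction abilities
  r <- cfg$training$r_reps
  fam_h2 <- vapply(fams, function(fm) {
    sub <- tp$pheno[tp$pheno$family == fm, ]
    ms <- stats::anova(stats::aov(value ~ line, sub))
    sg <- max((ms$`Mean Sq`[1L] - ms$`Mean Sq`[2L]) / r, 0)
    heritability(sg, ms$`Mean Sq`[2L], r = r, e = 1)
  }, numeric(1L))
  fam_gy <- vapply(fams, function(fm)
    mean(blues[names(tp$family)[tp$family == fm]]), numeric(1L))

  Aped <- pedigree_matrix(tp$pedigree)
  structures <- build_structures(cfg$preset, geno, seq_len(nrow(geno)),
                                 Aped[rownames(geno), rownames(geno)])
  cv <- cross_validate(blues, tp$family, structures,
                       mode = c("within", "between"),
                       k = cfg$cv$k, repeats = cfg$cv$repeats,
                       niter = cfg$cv$niter, burnin = cfg$cv$burnin,
                       thin = cfg$cv$thin)
  cvs <- attr(cv, "summary")
  getab <- function(md) stats::setNames(
    cvs$ability[cvs$mode == md][match(fams, cvs$family[cvs$mode == md])], fams)
  fam_summary <- data.frame(family = fams, mean_gy = fam_gy, h2 = fam_h2,
                            within = getab("within"), between = getab("between"))
  fam_summary[is.na(fam_summary)] <- 0

  sel_fams <- select_families(fam_summary, cfg$n_families_select)
  parents <- select_c0_parents(blues, tp$family, sel_fams, cfg$n_top_per_family)

  # C0 GEBVs of the selected parents from a training-only fit
  sp0 <- model_spec(terms = structures, niter = cfg$chain$niter,
                    burnin = cfg$chain$burnin, thin = cfg$chain$thin)
  fit0 <- fit_gs(stats::setNames(blues[rownames(geno)], rownames(geno)), sp0)
  gebv_c0 <- predict(fit0, parents)

  plan1 <- make_cross_plan(
    split(parents, tp$family[parents]),
    n_within_per_family = cfg$c1_within_per_family,
    n_between_pairs = cfg$c1_between_pairs,
    n_between_per_pair = cfg$c1_between_per_pair,
    min_family_intercross = cfg$min_family_intercross,
    between_scores = stats::setNames(fam_summary$between, fams)[sel_fams])

  ped_all <- tp$pedigree
  training <- list(geno = geno, blues = blues, ped = ped_all)
  get_parent_c1 <- function(id) tp$pop[id]

  cycles <- list()
  plants_all <- list()
  plan <- plan1
  get_parent <- get_parent_c1
  n_cycles <- length(cfg$n_f1_planted)
  for (ci in seq_len(n_cycles)) {
    lab <- paste0("C", ci)
    cand <- execute_plan(plan, get_parent, cfg$n_f1_planted[ci],
                         cfg$n_bulk_plants, tp$arch, lab, tp$pop$map)
    ped_all <- pedigree(id = c(ped_all$id, cand$entries$id),
                        parent1 = c(ped_all$parent1, cand$entries$parent1),
                        parent2 = c(ped_all$parent2, cand$entries$parent2),
                        selfing = c(ped_all$selfing,
                                    rep(0L, nrow(cand$entries))))
    training$ped <- ped_all
    last <- ci == n_cycles
    nsel <- if (last) cfg$n_select[length(cfg$n_select)] else cfg$n_select[ci]
    res <- run_cycle(cand, training, cfg, n_select = nsel,
                     n_within = if (last) NULL else cfg$cycle_within[ci],
                     n_between = if (last) NULL else cfg$cycle_between[ci],
                     n_advance = cfg$n_advance[ci])
    cycles[[lab]] <- list(entries = cand$entries, gebv = res$gebv,
                          selected = res$selected, advance = res$advance,
                          plan = res$plan, var_components = res$var_components)
    plants_all <- c(plants_all, cand$plants)
    if (!last) {
      plan <- res$plan
      get_parent <- function(id) {
        off <- plants_all[[id]]
        off[sample.int(length(off), 1L)]
      }
    }
  }

  # advance sampled entries to F6 lines and run the simulated yield trial
  eval_pops <- list(C0 = tp$pop[sample(parents, min(cfg$n_c0_eval,
                                                    length(parents)))])
  for (lab in names(cycles)) {
    adv <- cycles[[lab]]$advance
    lines <- lapply(adv, function(id) {
      pl <- plants_all[[id]]
      self_advance(pl[sample.int(length(pl), 1L)], cfg$selfing_to_line,
                   bulk_k = cfg$training$bulk_k, id = paste0(id, "_F6"),
                   generation = "F6")
    })
    eval_pops[[lab]] <- do.call(rbind_pops, lines)
  }

  trial <- list()
  for (yr in seq_len(cfg$eval_years)) {
    yeff <- stats::rnorm(1L, 0, cfg$year_sd)
    for (lab in names(eval_pops)) {
      g <- true_values(eval_pops[[lab]], tp$arch)
      n <- length(g)
      for (rp in seq_len(cfg$eval_reps))
        trial[[length(trial) + 1L]] <- data.frame(
          cycle = lab, line = names(g), year = yr, rep = rp,
          value = g + yeff + stats::rnorm(n, 0, sqrt(cfg$eval_env_var)))
    }
  }
  trial <- do.call(rbind, trial)
  cm <- cycle_means(trial)
  gain_pheno <- realized_gain(cm$combined[cm$cycle == "C0"],
                              cm$combined[cm$cycle == paste0("C", n_cycles)],
                              n_cycles)
  # true-value trajectory: C0 is the full training cohort, later points the
  # F1 candidate populations of each recurrent cycle
  tbv_means <- c(C0 = mean(tp$true_values),
                 vapply(names(cycles), function(lab)
                   mean(cycles[[lab]]$entries$tbv), numeric(1L)))
  gain_true <- realized_gain(tbv_means[[1L]], tbv_means[[length(tbv_means)]],
                             n_cycles)
  gebv_summary <- gebv_cycle_summary(c(list(C0 = gebv_c0),
                                       lapply(cycles, `[[`, "gebv")))

  diversity <- NULL
  if (isTRUE(cfg$compute_diversity))
    diversity <- diversity_summary(lapply(eval_pops, dosage))

  structure(list(
    config = cfg, seed = seed,
    qc_report = flt$report,
    family_summary = fam_summary,
    selected_families = sel_fams,
    c0_parents = parents,
    plan_c1 = plan1,
    cycles = cycles,
    trial = trial,
    cycle_means = cm,
    gain = gain_pheno,
    tbv_cycle_means = tbv_means,
    gain_true = gain_true,
    gebv_summary = gebv_summary,
    diversity = diversity),
    class = "rcgs_scheme")
}

#' @export
print.rcgs_scheme <- function(x, ...) {
  cat("rapid-cycle recurrent genomic selection run\n")
  cat(sprintf("  selected families: %s\n",
              paste(x$selected_families, collapse = ", ")))
  cat(sprintf("  mean GEBV per cycle: %s (increment %.3f)\n",
              paste(sprintf("%.2f", x$gebv_summary$means), collapse = " -> "),
              x$gebv_summary$increment))
  cat(sprintf("  trial means (combined): %s\n",
              paste(sprintf("%s=%.2f", x$cycle_means$cycle,
                            x$cycle_means$combined), collapse = ", ")))
  cat(sprintf("  realized gain: %.3f per cycle (%.1f%%)\n",
              x$gain$per_cycle, x$gain$percent))
  invisible(x)
}

#' Serialize the intermediates of a scheme run
#'
#' Writes the training/QC genotype matrix is not retained in the result;
#' this helper writes the per-cycle GEBV tables, crossing plans, cycle
#' means, gain report and diversity summary of a [run_scheme()] result as
#' CSV/JSON files.
#'
#' @param scheme a [run_scheme()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scheme_outputs <- function(scheme, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(scheme$cycles)) {
    cy <- scheme$cycles[[lab]]
    utils::write.csv(cy$gebv, file.path(dir, paste0("gebv_", lab, ".csv")),
                     row.names = FALSE)
    if (!is.null(cy$plan))
      utils::write.csv(as.data.frame(cy$plan),
                       file.path(dir, paste0("plan_", lab, ".csv")),
                       row.names = FALSE)
  }
  utils::write.csv(scheme$cycle_means, file.path(dir, "cycle_means.csv"),
                   row.names = FALSE)
  report <- list(gain = scheme$gain, gain_true = scheme$gain_true,
                 tbv_cycle_means = as.list(scheme$tbv_cycle_means),
                 gebv_means = as.list(scheme$gebv_summary$means),
                 gebv_increment = scheme$gebv_summary$increment)
  jsonlite::write_json(report, file.path(dir, "gain_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
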