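#' Simulated founder set
#'
#' Draws phased founder haplotypes for a wheat-like genome. Marker allele
#' frequencies are drawn per marker from Uniform(`freq_range`) so that a
#' downstream minor-allele-frequency filter has non-trivial action; founder
#' haplotype alleles are independent Bernoulli draws at those frequencies.
#' With `inbred = TRUE` (default, mirroring elite inbred parents) the two
#' haplotypes of a founder are identical, so founder dosages are 0 or 2.
#'
#' @param n_founders,n_markers,n_chromosomes positive counts.
#' @param seed optional integer seed.
#' @param chrom_length_morgan genetic length of each chromosome (Morgans).
#' @param freq_range range of per-marker allele frequencies.
#' @param inbred logical; fully homozygous founders.
#' @return A `sim_pop` object (see [sim_pop()]) of founders, with the marker
#'   map attached.
#' @export
make_founders <- function(n_founders, n_markers, n_chromosomes, seed = NULL,
                          chrom_length_morgan = 1, freq_range = c(0.1, 0.9),
                          inbred = TRUE) {
  n_founders <- check_count(n_founders, "n_founders")
  n_markers <- check_count(n_markers, "n_markers")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  set_seed_if(seed)
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_markers))
  pos <- stats::ave(rep(0, n_markers), chrom, FUN = function(z)
    sort(stats::runif(length(z), 0, chrom_length_morgan)))
  map <- data.frame(marker = sprintf("M%05d", seq_len(n_markers)),
                    chrom = chrom, pos = pos)
  f <- stats::runif(n_markers, freq_range[1L], freq_range[2L])
  draw <- function() matrix(stats::rbinom(n_founders * n_markers, 1L,
                                          rep(f, each = n_founders)),
                            nrow = n_founders)
  H1 <- draw()
  H2 <- if (inbred) H1 else draw()
  ids <- sprintf("P%02d", seq_len(n_founders))
  dimnames(H1) <- dimnames(H2) <- list(ids, map$marker)
  sim_pop(ids, H1, H2, parent1 = rep(NA_character_, n_founders),
          parent2 = rep(NA_character_, n_founders),
          generation = rep("founder", n_founders), map = map)
}

#' Simulated population container
#'
#' A phased population: two 0/1 haplotype matrices (individuals x markers),
#' pedigree links and a generation label per individual, plus the shared
#' marker map. Dosage is the haplotype sum. Subset individuals with `[`.
#'
#' @param ids character ids.
#' @param H1,H2 haplotype matrices (0/1), rows in id order.
#' @param parent1,parent2 parental ids (`NA` for founders).
#' @param generation character labels (e.g. "founder", "F1", "F4", "C1").
#' @param map marker map (`marker`, `chrom`, `pos` in Morgans).
#' @return An object of class `sim_pop`.
#' @export
sim_pop <- function(ids, H1, H2, parent1, parent2, generation, map) {
  stopifnot(length(ids) == nrow(H1), identical(dim(H1), dim(H2)),
            length(parent1) == length(ids), length(parent2) == length(ids),
            length(generation) == length(ids))
  if (anyDuplicated(ids)) stop_arg("duplicate individual ids in sim_pop")
  if (!all(H1 %in% c(0L, 1L)) || !all(H2 %in% c(0L, 1L)))
    stop_arg("haplotype entries must be 0/1")
  rownames(H1) <- rownames(H2) <- ids
  structure(list(ids = ids, H1 = H1, H2 = H2, parent1 = parent1,
                 parent2 = parent2, generation = generation, map = map),
            class = "sim_pop")
}

#' @export
print.sim_pop <- function(x, ...) {
  cat(sprintf("sim_pop: %d individuals x %d markers (%s)\n", length(x$ids),
              ncol(x$H1), paste(unique(x$generation), collapse = ", ")))
  invisible(x)
}

#' @export
`[.sim_pop` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  sim_pop(x$ids[i], x$H1[i, , drop = FALSE], x$H2[i, , drop = FALSE],
          x$parent1[i], x$parent2[i], x$generation[i], x$map)
}

#' @export
length.sim_pop <- function(x) length(x$ids)

#' Allele dosages of a simulated population
#'
#' @param pop a [sim_pop()].
#' @return Integer matrix of 0/1/2 dosages, individuals x markers.
#' @export
dosage <- function(pop) pop$H1 + pop$H2

# combine populations sharing a map
rbind_pops <- function(...) {
  ps <- list(...)
  sim_pop(unlist(lapply(ps, `[[`, "ids")),
          do.call(rbind, lapply(ps, `[[`, "H1")),
          do.call(rbind, lapply(ps, `[[`, "H2")),
          unlist(lapply(ps, `[[`, "parent1")),
          unlist(lapply(ps, `[[`, "parent2")),
          unlist(lapply(ps, `[[`, "generation")),
          ps[[1L]]$map)
}

#' Single meiosis with Haldane crossovers
#'
#' Generates one gamete from an individual. Per chromosome the crossover
#' count is Poisson(map length in Morgans) with positions uniform on the
#' chromosome (Haldane model, no interference); the starting haplotype is
#' chosen at random. The expected gamete allele dosage equals half the
#' parental dosage at every marker.
#'
#' @param parent a single-individual [sim_pop()].
#' @param seed optional integer seed.
#' @return Integer 0/1 vector of gamete alleles, one per marker.
#' @export
meiosis <- function(parent, seed = NULL) {
  if (length(parent$ids) != 1L) stop_arg("`parent` must hold exactly one individual")
  set_seed_if(seed)
  map <- parent$map
  h1 <- parent$H1[1L, ]
  h2 <- parent$H2[1L, ]
  gam <- integer(length(h1))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    p <- map$pos[idx]
    len <- max(p) - min(p)
    nxo <- stats::rpois(1L, len)
    start <- stats::rbinom(1L, 1L, 0.5)
    if (nxo == 0L) {
      src <- rep(start, length(idx))
    } else {
      xo <- sort(stats::runif(nxo, min(p), max(p)))
      src <- (start + findInterval(p, xo)) %% 2L
    }
    gam[idx] <- ifelse(src == 0L, h1[idx], h2[idx])
  }
  gam
}

#' Bi-parental cross
#'
#' Each offspring receives one independent gamete from each parent; pedigree
#' links are recorded.
#'
#' @param p1,p2 single-individual [sim_pop()] objects sharing a map.
#' @param n_offspring number of F1 individuals to produce.
#' @param seed optional integer seed.
#' @param ids optional offspring ids; default derives from the parents.
#' @param generation generation label for the offspring.
#' @return A [sim_pop()] of the offspring.
#' @export
cross <- function(p1, p2, n_offspring = 1L, seed = NULL, ids = NULL,
                  generation = "F1") {
  n_offspring <- check_count(n_offspring, "n_offspring")
  set_seed_if(seed)
  if (is.null(ids))
    ids <- sprintf("%sx%s_%02d", p1$ids, p2$ids, seq_len(n_offspring))
  H1 <- t(vapply(seq_len(n_offspring), function(i) meiosis(p1),
                 integer(ncol(p1$H1))))
  H2 <- t(vapply(seq_len(n_offspring), function(i) meiosis(p2),
                 integer(ncol(p2$H1))))
  colnames(H1) <- colnames(H2) <- colnames(p1$H1)
  sim_pop(ids, H1, H2, rep(p1$ids, n_offspring), rep(p2$ids, n_offspring),
          rep(generation, n_offspring), p1$map)
}

#' Advance an individual by repeated self-fertilization
#'
#' Single-seed descent by default: each generation one selfed offspring is
#' kept. `bulk_k > 1` emulates advancement via selected bulks: `bulk_k`
#' selfed candidates are produced each generation and one is kept at random
#' (visual within-bulk selection is not phenotype-informed here). Expected
#' per-marker heterozygosity halves each generation.
#'
#' @param ind a single-individual [sim_pop()].
#' @param n_generations number of selfing generations (>= 1).
#' @param bulk_k candidates produced per generation (default 1, SSD).
#' @param seed optional integer seed.
#' @param id id of the derived line; default keeps the input id.
#' @param generation label for the derived line.
#' @return A single-individual [sim_pop()].
#' @export
self_advance <- function(ind, n_generations, bulk_k = 1L, seed = NULL,
                         id = NULL, generation = NULL) {
  n_generations <- check_count(n_generations, "n_generations")
  bulk_k <- check_count(bulk_k, "bulk_k")
  if (length(ind$ids) != 1L) stop_arg("`ind` must hold exactly one individual")
  set_seed_if(seed)
  cur <- ind
  for (g in seq_len(n_generations)) {
    cands <- cross(cur, cur, n_offspring = bulk_k, generation = "self")
    cur <- cands[sample.int(bulk_k, 1L)]
  }
  out_id <- if (is.null(id)) ind$ids else id
  sim_pop(out_id, cur$H1, cur$H2, ind$parent1, ind$parent2,
          if (is.null(generation)) ind$generation else generation, ind$map)
}

#' Trait architecture for simulated phenotypes
#'
#' Additive per-marker effects, optional additive x additive epistatic pairs,
#' an intercept (trait scale, e.g. ton/ha) and a residual (plot) variance.
#' `family_h2_targets`, when given to [assign_phenotypes()], overrides
#' `env_variance` family by family so the realized line-mean heritability
#' approximates the target.
#'
#' @param additive_effects numeric vector, one effect per marker.
#' @param intercept trait-scale intercept.
#' @param env_variance residual variance per replicate plot (>= 0).
#' @param epistatic_pairs optional `data.frame` with columns `i`, `j`,
#'   `effect`: additive x additive terms `effect * (dos_i - 1) * (dos_j - 1)`.
#' @param family_h2_targets optional named numeric vector, family id ->
#'   target line-mean heritability.
#' @return An object of class `trait_arch`.
#' @export
trait_architecture <- function(additive_effects, intercept = 0,
                               env_variance = 1, epistatic_pairs = NULL,
                               family_h2_targets = NULL) {
  if (!all(is.finite(additive_effects))) stop_arg("additive effects must be finite")
  if (env_variance < 0) stop_arg("env_variance must be >= 0")
  if (!is.null(epistatic_pairs) &&
      !all(c("i", "j", "effect") %in% names(epistatic_pairs)))
    stop_arg("epistatic_pairs needs columns i, j, effect")
  structure(list(additive_effects = additive_effects, intercept = intercept,
                 env_variance = env_variance, epistatic_pairs = epistatic_pairs,
                 family_h2_targets = family_h2_targets),
            class = "trait_arch")
}

#' True genetic values under a trait architecture
#'
#' @param pop a [sim_pop()].
#' @param arch a [trait_architecture()].
#' @return Named numeric vector: intercept + additive + epistatic values.
#' @export
true_values <- function(pop, arch) {
  d <- dosage(pop)
  g <- drop(d %*% arch$additive_effects) + arch$intercept
  if (!is.null(arch$epistatic_pairs)) {
    ep <- arch$epistatic_pairs
    for (k in seq_len(nrow(ep)))
      g <- g + ep$effect[k] * (d[, ep$i[k]] - 1) * (d[, ep$j[k]] - 1)
  }
  names(g) <- pop$ids
  g
}

#' Simulate replicated phenotypes
#'
#' Phenotype of a plot = true genetic value + N(0, env_variance). When
#' `arch$family_h2_targets` is set and `family` is supplied, the residual
#' variance of each family is calibrated from that family's realized genetic
#' variance so the line-mean heritability over `r_reps` replicates matches
#' the target: `env_var = r * var_g * (1 - h2) / h2` (targets clamped to
#' \[0.001, 0.999\]; a family with zero genetic variance falls back to the
#' global `env_variance`).
#'
#' @param pop a [sim_pop()].
#' @param arch a [trait_architecture()].
#' @param r_reps replicates per line.
#' @param seed optional integer seed.
#' @param family optional named character vector (line id -> family).
#' @param year single year label stored in the table.
#' @return `data.frame` with columns `line`, `family`, `rep`, `year`,
#'   `value`, plus the vector of true values as attribute `"true_values"`.
#' @export
assign_phenotypes <- function(pop, arch, r_reps = 1L, seed = NULL,
                              family = NULL, year = 1L) {
  r_reps <- check_count(r_reps, "r_reps")
  set_seed_if(seed)
  g <- true_values(pop, arch)
  n <- length(g)
  fam <- if (is.null(family)) rep(NA_character_, n) else unname(family[pop$ids])
  ev <- rep(arch$env_variance, n)
  if (!is.null(arch$family_h2_targets) && !is.null(family)) {
    for (fm in names(arch$family_h2_targets)) {
      idx <- which(fam == fm)
      if (length(idx) < 2L) next
      vg <- stats::var(g[idx])
      h2 <- min(max(arch$family_h2_targets[[fm]], 0.001), 0.999)
      if (vg > 0) ev[idx] <- r_reps * vg * (1 - h2) / h2
    }
  }
  out <- data.frame(line = rep(pop$ids, each = r_reps),
                    family = rep(fam, each = r_reps),
                    rep = rep(seq_len(r_reps), n),
                    year = year,
                    value = rep(g, each = r_reps) +
                      stats::rnorm(n * r_reps, 0, rep(sqrt(ev), each = r_reps)))
  attr(out, "true_values") <- g
  out
}

#' Default training-population configuration
#'
#' The defaults emulate the study system: 16 inbred founders, 14 bi-parental
#' F2 families advanced to F4 lines with the published family sizes (total
#' 1,609), 7,000 markers on 21 chromosomes of 1 Morgan, family line-mean
#' heritability targets spanning 0.01-0.73, grain-yield-like scale
#' (intercept 6.71 ton/ha) and 2 replicates. `scale = "desk"` is a small
#' configuration of identical structure for examples and tests.
#'
#' @param scale `"study"` or `"desk"`.
#' @param ... named overrides of any configuration element.
#' @return A list of configuration values.
#' @export
training_pop_config <- function(scale = c("study", "desk"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    n_founders = 16L,
    n_markers = 7000L,
    n_chromosomes = 21L,
    family_sizes = c(94L, 190L, 190L, 95L, 95L, 95L, 95L, 95L, 94L, 95L,
                     95L, 95L, 95L, 186L),
    family_h2 = c(0.39, 0.44, 0.56, 0.73, 0.07, 0.55, 0.44, 0.01, 0.04,
                  0.32, 0.48, 0.55, 0.44, 0.28),
    selfing_generations = 2L,  # F2 -> F4
    bulk_k = 3L,               # selected-bulk candidates per generation
    r_reps = 2L,
    intercept = 6.71,
    genetic_sd = 0.5,
    maf_threshold = 0.05)
  if (scale == "desk") {
    cfg$n_markers <- 210L
    cfg$family_sizes <- rep(16L, 14L)
  }
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop_arg("unknown config fields: ",
                                  paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Simulate a multi-family training population
#'
#' Builds bi-parental families from the founders (founder pairs chosen so
#' every founder is used), produces one F1 per family, derives each line
#' from a distinct selfed F2 plant advanced by `selfing_generations`
#' generations of selfing (selected-bulk policy), and attaches replicated
#' phenotypes with per-family heritability calibration.
#'
#' @param config list from [training_pop_config()].
#' @param seed optional integer seed.
#' @return A list: `pop` ([sim_pop()] of lines), `founders`, `mm`
#'   ([marker_matrix()] of line dosages), `pedigree` (see [pedigree()]),
#'   `pheno` (replicated phenotype table), `family` (named vector line ->
#'   family), `arch` (the [trait_architecture()] used), `true_values`.
#' @export
make_training_population <- function(config = training_pop_config(), seed = NULL) {
  set_seed_if(seed)
  founders <- make_founders(config$n_founders, config$n_markers,
                            config$n_chromosomes)
  n_fam <- length(config$family_sizes)
  # founder pairs: a first pass uses every founder once, extra families
  # re-pair random distinct founders
  base_pairs <- matrix(sample(config$n_founders), ncol = 2L)
  pairs <- base_pairs
  while (nrow(pairs) < n_fam) {
    cand <- sort(sample(config$n_founders, 2L))
    if (!any(pairs[, 1L] == cand[1L] & pairs[, 2L] == cand[2L]))
      pairs <- rbind(pairs, cand)
  }
  pairs <- pairs[seq_len(n_fam), , drop = FALSE]

  eff <- stats::rnorm(config$n_markers) / sqrt(config$n_markers)
  fam_pops <- vector("list", n_fam)
  line_counter <- 0L
  for (fm in seq_len(n_fam)) {
    f1 <- cross(founders[pairs[fm, 1L]], founders[pairs[fm, 2L]], 1L,
                ids = sprintf("F1_%02d", fm))
    nl <- config$family_sizes[fm]
    lines <- vector("list", nl)
    for (l in seq_len(nl)) {
      line_counter <- line_counter + 1L
      f2 <- cross(f1, f1, 1L, ids = sprintf("L%04d", line_counter),
                  generation = "F2")
      lines[[l]] <- self_advance(f2, config$selfing_generations,
                                 bulk_k = config$bulk_k, generation = "F4")
    }
    fam_pops[[fm]] <- do.call(rbind_pops, lines)
  }
  pop <- do.call(rbind_pops, fam_pops)
  family <- stats::setNames(rep(sprintf("Fam%02d", seq_len(n_fam)),
                                config$family_sizes), pop$ids)

  # scale additive effects so line true values have the configured SD
  g0 <- drop(dosage(pop) %*% eff)
  s <- stats::sd(g0)
  if (s > 0) eff <- eff * config$genetic_sd / s
  h2t <- stats::setNames(config$family_h2, sprintf("Fam%02d", seq_len(n_fam)))
  arch <- trait_architecture(eff, intercept = config$intercept,
                             env_variance = config$genetic_sd^2,
                             family_h2_targets = h2t)
  pheno <- assign_phenotypes(pop, arch, r_reps = config$r_reps,
                             family = family)
  ped <- pedigree(
    id = c(founders$ids, sprintf("F1_%02d", seq_len(n_fam)), pop$ids),
    parent1 = c(rep(NA, config$n_founders), founders$ids[pairs[, 1L]],
                rep(sprintf("F1_%02d", seq_len(n_fam)), config$family_sizes)),
    parent2 = c(rep(NA, config$n_founders), founders$ids[pairs[, 2L]],
                rep(sprintf("F1_%02d", seq_len(n_fam)), config$family_sizes)),
    selfing = c(rep(0L, config$n_founders), rep(0L, n_fam),
                rep(config$selfing_generations, sum(config$family_sizes))))
  list(pop = pop, founders = founders,
       mm = marker_matrix(dosage(pop), pop$map),
       pedigree = ped, pheno = pheno, family = family, arch = arch,
       true_values = attr(pheno, "true_values"))
}
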