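#' Validate a pipeline configuration file
#'
#' Reads a YAML (or list) configuration describing a scheme run and checks
#' it against the configuration schema: only known keys are accepted, every
#' stochastic stage must carry an explicit seed, and count fields must be
#' positive integers. The `scheme` block accepts any [scheme_config()]
#' field (with `training` nested inside it).
#'
#' @param x path to a YAML file, or a list.
#' @return A validated list with elements `seed` (named seeds per stage)
#'   and `scheme` (a [scheme_config()]).
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop_arg("configuration must be a YAML mapping")
  known <- c("seeds", "scheme", "scale")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_arg("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seeds) || is.null(cfg$seeds$scheme))
    stop_arg("configuration must set seeds$scheme")
  for (s in names(cfg$seeds)) check_count(cfg$seeds[[s]], paste0("seeds$", s), 0L)
  scale <- if (is.null(cfg$scale)) "study" else cfg$scale
  over <- cfg$scheme
  if (!is.null(over$training))
    over$training <- do.call(training_pop_config,
                             c(list(scale = scale), over$training))
  scheme <- do.call(scheme_config, c(list(scale = scale), over))
  list(seeds = cfg$seeds, scheme = scheme)
}

#' Tiny bundled datasets for examples and tests
#'
#' `"mini14"` is a 14-family x 4-line training population on 120 markers
#' (6 chromosomes), generated deterministically at call time; it loads into
#' every module (marker matrix, pedigree, phenotypes, family labels).
#'
#' @param name fixture name.
#' @return The same structure as [make_training_population()].
#' @export
rcgs_fixture <- function(name = "mini14") {
  switch(name,
    mini14 = make_training_population(
      training_pop_config("desk", n_markers = 120L, n_chromosomes = 6L,
                          family_sizes = rep(4L, 14L)),
      seed = 20230126L),
    stop_arg("unknown fixture: ", name))
}
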