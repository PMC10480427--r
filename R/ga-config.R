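#' Genetic-algorithm configuration
#'
#' Collects the tunables shared by both search stages: `Ns` candidate
#' solutions per iteration, `Ni` iterations, the mutation factor `Mu`
#' scaling the mean-fitness survival threshold, and the train-to-test
#' ratio `Tr` used by the partition search. The remaining fields echo the
#' method's published parameter table (population size 100, chromosome
#' length 20, 10 runs, 100 iterations, selection rate 0.8, crossover rate
#' 0.9, mutation rate 0.2); `selection_rate` and `crossover_rate` are not
#' used by the mark/regenerate procedure this package implements and are
#' kept for configuration compatibility only.
#'
#' @param Ns Number of candidate solutions held per iteration (>= 1).
#' @param Ni Number of iterations (>= 1).
#' @param Mu Mutation factor in (0, 1]: solutions with fitness above
#'   `mean(fitness) * Mu` survive an iteration unchanged.
#' @param Tr Train-to-test ratio in (0, 1); fixes the training-set size
#'   of the partition search (rounded to equal per-class counts).
#' @param seed Integer seed; every stochastic draw of a run flows from it.
#' @param population_size,chromosome_length,n_runs,max_iterations,selection_rate,crossover_rate,mutation_rate
#'   Published parameter-table echoes (see Details).
#' @param regen_attempts Cap on regeneration attempts per solution slot
#'   per iteration before the best rejected candidate is kept.
#' @param inner_split Optional fraction in (0, 1): when set, the length
#'   search scores candidates on an inner validation split carved from the
#'   training set instead of the stage-one test partition.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(Ns = 10L, Ni = 10L, Mu = 0.2, Tr = 0.8, seed = 1L,
                      population_size = 100L, chromosome_length = 20L,
                      n_runs = 10L, max_iterations = 100L,
                      selection_rate = 0.8, crossover_rate = 0.9,
                      mutation_rate = 0.2, regen_attempts = 50L,
                      inner_split = NULL) {
  stopifnot(Ns >= 1, Ni >= 1)
  if (!is.numeric(Mu) || Mu <= 0 || Mu > 1) stop("Mu must lie in (0, 1]")
  if (!is.numeric(Tr) || Tr <= 0 || Tr >= 1) stop("Tr must lie in (0, 1)")
  for (r in c(selection_rate, crossover_rate, mutation_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (!is.null(inner_split) &&
      (!is.numeric(inner_split) || inner_split <= 0 || inner_split >= 1)) {
    stop("inner_split must lie in (0, 1)")
  }
  structure(
    list(Ns = as.integer(Ns), Ni = as.integer(Ni), Mu = Mu, Tr = Tr,
         seed = as.integer(seed), population_size = as.integer(population_size),
         chromosome_length = as.integer(chromosome_length),
         n_runs = as.integer(n_runs), max_iterations = as.integer(max_iterations),
         selection_rate = selection_rate, crossover_rate = crossover_rate,
         mutation_rate = mutation_rate, regen_attempts = as.integer(regen_attempts),
         inner_split = inner_split),
    class = "ga_config"
  )
}
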