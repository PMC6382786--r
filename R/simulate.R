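#' Simulate a growing pedigree to a target generation size
#'
#' Runs the demographic model forward from a founder population: pair
#' formation among unrelated opposite-gender agents, Poisson(`kappa`)
#' births per pair, strictly non-overlapping generations. The simulation
#' stops at the first generation whose size reaches `n_target`; randomly
#' chosen agents are then eliminated so that the returned generation has
#' exactly `n_target` members. With `kappa` above replacement (2 children
#' per couple) the population grows by roughly `kappa / 2` per generation.
#'
#' @param kappa Positive mean fertility per pair (the model is exercised
#'   over 2.5-5.0 but any positive value is accepted).
#' @param n_target Target final-generation size (500 and 2000 are the
#'   standard study sizes).
#' @param n_founders Founder count (default 100; 50-100 is the intended
#'   range).
#' @param max_generations Abort with a non-convergence error after this
#'   many generations.
#' @param seed Optional seed for the global RNG.
#' @return A `generation` of exactly `n_target` agents, with attributes
#'   `history` (list of every simulated generation, founders first) and
#'   `n_generations` (generations simulated after the founders).
#' @section Errors: A population that dies out (no agents, or no feasible
#'   pair) raises a condition of class `kinnet_extinction_error` carrying
#'   the generation reached; exceeding `max_generations` raises
#'   `kinnet_convergence_error`.
#' @examples
#' g <- simulate_pedigree(kappa = 5, n_target = 200, n_founders = 50,
#'                        seed = 1)
#' nrow(g)
#' @export
simulate_pedigree <- function(kappa, n_target, n_founders = 100,
                              max_generations = 60, seed = NULL) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop_kinnet("kappa must be a single positive number",
                "kinnet_invalid_argument")
  if (!is.numeric(n_target) || length(n_target) != 1L || n_target < 1)
    stop_kinnet("n_target must be a positive integer",
                "kinnet_invalid_argument")
  if (!is.numeric(max_generations) || max_generations < 1)
    stop_kinnet("max_generations must be a positive integer",
                "kinnet_invalid_argument")
  maybe_set_seed(seed)

  gen <- found_population(n_founders)
  history <- list(gen)
  repeat {
    if (nrow(gen) >= n_target) {
      out <- trim_to_target(gen, n_target)
      attr(out, "history") <- history
      attr(out, "n_generations") <- generation_index(gen)
      return(out)
    }
    if (generation_index(gen) >= max_generations)
      stop_kinnet(
        sprintf("population did not reach %d agents within %d generations",
                n_target, as.integer(max_generations)),
        "kinnet_convergence_error", generation = generation_index(gen))
    pairing <- form_pairs(gen)
    if (nrow(pairing) == 0L)
      stop_kinnet(
        sprintf("population extinct: no feasible pair in generation %d",
                generation_index(gen)),
        "kinnet_extinction_error", generation = generation_index(gen))
    gen <- reproduce(pairing, gen, kappa)
    if (nrow(gen) == 0L)
      stop_kinnet(
        sprintf("population extinct in generation %d", generation_index(gen)),
        "kinnet_extinction_error", generation = generation_index(gen))
    history[[length(history) + 1L]] <- gen
  }
}

#' Trim a generation to an exact size
#'
#' Keeps a uniformly random subset of exactly `n_target` agents; ancestry
#' fields are untouched.
#'
#' @param generation A `generation` with at least `n_target` members.
#' @param n_target Number of agents to keep.
#' @param seed Optional seed for the global RNG.
#' @return A `generation` of exactly `n_target` agents.
#' @export
trim_to_target <- function(generation, n_target, seed = NULL) {
  if (!inherits(generation, "generation"))
    stop_kinnet("expected a generation object", "kinnet_invalid_argument")
  if (nrow(generation) < n_target)
    stop_kinnet("generation smaller than n_target", "kinnet_invalid_argument")
  maybe_set_seed(seed)
  if (nrow(generation) == n_target) return(generation)
  keep <- sort(sample.int(nrow(generation), n_target))
  out <- generation[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "generation_index") <- generation_index(generation)
  class(out) <- c("generation", "data.frame")
  out
}
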