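#' Construct a generation of agents
#'
#' A generation is the basic population unit: a set of agents born in the
#' same (non-overlapping) generation, each carrying its recognised ancestor
#' set. An agent's ancestry holds the ids of its known mother, father and
#' up to four grandparents: empty for founders, the two parents for the
#' first generation, six ids from the second generation on. Kinship between
#' two agents is recognised exactly when their ancestry sets intersect,
#' which captures siblings and first cousins (and parent-child links within
#' a generation never arise because generations do not overlap).
#'
#' @param agent_id Integer vector of unique non-negative agent ids.
#' @param gender Integer vector of 0/1 genders.
#' @param mother_id,father_id Integer vectors of parent ids (`NA` for
#'   founders with unknown parents).
#' @param ancestry List of integer vectors, one per agent, each of length
#'   0, 2 or 6. If `NULL`, built from the non-`NA` parent ids (suitable for
#'   founder or first-generation tables; grandparents cannot be inferred
#'   from a single generation).
#' @param index Generation counter (0 for founders).
#' @return An object of class `generation`: a data frame with columns
#'   `agent_id`, `gender`, `mother_id`, `father_id` and list column
#'   `ancestry`, plus a `generation_index` attribute.
#' @examples
#' g <- generation(1:2, gender = c(0L, 1L))
#' @export
generation <- function(agent_id, gender, mother_id = NA_integer_,
                       father_id = NA_integer_, ancestry = NULL,
                       index = 0L) {
  n <- length(agent_id)
  agent_id <- as.integer(agent_id)
  gender <- as.integer(gender)
  mother_id <- rep_len(as.integer(mother_id), n)
  father_id <- rep_len(as.integer(father_id), n)
  if (is.null(ancestry)) {
    ancestry <- mapply(function(m, f) as.integer(c(m, f)[!is.na(c(m, f))]),
                       mother_id, father_id, SIMPLIFY = FALSE)
  }
  out <- data.frame(agent_id = agent_id, gender = gender,
                    mother_id = mother_id, father_id = father_id)
  out$ancestry <- ancestry
  attr(out, "generation_index") <- as.integer(index)
  class(out) <- c("generation", "data.frame")
  validate_generation(out)
  out
}

validate_generation <- function(x) {
  if (anyDuplicated(x$agent_id))
    stop_kinnet("duplicate agent ids in generation", "kinnet_integrity_error")
  if (any(is.na(x$agent_id)) || any(x$agent_id < 0L))
    stop_kinnet("agent ids must be non-negative and non-missing",
                "kinnet_invalid_argument")
  if (!all(x$gender %in% c(0L, 1L)))
    stop_kinnet("gender must be 0 or 1", "kinnet_invalid_argument")
  len <- lengths(x$ancestry)
  if (!all(len %in% c(0L, 2L, 6L)))
    stop_kinnet("ancestry sets must have 0, 2 or 6 elements",
                "kinnet_invalid_argument")
  self <- mapply(function(id, anc) id %in% anc, x$agent_id, x$ancestry)
  if (any(self))
    stop_kinnet("an agent cannot be its own ancestor",
                "kinnet_integrity_error")
  invisible(x)
}

#' @export
print.generation <- function(x, ...) {
  cat(sprintf("<generation %d: %d agents (%d female, %d male)>\n",
              generation_index(x), nrow(x), sum(x$gender == 1L),
              sum(x$gender == 0L)))
  invisible(x)
}

#' Generation index accessor
#' @param x A `generation`.
#' @return The integer generation counter.
#' @export
generation_index <- function(x) {
  attr(x, "generation_index")
}

#' Found a population of unrelated agents
#'
#' Creates generation 0: `n_founders` agents with empty ancestry sets and
#' independent uniform 0/1 genders. Founders are never recognised as kin
#' (empty set intersections), so any opposite-gender founder pair can mate.
#'
#' @param n_founders Number of founders (at least 2).
#' @param seed Optional seed for the global RNG.
#' @return A `generation` with index 0.
#' @examples
#' set.seed(1)
#' found_population(10)
#' @export
found_population <- function(n_founders, seed = NULL) {
  if (!is.numeric(n_founders) || length(n_founders) != 1L || n_founders < 2)
    stop_kinnet("n_founders must be a single integer >= 2",
                "kinnet_invalid_argument")
  maybe_set_seed(seed)
  n <- as.integer(n_founders)
  generation(agent_id = seq_len(n),
             gender = sample(c(0L, 1L), n, replace = TRUE),
             ancestry = rep(list(integer(0)), n),
             index = 0L)
}

#' Closed-form kin count under constant fertility
#'
#' In a deterministic pedigree where every couple has exactly `k` children
#' and all spouses are unrelated, an individual has `k - 1` siblings and
#' `2 k (k - 1)` first cousins (each parent has `k - 1` siblings, each with
#' `k` children), for a total of `(k - 1)(2 k + 1)` same-generation agents
#' sharing at least one grandparent. Falling fertility from 5 to 2 children
#' per couple collapses this count from 44 to 5.
#'
#' @param k Children per couple (integer, at least 1).
#' @return Named integer vector with elements `siblings`, `cousins`,
#'   `total`.
#' @examples
#' expected_kin_count(5)  # 4 siblings, 40 cousins, 44 total
#' expected_kin_count(2)  # 1 sibling, 4 cousins, 5 total
#' @export
expected_kin_count <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop_kinnet("k must be a single integer >= 1", "kinnet_invalid_argument")
  k <- as.integer(k)
  c(siblings = k - 1L, cousins = 2L * k * (k - 1L),
    total = (k - 1L) * (2L * k + 1L))
}
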