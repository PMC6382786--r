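# Gossip-based reputation dynamics: a single agent (the focal) is observed
# defecting by one contact; the bad belief then spreads through gossip
# between contacts who share the focal as an acquaintance, optionally
# decaying through independent per-round forgiving.

adj_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

#' Seed a reputation process with one observation
#'
#' Picks the focal agent uniformly at random, then one of its social
#' contacts uniformly as the observer; the observer's belief about the
#' focal is set to "bad" (1), every other belief is neutral (0), and the
#' round counter starts at 1.
#'
#' @param network A `social_network`.
#' @param seed Optional seed for the global RNG.
#' @return An object of class `reputation_state`: a list with `round`,
#'   `focal`, `observer` (node indices) and logical vector `beliefs`.
#' @export
seed_observation <- function(network, seed = NULL) {
  g <- as_graph(network)
  n <- igraph::vcount(g)
  if (n < 2L)
    stop_kinnet("need at least 2 agents", "kinnet_invalid_argument")
  maybe_set_seed(seed)
  focal <- sample.int(n, 1L)
  nb <- as.integer(igraph::neighbors(g, focal))
  if (length(nb) == 0L)
    stop_kinnet("focal agent has no contacts; cannot seed an observation",
                "kinnet_seeding_error")
  observer <- nb[sample.int(length(nb), 1L)]
  beliefs <- logical(n)
  beliefs[observer] <- TRUE
  structure(list(round = 1L, focal = focal, observer = observer,
                 beliefs = beliefs),
            class = "reputation_state")
}

#' @export
print.reputation_state <- function(x, ...) {
  cat(sprintf(
    "<reputation_state: round %d, focal %d, observer %d, %d informed>\n",
    x$round, x$focal, x$observer, sum(x$beliefs)))
  invisible(x)
}

eligible_agents <- function(variant, beliefs, focal, contacts) {
  uninformed <- switch(variant,
    shared_acquaintance = contacts[!beliefs[contacts]],
    noncontact = setdiff(which(!beliefs), c(focal, contacts)),
    broadcast = setdiff(which(!beliefs), focal),
    stop_kinnet(sprintf("unknown variant '%s'", variant),
                "kinnet_invalid_argument"))
  # ascending node order fixes the per-agent RNG draw order
  sort(as.integer(uninformed))
}

transmitter_agents <- function(variant, beliefs, contacts) {
  if (variant == "broadcast") which(beliefs)
  else contacts[beliefs[contacts]]
}

# Synchronous gossip update on a precomputed adjacency list. Consumes one
# uniform draw per eligible agent, in node-index order of `eligible`.
gossip_step <- function(beliefs, focal, contacts, adj, alpha, variant) {
  eligible <- eligible_agents(variant, beliefs, focal, contacts)
  if (length(eligible) == 0L) return(beliefs)
  transmitters <- transmitter_agents(variant, beliefs, contacts)
  beta <- vapply(adj[eligible],
                 function(nb) sum(nb %in% transmitters), integer(1L))
  p <- 1 - (1 - alpha)^beta
  flips <- stats::runif(length(eligible)) < p
  beliefs[eligible[flips]] <- TRUE
  beliefs
}

# TRUE when no eligible uninformed agent has a positive transmitter count
# (the no-forgiving fixed point).
gossip_stalled <- function(beliefs, focal, contacts, adj, variant) {
  eligible <- eligible_agents(variant, beliefs, focal, contacts)
  if (length(eligible) == 0L) return(TRUE)
  transmitters <- transmitter_agents(variant, beliefs, contacts)
  if (length(transmitters) == 0L) return(TRUE)
  all(vapply(adj[eligible],
             function(nb) !any(nb %in% transmitters), logical(1L)))
}

#' One synchronous gossip round
#'
#' Every eligible agent whose belief about the focal is still neutral
#' flips to "bad" with probability `1 - (1 - alpha)^beta`, where `beta`
#' counts its already-informed transmitters and `alpha` is the per-pair
#' gossip probability; all `beta` values are computed from the beliefs at
#' the start of the round. Which agents are eligible, and who transmits,
#' depends on the variant:
#'
#' * `"shared_acquaintance"` (default): contacts of the focal update;
#'   transmitters are informed mutual contacts — agents gossip with their
#'   contacts about a shared acquaintance.
#' * `"noncontact"`: only non-contacts of the focal update, while
#'   transmitters are still informed contacts, which confines the news to
#'   the observer's surroundings; kept selectable for sensitivity
#'   analysis.
#' * `"broadcast"`: every agent (except the focal) updates and every
#'   informed neighbour transmits, regardless of acquaintance with the
#'   focal.
#'
#' The focal agent itself never updates.
#'
#' @param state A `reputation_state`.
#' @param network The `social_network` the state lives on.
#' @param alpha Gossip probability in `[0, 1]`.
#' @param variant Update-rule variant (see above).
#' @return The updated `reputation_state` (round incremented).
#' @export
gossip_round <- function(state, network, alpha,
                         variant = c("shared_acquaintance", "noncontact",
                                     "broadcast")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop_kinnet("alpha must be in [0, 1]", "kinnet_invalid_argument")
  variant <- match.arg(variant)
  g <- as_graph(network)
  adj <- adj_list(g)
  contacts <- adj[[state$focal]]
  state$beliefs <- gossip_step(state$beliefs, state$focal, contacts, adj,
                               alpha, variant)
  state$round <- state$round + 1L
  state
}

#' Forgiving step
#'
#' Every currently "bad" belief (the original observer's included)
#' independently reverts to neutral with probability `pi`. Applied after
#' the gossip update of the same round.
#'
#' @param state A `reputation_state`.
#' @param pi Forgiving probability in `[0, 1]`.
#' @return The updated `reputation_state` (round unchanged).
#' @export
forgiving_step <- function(state, pi) {
  if (!is.numeric(pi) || length(pi) != 1L || pi < 0 || pi > 1)
    stop_kinnet("pi must be in [0, 1]", "kinnet_invalid_argument")
  informed <- which(state$beliefs)
  if (length(informed)) {
    forgiven <- stats::runif(length(informed)) < pi
    state$beliefs[informed[forgiven]] <- FALSE
  }
  state
}

#' Run a full reputation trajectory
#'
#' Seeds one observation, then alternates synchronous gossip rounds (and a
#' forgiving step when `pi` is given) until `max_rounds`, until every
#' belief has reverted to neutral (forgiving runs), or until no further
#' change is possible (no-forgiving fixed point: no uninformed eligible
#' agent has an informed transmitter). Without forgiving the informed
#' count is non-decreasing.
#'
#' @param network A `social_network`.
#' @param alpha Gossip probability.
#' @param pi Forgiving probability, or `NULL` for the no-forgiving
#'   dynamics.
#' @param max_rounds Round budget (default 100).
#' @param variant Update-rule variant, see [gossip_round()].
#' @param seed Optional seed for the global RNG.
#' @return An object of class `reputation_trajectory`: a list with
#'   `counts` (data frame of `round`, `informed_total`,
#'   `informed_contacts`), `focal`, `observer`, `n_contacts`,
#'   `time_to_half` (first round informing at least half of the focal's
#'   contacts, `NA` if never), `extinction_round` (`NA` unless a forgiving
#'   run died out), `stalled`, and the run parameters.
#' @export
run_reputation <- function(network, alpha, pi = NULL, max_rounds = 100,
                           variant = c("shared_acquaintance", "noncontact",
                                       "broadcast"),
                           seed = NULL) {
  if (!is.numeric(max_rounds) || length(max_rounds) != 1L || max_rounds < 1)
    stop_kinnet("max_rounds must be a positive integer",
                "kinnet_invalid_argument")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop_kinnet("alpha must be in [0, 1]", "kinnet_invalid_argument")
  if (!is.null(pi) && (!is.numeric(pi) || pi < 0 || pi > 1))
    stop_kinnet("pi must be in [0, 1] or NULL", "kinnet_invalid_argument")
  variant <- match.arg(variant)
  maybe_set_seed(seed)

  g <- as_graph(network)
  adj <- adj_list(g)
  state <- seed_observation(network)
  contacts <- adj[[state$focal]]
  max_rounds <- as.integer(max_rounds)

  rounds <- integer(max_rounds)
  total <- integer(max_rounds)
  on_contacts <- integer(max_rounds)
  record <- function(i, beliefs) {
    rounds[i] <<- i
    total[i] <<- sum(beliefs)
    on_contacts[i] <<- sum(beliefs[contacts])
  }
  record(1L, state$beliefs)

  extinction_round <- NA_integer_
  stalled <- FALSE
  last <- 1L
  while (state$round < max_rounds) {
    state$beliefs <- gossip_step(state$beliefs, state$focal, contacts, adj,
                                 alpha, variant)
    state$round <- state$round + 1L
    if (!is.null(pi)) state <- forgiving_step(state, pi)
    last <- state$round
    record(last, state$beliefs)
    if (!is.null(pi) && !any(state$beliefs)) {
      extinction_round <- last
      break
    }
    if (is.null(pi) &&
        gossip_stalled(state$beliefs, state$focal, contacts, adj, variant)) {
      stalled <- TRUE
      break
    }
  }

  counts <- data.frame(round = rounds[seq_len(last)],
                       informed_total = total[seq_len(last)],
                       informed_contacts = on_contacts[seq_len(last)])
  half <- which(counts$informed_contacts >= length(contacts) / 2)
  structure(list(counts = counts,
                 focal = state$focal, observer = state$observer,
                 n_contacts = length(contacts),
                 time_to_half = if (length(half)) counts$round[half[1L]]
                                else NA_integer_,
                 extinction_round = extinction_round,
                 stalled = stalled,
                 alpha = alpha, pi = pi, variant = variant,
                 max_rounds = max_rounds),
            class = "reputation_trajectory")
}

#' @export
print.reputation_trajectory <- function(x, ...) {
  final <- x$counts[nrow(x$counts), ]
  cat(sprintf(
    "<reputation_trajectory: %s, alpha = %g%s, %d rounds>\n",
    x$variant, x$alpha,
    if (is.null(x$pi)) "" else sprintf(", pi = %g", x$pi),
    nrow(x$counts)))
  cat(sprintf("  final: %d informed (%d of %d focal contacts)%s%s\n",
              final$informed_total, final$informed_contacts, x$n_contacts,
              if (!is.na(x$extinction_round))
                sprintf("; extinct at round %d", x$extinction_round) else "",
              if (x$stalled) "; stalled" else ""))
  invisible(x)
}
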