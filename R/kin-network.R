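#' Build the kin graph of a generation
#'
#' Two agents of the same generation are recognised kin exactly when their
#' ancestry sets intersect — they share a parent (siblings) or a
#' grandparent (first cousins). The resulting adjacency is symmetric with
#' a zero diagonal. Founders (empty ancestry) are never kin.
#'
#' @param generation A `generation` with at least one agent.
#' @return An object of class `kin_network`: a list with elements `graph`
#'   (undirected igraph, vertices named by agent id), `agent_ids`, and
#'   `kin_keys` (canonical keys of every kin pair, retained through
#'   truncation so friend completion can avoid kin).
#' @examples
#' ped <- make_fixture("deterministic_pedigree", k = 2)
#' net <- build_kin_adjacency(ped)
#' mean_kin_degree(net)  # 5 = 1 sibling + 4 cousins
#' @export
build_kin_adjacency <- function(generation) {
  if (!inherits(generation, "generation"))
    stop_kinnet("expected a generation object", "kinnet_invalid_argument")
  ids <- generation$agent_id
  if (anyDuplicated(ids))
    stop_kinnet("duplicate agent ids", "kinnet_integrity_error")
  n <- length(ids)
  anc <- generation$ancestry

  # group agents by shared ancestor; all pairs within a group are kin
  groups <- split(rep.int(seq_len(n), lengths(anc)), unlist(anc))
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups)) {
    pair_mat <- do.call(cbind, lapply(groups, function(g) utils::combn(g, 2L)))
    keys <- pair_key(pair_mat[1L, ], pair_mat[2L, ])
    keep <- !duplicated(keys)
    pair_mat <- pair_mat[, keep, drop = FALSE]
    keys <- keys[keep]
  } else {
    pair_mat <- matrix(integer(0), nrow = 2L)
    keys <- character(0)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(ids))
  if (ncol(pair_mat))
    g <- igraph::add_edges(g, as.vector(pair_mat))
  structure(list(graph = g, agent_ids = ids, kin_keys = keys),
            class = "kin_network")
}

#' @export
print.kin_network <- function(x, ...) {
  cat(sprintf("<kin_network: %d agents, %d kin edges, mean kin degree %.2f>\n",
              length(x$agent_ids), igraph::ecount(x$graph),
              if (length(x$agent_ids)) mean_kin_degree(x) else 0))
  invisible(x)
}

#' Mean kin degree of a kin network
#'
#' The average number of recognised relatives per agent: twice the kin
#' edge count divided by the number of agents. This is the model's
#' fertility proxy d(g); the fertility regime boundary sits at one third
#' of the social capacity.
#'
#' @param network A non-empty `kin_network`.
#' @return A non-negative number.
#' @export
mean_kin_degree <- function(network) {
  if (!inherits(network, "kin_network"))
    stop_kinnet("expected a kin_network", "kinnet_invalid_argument")
  n <- igraph::vcount(network$graph)
  if (n == 0L)
    stop_kinnet("empty network", "kinnet_invalid_argument")
  2 * igraph::ecount(network$graph) / n
}

#' Truncate kin degrees to the social capacity
#'
#' Agents with more relatives than the capacity `nu` drop a uniformly
#' random subset of their kin ties down to the limit. Over-capacity nodes
#' are visited in random order; removals are whole (symmetric) edges, so a
#' partner's degree may fall below `nu` as a side effect — the gap is
#' refilled later by friend edges. The set of recognised kin pairs
#' (`kin_keys`) is unchanged: truncation limits contacts, not recognition.
#'
#' @param network A `kin_network`.
#' @param nu Positive integer capacity (60 in the standard setup).
#' @param seed Optional seed for the global RNG.
#' @return A `kin_network` in which no node has kin degree above `nu`.
#' @export
truncate_kin_degree <- function(network, nu, seed = NULL) {
  if (!inherits(network, "kin_network"))
    stop_kinnet("expected a kin_network", "kinnet_invalid_argument")
  if (!is.numeric(nu) || length(nu) != 1L || nu < 1)
    stop_kinnet("nu must be a positive integer", "kinnet_invalid_argument")
  maybe_set_seed(seed)
  g <- network$graph
  deg <- igraph::degree(g)
  over <- which(deg > nu)
  if (length(over)) {
    for (v in over[sample.int(length(over))]) {
      dv <- igraph::degree(g, v)
      if (dv > nu) {
        inc <- as.integer(igraph::incident(g, v))
        drop <- inc[sample.int(length(inc), dv - nu)]
        g <- igraph::delete_edges(g, drop)
      }
    }
  }
  structure(list(graph = g, agent_ids = network$agent_ids,
                 kin_keys = network$kin_keys),
            class = "kin_network")
}

#' Complete a kin network to a uniform-degree social network
#'
#' Adds random "friend" edges between non-kin agents until every agent has
#' exactly `nu` social contacts, reflecting a fixed personal social
#' capacity. Completion uses stub matching over the multiset of
#' under-capacity nodes: repeatedly shuffle one stub per missing contact,
#' pair stubs, and keep the pairs that are legal (distinct, not already
#' connected, not recognised kin — even kin whose tie was truncated are
#' never made friends). If progress stalls (illegal draws exceeding a
#' budget of `100 * n`), the friend phase restarts from scratch with fresh
#' randomness.
#'
#' @param network A `kin_network` whose degrees are all at most `nu`
#'   (run [truncate_kin_degree()] first).
#' @param nu Positive integer capacity; `n * nu` must be even and
#'   `n > nu`.
#' @param max_restarts Restart budget before giving up (default 50).
#' @param seed Optional seed for the global RNG.
#' @return An object of class `social_network`: a list with `graph`
#'   (igraph, edge attribute `kind` in `{"kin", "friend"}`), `agent_ids`,
#'   `nu`, `kin_keys`.
#' @section Errors: infeasible completion raises
#'   `kinnet_completion_error` reporting the residual per-node deficits.
#' @export
add_random_friends <- function(network, nu, max_restarts = 50, seed = NULL) {
  if (!inherits(network, "kin_network"))
    stop_kinnet("expected a kin_network", "kinnet_invalid_argument")
  if (!is.numeric(nu) || length(nu) != 1L || nu < 1)
    stop_kinnet("nu must be a positive integer", "kinnet_invalid_argument")
  n <- length(network$agent_ids)
  if (n <= nu)
    stop_kinnet("degree nu is impossible: need more than nu agents",
                "kinnet_invalid_argument")
  if ((n * nu) %% 2 != 0)
    stop_kinnet("n * nu must be even for a nu-regular network",
                "kinnet_invalid_argument")
  deg0 <- igraph::degree(network$graph)
  if (any(deg0 > nu))
    stop_kinnet("kin degrees exceed nu; truncate first",
                "kinnet_invalid_argument")
  maybe_set_seed(seed)

  budget <- 100 * n
  deficit0 <- as.integer(nu - deg0)
  for (restart in seq_len(max_restarts)) {
    taken <- new.env(hash = TRUE, parent = emptyenv())
    for (k in network$kin_keys) assign(k, TRUE, envir = taken)
    is_taken <- function(keys)
      vapply(keys, exists, logical(1L), envir = taken, inherits = FALSE)
    deficit <- deficit0
    new_a <- integer(0)
    new_b <- integer(0)
    failures <- 0
    ok <- TRUE
    while (sum(deficit) > 0L) {
      active <- which(deficit > 0L)
      if (sum(deficit) <= 64L) {
        # residual phase: enumerate the legal pairs among the remaining
        # under-capacity nodes and draw one with stub-multiplicity
        # weights; an empty legal set is a dead end, so restart
        if (length(active) < 2L) {
          ok <- FALSE
          break
        }
        cmb <- utils::combn(active, 2L)
        keys <- pair_key(cmb[1L, ], cmb[2L, ])
        legal <- which(!is_taken(keys))
        if (length(legal) == 0L) {
          ok <- FALSE
          break
        }
        w <- deficit[cmb[1L, legal]] * deficit[cmb[2L, legal]]
        pick <- legal[sample.int(length(legal), 1L, prob = w)]
        a <- cmb[1L, pick]
        b <- cmb[2L, pick]
        assign(keys[pick], TRUE, envir = taken)
        new_a <- c(new_a, a)
        new_b <- c(new_b, b)
        deficit[c(a, b)] <- deficit[c(a, b)] - 1L
      } else {
        stubs <- rep.int(seq_len(n), deficit)
        stubs <- stubs[sample.int(length(stubs))]
        a <- stubs[c(TRUE, FALSE)]
        b <- stubs[c(FALSE, TRUE)]
        keys <- pair_key(a, b)
        legal <- a != b & !is_taken(keys) & !duplicated(keys)
        failures <- failures + sum(!legal)
        if (any(legal)) {
          for (k in keys[legal]) assign(k, TRUE, envir = taken)
          new_a <- c(new_a, a[legal])
          new_b <- c(new_b, b[legal])
          used <- tabulate(c(a[legal], b[legal]), n)
          deficit <- deficit - used
        }
        if (failures > budget) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      g <- network$graph
      if (igraph::ecount(g) > 0L)
        g <- igraph::set_edge_attr(g, "kind", value = "kin")
      if (length(new_a))
        g <- igraph::add_edges(g, as.vector(rbind(new_a, new_b)),
                               kind = "friend")
      stopifnot(all(igraph::degree(g) == nu))
      return(structure(list(graph = g, agent_ids = network$agent_ids,
                            nu = as.integer(nu),
                            kin_keys = network$kin_keys),
                       class = "social_network"))
    }
  }
  stop_kinnet(
    sprintf("friend completion failed after %d restarts (residual deficit %d)",
            max_restarts, sum(deficit)),
    "kinnet_completion_error", deficit = deficit)
}

#' @export
print.social_network <- function(x, ...) {
  kind <- igraph::edge_attr(x$graph, "kind")
  cat(sprintf(
    "<social_network: %d agents, capacity %s, %d kin + %d friend edges>\n",
    length(x$agent_ids), ifelse(is.na(x$nu), "?", x$nu),
    sum(kind == "kin"), sum(kind == "friend")))
  invisible(x)
}

#' Classify a network's fertility regime
#'
#' Low fertility means the average number of relatives is at most one
#' third of the social capacity (`d(g) <= nu / 3`, the boundary counting
#' as low by convention); high fertility means more than one third.
#'
#' @param mean_kin_degree Non-negative mean kin degree d(g).
#' @param nu Positive social capacity.
#' @return `"low"` or `"high"` (vectorised over `mean_kin_degree`).
#' @examples
#' classify_fertility_regime(10, 60)  # "low"
#' classify_fertility_regime(44, 60)  # "high"
#' @export
classify_fertility_regime <- function(mean_kin_degree, nu) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop_kinnet("nu must be positive", "kinnet_invalid_argument")
  if (any(!is.numeric(mean_kin_degree)) || any(mean_kin_degree < 0))
    stop_kinnet("mean_kin_degree must be non-negative",
                "kinnet_invalid_argument")
  ifelse(mean_kin_degree <= nu / 3, "low", "high")
}
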