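# Structural summaries of social networks: local clustering, graph
# distance, and k-step neighbourhood sizes.

as_graph <- function(network) {
  if (inherits(network, c("social_network", "kin_network"))) network$graph
  else if (igraph::is_igraph(network)) network
  else stop_kinnet("expected a social_network, kin_network or igraph",
                   "kinnet_invalid_argument")
}

#' Local clustering coefficient
#'
#' Fraction of an agent's contact pairs that are themselves connected
#' (closed triads around the agent out of all possible ones). Agents with
#' fewer than two contacts — possible only in imported networks — get a
#' coefficient of 0 rather than an undefined value; a message notes how
#' many were affected.
#'
#' @param network A `social_network` (or `kin_network`/igraph).
#' @param nodes Optional vector of node indices; default all nodes.
#' @return Numeric vector of coefficients in `[0, 1]`.
#' @examples
#' toy <- make_fixture("high_fertility_toy")
#' local_clustering(toy, 1)  # 0.6: 6 of 10 contact pairs are closed
#' @export
local_clustering <- function(network, nodes = NULL) {
  g <- as_graph(network)
  vids <- if (is.null(nodes)) igraph::V(g) else nodes
  chi <- igraph::transitivity(g, type = "local", vids = vids,
                              isolates = "NaN")
  low_deg <- is.nan(chi)
  if (any(low_deg)) {
    message(sum(low_deg), " node(s) with degree < 2: clustering set to 0")
    chi[low_deg] <- 0
  }
  unname(chi)
}

#' Average local clustering coefficient
#'
#' Unweighted mean of the local clustering coefficients over all nodes.
#'
#' @param network A `social_network` (or `kin_network`/igraph).
#' @return A number in `[0, 1]`.
#' @export
mean_clustering <- function(network) {
  g <- as_graph(network)
  if (igraph::vcount(g) == 0L)
    stop_kinnet("empty network", "kinnet_invalid_argument")
  mean(suppressMessages(local_clustering(g)))
}

#' Average graph distance
#'
#' Mean shortest-path hop count over all ordered pairs of distinct nodes.
#' On a disconnected network the mean is taken over reachable pairs only
#' and a warning is emitted; simulated uniform-degree networks are
#' essentially always connected.
#'
#' @param network A `social_network` (or `kin_network`/igraph).
#' @return A positive number.
#' @export
mean_graph_distance <- function(network) {
  g <- as_graph(network)
  if (igraph::vcount(g) < 2L)
    stop_kinnet("need at least 2 nodes", "kinnet_invalid_argument")
  if (!igraph::is_connected(g))
    warning("network is disconnected; mean distance over reachable pairs")
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Mean k-step neighbourhood sizes
#'
#' For each hop distance d, the mean over all egos of the number of nodes
#' at exact shortest-path distance d. Entry 0 is always 1 (the ego);
#' entry 1 is the mean degree, equal to the capacity on a uniform-degree
#' network. When the network is connected the entries sum to the number
#' of nodes.
#'
#' @param network A `social_network` (or `kin_network`/igraph).
#' @param max_steps Largest distance reported (default 6).
#' @param ego Optional single node index: report that ego's exact counts
#'   instead of the mean over all egos.
#' @return Named numeric vector with entries `"0"` ... `"max_steps"`.
#' @examples
#' toy <- make_fixture("low_fertility_toy")
#' step_distance_counts(toy, max_steps = 3, ego = 1)  # 1, 5, 8, 6
#' @export
step_distance_counts <- function(network, max_steps = 6, ego = NULL) {
  g <- as_graph(network)
  n <- igraph::vcount(g)
  if (n == 0L)
    stop_kinnet("empty network", "kinnet_invalid_argument")
  if (!is.numeric(max_steps) || max_steps < 1)
    stop_kinnet("max_steps must be a positive integer",
                "kinnet_invalid_argument")
  if (!is.null(ego)) {
    d <- as.vector(igraph::distances(g, v = ego))
    per_ego <- tabulate(d[is.finite(d) & d > 0], nbins = max_steps)
  } else {
    tab <- igraph::distance_table(g, directed = FALSE)$res
    per_ego <- 2 * tab / n  # unordered pair counts -> mean per ego
  }
  out <- numeric(max_steps + 1L)
  out[1L] <- 1
  upto <- min(max_steps, length(per_ego))
  if (upto >= 1L) out[1L + seq_len(upto)] <- per_ego[seq_len(upto)]
  names(out) <- as.character(0:max_steps)
  out
}

#' Summarise the structure of a social network
#'
#' Bundles the per-node clustering coefficients, their mean, the mean
#' graph distance, the mean k-step neighbourhood sizes and a
#' connectedness flag into one object.
#'
#' @param network A `social_network` (or `kin_network`/igraph).
#' @param max_steps Largest distance in the step-count profile.
#' @return An object of class `network_summary` (a list).
#' @export
network_summary <- function(network, max_steps = 6) {
  g <- as_graph(network)
  chi <- suppressMessages(local_clustering(g))
  connected <- igraph::is_connected(g)
  delta <- suppressWarnings(mean_graph_distance(g))
  structure(list(per_node_clustering = chi,
                 mean_clustering = mean(chi),
                 mean_distance = delta,
                 step_counts = step_distance_counts(g, max_steps),
                 connected = connected),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary: chi = %.4f, delta = %.3f, %s>\n",
              x$mean_clustering, x$mean_distance,
              if (x$connected) "connected" else "disconnected"))
  cat("  mean nodes at distance d:\n")
  print(round(x$step_counts, 2))
  invisible(x)
}
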