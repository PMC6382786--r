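# Brute-force oracles and hand-built fixtures, independent of the package's
# implementation paths.

# Local clustering by triple loop over the dense adjacency matrix.
oracle_local_clustering <- function(graph) {
  a <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    d <- length(nb)
    if (d < 2) return(0)
    closed <- 0
    for (j in nb) for (k in nb) if (j < k && a[j, k] == 1) closed <- closed + 1
    closed / (d * (d - 1) / 2)
  }, numeric(1))
}

# All-pairs shortest-path hop counts by repeated BFS in plain R.
oracle_distances <- function(graph) {
  a <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(a)
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] == 1))))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    out[s, ] <- dist
  }
  out
}

# Count same-generation kin of each agent by direct pairwise ancestry
# intersection (no graph machinery).
oracle_kin_counts <- function(generation) {
  anc <- generation$ancestry
  n <- nrow(generation)
  vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) {
      i != j && length(intersect(anc[[i]], anc[[j]])) > 0
    }, logical(1)))
  }, integer(1))
}

# Cousin counts: share a grandparent but no parent.
oracle_cousin_counts <- function(generation) {
  anc <- generation$ancestry
  par <- mapply(function(m, f) c(m, f), generation$mother_id,
                generation$father_id, SIMPLIFY = FALSE)
  n <- nrow(generation)
  vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) {
      i != j &&
        length(intersect(anc[[i]], anc[[j]])) > 0 &&
        length(intersect(par[[i]], par[[j]])) == 0
    }, logical(1)))
  }, integer(1))
}

# Full reputation-matrix reference: the n x n belief matrix of which only
# the focal's column ever changes. Mirrors the synchronous update and the
# ascending-node RNG draw order of the package's gossip step.
matrix_gossip_round <- function(r, adj_mat, focal, alpha, variant) {
  n <- nrow(r)
  contacts <- which(adj_mat[focal, ] == 1)
  eligible <- switch(variant,
    shared_acquaintance = contacts[r[contacts, focal] == 0],
    noncontact = setdiff(which(r[, focal] == 0), c(focal, contacts)),
    broadcast = setdiff(which(r[, focal] == 0), focal))
  eligible <- sort(eligible)
  transmitters <- if (variant == "broadcast") which(r[, focal] == 1)
                  else contacts[r[contacts, focal] == 1]
  if (length(eligible)) {
    beta <- vapply(eligible, function(i)
      sum(adj_mat[i, transmitters]), numeric(1))
    p <- 1 - (1 - alpha)^beta
    flips <- stats::runif(length(eligible)) < p
    r[eligible[flips], focal] <- 1
  }
  r
}

# A generation of unrelated agents with a fixed gender split.
balanced_generation <- function(n_female, n_male) {
  n <- n_female + n_male
  generation(agent_id = seq_len(n),
             gender = rep(c(1L, 0L), c(n_female, n_male)),
             ancestry = rep(list(integer(0)), n),
             index = 0L)
}

# Hand-built 3-couple pedigree: couples A and B are sibships of a shared
# founder pair, couple C is unrelated; children of A and B are first
# cousins, children of C are kin to no one else.
three_couple_generation <- function() {
  # founders 1-2 (parents of 3 and 5), 7-8 (parents of 4), 9-10 (parents of 6)
  # couple A = (3, 4), couple B = (5, 6), couple C = (11, 12) founders
  anc <- list(
    c(1L, 2L, 7L, 8L, 3L, 4L),    # child of A
    c(1L, 2L, 7L, 8L, 3L, 4L),    # child of A (full sibling)
    c(1L, 2L, 9L, 10L, 5L, 6L),   # child of B (cousin of A's children)
    c(11L, 12L)                   # child of C (unrelated)
  )
  generation(agent_id = 101:104, gender = c(0L, 1L, 0L, 1L),
             mother_id = c(3L, 3L, 5L, 11L),
             father_id = c(4L, 4L, 6L, 12L),
             ancestry = anc, index = 2L)
}

# Wrap a bare igraph as a kin_network (for truncation edge cases).
as_kin_network <- function(graph) {
  n <- igraph::vcount(graph)
  graph <- igraph::set_vertex_attr(graph, "name", value = as.character(seq_len(n)))
  ends <- igraph::as_edgelist(graph, names = FALSE)
  structure(list(graph = graph, agent_ids = seq_len(n),
                 kin_keys = if (nrow(ends)) paste(pmin(ends[, 1], ends[, 2]),
                                                  pmax(ends[, 1], ends[, 2]))
                            else character(0)),
            class = "kin_network")
}
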