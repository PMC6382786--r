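#' Deterministic test fixtures
#'
#' Small, fully deterministic inputs used in worked examples and tests.
#'
#' * `"high_fertility_toy"`: five mutually connected circle agents plus one
#'   distinct pendant contact each (10 nodes). Every circle agent has
#'   degree 5 and local clustering 0.6 (6 of its 10 contact pairs are
#'   closed) — a stylised high-fertility ego network.
#' * `"low_fertility_toy"`: a 5-cycle of circle agents plus three distinct
#'   pendants each (20 nodes). Every circle agent has degree 5 and local
#'   clustering 0 — the stylised low-fertility counterpart.
#' * `"deterministic_pedigree"`: a three-generation pedigree in which
#'   every couple has exactly `k` children and all spouses are unrelated,
#'   returned as the final generation. It is built on a ring of founder
#'   couples wide enough that maternal and paternal cousin sets never
#'   overlap, so every member has exactly `k - 1` siblings and
#'   `2 k (k - 1)` first cousins — the closed form of
#'   [expected_kin_count()] holds exactly for every agent.
#' * `"ring"`, `"complete"`, `"star"`: the elementary graphs on `n`
#'   nodes.
#'
#' @param name Fixture name (see above).
#' @param k Children per couple for `"deterministic_pedigree"`.
#' @param n Node count for `"ring"`, `"complete"`, `"star"`.
#' @return A `generation` for `"deterministic_pedigree"`, otherwise a
#'   `social_network` (capacity `NA`; edges flagged `"friend"`).
#' @examples
#' ped <- make_fixture("deterministic_pedigree", k = 5)
#' mean_kin_degree(build_kin_adjacency(ped))  # exactly 44
#' @export
make_fixture <- function(name, k = 5, n = 10) {
  switch(name,
    high_fertility_toy = {
      g <- igraph::make_full_graph(5)
      g <- igraph::add_vertices(g, 5)
      g <- igraph::add_edges(g, as.vector(rbind(1:5, 6:10)))
      toy_network(g)
    },
    low_fertility_toy = {
      g <- igraph::make_ring(5)
      g <- igraph::add_vertices(g, 15)
      pendants <- 5L + seq_len(15L)
      g <- igraph::add_edges(g, as.vector(rbind(rep(1:5, each = 3),
                                                pendants)))
      toy_network(g)
    },
    deterministic_pedigree = deterministic_pedigree(k),
    ring = toy_network(igraph::make_ring(n)),
    complete = toy_network(igraph::make_full_graph(n)),
    star = toy_network(igraph::make_star(n, mode = "undirected",
                                         center = 1)),
    stop_kinnet(sprintf("unknown fixture '%s'", name),
                "kinnet_invalid_argument"))
}

toy_network <- function(g) {
  g <- igraph::set_vertex_attr(g, "name",
                               value = as.character(seq_len(igraph::vcount(g))))
  if (igraph::ecount(g) > 0L)
    g <- igraph::set_edge_attr(g, "kind", value = "friend")
  deg <- igraph::degree(g)
  structure(list(graph = g, agent_ids = seq_len(igraph::vcount(g)),
                 nu = if (length(unique(deg)) == 1L) unique(deg)
                      else NA_integer_,
                 kin_keys = character(0)),
            class = "social_network")
}

# Ring construction: m = 2k + 1 "maternal" founder couples whose children
# are all daughters and m "paternal" founder couples whose children are
# all sons. Daughter j of maternal couple i marries son j of paternal
# couple (i + j) mod m, which guarantees that the husbands of sisters all
# come from different paternal families (and symmetrically), so cousin
# sets through the two parents are disjoint.
deterministic_pedigree <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop_kinnet("k must be a single integer >= 1", "kinnet_invalid_argument")
  k <- as.integer(k)
  m <- 2L * k + 1L
  # founder ids: maternal couples (mother, father), then paternal couples
  ef <- seq_len(m)                 # maternal-side grandmothers
  em <- m + seq_len(m)             # maternal-side grandfathers
  of <- 2L * m + seq_len(m)        # paternal-side grandmothers
  om <- 3L * m + seq_len(m)        # paternal-side grandfathers
  # generation 1: k daughters per maternal couple, k sons per paternal
  d_id <- function(i, j) 4L * m + (i - 1L) * k + j
  s_id <- function(l, j) 4L * m + m * k + (l - 1L) * k + j
  next_id <- 4L * m + 2L * m * k

  ids <- integer(0); gender <- integer(0)
  mother <- integer(0); father <- integer(0); anc <- list()
  for (i in seq_len(m)) for (j in seq_len(k)) {
    l <- ((i - 1L + j) %% m) + 1L  # paternal family the couple marries into
    d <- d_id(i, j); s <- s_id(l, j)
    child_anc <- c(ef[i], em[i], of[l], om[l], d, s)
    for (c in seq_len(k)) {
      ids <- c(ids, next_id + 1L); next_id <- next_id + 1L
      gender <- c(gender, (c - 1L) %% 2L)
      mother <- c(mother, d); father <- c(father, s)
      anc <- c(anc, list(child_anc))
    }
  }
  generation(agent_id = ids, gender = gender, mother_id = mother,
             father_id = father, ancestry = anc, index = 2L)
}
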