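# Flat-file interchange: PED-like pedigree tables and edge-list / GraphML
# networks.

#' Write a pedigree as a PED-like table
#'
#' Tab-separated, one row per agent with columns `agent_id`,
#' `generation`, `sex`, `mother_id`, `father_id` (empty for unknown
#' parents). If the generation carries its simulation `history` attribute
#' (as returned by [simulate_pedigree()]), every generation is written so
#' that grandparents can be reconstructed on re-import; a bare generation
#' writes only its own rows. A list of generations is also accepted.
#'
#' @param x A `generation` or a list of `generation` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(x, path) {
  gens <- if (inherits(x, "generation")) {
    h <- attr(x, "history")
    if (is.null(h)) list(x) else c(h[-length(h)], list(x))
  } else x
  stopifnot(all(vapply(gens, inherits, logical(1L), "generation")))
  rows <- do.call(rbind, lapply(gens, function(g) {
    data.frame(agent_id = g$agent_id,
               generation = generation_index(g),
               sex = g$gender,
               mother_id = g$mother_id,
               father_id = g$father_id)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a PED-like pedigree table
#'
#' Reads a table written by [write_pedigree()] and rebuilds one
#' `generation` object per generation index, reconstructing each agent's
#' ancestry (parents plus grandparents) by joining on the parent columns.
#' Grandparents of agents whose parents are absent from the table cannot
#' be recovered and are left out of the ancestry set.
#'
#' @param path Input file path.
#' @return A list of `generation` objects, ordered by generation index.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.delim(path, na.strings = c("", "NA"))
  need <- c("agent_id", "generation", "sex", "mother_id", "father_id")
  if (!all(need %in% names(tab)))
    stop_kinnet("pedigree table must have columns agent_id, generation, sex, mother_id, father_id",
                "kinnet_invalid_argument")
  row_of <- function(id) match(id, tab$agent_id)
  parents_of <- function(i) {
    p <- c(tab$mother_id[i], tab$father_id[i])
    as.integer(p[!is.na(p)])
  }
  lapply(sort(unique(tab$generation)), function(s) {
    idx <- which(tab$generation == s)
    anc <- lapply(idx, function(i) {
      par <- parents_of(i)
      gp <- unlist(lapply(row_of(par), function(j)
        if (is.na(j)) integer(0) else parents_of(j)))
      unique(as.integer(c(gp, par)))
    })
    generation(agent_id = tab$agent_id[idx], gender = tab$sex[idx],
               mother_id = tab$mother_id[idx],
               father_id = tab$father_id[idx],
               ancestry = anc, index = s)
  })
}

#' Write a social network to disk
#'
#' Either a tab-separated edge list with columns `source`, `target`,
#' `kind` (`kin` or `friend`), or GraphML with the same edge attribute
#' (format inferred from the file extension unless given).
#'
#' @param network A `social_network` (or `kin_network`, whose edges are
#'   all written as `kin`).
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`; default by extension
#'   (`.graphml` vs anything else).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = NULL) {
  g <- as_graph(network)
  if (igraph::ecount(g) > 0L && is.null(igraph::edge_attr(g, "kind")))
    g <- igraph::set_edge_attr(g, "kind", value = "kin")
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ends <- igraph::as_edgelist(g, names = TRUE)
    tab <- data.frame(source = ends[, 1L], target = ends[, 2L],
                      kind = if (igraph::ecount(g))
                        igraph::edge_attr(g, "kind") else character(0))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a social network from disk
#'
#' Accepts the edge-list TSV and GraphML formats written by
#' [write_network()]. The capacity slot is set to the common degree when
#' the imported network is regular, `NA` otherwise; kin pair keys are
#' rebuilt from the `kin`-flagged edges.
#'
#' @param path Input file path.
#' @param format `"edgelist"` or `"graphml"`; default by extension.
#' @return A `social_network`.
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
  } else {
    tab <- utils::read.delim(path,
                             colClasses = c("character", "character",
                                            "character"))
    if (!all(c("source", "target", "kind") %in% names(tab)))
      stop_kinnet("edge list must have columns source, target, kind",
                  "kinnet_invalid_argument")
    verts <- unique(c(tab$source, tab$target))
    g <- igraph::graph_from_data_frame(tab, directed = FALSE,
                                       vertices = verts)
  }
  ids <- suppressWarnings(as.integer(igraph::V(g)$name))
  if (any(is.na(ids))) ids <- seq_len(igraph::vcount(g))
  deg <- igraph::degree(g)
  kind <- igraph::edge_attr(g, "kind")
  kin_keys <- if (!is.null(kind) && any(kind == "kin")) {
    ends <- igraph::ends(g, igraph::E(g)[kind == "kin"], names = FALSE)
    pair_key(ends[, 1L], ends[, 2L])
  } else character(0)
  structure(list(graph = g, agent_ids = ids,
                 nu = if (length(unique(deg)) == 1L)
                   as.integer(unique(deg)) else NA_integer_,
                 kin_keys = kin_keys),
            class = "social_network")
}
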