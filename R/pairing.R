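#' Form monogamous mate pairs among unrelated agents
#'
#' Pairs opposite-gender agents of one generation whose ancestry sets are
#' disjoint (no shared parent or grandparent, i.e. incest exclusion up to
#' first cousin). The matching is greedy: both genders are shuffled
#' uniformly, then each female is matched to the first still-unmatched
#' male she is unrelated to. Each agent appears in at most one pair;
#' surplus agents of the more numerous gender (or agents related to every
#' available partner) remain unmatched and childless.
#'
#' @param generation A non-empty `generation`.
#' @return An object of class `mate_pairing`: a data frame with columns
#'   `female_id`, `male_id`, plus a `generation_index` attribute.
#' @examples
#' g <- generation(1:4, gender = c(1L, 1L, 0L, 0L))
#' set.seed(1)
#' form_pairs(g)
#' @export
form_pairs <- function(generation) {
  if (!inherits(generation, "generation"))
    stop_kinnet("expected a generation object", "kinnet_invalid_argument")
  if (nrow(generation) == 0L)
    stop_kinnet("generation is empty", "kinnet_invalid_argument")

  fem <- which(generation$gender == 1L)
  mal <- which(generation$gender == 0L)
  if (length(fem) == 0L || length(mal) == 0L) {
    return(new_mate_pairing(integer(0), integer(0),
                            generation_index(generation)))
  }
  fem <- fem[sample.int(length(fem))]
  mal <- mal[sample.int(length(mal))]

  # ancestor -> male row indices, to find each female's related males fast
  anc_m <- generation$ancestry[mal]
  amap <- split(rep.int(mal, lengths(anc_m)), unlist(anc_m))

  avail <- mal  # in shuffled order
  f_out <- integer(0)
  m_out <- integer(0)
  for (f in fem) {
    if (length(avail) == 0L) break
    anc_f <- generation$ancestry[[f]]
    related <- if (length(anc_f))
      unique(unlist(amap[as.character(anc_f)], use.names = FALSE))
    else integer(0)
    cand <- if (length(related)) avail[!(avail %in% related)] else avail
    if (length(cand) == 0L) next
    m <- cand[1L]
    avail <- avail[avail != m]
    f_out <- c(f_out, f)
    m_out <- c(m_out, m)
  }
  new_mate_pairing(generation$agent_id[f_out], generation$agent_id[m_out],
                  generation_index(generation))
}

new_mate_pairing <- function(female_id, male_id, index) {
  out <- data.frame(female_id = as.integer(female_id),
                    male_id = as.integer(male_id))
  attr(out, "generation_index") <- as.integer(index)
  class(out) <- c("mate_pairing", "data.frame")
  out
}

#' @export
print.mate_pairing <- function(x, ...) {
  cat(sprintf("<mate_pairing: %d pairs in generation %d>\n", nrow(x),
              attr(x, "generation_index")))
  invisible(x)
}

#' Draw the next generation from mated pairs
#'
#' Each pair's number of children is an independent Poisson draw with mean
#' `kappa` (the total fertility rate); child genders are independent
#' uniform 0/1. A child's ancestry set contains both parents plus the
#' parents' own parents where known, so generation-1 children carry two
#' ids and later generations carry six. Over a generation with `n` agents
#' and close to `n/2` pairs, the expected number of births is
#' approximately `kappa * n / 2`.
#'
#' @param pairing A `mate_pairing` over `parents`.
#' @param parents The `generation` the pairs were formed in.
#' @param kappa Positive mean fertility per pair.
#' @return A `generation` with index one above the parents'.
#' @export
reproduce <- function(pairing, parents, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop_kinnet("kappa must be a single positive number",
                "kinnet_invalid_argument")
  if (!all(c(pairing$female_id, pairing$male_id) %in% parents$agent_id))
    stop_kinnet("pairing refers to agents outside the parent generation",
                "kinnet_invalid_argument")
  idx_next <- generation_index(parents) + 1L
  npair <- nrow(pairing)
  if (npair == 0L) {
    return(generation(integer(0), integer(0),
                      ancestry = list(), index = idx_next))
  }
  row_of <- match(c(pairing$female_id, pairing$male_id), parents$agent_id)
  frow <- row_of[seq_len(npair)]
  mrow <- row_of[npair + seq_len(npair)]

  kids <- stats::rpois(npair, kappa)
  total <- sum(kids)
  if (total == 0L) {
    return(generation(integer(0), integer(0),
                      ancestry = list(), index = idx_next))
  }
  # per-pair child ancestry: both parents plus the known grandparents
  anc_pair <- lapply(seq_len(npair), function(p) {
    gp <- c(parents$mother_id[frow[p]], parents$father_id[frow[p]],
            parents$mother_id[mrow[p]], parents$father_id[mrow[p]])
    as.integer(c(gp[!is.na(gp)], pairing$female_id[p], pairing$male_id[p]))
  })
  which_pair <- rep.int(seq_len(npair), kids)
  start_id <- max(parents$agent_id) + 1L
  generation(agent_id = start_id + seq_len(total) - 1L,
             gender = sample(c(0L, 1L), total, replace = TRUE),
             mother_id = pairing$female_id[which_pair],
             father_id = pairing$male_id[which_pair],
             ancestry = anc_pair[which_pair],
             index = idx_next)
}
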