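make_state <- function(n, focal, observer) {
  beliefs <- logical(n)
  beliefs[observer] <- TRUE
  structure(list(round = 1L, focal = focal, observer = observer,
                 beliefs = beliefs),
            class = "reputation_state")
}

test_that("seeding marks exactly one uniformly chosen observation", {
  gen <- simulate_pedigree(kappa = 5, n_target = 100, n_founders = 60,
                           seed = 31)
  sn <- add_random_friends(truncate_kin_degree(build_kin_adjacency(gen), 60),
                           60)
  st <- seed_observation(sn, seed = 1)
  expect_equal(sum(st$beliefs), 1)
  expect_true(st$beliefs[st$observer])
  expect_equal(st$round, 1L)
  expect_true(st$observer %in%
                as.integer(igraph::neighbors(sn$graph, st$focal)))

  # two-node network: the observer is forced
  pair <- make_fixture("complete", n = 2)
  st2 <- seed_observation(pair, seed = 2)
  expect_equal(sort(c(st2$focal, st2$observer)), 1:2)

  # the focal draw is uniform over agents
  toy <- make_fixture("ring", n = 20)
  set.seed(33)
  focals <- replicate(2000, seed_observation(toy)$focal)
  expect_gt(stats::chisq.test(table(factor(focals, levels = 1:20)))$p.value,
            0.001)
})

test_that("gossip flip probabilities follow 1 - (1 - alpha)^beta", {
  # triangle {focal, observer, third}: third has beta = 1, so the flip
  # round is geometric with mean 1/alpha
  tri <- make_fixture("complete", n = 3)
  set.seed(41)
  rounds <- replicate(4000, {
    st <- make_state(3, focal = 1, observer = 2)
    r <- 0
    while (!st$beliefs[3] && r < 300) {
      st <- gossip_round(st, tri, alpha = 0.1)
      r <- r + 1
    }
    r
  })
  se <- stats::sd(rounds) / sqrt(length(rounds))
  expect_lt(abs(mean(rounds) - 10), 3 * se)

  # 4-clique with two informed contacts: beta = 2, one-round flip
  # probability 1 - 0.9^2 = 0.19
  quad <- make_fixture("complete", n = 4)
  set.seed(42)
  flips <- replicate(4000, {
    st <- make_state(4, focal = 1, observer = 2)
    st$beliefs[3] <- TRUE
    gossip_round(st, quad, alpha = 0.1)$beliefs[4]
  })
  expect_lt(abs(mean(flips) - 0.19), 3 * sqrt(0.19 * 0.81 / 4000))

  # beta = 0 and alpha = 0 never flip
  st <- make_state(4, focal = 1, observer = 2)
  expect_identical(gossip_round(st, quad, alpha = 0)$beliefs, st$beliefs)
  star <- make_fixture("star", n = 6)
  st_star <- make_state(6, focal = 1, observer = 2)
  set.seed(43)
  for (i in 1:20) st_star <- gossip_round(st_star, star, alpha = 0.9)
  expect_equal(sum(st_star$beliefs), 1)  # leaves share no informed contact

  expect_error(gossip_round(st, quad, alpha = 1.5),
               class = "kinnet_invalid_argument")
})

test_that("forgiving independently resets bad beliefs", {
  quad <- make_fixture("complete", n = 4)
  st <- make_state(4, focal = 1, observer = 2)
  st$beliefs[3:4] <- TRUE
  expect_identical(forgiving_step(st, 0)$beliefs, st$beliefs)
  expect_false(any(forgiving_step(st, 1)$beliefs))
  expect_error(forgiving_step(st, -0.1), class = "kinnet_invalid_argument")

  one <- make_state(4, focal = 1, observer = 2)
  set.seed(51)
  gone <- replicate(4000, !any(forgiving_step(one, 0.5)$beliefs))
  expect_lt(abs(mean(gone) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("the single-column state matches the full reputation-matrix dynamics", {
  set.seed(61)
  g <- igraph::sample_gnp(12, 0.4)
  net <- structure(list(graph = g, agent_ids = 1:12, nu = NA_integer_,
                        kin_keys = character(0)),
                   class = "social_network")
  adj_mat <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- igraph::degree(g)
  focal <- which(deg >= 2)[1]
  observer <- as.integer(igraph::neighbors(g, focal))[1]
  for (variant in c("shared_acquaintance", "noncontact", "broadcast")) {
    st <- make_state(12, focal, observer)
    r <- matrix(0L, 12, 12)
    r[observer, focal] <- 1L
    for (round in 1:6) {
      set.seed(700 + round)
      st <- gossip_round(st, net, alpha = 0.3, variant = variant)
      set.seed(700 + round)
      r <- matrix_gossip_round(r, adj_mat, focal, alpha = 0.3,
                               variant = variant)
    }
    expect_identical(which(st$beliefs), which(r[, focal] == 1),
                     label = variant)
    # only the focal's column ever evolves
    expect_true(all(r[, -focal] == 0))
  }
})

test_that("trajectories are monotone without forgiving and absorb with it", {
  gen <- simulate_pedigree(kappa = 5, n_target = 150, n_founders = 80,
                           seed = 71)
  sn <- add_random_friends(truncate_kin_degree(build_kin_adjacency(gen), 60),
                           60)
  tr <- run_reputation(sn, alpha = 0.1, pi = NULL, max_rounds = 60,
                       seed = 72)
  expect_true(all(diff(tr$counts$informed_total) >= 0))
  expect_true(all(tr$counts$informed_contacts <= tr$n_contacts))
  expect_true(all(tr$counts$informed_total <= 149))
  expect_true(is.na(tr$extinction_round))

  # alpha = 0: flat at the single seeded belief
  tr0 <- run_reputation(sn, alpha = 0, pi = NULL, max_rounds = 15, seed = 73)
  expect_true(all(tr0$counts$informed_total == 1))

  # pi = 1 extinguishes in the first forgiving sweep
  tr1 <- run_reputation(sn, alpha = 0.1, pi = 1, max_rounds = 30, seed = 74)
  expect_equal(tr1$extinction_round, 2L)
  expect_equal(tr1$counts$informed_total[nrow(tr1$counts)], 0)

  expect_error(run_reputation(sn, alpha = 0.1, max_rounds = 0),
               class = "kinnet_invalid_argument")
})
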