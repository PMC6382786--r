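test_that("founders are unrelated, uniquely numbered, and gender-balanced on average", {
  set.seed(11)
  g <- found_population(100)
  expect_s3_class(g, "generation")
  expect_equal(nrow(g), 100)
  expect_equal(generation_index(g), 0L)
  expect_false(anyDuplicated(g$agent_id) > 0)
  expect_true(all(lengths(g$ancestry) == 0))

  g2 <- found_population(2)
  expect_equal(nrow(g2), 2)

  expect_error(found_population(1), class = "kinnet_invalid_argument")
  expect_error(found_population(-5), class = "kinnet_invalid_argument")

  # binomial(100, 1/2): mean female count over 1000 runs within 3 SE
  set.seed(12)
  fem <- replicate(1000, sum(found_population(100)$gender == 1L))
  expect_lt(abs(mean(fem) - 50), 3 * 5 / sqrt(1000))
})

test_that("pair formation is monogamous, heterosexual and incest-excluding", {
  # one founder couple pairs
  g <- balanced_generation(1, 1)
  set.seed(1)
  expect_equal(nrow(form_pairs(g)), 1)

  # a shared grandparent id forbids the pair
  rel <- generation(agent_id = 1:2, gender = c(1L, 0L),
                    mother_id = c(10L, 12L), father_id = c(11L, 13L),
                    ancestry = list(c(5L, 6L, 7L, 8L, 10L, 11L),
                                    c(5L, 6L, 9L, 14L, 12L, 13L)))
  expect_equal(nrow(form_pairs(rel)), 0)

  # monogamy: 3 females + 1 male -> exactly one pair
  g31 <- balanced_generation(3, 1)
  set.seed(2)
  p <- form_pairs(g31)
  expect_equal(nrow(p), 1)

  # property: over simulated generations, no pair shares an ancestor
  set.seed(3)
  for (rep in 1:5) {
    sim <- simulate_pedigree(kappa = 4, n_target = 150, n_founders = 50)
    p <- form_pairs(sim)
    expect_gt(nrow(p), 0)
    anc <- sim$ancestry
    idx <- match(c(p$female_id, p$male_id), sim$agent_id)
    fa <- anc[idx[seq_len(nrow(p))]]
    ma <- anc[idx[nrow(p) + seq_len(nrow(p))]]
    overlap <- mapply(function(a, b) length(intersect(a, b)) > 0, fa, ma)
    expect_false(any(overlap))
    sex <- sim$gender[idx]
    expect_true(all(sex[seq_len(nrow(p))] == 1L))
    expect_true(all(sex[nrow(p) + seq_len(nrow(p))] == 0L))
  }
})

test_that("children carry both parents and the known grandparents", {
  gen1 <- generation(agent_id = 1:4, gender = c(1L, 0L, 1L, 0L),
                     mother_id = c(90L, 92L, 94L, 96L),
                     father_id = c(91L, 93L, 95L, 97L),
                     index = 1L)
  pairing <- form_pairs(gen1)
  set.seed(4)
  kids <- reproduce(pairing, gen1, kappa = 5)
  expect_gt(nrow(kids), 0)
  expect_equal(generation_index(kids), 2L)
  expect_true(all(lengths(kids$ancestry) == 6))
  for (i in seq_len(nrow(kids))) {
    expect_true(all(c(kids$mother_id[i], kids$father_id[i]) %in%
                      kids$ancestry[[i]]))
    mrow <- match(kids$mother_id[i], gen1$agent_id)
    expect_true(all(c(gen1$mother_id[mrow], gen1$father_id[mrow]) %in%
                      kids$ancestry[[i]]))
  }
  expect_error(reproduce(pairing, gen1, kappa = 0),
               class = "kinnet_invalid_argument")

  # vanishing fertility: an empty next generation, not an error
  set.seed(5)
  none <- reproduce(pairing, gen1, kappa = 1e-9)
  expect_equal(nrow(none), 0)
  expect_equal(generation_index(none), 2L)
})

test_that("expected births match kappa * n / 2 for fully paired generations", {
  g <- balanced_generation(50, 50)
  for (kappa in c(2.5, 5)) {
    set.seed(round(60 + 10 * kappa))
    births <- replicate(200, {
      p <- form_pairs(g)
      nrow(reproduce(p, g, kappa))
    })
    se <- stats::sd(births) / sqrt(length(births))
    expect_lt(abs(mean(births) - kappa * 50), 3 * se)
  }
})

test_that("offspring gender is uniform", {
  g <- balanced_generation(5000, 5000)
  set.seed(7)
  p <- form_pairs(g)
  kids <- reproduce(p, g, kappa = 2.5)
  n <- nrow(kids)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(kids$gender) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("closed-form kin counts match brute force on deterministic pedigrees", {
  expect_equal(expected_kin_count(5), c(siblings = 4L, cousins = 40L,
                                        total = 44L))
  expect_equal(expected_kin_count(2), c(siblings = 1L, cousins = 4L,
                                        total = 5L))
  expect_equal(expected_kin_count(1), c(siblings = 0L, cousins = 0L,
                                        total = 0L))
  expect_error(expected_kin_count(0), class = "kinnet_invalid_argument")

  for (k in 1:6) {
    ped <- make_fixture("deterministic_pedigree", k = k)
    kin <- oracle_kin_counts(ped)
    expect_true(all(kin == expected_kin_count(k)[["total"]]))
    cous <- oracle_cousin_counts(ped)
    expect_true(all(cous == expected_kin_count(k)[["cousins"]]))
  }
})

test_that("pedigree simulation reaches the target exactly and reproducibly", {
  g <- simulate_pedigree(kappa = 5, n_target = 500, n_founders = 100,
                         seed = 21)
  expect_equal(nrow(g), 500)

  g2 <- simulate_pedigree(kappa = 5, n_target = 500, n_founders = 100,
                          seed = 21)
  expect_identical(g$agent_id, g2$agent_id)
  expect_identical(g$ancestry, g2$ancestry)
  expect_identical(g$gender, g2$gender)

  # high fertility: growth factor ~ kappa/2 reaches 500 from 100 founders
  # within two generations
  g10 <- simulate_pedigree(kappa = 10, n_target = 500, n_founders = 100,
                           seed = 22)
  expect_lte(attr(g10, "n_generations"), 2)
})

test_that("trimming keeps a random subset of exactly the target size", {
  set.seed(30)
  g <- simulate_pedigree(kappa = 5, n_target = 300, n_founders = 100)
  full <- attr(g, "history")[[length(attr(g, "history"))]]
  expect_gte(nrow(full), 300)

  t1 <- trim_to_target(full, 250, seed = 1)
  expect_equal(nrow(t1), 250)
  expect_true(all(t1$agent_id %in% full$agent_id))
  t2 <- trim_to_target(full, 250, seed = 2)
  expect_equal(nrow(t2), 250)
  expect_false(identical(t1$agent_id, t2$agent_id))

  same <- trim_to_target(t1, 250)
  expect_identical(same$agent_id, t1$agent_id)
  expect_error(trim_to_target(t1, 251), class = "kinnet_invalid_argument")
})

test_that("collapse and non-convergence raise typed errors", {
  expect_error(simulate_pedigree(kappa = 0.1, n_target = 500,
                                 n_founders = 10, seed = 40),
               class = "kinnet_extinction_error")
  expect_error(simulate_pedigree(kappa = 2.5, n_target = 1e5,
                                 n_founders = 50, max_generations = 2,
                                 seed = 41),
               class = "kinnet_convergence_error")
})
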