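test_that("fitness map hits the published endpoints and is monotone", {
  expect_equal(abc_fitness(0), 1)
  expect_equal(abc_fitness(0.5), 1.5)
  # negative objective exercises the other branch of the two-branch map
  expect_equal(abc_fitness(-1), 0.5)
  ox <- sort(runif(20, -2, 2))
  expect_true(all(diff(abc_fitness(ox)) > 0))
})

test_that("neighbour candidate perturbs exactly one component and clips", {
  b <- default_bounds()
  members <- rbind(c(1.0, 0.2, 0.4, 1.0),
                   c(0.6, 0.1, 0.2, 0.8))
  cand <- neighbor_candidate(members, 1, b$lb, b$ub,
                             d = 1, partner = 2, phi = 0.5)
  expect_equal(unname(cand), c(1.2, 0.2, 0.4, 1.0))  # 1 + 0.5*(1-0.6)
  # phi = 0 is the identity
  expect_equal(neighbor_candidate(members, 1, b$lb, b$ub,
                                  d = 3, partner = 2, phi = 0),
               members[1, ])
  # identical sources: difference vanishes for any phi
  same <- rbind(c(0.5, 0.2, 0.3, 1), c(0.5, 0.2, 0.3, 1))
  expect_equal(neighbor_candidate(same, 1, b$lb, b$ub,
                                  d = 2, partner = 2, phi = 0.9),
               same[1, ])
  # perturbation beyond a bound is clipped
  big <- rbind(c(1.5, 0.2, 0.4, 1.0), c(0.1, 0.1, 0.2, 0.8))
  c2 <- neighbor_candidate(big, 1, b$lb, b$ub, d = 1, partner = 2, phi = 1)
  expect_equal(unname(c2[1]), 1.6)
})

test_that("onlooker probabilities follow the 0.9 fit/max + 0.1 rule", {
  fit <- c(4, 2, 0)
  expect_equal(onlooker_probabilities(fit), c(1.0, 0.55, 0.1))
  expect_equal(onlooker_probabilities(rep(0, 3)), rep(0.1, 3))
})

test_that("employed phase bookkeeping: trials reset on success, increment on failure", {
  set.seed(17)
  xi <- tiny_fixture_xi(9)
  ev <- make_evaluator(xi)
  b <- default_bounds()
  init <- init_population(6, b$lb, b$ub)
  colony <- new_colony(init, ev)
  old_fit <- colony$fitness
  old_members <- colony$members
  after <- employed_phase(colony, ev, b$lb, b$ub)
  for (j in 1:6) {
    if (after$trials[j] == 0L) {
      expect_gte(after$fitness[j], old_fit[j])        # replaced by >= candidate
    } else {
      expect_equal(after$trials[j], 1L)               # one failure recorded
      expect_equal(after$members[j, ], old_members[j, ])
    }
  }
  expect_true(all(after$fitness >= old_fit))          # greedy consequence
  expect_gte(after$best$ox, colony$best$ox)
})

test_that("tie in fitness replaces the source and resets its trial counter", {
  b <- default_bounds()
  members <- rbind(c(0.8, 0.2, 0.4, 1.0), c(0.6, 0.1, 0.2, 0.8))
  flat_ev <- function(p) 0.25          # every candidate ties every source
  colony <- new_colony(members, flat_ev)
  colony$trials <- c(3L, 5L)
  set.seed(4)
  after <- employed_phase(colony, flat_ev, b$lb, b$ub)
  expect_equal(after$trials, c(0L, 0L))
})

test_that("failing neighbours only increment trials and leave sources alone", {
  b <- default_bounds()
  members <- rbind(c(0.8, 0.2, 0.4, 1.0), c(0.6, 0.1, 0.2, 0.8))
  # sources score high; every new candidate scores lower -> all fail
  source_keys <- apply(members, 1, paste, collapse = ",")
  ev <- function(p) if (paste(p, collapse = ",") %in% source_keys) 1 else 0
  colony <- new_colony(members, ev)
  set.seed(6)
  after <- employed_phase(colony, ev, b$lb, b$ub)
  expect_equal(after$trials, c(1L, 1L))
  expect_identical(after$members, members)
  expect_equal(after$best$ox, 1)
})

test_that("scout phase replaces only the exhausted source, keeping the memorised best", {
  set.seed(23)
  b <- default_bounds()
  xi <- tiny_fixture_xi(10)
  ev <- make_evaluator(xi)
  colony <- new_colony(init_population(3, b$lb, b$ub), ev)

  colony$trials <- c(5L, 130L, 7L)
  best_before <- colony$best
  sc <- scout_phase(colony, limit = 120, b$lb, b$ub, ev)
  expect_equal(sc$replaced, 2L)
  expect_equal(sc$colony$trials, c(5L, 0L, 7L))
  expect_gte(sc$colony$best$ox, best_before$ox)

  # under the limit: untouched
  colony$trials <- c(5L, 120L, 7L)
  sc2 <- scout_phase(colony, limit = 120, b$lb, b$ub, ev)
  expect_true(is.na(sc2$replaced))
  expect_identical(sc2$colony$members, colony$members)

  # ties break to the lowest index
  colony$trials <- c(130L, 130L, 7L)
  sc3 <- scout_phase(colony, limit = 120, b$lb, b$ub, ev)
  expect_equal(sc3$replaced, 1L)
})

test_that("run_abc: zero iterations preserve the seeded best; trace never decreases", {
  xi <- tiny_fixture_xi(12)
  ev <- make_evaluator(xi)
  set.seed(3)
  init <- init_population(6, default_bounds()$lb, default_bounds()$ub)
  scores <- apply(init, 1, ev)

  abc0 <- run_abc(init = init, cfg = abc_config(iters = 0), evaluator = ev)
  expect_equal(abc0$best_ox, max(scores))

  abc <- run_abc(init = init, cfg = abc_config(iters = 8, seed = 41),
                 evaluator = ev)
  expect_true(all(diff(abc$trace$best_score) >= 0))
  expect_gte(abc$best_ox, max(scores))
  b <- default_bounds()
  expect_true(all(sweep(abc$colony$members, 2, b$lb, `>=`) &
                  sweep(abc$colony$members, 2, b$ub, `<=`)))
})

test_that("run_abc is reproducible under a fixed seed", {
  xi <- tiny_fixture_xi(14)
  set.seed(1); init <- init_population(5, default_bounds()$lb, default_bounds()$ub)
  a1 <- run_abc(xi, init = init, cfg = abc_config(iters = 5, seed = 55))
  a2 <- run_abc(xi, init = init, cfg = abc_config(iters = 5, seed = 55))
  expect_identical(a1$best_params, a2$best_params)
  expect_identical(a1$colony$members, a2$colony$members)
})

test_that("ABC recovers the DE-level optimum from a perturbed population", {
  # unimodal-ish small blurred-disc image; perturb the DE population away
  # from its optimum and check ABC climbs back in most seeds
  fx <- make_lesion_image(lesion_spec(rows = 24, cols = 24, noise_sd = 0,
                                      gradient_amplitude = 0, seed = 2))
  xi <- rgb_to_hsi(fx$image)$intensity
  ev <- make_evaluator(xi)
  set.seed(100)
  de <- run_de(cfg = de_config(np = 10, iters = 4), evaluator = ev)
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    b <- default_bounds()
    perturbed <- de$members + matrix(rnorm(40, 0, 0.1), 10, 4)
    perturbed <- t(apply(perturbed, 1, clip_bounds, lb = b$lb, ub = b$ub))
    abc <- run_abc(init = perturbed, cfg = abc_config(iters = 40), evaluator = ev)
    if (abc$best_ox >= de$best_score) wins <- wins + 1L
  }
  expect_gte(wins, 18L)  # >= 90% of seeds
})
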