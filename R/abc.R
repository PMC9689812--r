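#' Artificial Bee Colony configuration
#'
#' @param iters number of colony iterations (each = employed + onlooker +
#'   scout phase).
#' @param limit trial limit before scout renewal; default `NULL` means
#'   `np * 4` (population size times the number of decision variables), the
#'   standard ABC convention.
#' @param seed optional integer seed; when non-NULL [run_abc()] seeds the
#'   RNG before the first phase.
#' @return list of class `abc_config`.
#' @export
abc_config <- function(iters = 50, limit = NULL, seed = NULL) {
  stopifnot(iters >= 0, is.null(limit) || limit >= 1)
  structure(list(iters = as.integer(iters), limit = limit, seed = seed),
            class = "abc_config")
}

#' ABC fitness of an objective value
#'
#' The colony minimises a cost `f`; since the enhancement objective `Ox` is
#' maximised, it enters as `f = -Ox`. The standard two-branch map
#' `1/(1+f)` for `f >= 0`, `1 + |f|` otherwise, then reduces to
#' `fitness = 1 + Ox` for `Ox >= 0`: strictly increasing in `Ox`, so both
#' optimiser stages pull in the same direction.
#'
#' @param ox objective value(s).
#' @return fitness value(s), always positive.
#' @export
abc_fitness <- function(ox) {
  f <- -ox
  ifelse(f >= 0, 1 / (1 + f), 1 + abs(f))
}

#' Seed a colony from a population
#'
#' @param members matrix of food sources (one per row), e.g. the DE-final
#'   population.
#' @param evaluator objective evaluator from [make_evaluator()].
#' @return list of class `abc_colony` with members, objective values,
#'   fitness, trial counters and the memorised global best.
#' @export
new_colony <- function(members, evaluator) {
  ox <- apply(members, 1, evaluator)
  b <- which.max(ox)
  structure(list(members = members, ox = ox, fitness = abc_fitness(ox),
                 trials = integer(nrow(members)),
                 best = list(params = members[b, ], ox = ox[b])),
            class = "abc_colony")
}

#' Single-component neighbour of a food source
#'
#' Copies source `j` and perturbs exactly one randomly chosen component `d`
#' to `x_jd + phi * (x_jd - x_pd)` using a random partner source `p != j`
#' and `phi ~ U(-1, 1)`, then clips into the bounds.
#'
#' @param members food-source matrix.
#' @param j source index to exploit.
#' @param lb,ub bounds.
#' @param d,partner,phi optional overrides for deterministic testing;
#'   drawn randomly when NULL.
#' @return candidate parameter vector (in bounds).
#' @export
neighbor_candidate <- function(members, j, lb, ub,
                               d = NULL, partner = NULL, phi = NULL) {
  np <- nrow(members)
  stopifnot(np >= 2)
  if (is.null(d)) d <- sample.int(ncol(members), 1)
  if (is.null(partner)) {
    partner <- sample.int(np - 1L, 1)
    if (partner >= j) partner <- partner + 1L
  }
  if (is.null(phi)) phi <- runif(1, -1, 1)
  cand <- members[j, ]
  cand[d] <- cand[d] + phi * (cand[d] - members[partner, d])
  clip_bounds(cand, lb, ub)
}

exploit_source <- function(colony, j, evaluator, lb, ub) {
  cand <- neighbor_candidate(colony$members, j, lb, ub)
  ox_new <- evaluator(cand)
  fit_new <- abc_fitness(ox_new)
  if (ox_new > colony$best$ox)
    colony$best <- list(params = cand, ox = ox_new)
  if (fit_new >= colony$fitness[j]) {   # parent kept only when strictly fitter
    colony$members[j, ] <- cand
    colony$ox[j] <- ox_new
    colony$fitness[j] <- fit_new
    colony$trials[j] <- 0L
  } else {
    colony$trials[j] <- colony$trials[j] + 1L
  }
  colony
}

#' Employed-bee phase
#'
#' Every food source is exploited once: a single-component neighbour is
#' generated, evaluated, and replaces the source when its fitness is at
#' least as good (ties favour the candidate). Success resets the source's
#' trial counter; failure increments it. The global best is updated from
#' every evaluated candidate.
#'
#' @param colony an `abc_colony`.
#' @param evaluator objective evaluator.
#' @param lb,ub bounds.
#' @return updated colony.
#' @export
employed_phase <- function(colony, evaluator, lb, ub) {
  for (j in seq_len(nrow(colony$members)))
    colony <- exploit_source(colony, j, evaluator, lb, ub)
  colony
}

#' Onlooker selection probabilities
#'
#' `prob_i = 0.9 * fit_i / max(fit) + 0.1`, so the best source is always
#' exploited (probability 1) and even a zero-fitness source keeps a 0.1
#' floor. An all-zero fitness vector degenerates to the uniform floor.
#'
#' @param fitness numeric vector of source fitness values.
#' @return probabilities in `[0.1, 1]`.
#' @export
onlooker_probabilities <- function(fitness) {
  mx <- max(fitness)
  if (mx <= 0) return(rep(0.1, length(fitness)))
  0.9 * fitness / mx + 0.1
}

#' Onlooker-bee phase
#'
#' One sweep over the sources in index order with probabilities fixed at
#' phase entry: for each source a uniform draw decides whether the full
#' exploitation step (neighbour, evaluation, greedy selection, trial update)
#' runs; otherwise the trial counter is left untouched and the bee moves on.
#'
#' @inheritParams employed_phase
#' @return updated colony.
#' @export
onlooker_phase <- function(colony, evaluator, lb, ub) {
  probs <- onlooker_probabilities(colony$fitness)
  for (j in seq_len(nrow(colony$members))) {
    if (runif(1) < probs[j])
      colony <- exploit_source(colony, j, evaluator, lb, ub)
  }
  colony
}

#' Scout-bee phase
#'
#' If the largest trial counter exceeds the limit, that single source
#' (lowest index on ties) is abandoned and replaced by a fresh uniform draw
#' from the box with no greedy comparison; its trial counter resets. At most
#' one replacement per iteration. The memorised global best is kept outside
#' the colony, so renewal can never lose it.
#'
#' @param colony an `abc_colony`.
#' @param limit trial limit.
#' @param lb,ub bounds.
#' @param evaluator objective evaluator (scores the fresh source).
#' @return list with the updated `colony` and `replaced` (index or NA).
#' @export
scout_phase <- function(colony, limit, lb, ub, evaluator) {
  replaced <- NA_integer_
  if (max(colony$trials) > limit) {
    j <- which.max(colony$trials)
    fresh <- init_population(1, lb, ub)[1, ]
    ox_new <- evaluator(fresh)
    if (ox_new > colony$best$ox)
      colony$best <- list(params = fresh, ox = ox_new)
    colony$members[j, ] <- fresh
    colony$ox[j] <- ox_new
    colony$fitness[j] <- abc_fitness(ox_new)
    colony$trials[j] <- 0L
    replaced <- j
  }
  list(colony = colony, replaced = replaced)
}

#' Run the Artificial Bee Colony refinement stage
#'
#' Seeds the colony with a population (typically the DE-final one, whose
#' scores are re-evaluated through the shared evaluator), then iterates
#' employed, onlooker and scout phases, memorising the global best across
#' all phases.
#'
#' @param xi intensity matrix; ignored when `evaluator` is supplied.
#' @param init matrix of initial food sources.
#' @param cfg an [abc_config()].
#' @param lb,ub bounds (default [default_bounds()]).
#' @param evaluator optional shared evaluator from [make_evaluator()].
#' @return list with `best_params`, `best_ox`, the final `colony`, and a
#'   per-iteration `trace` data frame (iteration 0 = the seeded colony).
#' @export
run_abc <- function(xi = NULL, init, cfg = abc_config(),
                    lb = default_bounds()$lb, ub = default_bounds()$ub,
                    evaluator = NULL) {
  if (is.null(evaluator)) {
    stopifnot(!is.null(xi))
    evaluator <- make_evaluator(xi)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  colony <- new_colony(init, evaluator)
  limit <- if (is.null(cfg$limit)) nrow(init) * ncol(init) else cfg$limit
  trace <- data.frame(iteration = 0L, best_score = colony$best$ox,
                      max_trial = 0L, replaced = NA_integer_)
  if (cfg$iters > 0) for (it in seq_len(cfg$iters)) {
    colony <- employed_phase(colony, evaluator, lb, ub)
    colony <- onlooker_phase(colony, evaluator, lb, ub)
    sc <- scout_phase(colony, limit, lb, ub, evaluator)
    colony <- sc$colony
    trace <- rbind(trace, data.frame(iteration = it,
                                     best_score = colony$best$ox,
                                     max_trial = max(colony$trials),
                                     replaced = sc$replaced))
  }
  list(best_params = colony$best$params, best_ox = colony$best$ox,
       colony = colony, trace = trace)
}
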