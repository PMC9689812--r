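#' Differential Evolution configuration
#'
#' @param np population size (>= 5 so a best vector plus four distinct
#'   partners different from the target exist).
#' @param iters number of generations.
#' @param cr crossover rate in `[0, 1]`, or the string `"random"` for a
#'   fresh uniform draw per crossover call (the literal reading in which the
#'   comparison probability itself is random).
#' @param seed optional integer seed; when non-NULL [run_de()] seeds the RNG
#'   before initialisation.
#' @return list of class `de_config`.
#' @export
de_config <- function(np = 30, iters = 50, cr = 0.9, seed = NULL) {
  stopifnot(np >= 5, iters >= 0)
  if (!identical(cr, "random")) stopifnot(is.numeric(cr), cr >= 0, cr <= 1)
  structure(list(np = as.integer(np), iters = as.integer(iters),
                 cr = cr, seed = seed), class = "de_config")
}

#' Random population initialisation
#'
#' Each member is `lb + u * (ub - lb)` with independent uniform `u` per
#' component, so the population fills the search box.
#'
#' @param n number of members.
#' @param lb,ub componentwise bounds with `lb < ub`.
#' @return `n x 4` matrix, one member per row.
#' @export
init_population <- function(n, lb, ub) {
  d <- length(lb)
  stopifnot(length(ub) == d, all(lb < ub), n >= 1)
  u <- matrix(runif(n * d), n, d)
  m <- sweep(sweep(u, 2, ub - lb, `*`), 2, lb, `+`)
  colnames(m) <- names(lb)
  m
}

#' DE/best/2 mutation
#'
#' Donor vector `M_i = P_best + F (P_r1 - P_r2) + F (P_r3 - P_r4)` with the
#' four partner indices drawn without replacement from the population
#' excluding the target (so `r1 != r2 != r3 != r4 != i`). The donor is not
#' clipped; [clip_bounds()] is applied after crossover.
#'
#' @param members population matrix (one member per row).
#' @param best_index row index of the best-scoring member.
#' @param target_index row index of the target vector `i`.
#' @param f scaling factor in `[0, 1]`.
#' @param idx optional integer vector of 4 partner indices (for
#'   deterministic testing); drawn randomly when NULL.
#' @return donor parameter vector.
#' @export
de_mutate <- function(members, best_index, target_index, f, idx = NULL) {
  np <- nrow(members)
  if (is.null(idx)) {
    avail <- setdiff(seq_len(np), target_index)
    if (length(avail) < 4) stop("population too small for best/2 mutation")
    idx <- sample(avail, 4)
  }
  members[best_index, ] +
    f * (members[idx[1], ] - members[idx[2], ]) +
    f * (members[idx[3], ] - members[idx[4], ])
}

#' Binomial crossover
#'
#' Component `d` of the child comes from the donor when `r_d <= cr` or when
#' `d` equals the forced index, ensuring at least one donor component is
#' always inherited; otherwise it comes from the parent.
#'
#' @param parent,donor parameter vectors.
#' @param cr crossover rate in `[0, 1]`.
#' @param r optional uniform draws, one per component (for testing).
#' @param forced optional forced donor index (for testing); drawn uniformly
#'   over the components when NULL.
#' @return child parameter vector.
#' @export
de_crossover <- function(parent, donor, cr, r = NULL, forced = NULL) {
  d <- length(parent)
  if (is.null(r)) r <- runif(d)
  if (is.null(forced)) forced <- sample.int(d, 1)
  take <- r <= cr
  take[forced] <- TRUE
  out <- parent
  out[take] <- donor[take]
  out
}

#' Greedy survivor selection
#'
#' The parent survives only when its score strictly exceeds the child's;
#' on a tie the child replaces it.
#'
#' @param parent,child parameter vectors.
#' @param parent_score,child_score their objective scores.
#' @return list with `vector`, `score` and logical `child_won`.
#' @export
greedy_select <- function(parent, child, parent_score, child_score) {
  if (parent_score > child_score)
    list(vector = parent, score = parent_score, child_won = FALSE)
  else
    list(vector = child, score = child_score, child_won = TRUE)
}

#' Run the Differential Evolution stage
#'
#' Initialises a population in the box, then for each generation and each
#' target vector performs best/2 mutation (a fresh `F ~ U(0, 1)` per
#' mutant), binomial crossover, clipping to bounds, evaluation and greedy
#' selection. Maximises the objective.
#'
#' @param xi intensity matrix; ignored when `evaluator` is supplied.
#' @param cfg a [de_config()].
#' @param lb,ub bounds (default [default_bounds()]).
#' @param evaluator optional evaluator from [make_evaluator()]; built from
#'   `xi` with defaults when NULL.
#' @param init optional initial population matrix (used by tests and by the
#'   pipeline when chaining stages); drawn via [init_population()] when NULL.
#' @return list with `members`, `scores`, `best_index`, `best_params`,
#'   `best_score`, and a per-generation `trace` data frame
#'   (generation 0 = the initial population).
#' @export
run_de <- function(xi = NULL, cfg = de_config(), lb = default_bounds()$lb,
                   ub = default_bounds()$ub, evaluator = NULL, init = NULL) {
  if (is.null(evaluator)) {
    stopifnot(!is.null(xi))
    evaluator <- make_evaluator(xi)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  members <- if (is.null(init)) init_population(cfg$np, lb, ub) else init
  np <- nrow(members)
  scores <- apply(members, 1, evaluator)
  trace <- data.frame(generation = 0L, best_score = max(scores),
                      mean_score = mean(scores))
  if (cfg$iters > 0) for (gen in seq_len(cfg$iters)) {
    best <- which.max(scores)
    for (i in seq_len(np)) {
      f <- runif(1)
      cr <- if (identical(cfg$cr, "random")) runif(1) else cfg$cr
      donor <- de_mutate(members, best, i, f)
      child <- clip_bounds(de_crossover(members[i, ], donor, cr), lb, ub)
      cs <- evaluator(child)
      sel <- greedy_select(members[i, ], child, scores[i], cs)
      if (sel$child_won) {
        members[i, ] <- child
        scores[i] <- cs
        if (cs > scores[best]) best <- i
      }
    }
    trace <- rbind(trace, data.frame(generation = gen,
                                     best_score = max(scores),
                                     mean_score = mean(scores)))
  }
  bi <- which.max(scores)
  list(members = members, scores = scores, best_index = bi,
       best_params = members[bi, ], best_score = scores[bi], trace = trace)
}
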