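# Elitist non-dominated-sorting genetic algorithm (NSGA-II style) for
# two-objective minimization, written against a *vectorized* objective:
# fn(pop) takes an n x n_var matrix and returns an n x 2 matrix, so a whole
# generation is evaluated in one call.

# Fast non-dominated sort: returns integer rank per individual (1 = front 1).
# The pairwise domination matrix is built with vectorised comparisons and
# fronts are peeled off by repeated domination counting.
nd_rank <- function(obj) {
  n <- nrow(obj)
  f1 <- obj[, 1]
  f2 <- obj[, 2]
  le1 <- outer(f1, f1, "<=")
  le2 <- outer(f2, f2, "<=")
  lt1 <- outer(f1, f1, "<")
  lt2 <- outer(f2, f2, "<")
  dom <- le1 & le2 & (lt1 | lt2) # dom[i, j]: i dominates j
  n_dom_by <- colSums(dom)
  rank <- integer(n)
  r <- 1L
  remaining <- n
  while (remaining > 0) {
    current <- which(rank == 0L & n_dom_by == 0)
    rank[current] <- r
    remaining <- remaining - length(current)
    if (remaining == 0) break
    n_dom_by <- n_dom_by - colSums(dom[current, , drop = FALSE])
    n_dom_by[rank > 0L] <- Inf
    r <- r + 1L
  }
  rank
}

# Crowding distance within one front (rows of obj).
crowding <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) {
    return(rep(Inf, n))
  }
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2)], k]) / rng
    }
  }
  d
}

# Simulated binary crossover on a pair of parents (vectors), bounded.
sbx_pair <- function(p1, p2, lo, hi, eta) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5,
    (2 * u)^(1 / (eta + 1)),
    (1 / (2 * (1 - u)))^(1 / (eta + 1))
  )
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

# Polynomial mutation, applied per gene with probability p_mut.
poly_mutate <- function(x, lo, hi, eta, p_mut) {
  hit <- stats::runif(length(x)) < p_mut
  if (!any(hit)) {
    return(x)
  }
  u <- stats::runif(sum(hit))
  span <- (hi - lo)[hit]
  xi <- x[hit]
  d1 <- (xi - lo[hit]) / span
  d2 <- (hi[hit] - xi) / span
  delta <- ifelse(u < 0.5,
    (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^(1 / (eta + 1)) - 1,
    1 - (2 * (1 - u) + (2 * u - 1) * (1 - d2)^(eta + 1))^(1 / (eta + 1))
  )
  x[hit] <- pmin(pmax(xi + delta * span, lo[hit]), hi[hit])
  x
}

#' Two-objective evolutionary minimization
#'
#' An elitist non-dominated-sorting genetic algorithm (NSGA-II style) with
#' simulated binary crossover and polynomial mutation, for real-valued
#' decision vectors and two objectives. The run is fully reproducible from
#' `seed`; no global random state is consumed.
#'
#' @param fn Vectorized objective: takes an `n x n_var` matrix of decision
#'   vectors (rows) and returns an `n x 2` matrix of objective values to
#'   minimize.
#' @param bounds A `n_var x 2` matrix (or 2-column data frame) of lower and
#'   upper bounds.
#' @param population Population size (>= 10, even).
#' @param generations Number of generations.
#' @param seed Integer seed.
#' @param p_crossover,eta_crossover SBX probability and distribution index.
#' @param p_mutation,eta_mutation Per-gene mutation probability (default
#'   `1/n_var`) and distribution index.
#' @param verbose Print per-generation progress (best minimax objective).
#' @return A list with `par` (matrix of non-dominated decision vectors,
#'   sorted by the first objective), `objectives` (matching matrix), and
#'   `history` (tibble with per-generation best minimax value).
#' @examples
#' # Convex bi-objective with known Pareto set x in [-1, 1]:
#' fn <- function(x) cbind((x[, 1] - 1)^2, (x[, 1] + 1)^2)
#' res <- nsga2(fn, rbind(c(-4, 4)), population = 40, generations = 30, seed = 1)
#' range(res$par)
#' @export
nsga2 <- function(fn, bounds, population = 100, generations = 100, seed = 1,
                  p_crossover = 0.9, eta_crossover = 15,
                  p_mutation = NULL, eta_mutation = 20, verbose = FALSE) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || any(!is.finite(bounds)) ||
      any(bounds[, 1] >= bounds[, 2])) {
    abort("`bounds` must be a matrix of finite rows with lower < upper")
  }
  n_var <- nrow(bounds)
  lo <- bounds[, 1]
  hi <- bounds[, 2]
  if (population < 10) abort("`population` must be at least 10")
  n_pop <- as.integer(population)
  if (n_pop %% 2L == 1L) n_pop <- n_pop + 1L
  p_mutation <- p_mutation %||% (1 / n_var)

  withr::with_seed(as.integer(seed), {
    pop <- matrix(stats::runif(n_pop * n_var, rep(lo, each = n_pop),
      rep(hi, each = n_pop)
    ), nrow = n_pop)
    obj <- fn(pop)
    rank <- nd_rank(obj)
    crowd <- numeric(n_pop)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding(obj[idx, , drop = FALSE])
    }
    history <- numeric(generations)

    tournament <- function() {
      cand <- sample.int(n_pop, 2)
      a <- cand[1]
      b <- cand[2]
      if (rank[a] < rank[b]) {
        a
      } else if (rank[b] < rank[a]) {
        b
      } else if (crowd[a] >= crowd[b]) a else b
    }

    for (gen in seq_len(generations)) {
      child <- matrix(0, n_pop, n_var)
      for (i in seq(1, n_pop, by = 2)) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        if (stats::runif(1) < p_crossover) {
          cc <- sbx_pair(p1, p2, lo, hi, eta_crossover)
        } else {
          cc <- list(p1, p2)
        }
        child[i, ] <- poly_mutate(cc[[1]], lo, hi, eta_mutation, p_mutation)
        child[i + 1, ] <- poly_mutate(cc[[2]], lo, hi, eta_mutation, p_mutation)
      }
      obj_child <- fn(child)
      all_pop <- rbind(pop, child)
      all_obj <- rbind(obj, obj_child)
      all_rank <- nd_rank(all_obj)
      all_crowd <- numeric(nrow(all_pop))
      for (r in unique(all_rank)) {
        idx <- which(all_rank == r)
        all_crowd[idx] <- crowding(all_obj[idx, , drop = FALSE])
      }
      keep <- order(all_rank, -all_crowd)[seq_len(n_pop)]
      pop <- all_pop[keep, , drop = FALSE]
      obj <- all_obj[keep, , drop = FALSE]
      rank <- all_rank[keep]
      crowd <- all_crowd[keep]
      history[gen] <- min(pmax(obj[, 1], obj[, 2]))
      if (verbose) {
        message(sprintf(
          "generation %d: best minimax objective %.3e", gen, history[gen]
        ))
      }
    }

    front_idx <- which(rank == 1L)
    # deduplicate identical decision vectors, then sort by first objective
    key <- apply(pop[front_idx, , drop = FALSE], 1, paste, collapse = "\r")
    front_idx <- front_idx[!duplicated(key)]
    o <- front_idx[order(obj[front_idx, 1])]
    list(
      par = pop[o, , drop = FALSE],
      objectives = obj[o, , drop = FALSE],
      history = tibble(
        generation = seq_len(generations), best_minimax = history
      )
    )
  })
}
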