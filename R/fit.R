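#' Configuration for parameter identification
#'
#' Collects the settings of the two-objective evolutionary calibration. The
#' defaults (population 200, 300 generations) converge on synthetic recovery
#' problems in minutes on a single CPU; reduce them for quick exploratory
#' fits.
#'
#' @param population Population size (>= 10).
#' @param generations Number of generations.
#' @param bounds Per-parameter search bounds: an 11 x 2 matrix with rows in
#'   the order `a1, a2, a3, c2, c3, c4, e2, e3, e4, beta1, beta2`, as built
#'   by [default_bounds()]. Default: coefficients in `[-1e7, 1e7]` Pa,
#'   angles in `[0, 180)` degrees.
#' @param seed Integer seed; every stochastic step derives from it.
#' @param stress Stress measure of the objective curves, `"engineering"` or
#'   `"true"`.
#' @param aggregate How multiple specimen curves enter the objectives:
#'   `"pooled"` (all points) or `"mean_curve"` (average per strain).
#' @param p_crossover,eta_crossover,p_mutation,eta_mutation Genetic-operator
#'   settings, see [nsga2()].
#' @param verbose Print per-generation progress.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(population = 200, generations = 300,
                       bounds = default_bounds(), seed = 1,
                       stress = c("engineering", "true"),
                       aggregate = c("pooled", "mean_curve"),
                       p_crossover = 0.9, eta_crossover = 15,
                       p_mutation = NULL, eta_mutation = 20,
                       verbose = FALSE) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 11 || ncol(bounds) != 2 || any(!is.finite(bounds)) ||
      any(bounds[, 1] >= bounds[, 2])) {
    abort("`bounds` must be an 11 x 2 matrix of finite rows with lower < upper")
  }
  if (population < 10) abort("`population` must be at least 10")
  rownames(bounds) <- param_names()
  structure(
    list(
      population = as.integer(population),
      generations = as.integer(generations),
      bounds = bounds, seed = as.integer(seed),
      stress = match.arg(stress), aggregate = match.arg(aggregate),
      p_crossover = p_crossover, eta_crossover = eta_crossover,
      p_mutation = p_mutation, eta_mutation = eta_mutation,
      verbose = verbose
    ),
    class = "fit_config"
  )
}

#' Default search bounds for the eleven model parameters
#'
#' Without a reference set, coefficients span `[-1e7, 1e7]` Pa (two orders
#' of magnitude around typical colorectal stiffness values) and the fiber
#' angles span `[0, 180)` degrees. Given a reference parameter set, each
#' coefficient instead spans 0.1 to 10 times its reference value with the
#' sign preserved; angles still span `[0, 180)`.
#'
#' @param params Optional [material_parameters()] reference set.
#' @return An 11 x 2 bounds matrix with rows named after the parameters.
#' @examples
#' default_bounds()
#' default_bounds(colorectal_params())
#' @export
default_bounds <- function(params = NULL) {
  nm <- param_names()
  if (is.null(params)) {
    b <- cbind(rep(-1e7, 11), rep(1e7, 11))
    b[10:11, ] <- c(0, 0, 180 - 1e-9, 180 - 1e-9)
  } else {
    p <- as_material_parameters(params)
    v <- unlist(p[nm[1:9]])
    lo <- ifelse(v >= 0, 0.1 * v, 10 * v)
    hi <- ifelse(v >= 0, 10 * v, 0.1 * v)
    zero <- v == 0
    lo[zero] <- -1e3
    hi[zero] <- 1e3
    b <- rbind(cbind(lo, hi), c(0, 180 - 1e-9), c(0, 180 - 1e-9))
  }
  dimnames(b) <- list(nm, c("lower", "upper"))
  b
}

#' Fit the constitutive model to stress-strain curves
#'
#' Identifies the eleven material parameters by two-objective evolutionary
#' minimization of the normalized circumferential and longitudinal errors
#' (`Ec`, `Et`), returning the full Pareto front and the balanced solution
#' (the front member minimizing `max(Ec, Et)`). Both orientations must be
#' present in `curves` so the anisotropy is identifiable.
#'
#' @param curves A data frame of experimental or synthetic points with
#'   columns `strain`, `stress_pa`, `orientation` (and optionally
#'   `specimen`).
#' @param config A [fit_config()].
#' @return An object of class `tissue_fit` with elements `front` (tibble of
#'   canonicalized parameter sets and their `Ec`, `Et`, sorted by `Ec`),
#'   `balanced` ([material_parameters()] of the balanced solution),
#'   `objectives` (its `Ec`, `Et`), `history` and `config`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' p <- colorectal_params()
#' curves <- dplyr::bind_rows(
#'   generate_curves(p, "circ", 1, noise_cv = 0, seed = 1),
#'   generate_curves(p, "long", 1, noise_cv = 0, seed = 2)
#' )
#' fit <- fit_material(curves, fit_config(
#'   population = 60, generations = 40,
#'   bounds = default_bounds(p), seed = 1
#' ))
#' glance(fit)
#' }
#' @export
fit_material <- function(curves, config = fit_config()) {
  if (!inherits(config, "fit_config")) {
    abort("`config` must be a fit_config() object")
  }
  data <- prepare_objective_data(curves, config$aggregate)
  fn <- function(pop) {
    colnames(pop) <- param_names()
    objective_batch(pop, data, config$stress)
  }
  res <- nsga2(fn, config$bounds,
    population = config$population,
    generations = config$generations, seed = config$seed,
    p_crossover = config$p_crossover, eta_crossover = config$eta_crossover,
    p_mutation = config$p_mutation, eta_mutation = config$eta_mutation,
    verbose = config$verbose
  )
  colnames(res$par) <- param_names()
  front <- as_tibble(as.data.frame(res$par))
  # canonicalize each member (pure relabelling; objectives unchanged)
  front <- dplyr::bind_rows(lapply(seq_len(nrow(front)), function(i) {
    as_tibble(unclass(canonicalize(as.list(front[i, ]))))
  }))
  front$Ec <- res$objectives[, 1]
  front$Et <- res$objectives[, 2]
  bal <- select_balanced(front)
  structure(
    list(
      front = front,
      balanced = as_material_parameters(as.list(bal[param_names()])),
      objectives = bal[c("Ec", "Et")],
      history = res$history,
      config = config
    ),
    class = "tissue_fit"
  )
}

#' Pick the balanced solution from a Pareto front
#'
#' Returns the front member with the smallest worse-of-the-two normalized
#' errors, i.e. minimizing `max(Ec, Et)`. Ties are broken by smaller
#' `Ec + Et`, then by input order.
#'
#' @param front A data frame with columns `Ec` and `Et` (e.g. the `front`
#'   element of a [fit_material()] result), or a `tissue_fit` object.
#' @return The selected row as a one-row tibble.
#' @examples
#' front <- tibble::tibble(Ec = c(0.10, 0.00, 0.03), Et = c(0.00, 0.10, 0.04))
#' select_balanced(front)
#' @export
select_balanced <- function(front) {
  if (inherits(front, "tissue_fit")) front <- front$front
  if (!is.data.frame(front) || !all(c("Ec", "Et") %in% names(front)) ||
      nrow(front) == 0) {
    abort("`front` must be a non-empty data frame with columns Ec and Et")
  }
  worst <- pmax(front$Ec, front$Et)
  cand <- which(worst == min(worst))
  if (length(cand) > 1) {
    sums <- front$Ec[cand] + front$Et[cand]
    cand <- cand[sums == min(sums)]
  }
  front[cand[1], ]
}

#' @export
print.tissue_fit <- function(x, ...) {
  cat(
    "<tissue_fit> Pareto front with", nrow(x$front), "solutions;",
    "balanced: Ec =", format(x$objectives$Ec, digits = 4),
    ", Et =", format(x$objectives$Et, digits = 4), "\n"
  )
  print(x$balanced)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the balanced solution of a fit
#'
#' @param x A `tissue_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @method tidy tissue_fit
#' @export
tidy.tissue_fit <- function(x, ...) {
  p <- unlist(unclass(x$balanced))
  tibble(
    term = names(p),
    estimate = unname(p),
    unit = c(rep("Pa", 9), rep("degrees", 2))
  )
}

#' One-row summary of a fit
#'
#' @param x A `tissue_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: balanced `Ec`, `Et`, their maximum, the front
#'   size and the GA settings.
#' @method glance tissue_fit
#' @export
glance.tissue_fit <- function(x, ...) {
  tibble(
    Ec = x$objectives$Ec,
    Et = x$objectives$Et,
    minimax = max(x$objectives$Ec, x$objectives$Et),
    front_size = nrow(x$front),
    population = x$config$population,
    generations = x$config$generations,
    seed = x$config$seed
  )
}

#' Plot a Pareto front
#'
#' @param object A `tissue_fit` object.
#' @param ... Unused.
#' @return A ggplot: the front in the `(Ec, Et)` plane with the balanced
#'   solution highlighted.
#' @method autoplot tissue_fit
#' @export
autoplot.tissue_fit <- function(object, ...) {
  bal <- object$objectives
  ggplot2::ggplot(object$front, ggplot2::aes(x = .data$Ec, y = .data$Et)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(
      data = as.data.frame(bal), colour = "red", size = 3, shape = 17
    ) +
    ggplot2::labs(
      x = "normalized circumferential error Ec",
      y = "normalized longitudinal error Et",
      title = "Pareto front (balanced solution in red)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
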