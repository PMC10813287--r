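#' Normalized curve-fitting error
#'
#' The dimensionless misfit between a model curve and an experimental curve
#' sampled at the same points:
#' \deqn{E = \frac{\sum_l (\sigma^e_l - \sigma^m_l)^2}{\sum_l (\sigma^e_l)^2}}
#' It is 0 for an exact match and 1 for a model that predicts zero stress
#' everywhere.
#'
#' @param model Numeric vector of model stresses (Pa).
#' @param experimental Numeric vector of experimental stresses (Pa), same
#'   length.
#' @return A single dimensionless number, >= 0.
#' @examples
#' normalized_error(c(1, 2, 3), c(1.1, 2.2, 3.3))
#' @export
normalized_error <- function(model, experimental) {
  if (length(model) == 0 || length(model) != length(experimental)) {
    abort("`model` and `experimental` must be non-empty and of equal length")
  }
  ss <- sum(experimental^2)
  if (ss == 0) {
    abort("experimental stresses are all zero; normalization is degenerate")
  }
  sum((experimental - model)^2) / ss
}

# Validate a curve table and index its points against a unique strain grid
# per orientation. Used by both the scalar evaluator and the GA batch path.
prepare_objective_data <- function(curves,
                                   aggregate = c("pooled", "mean_curve")) {
  aggregate <- match.arg(aggregate)
  req <- c("strain", "stress_pa", "orientation")
  if (!is.data.frame(curves) || !all(req %in% names(curves))) {
    abort(
      "`curves` must be a data frame with columns strain, stress_pa, orientation"
    )
  }
  axis_of <- vapply(curves$orientation, match_axis, integer(1))
  out <- lapply(1:2, function(ax) {
    strain <- curves$strain[axis_of == ax]
    stress <- curves$stress_pa[axis_of == ax]
    if (length(strain) == 0) {
      abort(paste0("no ", axis_label(ax), " data points supplied"))
    }
    if (aggregate == "mean_curve") {
      m <- tapply(stress, strain, mean)
      strain <- as.numeric(names(m))
      stress <- as.numeric(m)
    }
    grid <- sort(unique(strain))
    ss <- sum(stress^2)
    if (ss == 0) {
      abort(paste0(
        "all ", axis_label(ax),
        " experimental stresses are zero; normalization is degenerate"
      ))
    }
    list(
      grid = grid, idx = match(strain, grid), stress = stress, ss = ss
    )
  })
  names(out) <- c("circumferential", "longitudinal")
  out
}

# Evaluate (Ec, Et) for a whole population at once. `pop` is an n x 11
# matrix with columns in param_names() order; everything is dense matrix
# arithmetic so GA generations cost milliseconds.
objective_batch <- function(pop, data, stress = "engineering") {
  n <- nrow(pop)
  errs <- vapply(1:2, function(ax) {
    d <- data[[ax]]
    lam <- 1 + d$grid
    lam2 <- lam^2
    lami <- 1 / lam
    C11 <- if (ax == 1L) lam2 else lami
    C22 <- if (ax == 2L) lam2 else lami
    X <- (C11 - 1) + (C22 - 1) + (lami - 1) # I1 - 3, shared across individuals

    b1 <- pop[, "beta1"] * pi / 180
    b2 <- pop[, "beta2"] * pi / 180
    cb1 <- cos(b1)^2
    sb1 <- sin(b1)^2
    cb2 <- cos(b2)^2
    sb2 <- sin(b2)^2

    Y <- outer(cb1, C11 - 1) + outer(sb1, C22 - 1) # I4 - 1, n x m
    Z <- outer(cb2, C11 - 1) + outer(sb2, C22 - 1) # I6 - 1

    d_iso <- outer(pop[, "a1"], rep(1, length(lam))) +
      outer(2 * pop[, "a2"], X) + outer(3 * pop[, "a3"], X^2)
    d_f1 <- Y * (2 * pop[, "c2"]) + Y^2 * (3 * pop[, "c3"]) +
      Y^3 * (4 * pop[, "c4"])
    d_f2 <- Z * (2 * pop[, "e2"]) + Z^2 * (3 * pop[, "e3"]) +
      Z^3 * (4 * pop[, "e4"])

    w1 <- if (ax == 1L) cb1 else sb1
    w2 <- if (ax == 1L) cb2 else sb2
    s_ax <- 2 * (d_iso + d_f1 * w1 + d_f2 * w2)
    s33 <- 2 * d_iso
    S <- s_ax - sweep(s33, 2, lam^3, "/")
    sig <- if (stress == "engineering") {
      sweep(S, 2, lam, "*")
    } else {
      sweep(S, 2, lam2, "*")
    }
    resid <- sweep(sig[, d$idx, drop = FALSE], 2, d$stress, "-")
    rowSums(resid^2) / d$ss
  }, numeric(n))
  matrix(errs, nrow = n, dimnames = list(NULL, c("Ec", "Et")))
}

#' Evaluate the two calibration objectives
#'
#' Computes the normalized circumferential error `Ec` and longitudinal error
#' `Et` of a parameter set against a table of experimental (or synthetic)
#' stress-strain points.
#'
#' @param curves A data frame with columns `strain`, `stress_pa`,
#'   `orientation` (and optionally `specimen`); both orientations must be
#'   present.
#' @param params A [material_parameters()] object.
#' @param stress Stress measure the curves report: `"engineering"` (default)
#'   or `"true"`.
#' @param aggregate `"pooled"` (default) pools all sample points across
#'   specimens per direction; `"mean_curve"` first averages the stress across
#'   specimens at each strain, matching the use of averaged curves.
#' @return A one-row tibble with columns `Ec` and `Et`.
#' @examples
#' p <- colorectal_params()
#' curves <- dplyr::bind_rows(
#'   predict_curve(p, seq(0.01, 0.2, 0.01), "circ"),
#'   predict_curve(p, seq(0.01, 0.2, 0.01), "long")
#' )
#' evaluate_objectives(curves, p) # (0, 0): self-consistency
#' @export
evaluate_objectives <- function(curves, params,
                                stress = c("engineering", "true"),
                                aggregate = c("pooled", "mean_curve")) {
  stress <- match.arg(stress)
  p <- as_material_parameters(params)
  data <- prepare_objective_data(curves, match.arg(aggregate))
  pop <- matrix(unlist(p[param_names()]),
    nrow = 1,
    dimnames = list(NULL, param_names())
  )
  e <- objective_batch(pop, data, stress)
  tibble(Ec = unname(e[1, "Ec"]), Et = unname(e[1, "Et"]))
}
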