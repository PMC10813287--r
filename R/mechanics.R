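#' @importFrom rlang %||% abort
#' @importFrom tibble tibble as_tibble
NULL

#' Resolve a loading-direction specifier
#'
#' The two tested orientations are `"circumferential"` (axis 1, the hoop
#' direction of the colon) and `"longitudinal"` (axis 2). Abbreviations
#' `"circ"`/`"long"` and the axis numbers 1/2 are accepted anywhere a
#' direction is expected.
#'
#' @param direction Direction specifier.
#' @return Integer axis, 1 or 2.
#' @keywords internal
match_axis <- function(direction) {
  if (length(direction) != 1L) {
    abort("`direction` must be a single value")
  }
  if (is.numeric(direction) && direction %in% c(1, 2)) {
    return(as.integer(direction))
  }
  if (is.character(direction)) {
    d <- tolower(direction)
    if (startsWith("circumferential", d)) {
      return(1L)
    }
    if (startsWith("longitudinal", d)) {
      return(2L)
    }
  }
  abort(paste0(
    "unknown direction ", deparse(direction),
    "; use \"circumferential\"/\"circ\"/1 or \"longitudinal\"/\"long\"/2"
  ))
}

axis_label <- function(axis) {
  c("circumferential", "longitudinal")[axis]
}

#' Undeformed fiber direction vector
#'
#' Fibers lie in the circumferential-longitudinal plane; a family at angle
#' `beta` (degrees from the circumferential axis) has unit direction
#' `(cos beta, sin beta, 0)`.
#'
#' @param beta Fiber angle in degrees.
#' @return Unit 3-vector.
#' @examples
#' fiber_direction(0) # circumferential
#' fiber_direction(90) # longitudinal
#' @export
fiber_direction <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    abort("`beta` must be a single finite number (degrees)")
  }
  b <- beta * pi / 180
  c(cos(b), sin(b), 0)
}

#' Incompressible uniaxial kinematics
#'
#' Under incompressible uniaxial tension at stretch `lambda` the transverse
#' stretches are both `lambda^(-1/2)`, so the (modified) right Cauchy-Green
#' tensor is `diag(lambda^2, 1/lambda, 1/lambda)` for circumferential loading
#' and `diag(1/lambda, lambda^2, 1/lambda)` for longitudinal loading; its
#' determinant is exactly 1.
#'
#' @param stretch Axial stretch `lambda > 0` (scalar).
#' @param direction Loading direction, see [match_axis()].
#' @return An object of class `uniaxial_kinematics` with fields `stretch`,
#'   `axis`, `cbar` (3x3 diagonal matrix) and `J` (= 1).
#' @examples
#' uniaxial_kinematics(1.2, "circ")$cbar
#' @export
uniaxial_kinematics <- function(stretch, direction) {
  if (!is.numeric(stretch) || length(stretch) != 1L || !is.finite(stretch) ||
      stretch <= 0) {
    abort("`stretch` must be a single positive number")
  }
  axis <- match_axis(direction)
  d <- rep(1 / stretch, 3)
  d[axis] <- stretch^2
  structure(
    list(stretch = stretch, axis = axis, cbar = diag(d), J = 1),
    class = "uniaxial_kinematics"
  )
}

#' Strain invariants and fiber pseudo-invariants
#'
#' For a uniaxial state this returns the first invariant
#' `I1 = tr(Cbar)` and the two fiber pseudo-invariants `I4 = a . Cbar a`
#' and `I6 = g . Cbar g`, the squared stretches along each fiber family.
#'
#' @param kin A [uniaxial_kinematics()] object.
#' @param params A [material_parameters()] object (supplies the fiber angles).
#' @return An object of class `invariant_set` with fields `I1bar`, `I4bar`,
#'   `I6bar`, `a_vec`, `g_vec`.
#' @examples
#' invariants(uniaxial_kinematics(1.2, "circ"), colorectal_params())
#' @export
invariants <- function(kin, params) {
  stopifnot(inherits(kin, "uniaxial_kinematics"))
  p <- as_material_parameters(params)
  a <- fiber_direction(p$beta1)
  g <- fiber_direction(p$beta2)
  structure(
    list(
      I1bar = sum(diag(kin$cbar)),
      I4bar = drop(a %*% kin$cbar %*% a),
      I6bar = drop(g %*% kin$cbar %*% g),
      a_vec = a, g_vec = g
    ),
    class = "invariant_set"
  )
}

# Vectorised evaluation of every model quantity on a stretch grid.
# Returns parallel numeric vectors; the single place the constitutive
# equations are written down.
model_terms <- function(p, lambda, axis, tension_only = FALSE,
                        legacy_denominator = FALSE) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort("stretches must be finite and > 0")
  }
  lam2 <- lambda^2
  lami <- 1 / lambda
  # diagonal Cbar: loading axis gets lambda^2, both transverse 1/lambda
  C11 <- if (axis == 1L) lam2 else lami
  C22 <- if (axis == 2L) lam2 else lami
  I1 <- C11 + C22 + lami

  b1 <- p$beta1 * pi / 180
  b2 <- p$beta2 * pi / 180
  cb1 <- cos(b1)^2
  sb1 <- sin(b1)^2
  cb2 <- cos(b2)^2
  sb2 <- sin(b2)^2
  # difference forms are exactly zero at lambda = 1 (cos^2 + sin^2 need not
  # round to 1), keeping the reference state exactly stress-free
  X <- (C11 - 1) + (C22 - 1) + (lami - 1) # I1 - 3
  Y <- cb1 * (C11 - 1) + sb1 * (C22 - 1) # I4 - 1
  Z <- cb2 * (C11 - 1) + sb2 * (C22 - 1) # I6 - 1
  I4 <- 1 + Y
  I6 <- 1 + Z
  d_iso <- p$a1 + 2 * p$a2 * X + 3 * p$a3 * X^2
  d_f1 <- 2 * p$c2 * Y + 3 * p$c3 * Y^2 + 4 * p$c4 * Y^3
  d_f2 <- 2 * p$e2 * Z + 3 * p$e3 * Z^2 + 4 * p$e4 * Z^3
  if (tension_only) {
    d_f1[Y <= 0] <- 0
    d_f2[Z <= 0] <- 0
  }

  s11 <- 2 * (d_iso + d_f1 * cb1 + d_f2 * cb2)
  s22 <- 2 * (d_iso + d_f1 * sb1 + d_f2 * sb2)
  s33 <- 2 * d_iso
  s_ax <- if (axis == 1L) s11 else s22
  denom <- if (legacy_denominator) 3 * lambda^3 else lambda^3
  S <- s_ax - s33 / denom

  psi_f1 <- p$c2 * Y^2 + p$c3 * Y^3 + p$c4 * Y^4
  psi_f2 <- p$e2 * Z^2 + p$e3 * Z^3 + p$e4 * Z^4
  if (tension_only) {
    psi_f1[Y <= 0] <- 0
    psi_f2[Z <= 0] <- 0
  }
  psi <- p$a1 * X + p$a2 * X^2 + p$a3 * X^3 + psi_f1 + psi_f2

  list(
    I1 = I1, I4 = I4, I6 = I6, psi = psi,
    stilde_11 = s11, stilde_22 = s22, stilde_33 = s33,
    s_axial = S, sigma_true = lam2 * S, p_eng = lambda * S,
    pressure = s33 / lambda
  )
}

#' Strain-energy density
#'
#' Evaluates the anisotropic hyperelastic strain energy
#' \deqn{\Psi = \sum_{i=1}^{3} a_i (I_1-3)^i + \sum_{j=2}^{4} c_j (I_4-1)^j
#'   + \sum_{k=2}^{4} e_k (I_6-1)^k}
#' on a stretch grid under incompressible uniaxial kinematics. The energy is
#' zero in the reference state.
#'
#' @param params A [material_parameters()] object.
#' @param stretch Numeric vector of axial stretches (> 0).
#' @param direction Loading direction, see [match_axis()].
#' @param tension_only If `TRUE`, fiber families store energy only when
#'   stretched beyond their reference length (`I4 > 1`). Default `FALSE`:
#'   the polynomial terms are evaluated as written, which is smooth because
#'   the fiber sums start at power 2.
#' @return Numeric vector of energy densities, Pa.
#' @examples
#' strain_energy(colorectal_params(), c(1, 1.1, 1.2), "circ")
#' @export
strain_energy <- function(params, stretch, direction, tension_only = FALSE) {
  p <- as_material_parameters(params)
  model_terms(p, stretch, match_axis(direction), tension_only)$psi
}

#' Referential stress derivatives (S-tilde components)
#'
#' The diagonal components of `2 dPsi/dCbar` before the hydrostatic pressure
#' is eliminated. Because both fiber families lie in the 1-2 plane,
#' `stilde_33` carries no fiber contribution: it equals twice the isotropic
#' derivative. The power-zero convention `(I1-3)^0 = 1` is applied to the
#' first isotropic term, so at `lambda = 1` all three components equal
#' `2 * a1`.
#'
#' @inheritParams strain_energy
#' @return A tibble with columns `stretch`, `stilde_11`, `stilde_22`,
#'   `stilde_33` (Pa).
#' @examples
#' stilde_components(colorectal_params(), 1.2, "circ")
#' @export
stilde_components <- function(params, stretch, direction,
                              tension_only = FALSE) {
  p <- as_material_parameters(params)
  m <- model_terms(p, stretch, match_axis(direction), tension_only)
  tibble(
    stretch = stretch,
    stilde_11 = m$stilde_11,
    stilde_22 = m$stilde_22,
    stilde_33 = m$stilde_33
  )
}

#' Incompressible uniaxial stress response
#'
#' Computes the axial second Piola-Kirchhoff stress by eliminating the
#' hydrostatic pressure through the traction-free transverse condition
#' (`S33 = 0`), giving `S = stilde_axial - stilde_33 / lambda^3`, and the
#' derived Cauchy (true) stress `sigma = lambda^2 S` and engineering (first
#' Piola-Kirchhoff) stress `P = lambda S`. All stresses vanish identically
#' at `lambda = 1`.
#'
#' @inheritParams strain_energy
#' @param legacy_denominator If `TRUE`, use an alternative pressure
#'   elimination with denominator `3 lambda^3` instead of `lambda^3`,
#'   retained for sensitivity analysis; the default follows from the
#'   pressure-elimination derivation and is the form that reproduces
#'   published colorectal stress levels.
#' @return A tibble with columns `stretch`, `s_axial_pa`, `sigma_true_pa`,
#'   `p_eng_pa`, `pressure_pa`, `stilde_11_pa`, `stilde_22_pa`,
#'   `stilde_33_pa`.
#' @examples
#' uniaxial_stress(colorectal_params(), c(1, 1.1, 1.2), "circ")
#' @export
uniaxial_stress <- function(params, stretch, direction,
                            tension_only = FALSE,
                            legacy_denominator = FALSE) {
  p <- as_material_parameters(params)
  m <- model_terms(p, stretch, match_axis(direction), tension_only,
    legacy_denominator = legacy_denominator
  )
  tibble(
    stretch = stretch,
    s_axial_pa = m$s_axial,
    sigma_true_pa = m$sigma_true,
    p_eng_pa = m$p_eng,
    pressure_pa = m$pressure,
    stilde_11_pa = m$stilde_11,
    stilde_22_pa = m$stilde_22,
    stilde_33_pa = m$stilde_33
  )
}

#' Predict a stress-strain curve
#'
#' Samples the uniaxial model on an engineering-strain grid
#' (`lambda = 1 + strain`) and returns a tidy curve.
#'
#' @inheritParams uniaxial_stress
#' @param strain Numeric vector of engineering strains, non-negative and
#'   strictly increasing.
#' @param stress Which stress measure to report: `"engineering"` (force per
#'   undeformed area; the measure used for published tensile curves) or
#'   `"true"` (Cauchy).
#' @return A tibble with columns `strain`, `stress_pa`, `orientation`.
#' @examples
#' predict_curve(colorectal_params(), seq(0, 0.2, 0.05), "circ")
#' @export
predict_curve <- function(params, strain, direction,
                          stress = c("engineering", "true"),
                          tension_only = FALSE,
                          legacy_denominator = FALSE) {
  stress <- match.arg(stress)
  if (!is.numeric(strain) || length(strain) == 0 || anyNA(strain)) {
    abort("`strain` must be a non-empty numeric vector")
  }
  if (any(strain < 0)) {
    abort("engineering strains must be non-negative")
  }
  if (length(strain) > 1 && any(diff(strain) <= 0)) {
    abort("`strain` must be strictly increasing")
  }
  axis <- match_axis(direction)
  res <- uniaxial_stress(params, 1 + strain, axis,
    tension_only = tension_only, legacy_denominator = legacy_denominator
  )
  tibble(
    strain = strain,
    stress_pa = if (stress == "engineering") res$p_eng_pa else res$sigma_true_pa,
    orientation = axis_label(axis)
  )
}
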