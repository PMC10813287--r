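#' Material parameters of the anisotropic hyperelastic tissue model
#'
#' Bundles the eleven coefficients of the fiber-reinforced Yeoh model:
#' three isotropic matrix coefficients `a1..a3` (Pa), three polynomial
#' coefficients per fiber family `c2..c4` and `e2..e4` (Pa), and the two
#' undeformed fiber angles `beta1`, `beta2` (degrees, measured from the
#' circumferential axis in the circumferential-longitudinal plane). The
#' polynomial orders are fixed: the isotropic sum runs over powers 1..3 of
#' `(I1 - 3)` and each fiber sum over powers 2..4 of `(I4 - 1)` or `(I6 - 1)`.
#'
#' @param a1,a2,a3 Isotropic (Yeoh) coefficients, Pa.
#' @param c2,c3,c4 Coefficients of the first fiber family, Pa.
#' @param e2,e3,e4 Coefficients of the second fiber family, Pa.
#' @param beta1,beta2 Undeformed fiber angles, degrees.
#'
#' @return An object of class `material_parameters`: a named list of the
#'   eleven coefficients.
#' @examples
#' mp <- material_parameters(
#'   a1 = 1.4e5, a2 = -9.6e3, a3 = -2e3,
#'   c2 = 4.9e5, c3 = -3e5, c4 = 6.5e3,
#'   e2 = 3e4, e3 = -3e4, e4 = -740,
#'   beta1 = 0.8, beta2 = 90.1
#' )
#' mp
#' @export
material_parameters <- function(a1, a2, a3, c2, c3, c4, e2, e3, e4,
                                beta1, beta2) {
  vals <- c(
    a1 = a1, a2 = a2, a3 = a3, c2 = c2, c3 = c3, c4 = c4,
    e2 = e2, e3 = e3, e4 = e4, beta1 = beta1, beta2 = beta2
  )
  if (!is.numeric(vals) || length(vals) != 11L || anyNA(vals) ||
      any(!is.finite(vals))) {
    stop("all eleven material parameters must be finite numbers",
      call. = FALSE
    )
  }
  structure(as.list(vals), class = "material_parameters")
}

#' @export
print.material_parameters <- function(x, ...) {
  cat("<material_parameters>\n")
  cat(
    "  isotropic matrix (Pa):  a1 =", format(x$a1), " a2 =", format(x$a2),
    " a3 =", format(x$a3), "\n"
  )
  cat(
    "  fiber family 1   (Pa):  c2 =", format(x$c2), " c3 =", format(x$c3),
    " c4 =", format(x$c4), "  beta1 =", format(x$beta1), "deg\n"
  )
  cat(
    "  fiber family 2   (Pa):  e2 =", format(x$e2), " e3 =", format(x$e3),
    " e4 =", format(x$e4), "  beta2 =", format(x$beta2), "deg\n"
  )
  invisible(x)
}

param_names <- function() {
  c("a1", "a2", "a3", "c2", "c3", "c4", "e2", "e3", "e4", "beta1", "beta2")
}

as_material_parameters <- function(x) {
  if (inherits(x, "material_parameters")) {
    return(x)
  }
  x <- as.list(x)
  missing <- setdiff(param_names(), names(x))
  if (length(missing) > 0) {
    stop(
      "missing material parameters: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(material_parameters, x[param_names()])
}

#' Canonicalize a parameter set
#'
#' The two fiber families enter the strain energy symmetrically, so any
#' parameter set has a label-switching twin (swap `c` with `e` and `beta1`
#' with `beta2`) and each angle is equivalent to its value modulo 180 degrees
#' (a fiber direction and its negative give the same pseudo-invariant).
#' Canonicalization maps both angles into `[0, 180)` and orders the families
#' so `beta1 <= beta2`. The predicted stress response is invariant.
#'
#' @param params A [material_parameters()] object (or coercible named list).
#' @return A `material_parameters` object in canonical form.
#' @examples
#' p <- material_parameters(
#'   a1 = 1e5, a2 = 0, a3 = 0, c2 = 1e4, c3 = 0, c4 = 0,
#'   e2 = 2e4, e3 = 0, e4 = 0, beta1 = 190, beta2 = 3
#' )
#' canonicalize(p) # beta1 = 3 (family swapped), beta2 = 10
#' @export
canonicalize <- function(params) {
  p <- as_material_parameters(params)
  p$beta1 <- p$beta1 %% 180
  p$beta2 <- p$beta2 %% 180
  if (p$beta1 > p$beta2) {
    p[c("c2", "c3", "c4", "e2", "e3", "e4", "beta1", "beta2")] <-
      p[c("e2", "e3", "e4", "c2", "c3", "c4", "beta2", "beta1")]
  }
  p
}

#' Published coefficient set for porcine colorectal tissue
#'
#' Loads the packaged reference coefficients identified for fresh porcine
#' colorectal tissue by two-objective calibration against circumferential and
#' longitudinal uniaxial tensile curves (the balanced Pareto solution). The
#' fitted fiber angles are nearly 0 and 90 degrees, i.e. the two families are
#' almost aligned with the circumferential and longitudinal axes.
#'
#' @return A [material_parameters()] object.
#' @examples
#' colorectal_params()
#' @export
colorectal_params <- function() {
  read_params(system.file("extdata", "porcine_colorectal_params.json",
    package = "colonmech", mustWork = TRUE
  ))
}

#' Read and write parameter files
#'
#' Parameter files are JSON objects with keys `a1..a3`, `c2..c4`, `e2..e4`
#' (Pa) and `beta1_deg`, `beta2_deg` (degrees). Plain `beta1`/`beta2` keys
#' are also accepted on read.
#'
#' @param path File path.
#' @param params A [material_parameters()] object.
#' @return `read_params()` returns a `material_parameters` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$beta1_deg)) x$beta1 <- x$beta1_deg
  if (!is.null(x$beta2_deg)) x$beta2 <- x$beta2_deg
  as_material_parameters(x)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  p <- as_material_parameters(params)
  out <- p[c("a1", "a2", "a3", "c2", "c3", "c4", "e2", "e3", "e4")]
  out$beta1_deg <- p$beta1
  out$beta2_deg <- p$beta2
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
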