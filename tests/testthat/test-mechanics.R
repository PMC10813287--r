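ref <- colorectal_params()

test_that("fiber directions are unit vectors in the tissue plane", {
  expect_equal(fiber_direction(0), c(1, 0, 0))
  expect_equal(fiber_direction(90), c(0, 1, 0), tolerance = 1e-12)
  # near-circumferential family of the fitted coefficient set
  expect_equal(fiber_direction(0.790), c(0.999905, 0.013788, 0),
    tolerance = 1e-5
  )
  for (beta in seq(-350, 350, by = 37.3)) {
    expect_equal(sqrt(sum(fiber_direction(beta)^2)), 1, tolerance = 1e-12)
  }
  expect_error(fiber_direction(NaN), "finite")
})

test_that("incompressible uniaxial kinematics have unit determinant", {
  k <- uniaxial_kinematics(1, "circ")
  expect_equal(k$cbar, diag(3))
  expect_equal(
    diag(uniaxial_kinematics(1.2, "circumferential")$cbar),
    c(1.44, 0.8333333, 0.8333333),
    tolerance = 1e-7
  )
  expect_equal(
    diag(uniaxial_kinematics(1.18, "longitudinal")$cbar),
    c(0.8474576, 1.3924, 0.8474576),
    tolerance = 1e-7
  )
  for (lam in c(0.5, 0.9, 1.01, 1.3, 2.7)) {
    for (dir in 1:2) {
      expect_equal(det(uniaxial_kinematics(lam, dir)$cbar), 1,
        tolerance = 1e-12
      )
    }
  }
  expect_error(uniaxial_kinematics(0, "circ"), "positive")
  expect_error(uniaxial_kinematics(-1, "circ"), "positive")
})

test_that("invariants reduce correctly at the reference state and axis-aligned fibers", {
  inv0 <- invariants(uniaxial_kinematics(1, "circ"), ref)
  expect_equal(inv0$I1bar, 3)
  expect_equal(inv0$I4bar, 1, tolerance = 1e-12)
  expect_equal(inv0$I6bar, 1, tolerance = 1e-12)

  aligned <- material_parameters(
    a1 = 1, a2 = 0, a3 = 0, c2 = 0, c3 = 0, c4 = 0,
    e2 = 0, e3 = 0, e4 = 0, beta1 = 0, beta2 = 90
  )
  inv <- invariants(uniaxial_kinematics(1.2, "circ"), aligned)
  expect_equal(inv$I4bar, 1.44, tolerance = 1e-12) # fiber parallel to load
  expect_equal(inv$I1bar, 3.1066667, tolerance = 1e-7) # lambda^2 + 2/lambda

  # I1 >= 3 for any incompressible state, pseudo-invariants positive
  for (lam in c(0.6, 0.95, 1.2, 1.8)) {
    inv <- invariants(uniaxial_kinematics(lam, "long"), rand_params(7))
    expect_gte(inv$I1bar, 3)
    expect_gt(inv$I4bar, 0)
    expect_gt(inv$I6bar, 0)
  }
})

test_that("strain energy vanishes at the reference state and matches hand sums", {
  for (seed in 1:5) {
    expect_identical(strain_energy(rand_params(seed), 1, "circ"), 0)
  }
  neo <- material_parameters(
    a1 = 1, a2 = 0, a3 = 0, c2 = 0, c3 = 0, c4 = 0,
    e2 = 0, e3 = 0, e4 = 0, beta1 = 0, beta2 = 90
  )
  expect_equal(strain_energy(neo, 1.2, "circ"), 0.1066667, tolerance = 1e-6)

  # full coefficient set against the independent term-by-term summation
  psi <- strain_energy(ref, 1.2, "circ")
  expect_equal(psi, psi_oracle(ref, c(1.44, 1 / 1.2, 1 / 1.2)),
    tolerance = 1e-9
  )
})

test_that("S-tilde components match numerical differentiation of the energy", {
  st0 <- stilde_components(ref, 1, "circ")
  expect_equal(st0$stilde_11, 2 * ref$a1, tolerance = 1e-12)
  expect_equal(st0$stilde_22, 2 * ref$a1, tolerance = 1e-12)
  expect_equal(st0$stilde_33, 2.8e5, tolerance = 1e-12)

  for (case in list(list(ref, 1.2, 1L), list(rand_params(11), 1.15, 2L))) {
    p <- case[[1]]
    lam <- case[[2]]
    axis <- case[[3]]
    cdiag <- rep(1 / lam, 3)
    cdiag[axis] <- lam^2
    st <- stilde_components(p, lam, axis)
    fd <- stilde_oracle(p, cdiag)
    expect_equal(
      c(st$stilde_11, st$stilde_22, st$stilde_33), fd,
      tolerance = 1e-8
    )
  }
})

test_that("the out-of-plane S-tilde component carries no fiber contribution", {
  base <- rand_params(2)
  altered <- base
  altered[c("c2", "c3", "c4", "e2", "e3", "e4")] <-
    list(7e4, -3e4, 2e3, 9e4, -1e4, 5e2)
  altered$beta1 <- 33
  altered$beta2 <- 121
  for (lam in c(0.9, 1.1, 1.25)) {
    expect_equal(
      stilde_components(as_mp(altered), lam, "circ")$stilde_33,
      stilde_components(base, lam, "circ")$stilde_33,
      tolerance = 1e-12
    )
  }
})

test_that("stress vanishes identically at the reference state", {
  for (seed in 1:10) {
    s <- uniaxial_stress(rand_params(seed), 1, sample(1:2, 1))
    expect_identical(s$s_axial_pa, 0)
    expect_identical(s$sigma_true_pa, 0)
    expect_identical(s$p_eng_pa, 0)
  }
})

test_that("fiber-free parameters reproduce the classical Yeoh closed form", {
  yeoh <- material_parameters(
    a1 = 1.2e5, a2 = -8e3, a3 = 2e3, c2 = 0, c3 = 0, c4 = 0,
    e2 = 0, e3 = 0, e4 = 0, beta1 = 10, beta2 = 70
  )
  lam <- seq(0.9, 1.3, by = 0.05)
  got <- uniaxial_stress(yeoh, lam, "circ")$sigma_true_pa
  I1 <- lam^2 + 2 / lam
  dpsi <- yeoh$a1 + 2 * yeoh$a2 * (I1 - 3) + 3 * yeoh$a3 * (I1 - 3)^2
  closed <- 2 * (lam^2 - 1 / lam) * dpsi
  expect_equal(got, closed, tolerance = 1e-9)
})

test_that("swapping the two fiber families leaves all stresses unchanged", {
  for (seed in c(4, 5, 6)) {
    p <- rand_params(seed)
    q <- p
    q[c("c2", "c3", "c4", "beta1", "e2", "e3", "e4", "beta2")] <-
      p[c("e2", "e3", "e4", "beta2", "c2", "c3", "c4", "beta1")]
    lam <- c(0.9, 1.05, 1.2, 1.3)
    for (dir in c("circ", "long")) {
      expect_equal(
        uniaxial_stress(as_mp(q), lam, dir)$s_axial_pa,
        uniaxial_stress(p, lam, dir)$s_axial_pa,
        tolerance = 1e-12
      )
    }
  }
})

test_that("analytic stress agrees with the Lagrange-multiplier oracle", {
  # spot check here; the full 100-parameter-set sweep runs in the
  # acceptance suite
  lams <- c(0.9, 0.97, 1.08, 1.2, 1.3)
  for (seed in 1:10) {
    p <- rand_params(seed)
    for (axis in 1:2) {
      got <- uniaxial_stress(p, lams, axis)$s_axial_pa
      want <- vapply(lams, function(l) stress_oracle(p, l, axis), numeric(1))
      expect_lt(max(rel_diff(got, want, max(abs(want)))), 1e-6)
    }
  }
})

test_that("circumferential engineering stress rises strictly over the tested range", {
  lam <- seq(1, 1.22, length.out = 200)
  peng <- uniaxial_stress(ref, lam, "circ")$p_eng_pa
  expect_true(all(diff(peng) > 0))
})

test_that("predict_curve is a vectorisation of the scalar stress evaluation", {
  expect_equal(predict_curve(ref, 0, "circ")$stress_pa, 0)
  grid <- c(0, 0.07, 0.13, 0.2)
  for (dir in c("circ", "long")) {
    for (kind in c("engineering", "true")) {
      curve <- predict_curve(ref, grid, dir, stress = kind)
      pointwise <- vapply(grid, function(e) {
        s <- uniaxial_stress(ref, 1 + e, dir)
        if (kind == "engineering") s$p_eng_pa else s$sigma_true_pa
      }, numeric(1))
      expect_equal(curve$stress_pa, pointwise)
      expect_equal(nrow(curve), length(grid))
    }
  }
  expect_error(predict_curve(ref, c(-0.1, 0.1), "circ"), "non-negative")
  expect_error(predict_curve(ref, c(0.2, 0.1), "circ"), "increasing")
})

test_that("the alternative pressure-elimination denominator is a distinct mode", {
  s_main <- uniaxial_stress(ref, 1.2, "circ")$p_eng_pa
  s_alt <- uniaxial_stress(ref, 1.2, "circ",
    legacy_denominator = TRUE
  )$p_eng_pa
  expect_gt(abs(s_main - s_alt), 1e3) # materially different predictions
  expect_gt(s_alt, s_main) # weaker pressure correction -> higher stress
})
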