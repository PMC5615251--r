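e0_setting <- function() ref_params(lam = 0, lamN = 0.02)
e1_setting <- function() ref_params(lam = 35, lamN = 0.027)

test_that("E0 closed form and residual", {
  eq <- equilibrium_E0(e0_setting())
  expect_equal(eq$state, c(0, 0.8, 1.2, 0, 0.8, 1.2))
  expect_lt(max(abs(two_cell_rhs(eq$state, e0_setting()))), 1e-10)

  # boundary case lamN = a
  eqb <- equilibrium_E0(notch_params(lam = 0, lamN = 0.012))
  expect_equal(eqb$state[2], 0)
  expect_equal(eqb$state[3], 1.2)

  # lamN < a: equilibrium leaves the orthant but is flagged, not rejected
  expect_warning(eqn <- equilibrium_E0(notch_params(lam = 0, lamN = 0.001)),
                 "orthant")
  expect_lt(eqn$state[2], 0)
  expect_lt(max(abs(two_cell_rhs(eqn$state,
                                 notch_params(lam = 0, lamN = 0.001)))),
            1e-10)
  expect_error(equilibrium_E0(e1_setting()), "lam = 0")
})

test_that("cubic coefficients carry their structural signs", {
  m <- cubic_coefficients(e1_setting())
  expect_lt(m[["m1"]], 0)
  expect_lt(m[["m4"]], 0)
  set.seed(21)
  for (k in 1:20) {
    p <- random_params_E1()
    m <- cubic_coefficients(p)
    expect_lt(m[["m1"]], 0)
    expect_lt(m[["m4"]], 0)
  }
  expect_error(cubic_coefficients(e0_setting()), "lam > 0")
})

test_that("the admissible cubic root is exact, bracketed and branch-stable", {
  p <- e1_setting()
  m <- cubic_coefficients(p)
  A1 <- as.numeric(solve_A1(p))
  resid <- ((m[["m1"]] * A1 + m[["m2"]]) * A1 + m[["m3"]]) * A1 + m[["m4"]]
  expect_lt(abs(resid), 1e-9)
  expect_gt(A1, 0)
  expect_lt(A1, p$a / p$d3)

  # Cardano and companion-matrix routes agree
  expect_equal(as.numeric(solve_A1(p, method = "cardano")),
               as.numeric(solve_A1(p, method = "polyroot")),
               tolerance = 1e-9)

  # continuity: +-1% in lam moves the root smoothly, no branch jump
  grid <- seq(0.99, 1.01, length.out = 21) * p$lam
  roots <- vapply(grid, function(l)
    as.numeric(solve_A1(notch_params(lam = l, lamN = p$lamN))), numeric(1))
  expect_true(all(abs(diff(roots)) < 1e-3))
  expect_true(all(diff(roots) > 0) || all(diff(roots) < 0))
})

test_that("E1 back-substitution is symmetric, exact and has the right limit", {
  p <- e1_setting()
  eq <- equilibrium_E1(p)
  s <- eq$state
  expect_equal(s[1:3], s[4:6])
  expect_lt(max(abs(two_cell_rhs(s, p))), 1e-8)
  expect_gt(s[2], 0)  # admissibility guarantees positive Notch

  # Delta_inh -> 0: D tends to lam/(d1+f1)
  p0 <- notch_params(lam = 2, lamN = 0.05, Delta_inh = 1e-9)
  eq0 <- equilibrium_E1(p0)
  expect_equal(eq0$state[1], p0$lam / (p0$d1 + p0$f1), tolerance = 1e-4)
})

test_that("two-cell Jacobian matches finite differences and the symmetry", {
  p <- e1_setting()
  set.seed(17)
  for (k in 1:20) {
    s <- runif(6, 0.05, 3)
    Ja <- jacobian_two_cell(p, s)
    Jn <- numeric_jacobian(function(z) two_cell_rhs(z, p), s, h = 1e-7)
    expect_equal(Ja, Jn, tolerance = 1e-5)
  }
  # exchanging the cells conjugates the Jacobian
  s <- runif(6, 0.05, 3)
  P <- diag(6)[c(4, 5, 6, 1, 2, 3), ]
  expect_equal(jacobian_two_cell(p, s[c(4, 5, 6, 1, 2, 3)]),
               P %*% jacobian_two_cell(p, s) %*% t(P))
  # the Delta-production column entry at E1 is -Delta*lam/(1+Delta*A)^2
  eq <- equilibrium_E1(p)
  J <- jacobian_two_cell(p, eq$state)
  expect_equal(J[1, 3],
               -p$Delta_inh * p$lam / (1 + p$Delta_inh * eq$state[3])^2)
  expect_error(jacobian_two_cell(p, c(0, 0, 1, 1, 1, 1)), "singular")
})

test_that("E0 is stable with the factorized eigenvalue multiset", {
  rep0 <- stability_E0(e0_setting())
  expect_identical(rep0$verdict, "stable")
  expect_equal(sort(Re(rep0$eigenvalues)),
               sort(c(-0.675, -0.675, -0.01, -0.01, -0.01, -0.01)),
               tolerance = 1e-10)
  expect_true(all(abs(Im(rep0$eigenvalues)) < 1e-12))

  set.seed(31)
  for (k in 1:25) {
    p <- random_params_E0()
    r <- stability_E0(p)
    expect_identical(r$verdict, "stable")
    expect_equal(sort(Re(r$eigenvalues)), sort(r$closed_form_eigenvalues),
                 tolerance = 1e-8)
  }
})

test_that("cubic factor coefficients match the numeric characteristic polynomial", {
  # elementary-symmetric-function oracle for det(S*I - M) of a 3x3 block
  char_coefs <- function(M) {
    c1 <- M[1, 1] * M[2, 2] + M[1, 1] * M[3, 3] + M[2, 2] * M[3, 3] -
      (M[1, 2] * M[2, 1] + M[1, 3] * M[3, 1] + M[2, 3] * M[3, 2])
    c(M1 = -sum(diag(M)), M2 = c1, M3 = -det(M))
  }
  set.seed(41)
  for (k in 1:10) {
    p <- random_params_E1()
    r <- stability_E1(p)
    J <- r$jacobian
    B <- J[1:3, 1:3]
    C <- matrix(0, 3, 3); C[2, 1] <- p$f2
    plus <- char_coefs(B + C); minus <- char_coefs(B - C)
    expect_equal(unname(plus["M1"]), r$M1, tolerance = 1e-10)
    expect_equal(unname(plus["M2"]), r$M2, tolerance = 1e-10)
    expect_equal(unname(plus["M3"]), r$M3, tolerance = 1e-10)
    expect_equal(unname(minus["M2"]), r$M2, tolerance = 1e-10)
    expect_equal(unname(minus["M3"]), r$M3prime, tolerance = 1e-10)
  }
})

test_that("Routh-Hurwitz verdict matches the numeric spectrum", {
  r <- stability_E1(e1_setting())
  expect_identical(r$verdict, "stable")
  expect_lt(r$ratio, 1)
  expect_lt(r$max_re, 0)
  expect_gt(r$M3, r$M3prime)  # strict whenever f2 > 0

  set.seed(37)
  for (k in 1:25) {
    p <- random_params_E1()
    r <- stability_E1(p)
    expect_gt(r$M3, r$M3prime)
    if (abs(r$margin) > 1e-8) {
      expect_identical(r$verdict, if (r$margin > 0) "stable" else "unstable")
      expect_identical(r$max_re < 0, r$verdict == "stable")
    }
  }
})

test_that("small kicks off a stable equilibrium relax back by t = 1500", {
  p <- e1_setting()
  eq <- equilibrium_E1(p)
  kick <- eq$state * (1 + c(1, -1, 1, -1, 1, -1) * 1e-3)
  init <- kick[c(1, 4, 2, 5, 3, 6)]  # (D,D,N,N,A,A) lattice layout
  sim <- simulate_two_cell(p, t_end = 1500, init = init)
  expect_lt(max(abs(sim$final_e - eq$state)), 1e-4)
})
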