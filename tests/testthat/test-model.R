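test_that("conversion flux follows the saturating cis-inhibited form", {
  # Delta-free cell converts at the full rate a
  expect_equal(conversion_flux(0, 0.5, 0.012, 69), 0.012)
  # empty cell converts nothing (guarded 0/0)
  expect_equal(conversion_flux(0, 0, 0.012, 69), 0)
  expect_equal(conversion_flux(0, 0, 0.5, 3), 0)
  # direct substitution
  expect_equal(conversion_flux(1, 1, 0.012, 69), 0.012 / 70)
  # vectorized and bounded by a on the non-negative orthant
  set.seed(7)
  D <- runif(100, 0, 5); N <- runif(100, 0, 5)
  fl <- conversion_flux(D, N, 0.012, 69)
  expect_length(fl, 100)
  expect_true(all(fl >= 0 & fl <= 0.012))
})

test_that("zero state yields pure production derivatives", {
  lat <- ref_lattice()
  p <- ref_params(lam = 9, lamN = 0.008)
  pp <- prepattern(lat, 9, 3)
  d <- notch_rhs(rep(0, 180), p, lat, pp)
  n <- lat$n_cells
  dD <- d[1:n]; dN <- d[n + 1:n]; dA <- d[2 * n + 1:n]
  expect_equal(dD, ifelse(lat$row_of <= 3, 0, 9))
  expect_equal(dN, rep(0.008, n))
  expect_equal(dA, rep(0, n))
})

test_that("conversion cancels in the N + A balance", {
  lat <- ref_lattice()
  p <- ref_params(lam = 9, lamN = 0.0005)
  pp <- prepattern(lat, 9, 3)
  set.seed(11)
  n <- lat$n_cells
  for (rep in 1:5) {
    s <- random_state(n)
    d <- notch_rhs(s, p, lat, pp)
    dN <- d[n + 1:n]; dA <- d[2 * n + 1:n]
    lhs <- dN + dA
    rhs <- p$lamN - p$d2 * s[, "N"] +
      p$f2 * as.vector(lat$adjacency %*% s[, "D"]) - p$d3 * s[, "A"]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("two-cell field agrees with the lattice field on a 1x2 ring", {
  p <- ref_params(lam = 35, lamN = 0.027)
  lat2 <- hex_lattice(1, 2, wrap_columns = TRUE)
  expect_identical(lat2$neighbors, list(2L, 1L))
  set.seed(3)
  perm <- c(1, 3, 5, 2, 4, 6)  # (D1,D2,N1,N2,A1,A2) -> (D1,N1,A1,D2,N2,A2)
  for (k in 1:100) {
    e_state <- runif(6, 0.01, 4)        # (D1,N1,A1,D2,N2,A2)
    block <- e_state[c(1, 4, 2, 5, 3, 6)]  # (D,D,N,N,A,A) lattice layout
    d_lat <- notch_rhs(block, p, lat2, rep(p$lam, 2))
    d_two <- two_cell_rhs(e_state, p)
    expect_equal(d_lat[perm], d_two, tolerance = 1e-12)
  }
})

test_that("two-cell field has exchange symmetry and lam = 0 Delta decay", {
  p <- ref_params(lam = 2, lamN = 0.01)
  s <- c(0.4, 1.2, 0.3, 0.4, 1.2, 0.3)
  d <- two_cell_rhs(s, p)
  expect_equal(d[1:3], d[4:6])

  p0 <- ref_params(lam = 0, lamN = 0.05)
  for (k in 1:5) {
    s <- runif(6, 0.01, 2)
    d <- two_cell_rhs(s, p0)
    expect_equal(d[1], -(p0$d1 + p0$f1) * s[1])
    expect_equal(d[4], -(p0$d1 + p0$f1) * s[4])
  }
})

test_that("analytic lattice Jacobian matches central finite differences", {
  lat <- hex_lattice(3, 4)
  p <- ref_params(lam = 5, lamN = 0.01)
  pp <- prepattern(lat, 5, 1)
  vf <- notchsim:::make_vector_field(p, lat, pp)
  set.seed(5)
  for (k in 1:5) {
    y <- as.vector(random_state(lat$n_cells, min = 0.1, max = 2))
    Ja <- vf$jac(0, y, NULL)
    Jn <- numeric_jacobian(function(z) vf$rhs(0, z, NULL)[[1]], y, h = 1e-6)
    expect_equal(Ja, Jn, tolerance = 1e-5)
  }
})

test_that("column rotation of a wrapped lattice permutes the field", {
  lat <- ref_lattice()
  p <- ref_params(lam = 9, lamN = 0.0005)
  pp <- prepattern(lat, 9, 3)
  n <- lat$n_cells
  # rotate every row one column to the right
  sigma <- (lat$row_of - 1L) * lat$n_cols + (lat$col_of %% lat$n_cols) + 1L
  set.seed(9)
  s <- random_state(n)
  d <- notch_rhs(s, p, lat, pp)
  s_rot <- s[order(sigma), , drop = FALSE]  # state moved onto rotated cells
  d_rot <- notch_rhs(s_rot, p, lat, pp)
  for (blk in 0:2) {
    expect_equal(d_rot[blk * n + 1:n], d[blk * n + 1:n][order(sigma)],
                 tolerance = 1e-12)
  }
})

test_that("overrides shift per-cell parameters and reject bad input", {
  lat <- hex_lattice(2, 3)
  p <- ref_params(lam = 1, lamN = 0.01)
  n <- lat$n_cells
  off <- seq(-0.001, 0.001, length.out = n)
  ov <- cellwise_override("a", off)
  s <- random_state(n, 0.2, 1)
  d0 <- notch_rhs(s, p, lat, rep(1, n))
  d1 <- notch_rhs(s, p, lat, rep(1, n), overrides = ov)
  cf0 <- conversion_flux(s[, "D"], s[, "N"], p$a, p$b)
  cf1 <- conversion_flux(s[, "D"], s[, "N"], p$a + off, p$b)
  expect_equal(d1[2 * n + 1:n] - d0[2 * n + 1:n], cf1 - cf0)
  # f override applies to both the cell's Delta loss and its Notch gain
  ovf <- cellwise_override("f", rep(0.1, n))
  df <- notch_rhs(s, p, lat, rep(1, n), overrides = ovf)
  deg <- lengths(lat$neighbors)
  expect_equal(df[1:n] - d0[1:n], -deg * 0.1 * s[, "D"])
  expect_equal(df[n + 1:n] - d0[n + 1:n],
               0.1 * as.vector(lat$adjacency %*% s[, "D"]))
  # wrong length and negative effective parameter are configuration errors
  expect_error(notch_rhs(s, p, lat, rep(1, n),
                         overrides = cellwise_override("a", rep(0, 5))),
               "length")
  expect_error(notch_rhs(s, p, lat, rep(1, n),
                         overrides = cellwise_override("a", rep(-1, n))),
               "negative")
})

test_that("uniform override sampling respects bounds and resampling", {
  p <- ref_params()
  set.seed(123)
  ov <- sample_override("a", 1e-4, 500, p)
  expect_true(all(abs(ov$offsets) <= 1e-4))
  expect_true(all(p$a + ov$offsets >= 0))
  # epsilon larger than the parameter: resampling keeps effective value >= 0
  ovb <- sample_override("lamN", 0.5, 500, notch_params(lamN = 0.2))
  expect_true(all(0.2 + ovb$offsets >= 0))
  expect_true(all(abs(ovb$offsets) <= 0.5))
})
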