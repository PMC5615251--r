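test_that("sweeps are deterministic, ordered and record transitions", {
  lat <- ref_lattice()
  p <- ref_params(lam = 9)
  sw1 <- sweep_parameter(p, lat, "lamN", values = c(0, 1e-4, 2e-4))
  sw2 <- sweep_parameter(p, lat, "lamN", values = c(0, 1e-4, 2e-4))
  expect_identical(sw1$results, sw2$results)
  expect_identical(sw1$transitions, sw2$transitions)
  # the Notch-production onset: dorsal rows light up at the first positive value
  expect_equal(sw1$results$boundary_count, c(12L, 36L, 36L))
  expect_equal(nrow(sw1$transitions), 1L)
  expect_equal(sw1$transitions$value, 1e-4)

  # empty grid
  sw0 <- sweep_parameter(p, lat, "lam", lo = 1, hi = 0, step = 0.1)
  expect_length(sw0$grid, 0)
  expect_equal(nrow(sw0$results), 0L)
  expect_error(sweep_parameter(p, lat, "lam", values = c(2, 1)),
               "increasing")
})

test_that("sweep_threshold reads off smallest/largest matching grid values", {
  lat <- ref_lattice()
  sw <- sweep_parameter(ref_params(lam = 9), lat, "lamN",
                        values = c(0, 1e-4, 2e-4))
  expect_equal(sweep_threshold(sw, 1:3, "smallest"), 1e-4)
  expect_equal(sweep_threshold(sw, 3, "largest"), 2e-4)
  expect_true(is.na(sweep_threshold(sw, 1:5, "smallest")))
})

test_that("zero perturbation reproduces the deterministic run; seeds pin replicates", {
  lat <- ref_lattice()
  p <- ref_params(lam = 9, lamN = 0.008)
  pp <- prepattern(lat, 9, 3)
  base <- simulate_phenotype(p, lat, pp)$boundary_count
  c0 <- perturb_once(p, lat, pp, target = "a", epsilon = 0, seed = 4)
  expect_equal(as.integer(c0), base)
  c1 <- perturb_once(p, lat, pp, target = "a", epsilon = 1e-4, seed = 99)
  c2 <- perturb_once(p, lat, pp, target = "a", epsilon = 1e-4, seed = 99)
  expect_identical(as.integer(c1), as.integer(c2))
  expect_identical(attr(c1, "override")$offsets, attr(c2, "override")$offsets)
})

test_that("perturbation summaries follow the replicate mean/variance formulas", {
  lat <- ref_lattice()
  p <- ref_params(lam = 9, lamN = 0.008)
  pp <- prepattern(lat, 9, 3)
  st <- perturbation_study(p, lat, pp, target = "b",
                           epsilons = c(0.01, 0.2), K = 4, seed = 8)
  expect_equal(dim(st$counts), c(4L, 2L))
  for (j in 1:2) {
    y <- st$counts[, j]
    expect_equal(st$summary$mean[j], sum(y) / length(y))
    expect_equal(st$summary$variance[j],
                 sum((y - mean(y))^2) / (length(y) - 1))
    expect_equal(st$summary$standard_error[j],
                 sqrt(st$summary$variance[j] / length(y)))
    # textbook two-pass computation agrees
    expect_equal(st$summary$variance[j], stats::var(y))
  }
  # reproducible child seeds
  st2 <- perturbation_study(p, lat, pp, target = "b",
                            epsilons = c(0.01, 0.2), K = 4, seed = 8)
  expect_identical(st$counts, st2$counts)
  expect_identical(st$seeds, st2$seeds)
})

test_that("zero-width Notch-production noise equals the deterministic phenotype", {
  lat <- ref_lattice()
  p <- ref_params(lam = 0.3, lamN = 5e-4)
  pp <- prepattern(lat, 0.3, 3)
  det <- simulate_phenotype(p, lat, pp)
  noisy <- simulate_with_lamN_noise(p, lat, pp, half_width = 0, seed = 5)
  expect_identical(noisy$boundary_mask, det$boundary_mask)
  # sampled offsets respect the half-width and keep rates non-negative
  ph <- simulate_with_lamN_noise(p, lat, pp, half_width = 5e-4, seed = 6)
  off <- attr(ph, "override")$offsets
  expect_true(all(abs(off) <= 5e-4))
  expect_true(all(p$lamN + off >= 0))
})
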