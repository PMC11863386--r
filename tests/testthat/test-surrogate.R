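test_that("state ensembles honor the generator contract", {
  # zero-variance state gives identical rows
  sp <- state_spec("RS", feature_means = 3.0, feature_sds = 0.0,
                   class = 0L)
  ens <- generate_state_ensembles(list(sp), 5, seed = 1)
  expect_equal(ens$f1, rep(3.0, 5))
  expect_equal(ens$class, rep(0L, 5))

  # determinism: same seed, byte-identical tables
  specs <- surrogate_state_specs(6)
  a <- generate_state_ensembles(specs, 50, seed = 42)
  b <- generate_state_ensembles(specs, 50, seed = 42)
  expect_identical(a, b)
  c <- generate_state_ensembles(specs, 50, seed = 43)
  expect_false(identical(a, c))

  # law of large numbers against the generator's own parameters
  n <- 1e4
  ens <- generate_state_ensembles(specs, n, seed = 7)
  for (s in specs) {
    sub <- as.matrix(ens[ens$state == s$label, paste0("f", 1:6)])
    expect_true(all(abs(colMeans(sub) - s$feature_means) <
                      5 * s$feature_sds / sqrt(n)))
  }

  # per-replica mode partitions rows
  pr <- generate_state_ensembles(specs, 16, seed = 1,
                                 mode = "per_replica", n_replicas = 8)
  expect_true("replica" %in% names(pr))
  expect_equal(sort(unique(pr$replica)), 1:8)
})

test_that("ensemble argument errors are reported", {
  specs <- list(state_spec("RS", c(1, 2), c(0.1, 0.1), 0L),
                state_spec("INT", 1, 0.1, 1L))
  expect_error(generate_state_ensembles(specs, 10, 1), "dimensionality")
  expect_error(generate_state_ensembles(list(specs[[1]]), 1, 1),
               "argument error")
  expect_error(state_spec("RS", c(1, 2), 0.1), "identical length")
})

test_that("unbiased Langevin sampling is Boltzmann-consistent", {
  # harmonic well, kT = 1: closed-form variance of x is 1
  pot <- surrogate_potential(poly = c(0, 0, 0.5), basin_centers = 0)
  tr <- langevin_sample(pot, langevin_config(timestep = 0.02,
                                             friction = 2,
                                             n_steps = 5e5, seed = 4))
  expect_lt(abs(var(tr$positions) - 1), 0.05)

  # zero-temperature limit started at the minimum stays there
  tr0 <- langevin_sample(pot, langevin_config(timestep = 0.01, kT = 0,
                                              n_steps = 1000, seed = 1,
                                              initial_position = 0))
  expect_lt(max(abs(tr0$positions)), 1e-8)

  # histogram converges to the Boltzmann density of the potential
  dw <- double_well(barrier = 3)
  tr <- langevin_sample(dw, langevin_config(timestep = 0.01,
                                            friction = 1, n_steps = 4e5,
                                            seed = 9,
                                            initial_position = -1))
  grid <- seq(-2, 2, length.out = 60)
  fx <- exact_fes(dw, grid)
  p_exact <- exp(-fx$free_energy); p_exact <- p_exact / sum(p_exact)
  edges <- c(grid - diff(grid)[1] / 2, max(grid) + diff(grid)[1] / 2)
  h <- tabulate(findInterval(tr$positions, edges), nbins = 60)
  p_emp <- h / sum(h)
  expect_lt(sqrt(mean((p_emp - p_exact)^2)), 3 * 0.002)
})

test_that("identical seeds give identical trajectories", {
  pot <- double_well(barrier = 5)
  cfg <- langevin_config(timestep = 0.01, n_steps = 2000, seed = 31,
                         initial_position = -1)
  t1 <- langevin_sample(pot, cfg)
  t2 <- langevin_sample(pot, cfg)
  expect_identical(t1$positions, t2$positions)
})

test_that("divergent trajectories raise an integration error", {
  # inverted quartic: unbounded below, walker escapes
  bad <- surrogate_potential(poly = c(0, 0, 0, 0, -1), basin_centers = 1)
  expect_error(
    langevin_sample(bad, langevin_config(timestep = 0.05, n_steps = 1e4,
                                         seed = 1,
                                         initial_position = 1.5)),
    "step")
})

test_that("exact_fes matches construction, symmetry and flatness", {
  dw <- double_well(barrier = 10)
  g <- seq(-2, 2, length.out = 801)
  f <- exact_fes(dw, g)
  expect_equal(min(f$free_energy), 0)
  # symmetric double well: F(x) = F(-x)
  expect_lt(max(abs(f$free_energy - rev(f$free_energy))), 1e-8)

  # constructed 10 kT barrier recovered; fine grid so that bin-averaging
  # error is below 1e-6
  gf <- seq(-1.02, 1.02, by = 1e-4)
  ff <- exact_fes(double_well(barrier = 10), gf, n_quad = 8)
  barrier_est <- ff$free_energy[which.min(abs(gf))] -
    min(ff$free_energy)
  expect_lt(abs(barrier_est - 10), 1e-6)

  # flat potential: constant FES within quadrature tolerance
  flat <- surrogate_potential(poly = 0, basin_centers = 0)
  fl <- exact_fes(flat, seq(-1, 1, length.out = 100))
  expect_lt(diff(range(fl$free_energy)), 1e-10)

  # grid excluding a basin is a coverage error
  expect_error(exact_fes(dw, seq(0, 2, length.out = 50)), "coverage")
})

test_that("spectator-charge barrier shifts are linear in q", {
  g <- seq(-2, 2, length.out = 1001)
  ddg <- vapply(c(0.5, 1, 2, 3), function(q) {
    fq <- exact_fes(double_well(10, q = q), g)
    f0 <- exact_fes(double_well(10, q = 0), g)
    bq <- fq$free_energy[which.min(abs(g))] -
      min(fq$free_energy[g < -0.4])
    b0 <- f0$free_energy[which.min(abs(g))] -
      min(f0$free_energy[g < -0.4])
    bq - b0
  }, numeric(1))
  fit <- summary(lm(ddg ~ c(0.5, 1, 2, 3)))
  expect_gt(fit$r.squared, 0.99)

  # a charge chosen for a 1 kT shift produces exactly that shift in the
  # quadrature FES
  shift_of <- function(q) {
    fq <- exact_fes(double_well(10, q = q), g)
    f0 <- exact_fes(double_well(10), g)
    (fq$free_energy[which.min(abs(g))] - min(fq$free_energy[g < -0.4])) -
      (f0$free_energy[which.min(abs(g))] - min(f0$free_energy[g < -0.4]))
  }
  q1 <- uniroot(function(q) shift_of(q) - 1, c(0.5, 1.5), tol = 1e-10)$root
  expect_lt(abs(shift_of(q1) - 1), 1e-8)
})
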