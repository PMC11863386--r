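# minimal hand-built biased-trajectory object for estimator unit tests
fake_traj <- function(x, bias = 0 * x, rct = rep(0, length(x))) {
  structure(list(positions = matrix(x, ncol = 1),
                 cv = matrix(x, ncol = 1),
                 bias = matrix(bias, ncol = 1),
                 wall = matrix(0, length(x), 1),
                 rct = rct,
                 config = opes_config(barrier = 10, n_steps = length(x)),
                 step = seq_along(x)),
            class = "opes_trajectory")
}

test_that("burn-in detection follows the stabilization rule", {
  # constant series: nothing discarded
  expect_equal(detect_burn_in(rep(2, 100)), 1L)

  # saturating series with tau = 5% of the run stabilizes near 3 tau
  n <- 1000; tau <- 0.05 * n
  s <- 1 - exp(-(1:n) / tau)
  r <- detect_burn_in(s)
  expect_gt(r, 2 * tau)
  expect_lt(r, 4 * tau)

  # production convention: a 100-update run discards about the first 5
  n <- 100; tau <- 5 / 3
  r <- detect_burn_in(1 - exp(-(1:n) / tau))
  expect_gte(r, 2); expect_lte(r, 8)

  # never-stabilizing series: capped with a warning
  expect_warning(rc <- detect_burn_in(1:100), "never stabilized")
  expect_equal(rc, 25)

  expect_error(detect_burn_in(1:5), "at least 10")
})

test_that("zero bias reduces reweighting to a plain histogram", {
  set.seed(14)
  x <- rnorm(20000)
  grid <- seq(-3, 3, length.out = 61)
  f <- reweighted_fes(list(fake_traj(x)), grid)
  edges <- c(grid - diff(grid)[1] / 2, max(grid) + diff(grid)[1] / 2)
  h <- tabulate(findInterval(x, edges), nbins = 61)
  manual <- ifelse(h > 0, -log(h), NA_real_)
  manual <- manual - min(manual, na.rm = TRUE)
  expect_equal(f$free_energy, manual)
  # identical replicates have zero SEM
  f2 <- reweighted_fes(list(fake_traj(x), fake_traj(x)), grid)
  expect_true(all(f2$sem == 0))
  expect_equal(f2$n_replicates, 2L)
})

test_that("reweighted biased runs recover the quadrature truth", {
  dw <- double_well(barrier = 8)
  cfg <- opes_config(barrier = 32, n_steps = 5e4)
  run <- discard_burn_in(run_opes(dw, cfg, seed = 17))
  grid <- seq(-1.8, 1.8, length.out = 150)
  fe <- reweighted_fes(list(run), grid)
  fx <- exact_fes(dw, grid)
  sel <- fx$free_energy < 6 & !is.na(fe$free_energy)
  expect_lt(sqrt(mean((fe$free_energy[sel] - fx$free_energy[sel])^2)),
            0.25)
})

test_that("estimator error shrinks with budget", {
  dw <- double_well(barrier = 6)
  grid <- seq(-1.8, 1.8, length.out = 100)
  fx <- exact_fes(dw, grid)
  rmse_at <- function(steps, seed) {
    cfg <- opes_config(barrier = 24, n_steps = steps, n_walkers = 4)
    fe <- reweighted_fes(list(discard_burn_in(run_opes(dw, cfg,
                                                       seed = seed))),
                         grid)
    sel <- fx$free_energy < 5 & !is.na(fe$free_energy)
    sqrt(mean((fe$free_energy[sel] - fx$free_energy[sel])^2))
  }
  expect_lt(rmse_at(8e4, 23), rmse_at(2e4, 23))
})

test_that("state energetics are extracted relative to RS", {
  # constructed profile: minima at 0 and 5 kT, barrier maximum at 12 kT
  grid <- seq(-2, 2, length.out = 401)
  # piecewise quadratic wells at -1 (bottom 0) and +1 (bottom 5),
  # meeting at the 12 kT barrier top at 0
  f <- ifelse(grid < 0, 12 * pmin((grid + 1)^2, 1),
              5 + 7 * pmin((grid - 1)^2, 1))
  prof <- fes_profile(grid, f, sem = rep(0.1, length(grid)))
  se <- extract_state_energies(prof, list(RS = c(-1.6, -0.4),
                                          TS = c(-0.4, 0.4),
                                          PS = c(0.4, 1.6)))
  expect_equal(se$dG[se$transition == "RS->TS"], 12)
  expect_equal(se$dG[se$transition == "RS->PS"], 5)
  expect_equal(se$sem, rep(sqrt(0.1^2 + 0.1^2), 2))

  # flat profile has no interior extremum
  flat <- fes_profile(grid, rep(1, length(grid)))
  expect_error(extract_state_energies(flat, list(RS = c(-1.6, -0.4),
                                                 TS = c(-0.4, 0.4))),
               "extraction error")
})

test_that("ddG entries negate exactly under run swap", {
  grid <- seq(-2, 2, length.out = 201)
  mk <- function(b) {
    f <- ifelse(grid < 0, b * pmin((grid + 1)^2, 1),
                2 + (b - 2) * pmin((grid - 1)^2, 1))
    extract_state_energies(fes_profile(grid, f, rep(0.05, length(grid))),
                           list(RS = c(-1.6, -0.4), TS = c(-0.4, 0.4),
                                PS = c(0.4, 1.6)))
  }
  a <- mk(12); b <- mk(9)
  ab <- delta_delta_g(a, b); ba <- delta_delta_g(b, a)
  expect_identical(ab$ddG, -ba$ddG)
  expect_identical(ab$sem, ba$sem)
})

test_that("degeneracy audit separates faithful and degenerate CVs", {
  set.seed(30)
  # faithful case: the CV is the rational coordinate itself
  x <- c(rnorm(4000, -1, 0.2), rnorm(4000, 1, 0.2),
         rnorm(800, 0, 0.1))
  rat <- rational_variable("coord", x, ts_window = c(-0.3, 0.3))
  a <- degeneracy_audit(x, rat, ts_cv_window = c(-0.3, 0.3))
  expect_equal(a$status, "pass")

  # planted degeneracy: two rational basins map to one CV value, the
  # spurious one 2 kT deeper than the true TS
  ts_n <- 400
  cv_ts <- rnorm(ts_n, 0, 0.05)
  rat_true <- rnorm(ts_n / 2, 0, 0.05)
  rat_spur <- rnorm(ts_n / 2, 2, 0.05)
  w_ts <- c(rep(1, ts_n / 2), rep(exp(2), ts_n / 2))
  cv_all <- c(rnorm(4000, -10, 0.4), rnorm(4000, 10, 0.4), cv_ts)
  rat_all <- c(rnorm(4000, -1, 0.1), rnorm(4000, 1, 0.1), rat_true,
               rat_spur)
  w_all <- c(rep(1, 8000), w_ts)
  rat2 <- rational_variable("proton", rat_all, ts_window = c(-0.3, 0.3))
  d <- degeneracy_audit(cv_all, rat2, weights = w_all,
                        ts_cv_window = c(-1, 1))
  expect_equal(d$status, "fail")
  expect_gt(d$undercut, 1)

  # empty TS occupancy is inconclusive, not a verdict
  cv3 <- c(rnorm(1000, -10, 0.3), rnorm(1000, 10, 0.3))
  rat3 <- rational_variable("d", rnorm(2000), c(-0.5, 0.5))
  e <- degeneracy_audit(cv3, rat3, ts_cv_window = c(-1, 1))
  expect_equal(e$status, "inconclusive")
})

test_that("profiles serialize with the min-shift convention", {
  grid <- seq(0, 1, length.out = 11)
  p <- fes_profile(grid, 5 + (grid - 0.5)^2)
  expect_equal(min(p$free_energy), 0)
  path <- tempfile(fileext = ".csv")
  write_fes_csv(p, path)
  back <- read.csv(path)
  expect_equal(back$free_energy, p$free_energy)
})
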