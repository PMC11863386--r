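#' Configuration for the adaptive-bias (OPES explore) sampler
#'
#' Parameters of the on-the-fly probability enhanced-sampling scheme in
#' its "explore" variant: the bias is built from a kernel-density
#' estimate of the *sampled* collective-variable distribution,
#' \deqn{V(s) = (\gamma - 1)\,kT\,\log(\hat P(s)/Z + \epsilon)}
#' with bias factor \eqn{\gamma = \Delta E / kT} set by the barrier
#' parameter \eqn{\Delta E}, regularizer
#' \eqn{\epsilon = e^{-\Delta E/((\gamma-1) kT)}} (which bounds the bias
#' depth by the barrier parameter), and normalization \eqn{Z} estimated
#' as the mean kernel density over the deposited kernel centers. The
#' reference conditions mirror a production setup of 8 parallel walkers
#' sharing one bias, deposits every 200 steps, and a kernel-width floor
#' of 0.3 CV units.
#'
#' @param barrier barrier parameter \eqn{\Delta E} in energy units;
#'   should exceed the highest barrier to be crossed.
#' @param pace steps between kernel deposits.
#' @param sigma_min kernel-width floor in CV units.
#' @param n_walkers number of parallel walkers sharing the bias.
#' @param n_steps steps per walker.
#' @param dt integration timestep (reduced time units).
#' @param friction Langevin friction (inverse time).
#' @param mass particle mass.
#' @param kT thermal energy.
#' @param merge_threshold kernels closer than this are merged; `NULL`
#'   (default) uses the current adaptive bandwidth.
#' @param stride recording stride for trajectory frames.
#' @return an object of class `opes_config`.
#' @export
opes_config <- function(barrier, pace = 200L, sigma_min = 0.3,
                        n_walkers = 8L, n_steps = 1e5L, dt = 0.005,
                        friction = 1, mass = 1, kT = 1,
                        merge_threshold = NULL, stride = 1L) {
  stopifnot(barrier > 0, pace >= 1, sigma_min > 0, n_walkers >= 1,
            dt > 0, friction > 0, kT > 0)
  gamma <- barrier / kT
  if (gamma <= 1) stop("barrier parameter must exceed kT (bias factor > 1)")
  structure(list(barrier = barrier, pace = as.integer(pace),
                 sigma_min = sigma_min, n_walkers = as.integer(n_walkers),
                 n_steps = as.integer(n_steps), dt = dt,
                 friction = friction, mass = mass, kT = kT,
                 merge_threshold = merge_threshold,
                 stride = as.integer(stride), gamma = gamma,
                 pref = (gamma - 1) * kT,
                 epsilon = exp(-barrier / ((gamma - 1) * kT))),
            class = "opes_config")
}

#' Create an empty bias state
#'
#' The bias state holds the deposited kernels (center, width, height),
#' the running normalization estimate \eqn{Z_n}, and the time series of
#' the reweighting offset \eqn{c(t)} used to detect bias stabilization
#' (burn-in) and to reweight frames.
#'
#' @param config an [opes_config()].
#' @param grid CV grid over which \eqn{c(t)} is evaluated at each
#'   deposit.
#' @return an object of class `bias_state`.
#' @export
new_bias_state <- function(config, grid) {
  stopifnot(inherits(config, "opes_config"), length(grid) >= 2)
  structure(list(kernels = data.frame(center = numeric(0),
                                      width = numeric(0),
                                      height = numeric(0)),
                 Z = 1, normalization_series = numeric(0),
                 rct_series = numeric(0), grid = as.numeric(grid),
                 n_samples = 0L, sum_s = 0, sum_s2 = 0),
            class = "bias_state")
}

# kernel-density estimate of the sampled CV distribution at s
.opes_density <- function(s, kernels) {
  if (nrow(kernels) == 0) return(rep(0, length(s)))
  H <- sum(kernels$height)
  out <- numeric(length(s))
  for (j in seq_len(nrow(kernels))) {
    out <- out + kernels$height[j] *
      stats::dnorm(s, kernels$center[j], kernels$width[j])
  }
  out / H
}

#' Bias energy at a CV value
#'
#' Evaluates \eqn{V(s) = (\gamma-1) kT \log(\hat P(s)/Z + \epsilon)}.
#' With an empty kernel list the bias is the constant baseline 0 (the
#' bias is defined up to a constant).
#'
#' @param s CV value(s).
#' @param state a [new_bias_state()] object.
#' @param config an [opes_config()].
#' @return bias energy, finite for every `s`, vectorized.
#' @export
bias_energy <- function(s, state, config) {
  stopifnot(inherits(state, "bias_state"), inherits(config, "opes_config"))
  if (nrow(state$kernels) == 0) return(rep(0, length(s)))
  P <- .opes_density(s, state$kernels)
  config$pref * log(P / state$Z + config$epsilon)
}

#' Deposit walker CV values into the bias
#'
#' Called every `pace` steps with one current CV value per walker.
#' Each value becomes a kernel with adaptive bandwidth
#' \eqn{\max(\hat\sigma\, n^{-1/5}, \sigma_{min})} (Silverman-style
#' shrinkage of the running CV spread, floored at the configured
#' minimum). A new kernel closer than the merge threshold to an existing
#' one is merged into it (height-weighted mean center, pooled width),
#' keeping the kernel count bounded. The normalization \eqn{Z} is
#' re-estimated as the mean density over kernel centers and the
#' reweighting offset \eqn{c(t) = kT \log \langle e^{V(s)/kT}
#' \rangle_{grid}} is appended.
#'
#' @param s_values numeric vector, one CV value per walker.
#' @param state a `bias_state`.
#' @param config an [opes_config()].
#' @return the updated `bias_state`.
#' @export
deposit <- function(s_values, state, config) {
  stopifnot(inherits(state, "bias_state"), inherits(config, "opes_config"))
  bad <- which(!is.finite(s_values))
  if (length(bad) > 0) {
    stop("non-finite CV value from walker ", bad[1], " (sampler error)")
  }
  state$n_samples <- state$n_samples + length(s_values)
  state$sum_s <- state$sum_s + sum(s_values)
  state$sum_s2 <- state$sum_s2 + sum(s_values^2)
  n <- state$n_samples
  var_hat <- if (n >= 2) {
    max(0, (state$sum_s2 - state$sum_s^2 / n) / (n - 1))
  } else 0
  width <- max(sqrt(var_hat) * n^(-1 / 5), config$sigma_min)
  thr <- if (is.null(config$merge_threshold)) width else config$merge_threshold

  kern <- state$kernels
  for (s in s_values) {
    if (nrow(kern) > 0) {
      j <- which.min(abs(kern$center - s))
      if (abs(kern$center[j] - s) < thr) {
        h <- kern$height[j]
        c_new <- (h * kern$center[j] + s) / (h + 1)
        m2 <- (h * (kern$width[j]^2 + kern$center[j]^2) +
                 (width^2 + s^2)) / (h + 1)
        kern$center[j] <- c_new
        kern$width[j] <- sqrt(max(m2 - c_new^2, config$sigma_min^2))
        kern$height[j] <- h + 1
        next
      }
    }
    kern <- rbind(kern, data.frame(center = s, width = width, height = 1))
  }
  state$kernels <- kern
  dens_at_centers <- .opes_density(kern$center, kern)
  state$Z <- mean(dens_at_centers)
  state$normalization_series <- c(state$normalization_series, state$Z)
  v_grid <- bias_energy(state$grid, state, config)
  rct <- config$kT * log(mean(exp(v_grid / config$kT)))
  state$rct_series <- c(state$rct_series, rct)
  state
}

#' Run multi-walker adaptive-bias sampling on a surrogate potential
#'
#' Propagates `n_walkers` Langevin walkers (BAOAB discretization) on a
#' [surrogate_potential()], sharing a single OPES-explore bias along the
#' collective variable. Deposits happen synchronously every `pace`
#' steps with all walkers' current CV values. Outputs carry per-frame
#' CV, bias energy, wall energy and the \eqn{c(t)} offset in force at
#' recording time, which is sufficient for reweighting.
#'
#' @param potential a [surrogate_potential()].
#' @param config an [opes_config()].
#' @param cv `NULL` for the identity CV (the reaction coordinate
#'   itself), or a vectorized function `s(x)`; a trained CV model can be
#'   passed as `function(x) evaluate_cv(model, feature_map(x))$values`.
#'   The function is tabulated on a dense grid and differentiated
#'   numerically for the chain-rule bias force.
#' @param walls optional `list(lo=, hi=, k=)` harmonic walls on the raw
#'   coordinate, e.g. from the training-data hull.
#' @param x0 initial walker positions; defaults to the first basin
#'   center of the potential.
#' @param seed integer seed; the run is deterministic given seed and
#'   configuration.
#' @param cv_range CV grid range for the \eqn{c(t)} evaluation; defaults
#'   to the CV image of the walled/basin region.
#' @return an object of class `opes_trajectory` with matrices
#'   `positions`, `cv`, `bias`, `wall` (frames x walkers), the per-frame
#'   `rct` offset, the final `bias_state`, and the recrossing count of
#'   the central barrier.
#' @export
run_opes <- function(potential, config, cv = NULL, walls = NULL,
                     x0 = NULL, seed = 1L, cv_range = NULL) {
  stopifnot(inherits(potential, "surrogate_potential"),
            inherits(config, "opes_config"))
  nw <- config$n_walkers
  if (is.null(x0)) x0 <- rep(potential$basin_centers[1], nw)
  if (length(x0) == 1) x0 <- rep(x0, nw)
  stopifnot(length(x0) == nw)
  if (any(!is.finite(potential_energy(potential, x0)))) {
    stop("potential not finite at initial position")
  }

  lo <- if (is.null(walls)) -potential$domain_guard / 2 else walls$lo
  hi <- if (is.null(walls)) potential$domain_guard / 2 else walls$hi
  wall_k <- if (is.null(walls)) 0 else walls$k

  # tabulate the CV map (identity if cv is NULL)
  xg <- seq(min(potential$basin_centers) - 2, max(potential$basin_centers) + 2,
            length.out = 2001L)
  xg <- xg[xg >= -potential$domain_guard & xg <= potential$domain_guard]
  if (is.null(cv)) {
    cv_tab <- list(grid = numeric(0), s = numeric(0), dsdx = numeric(0))
    s_of <- identity
  } else {
    sg <- cv(xg)
    dg <- xg[2] - xg[1]
    dsdx <- c(diff(sg)[1], diff(sg, lag = 2) / (2 * dg), rev(diff(sg))[1])
    dsdx[c(1, length(dsdx))] <- c(diff(sg)[1] / dg, rev(diff(sg))[1] / dg)
    cv_tab <- list(grid = xg, s = sg, dsdx = dsdx)
    s_of <- cv
  }
  if (is.null(cv_range)) {
    sr <- range(if (is.null(cv)) c(lo, hi) else s_of(seq(lo, hi, length.out = 201)))
  } else sr <- range(cv_range)
  state <- new_bias_state(config, seq(sr[1], sr[2], length.out = 201))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  n_seg <- ceiling(config$n_steps / config$pace)
  rec_per_seg <- config$pace %/% config$stride
  n_rec <- n_seg * rec_per_seg
  positions <- cvm <- biasm <- wallm <- potm <- matrix(NA_real_, n_rec, nw)
  rct_frame <- numeric(n_rec)
  x <- x0; v <- rep(0, nw)

  for (i in seq_len(n_seg)) {
    seg <- .opes_segment_cpp(
      x, v, config$pace, config$dt, config$friction, config$kT,
      config$mass, potential$poly, potential$gauss$height,
      potential$gauss$center, potential$gauss$width, potential$q,
      potential$phi_center, potential$phi_width,
      cv_tab$grid, cv_tab$s, cv_tab$dsdx,
      state$kernels$center, state$kernels$width, state$kernels$height,
      state$Z, config$epsilon, config$pref,
      numeric(0), numeric(0), numeric(0),
      lo, hi, wall_k, potential$domain_guard, config$stride)
    rows <- ((i - 1) * rec_per_seg + 1):(i * rec_per_seg)
    positions[rows, ] <- seg$positions
    cvm[rows, ] <- seg$cv
    biasm[rows, ] <- seg$bias
    wallm[rows, ] <- seg$wall
    potm[rows, ] <- seg$potential
    rct_frame[rows] <- if (i == 1) 0 else
      state$rct_series[length(state$rct_series)]
    x <- seg$x_final; v <- seg$v_final
    state <- deposit(seg$cv[rec_per_seg, ], state, config)
  }

  recross <- count_recrossings(positions, potential)
  if (recross < 2) {
    warning("fewer than 2 barrier recrossings within the sampling budget; ",
            "free-energy estimates may not be converged")
  }
  structure(list(positions = positions, cv = cvm, bias = biasm,
                 wall = wallm, potential_energy = potm,
                 rct = rct_frame, bias_state = state, config = config,
                 potential = potential, walls = walls, seed = seed,
                 recrossings = recross,
                 step = seq_len(n_rec) * config$stride),
            class = "opes_trajectory")
}

#' Count recrossings of the central barrier
#'
#' Transitions between the outer basins, counted with hysteresis: a
#' crossing registers when a walker moves from within half a basin
#' separation of one outer basin to within half a separation of the
#' other.
#'
#' @param positions frames x walkers matrix of positions.
#' @param potential the `surrogate_potential` sampled.
#' @return total number of basin-to-basin transitions over all walkers.
#' @export
count_recrossings <- function(positions, potential) {
  b <- range(potential$basin_centers)
  lo <- b[1] + diff(b) / 4
  hi <- b[2] - diff(b) / 4
  total <- 0L
  for (w in seq_len(ncol(positions))) {
    x <- positions[, w]
    side <- 0L
    for (xi in x) {
      if (xi < lo) {
        if (side == 1L) total <- total + 1L
        side <- -1L
      } else if (xi > hi) {
        if (side == -1L) total <- total + 1L
        side <- 1L
      }
    }
  }
  total
}

#' Unbiased or externally biased Langevin sampling
#'
#' Propagates a single Langevin trajectory (BAOAB discretization) on a
#' surrogate potential, optionally under a fixed external bias. With no
#' bias, the long-trajectory position histogram converges to the
#' Boltzmann density of the potential.
#'
#' @param potential a [surrogate_potential()].
#' @param config a [langevin_config()].
#' @param bias optional vectorized function `V(x)` added to the
#'   potential (tabulated internally).
#' @return list with `positions`, `potential_energy`, `bias_energy` per
#'   recorded frame and the `config` echo.
#' @export
langevin_sample <- function(potential, config, bias = NULL) {
  stopifnot(inherits(potential, "surrogate_potential"),
            inherits(config, "langevin_config"))
  if (!is.finite(potential_energy(potential, config$initial_position))) {
    stop("potential not finite at initial position")
  }
  if (is.null(bias)) {
    bt <- list(grid = numeric(0), V = numeric(0), dV = numeric(0))
  } else {
    g <- seq(-potential$domain_guard, potential$domain_guard,
             length.out = 4001L)
    Vg <- bias(g)
    dg <- g[2] - g[1]
    dV <- c(diff(Vg)[1] / dg, diff(Vg, lag = 2) / (2 * dg),
            rev(diff(Vg))[1] / dg)
    bt <- list(grid = g, V = Vg, dV = dV)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(config$seed))
  seg <- .opes_segment_cpp(
    config$initial_position, 0, config$n_steps, config$timestep,
    config$friction, config$kT, config$mass, potential$poly,
    potential$gauss$height, potential$gauss$center, potential$gauss$width,
    potential$q, potential$phi_center, potential$phi_width,
    numeric(0), numeric(0), numeric(0),
    numeric(0), numeric(0), numeric(0), 1, 0, 0,
    bt$grid, bt$V, bt$dV,
    0, 0, 0, potential$domain_guard, config$stride_out)
  list(positions = drop(seg$positions),
       potential_energy = drop(seg$potential),
       bias_energy = drop(seg$bias), config = config)
}

#' Langevin propagator configuration
#'
#' @param timestep integration step in reduced time units.
#' @param friction Langevin friction (inverse time).
#' @param n_steps number of steps.
#' @param seed integer seed; identical seed and config give an identical
#'   trajectory.
#' @param initial_position starting coordinate.
#' @param kT thermal energy (0 allowed for the deterministic
#'   zero-temperature limit).
#' @param mass particle mass.
#' @param stride_out recording stride.
#' @return an object of class `langevin_config`.
#' @export
langevin_config <- function(timestep = 0.005, friction = 1,
                            n_steps = 1e5L, seed = 1L,
                            initial_position = 0, kT = 1, mass = 1,
                            stride_out = 1L) {
  stopifnot(timestep > 0, friction > 0, n_steps >= 1, kT >= 0)
  structure(list(timestep = timestep, friction = friction,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 initial_position = initial_position, kT = kT,
                 mass = mass, stride_out = as.integer(stride_out)),
            class = "langevin_config")
}
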