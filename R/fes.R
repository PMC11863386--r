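#' Gridded free-energy profile
#'
#' Container for a 1-D free-energy estimate: bin centers, free energy
#' (min-shifted to zero), per-bin standard error over replicates, and
#' the replicate count. Bins never visited in any replicate are `NA`
#' (unset), never zero.
#'
#' @param grid strictly increasing bin centers (CV units).
#' @param free_energy energies per bin (energy units).
#' @param sem non-negative per-bin standard error of the mean.
#' @param n_replicates number of independent replicates behind `sem`.
#' @return an object of class `fes_profile`.
#' @export
fes_profile <- function(grid, free_energy, sem = rep(0, length(grid)),
                        n_replicates = 1L) {
  stopifnot(length(grid) == length(free_energy),
            length(sem) == length(free_energy),
            all(diff(grid) > 0), all(sem >= 0, na.rm = TRUE))
  m <- min(free_energy, na.rm = TRUE)
  structure(list(grid = as.numeric(grid),
                 free_energy = as.numeric(free_energy) - m,
                 sem = as.numeric(sem),
                 n_replicates = as.integer(n_replicates)),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat("<fes_profile> ", length(x$grid), " bins on [",
      format(min(x$grid)), ", ", format(max(x$grid)), "], ",
      x$n_replicates, " replicate(s), max F = ",
      format(max(x$free_energy, na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Detect bias burn-in from the c(t) series
#'
#' Production convention: early sampling is discarded once the
#' reweighting offset \eqn{c(t)} has stabilized. The default rule scans
#' a trailing window and declares stabilization when the fitted slope,
#' extrapolated over the whole series, drops below `slope_threshold`
#' times the series range; the retained portion starts at the first
#' index of that window. The result is capped at `fraction_cap` of the
#' run; a never-stabilizing series returns the cap with a warning.
#'
#' @param rct_series numeric series of the reweighting offset, one value
#'   per bias update (length at least 10).
#' @param fraction_cap maximum fraction of the run that may be
#'   discarded.
#' @param window trailing-window length; default
#'   `max(5, ceiling(0.02 * length))`.
#' @param slope_threshold dimensionless stabilization threshold.
#' @return first retained index (1-based).
#' @export
detect_burn_in <- function(rct_series, fraction_cap = 0.25,
                           window = NULL, slope_threshold = 1) {
  n <- length(rct_series)
  if (n < 10) stop("rct series must have at least 10 points")
  w <- if (is.null(window)) max(5L, ceiling(0.02 * n)) else as.integer(window)
  rng <- diff(range(rct_series))
  if (rng < 1e-12) return(1L)
  cap <- max(1L, ceiling(fraction_cap * n))
  idx <- seq_len(w)
  sxx <- sum((idx - mean(idx))^2)
  for (t in w:n) {
    y <- rct_series[(t - w + 1):t]
    slope <- sum((idx - mean(idx)) * (y - mean(y))) / sxx
    if (abs(slope) * n <= slope_threshold * rng) {
      return(min(as.integer(t - w + 1), cap))
    }
  }
  warning("c(t) series never stabilized; discarding the capped fraction")
  cap
}

#' Remove burn-in frames from a biased trajectory
#'
#' Applies [detect_burn_in()] to the trajectory's \eqn{c(t)} series and
#' drops all frames recorded before the retained bias update.
#'
#' @param traj an `opes_trajectory` from [run_opes()].
#' @param ... passed to [detect_burn_in()].
#' @return the trimmed trajectory.
#' @export
discard_burn_in <- function(traj, ...) {
  stopifnot(inherits(traj, "opes_trajectory"))
  r <- detect_burn_in(traj$bias_state$rct_series, ...)
  first_step <- r * traj$config$pace
  keep <- traj$step > first_step
  for (f in c("positions", "cv", "bias", "wall", "potential_energy")) {
    traj[[f]] <- traj[[f]][keep, , drop = FALSE]
  }
  traj$rct <- traj$rct[keep]
  traj$step <- traj$step[keep]
  traj$burn_in_steps <- first_step
  traj
}

#' Reweighted free-energy profile from biased trajectories
#'
#' Recovers the unbiased free energy along the CV from adaptive-bias
#' runs using the standard reweighting identity: each frame carries
#' weight \eqn{w = e^{(V(s) + V_{wall} - c(t))/kT}} with the bias and
#' offset in force when the frame was recorded. Per replicate, a
#' weighted histogram on `grid` gives \eqn{F = -kT\log \hat p}, shifted
#' to zero minimum; the profile reports the across-replicate mean and
#' standard error per bin. Burn-in must already be removed (see
#' [discard_burn_in()]).
#'
#' @param trajs list of `opes_trajectory` replicates (at least one; at
#'   least two for a nonzero SEM).
#' @param grid strictly increasing bin centers for the profile.
#' @param kT thermal energy.
#' @return a [fes_profile()].
#' @export
reweighted_fes <- function(trajs, grid, kT = 1) {
  if (inherits(trajs, "opes_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, all(diff(grid) > 0))
  dx <- grid[2] - grid[1]
  edges <- c(grid - dx / 2, grid[length(grid)] + dx / 2)
  per_rep <- vapply(trajs, function(tr) {
    s <- as.vector(tr$cv)
    nwalk <- ncol(tr$cv)
    logw <- (as.vector(tr$bias + tr$wall) - rep(tr$rct, times = nwalk)) / kT
    w <- exp(logw - max(logw))
    bin <- findInterval(s, edges, all.inside = FALSE)
    ok <- bin >= 1 & bin <= length(grid)
    hw <- rep(0, length(grid))
    tw <- rowsum(w[ok], bin[ok])
    hw[as.integer(rownames(tw))] <- tw
    f <- ifelse(hw > 0, -kT * log(hw), NA_real_)
    f - min(f, na.rm = TRUE)
  }, numeric(length(grid)))
  per_rep <- matrix(per_rep, nrow = length(grid))
  n_ok <- rowSums(!is.na(per_rep))
  fmean <- ifelse(n_ok > 0, rowMeans(per_rep, na.rm = TRUE), NA_real_)
  fsd <- apply(per_rep, 1, stats::sd, na.rm = TRUE)
  sem <- ifelse(n_ok >= 2, fsd / sqrt(n_ok), 0)
  sem[is.na(sem)] <- 0
  fes_profile(grid, fmean, sem, n_replicates = length(trajs))
}

#' Extract state free energies from a profile
#'
#' Table-1-style energetics: within each labeled CV window, the basin
#' free energy is the interior minimum (labels `RS`, `INT`, `PS`) and
#' the barrier free energy the interior maximum (labels starting with
#' `TS`). All values are reported relative to the RS minimum with SEM
#' propagated as the root sum of squares of the two bins' SEMs.
#'
#' @param profile a [fes_profile()].
#' @param state_windows named list mapping labels (must include `RS`)
#'   to `c(lo, hi)` CV intervals inside the grid.
#' @return an object of class `state_energies`: data.frame with columns
#'   `transition` (e.g. `"RS->TS1"`), `dG`, `sem`.
#' @export
extract_state_energies <- function(profile, state_windows) {
  stopifnot(inherits(profile, "fes_profile"), "RS" %in% names(state_windows))
  pick <- function(label, win) {
    idx <- which(profile$grid >= win[1] & profile$grid <= win[2] &
                   !is.na(profile$free_energy))
    if (length(idx) < 3) {
      stop("window for ", label, " has too few occupied bins ",
           "(extraction error)")
    }
    f <- profile$free_energy[idx]
    j <- if (startsWith(label, "TS")) which.max(f) else which.min(f)
    if (j == 1 || j == length(idx)) {
      stop("no interior extremum in the window for ", label,
           " (extraction error)")
    }
    c(value = f[j], sem = profile$sem[idx[j]])
  }
  vals <- lapply(names(state_windows), function(l) pick(l, state_windows[[l]]))
  names(vals) <- names(state_windows)
  rs <- vals[["RS"]]
  others <- setdiff(names(state_windows), "RS")
  out <- data.frame(
    transition = paste0("RS->", others),
    dG = vapply(others, function(l) vals[[l]]["value"] - rs["value"],
                numeric(1)),
    sem = vapply(others, function(l) sqrt(vals[[l]]["sem"]^2 + rs["sem"]^2),
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("state_energies", "data.frame"))
}

#' Free-energy differences between two perturbation runs
#'
#' \eqn{\Delta\Delta G} per transition between two [extract_state_energies()]
#' tables (e.g. charge-perturbed minus reference). Swapping the
#' arguments negates every entry exactly; SEMs pool as root sum of
#' squares.
#'
#' @param a,b `state_energies` tables with identical transitions.
#' @return data.frame with columns `transition`, `ddG`, `sem`.
#' @export
delta_delta_g <- function(a, b) {
  stopifnot(inherits(a, "state_energies"), inherits(b, "state_energies"),
            identical(a$transition, b$transition))
  data.frame(transition = a$transition, ddG = a$dG - b$dG,
             sem = sqrt(a$sem^2 + b$sem^2), stringsAsFactors = FALSE)
}

#' Rational (chemically interpretable) variable
#'
#' A per-frame series of a physically meaningful coordinate (for a
#' serine-protease reaction, e.g. the transferring-proton distance) with
#' the value range it is expected to occupy at the transition state.
#' Used to audit the learned CV for transition-state degeneracy.
#'
#' @param name variable name.
#' @param values per-frame numeric series.
#' @param ts_window `c(lo, hi)` expected range at the transition state.
#' @return an object of class `rational_variable`.
#' @export
rational_variable <- function(name, values, ts_window) {
  stopifnot(is.character(name), length(ts_window) == 2,
            ts_window[1] < ts_window[2])
  structure(list(name = name, values = as.numeric(values),
                 ts_window = as.numeric(ts_window)),
            class = "rational_variable")
}

#' Transition-state degeneracy audit
#'
#' A learned CV is degenerate when configurations that are chemically
#' distinct project onto the transition-state CV values. The audit
#' builds the reweighted 2-D free-energy surface over (CV, rational
#' variable) and, within the TS window of the CV, checks that (i) the
#' minimum-free-energy rational value lies inside the expected TS range
#' and (ii) no bin with a rational value outside that range undercuts
#' the TS free energy by more than `tol`. Empty TS-window occupancy
#' yields status `"inconclusive"` rather than a verdict.
#'
#' @param cv per-frame CV series.
#' @param rational a [rational_variable()] with values aligned to `cv`.
#' @param weights per-frame reweighting factors (e.g.
#'   `exp((bias - rct)/kT)`); uniform by default.
#' @param ts_cv_window `c(lo, hi)` CV interval of the transition state.
#' @param kT thermal energy.
#' @param n_bins bins per axis for the 2-D surface.
#' @param tol undercut tolerance in energy units.
#' @return list with `status` (`"pass"`, `"fail"`, `"inconclusive"`),
#'   the 2-D free-energy matrix `fes2d` with axes `cv_grid`,
#'   `rational_grid`, the TS free energy and the offending undercut (if
#'   any).
#' @export
degeneracy_audit <- function(cv, rational, weights = NULL, ts_cv_window,
                             kT = 1, n_bins = c(60L, 60L), tol = 0.5) {
  stopifnot(inherits(rational, "rational_variable"),
            length(cv) == length(rational$values))
  if (is.null(weights)) weights <- rep(1, length(cv))
  r <- rational$values
  cv_edges <- seq(min(cv), max(cv), length.out = n_bins[1] + 1)
  r_edges <- seq(min(r), max(r), length.out = n_bins[2] + 1)
  bi <- pmin(pmax(findInterval(cv, cv_edges, all.inside = TRUE), 1), n_bins[1])
  bj <- pmin(pmax(findInterval(r, r_edges, all.inside = TRUE), 1), n_bins[2])
  W <- matrix(0, n_bins[1], n_bins[2])
  for (k in seq_along(cv)) W[bi[k], bj[k]] <- W[bi[k], bj[k]] + weights[k]
  F2 <- ifelse(W > 0, -kT * log(W), NA_real_)
  F2 <- F2 - min(F2, na.rm = TRUE)
  cv_centers <- (cv_edges[-1] + cv_edges[-length(cv_edges)]) / 2
  r_centers <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  in_ts_cv <- cv_centers >= ts_cv_window[1] & cv_centers <= ts_cv_window[2]
  sub <- F2[in_ts_cv, , drop = FALSE]
  if (all(is.na(sub))) {
    return(list(status = "inconclusive", fes2d = F2, cv_grid = cv_centers,
                rational_grid = r_centers, ts_free_energy = NA_real_,
                undercut = NA_real_))
  }
  in_r <- r_centers >= rational$ts_window[1] &
    r_centers <= rational$ts_window[2]
  min_all <- min(sub, na.rm = TRUE)
  jmin <- which(sub == min_all, arr.ind = TRUE)[1, 2]
  min_inside <- if (any(!is.na(sub[, in_r, drop = FALSE]))) {
    min(sub[, in_r, drop = FALSE], na.rm = TRUE)
  } else Inf
  min_outside <- if (any(!is.na(sub[, !in_r, drop = FALSE]))) {
    min(sub[, !in_r, drop = FALSE], na.rm = TRUE)
  } else Inf
  undercut <- min_inside - min_outside
  pass <- in_r[jmin] && (undercut <= tol)
  list(status = if (pass) "pass" else "fail", fes2d = F2,
       cv_grid = cv_centers, rational_grid = r_centers,
       ts_free_energy = min_inside,
       undercut = if (is.finite(undercut)) undercut else 0)
}

#' Write a free-energy profile to CSV
#'
#' @param profile a [fes_profile()].
#' @param path output file.
#' @export
write_fes_csv <- function(profile, path) {
  stopifnot(inherits(profile, "fes_profile"))
  utils::write.csv(data.frame(cv = profile$grid,
                              free_energy = profile$free_energy,
                              sem = profile$sem), path, row.names = FALSE)
}
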