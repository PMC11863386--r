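#' Analytic surrogate potentials on a 1-D reaction coordinate
#'
#' A surrogate potential is a smooth, bounded-below 1-D energy function
#' \deqn{U(x) = \sum_i p_i x^i + \sum_j A_j e^{-(x-c_j)^2/2w_j^2} + q\,\phi(x)}
#' combining a polynomial backbone, Gaussian wells/bumps, and a spectator
#' "charge" coupling \eqn{q \phi(x)} with \eqn{\phi} a narrow Gaussian
#' localized at a transition region. Because the system is one-dimensional,
#' the exact free energy along \eqn{x} is available by quadrature, which is
#' what makes the surrogate useful as a ground-truth oracle for the
#' enhanced-sampling and reweighting machinery. All quantities are in
#' reduced units (energies in kT at the reference temperature, kT = 1).
#'
#' @param poly numeric vector of polynomial coefficients, constant term first.
#' @param gauss data.frame with columns `height`, `center`, `width` (one
#'   Gaussian term per row); `height < 0` digs a well, `height > 0` a bump.
#' @param q spectator charge (reduced units) multiplying the coupling
#'   function.
#' @param phi_center,phi_width location and width of the Gaussian coupling
#'   function \eqn{\phi(x) = e^{-(x-\phi_c)^2/2\phi_w^2}}.
#' @param kT thermal energy in reduced units.
#' @param basin_centers positions of the metastable basins; used to place
#'   the divergence guard and to report coverage errors.
#' @param domain_guard trajectory positions beyond this absolute value
#'   trigger an integration error; defaults to 10x the outermost basin
#'   center.
#' @return an object of class `surrogate_potential`.
#' @export
surrogate_potential <- function(poly = 0, gauss = NULL, q = 0,
                                phi_center = 0, phi_width = 0.25,
                                kT = 1, basin_centers = 0,
                                domain_guard = NULL) {
  stopifnot(is.numeric(poly), length(poly) >= 1, kT > 0, phi_width > 0)
  if (is.null(gauss)) {
    gauss <- data.frame(height = numeric(0), center = numeric(0),
                        width = numeric(0))
  }
  stopifnot(all(c("height", "center", "width") %in% names(gauss)))
  if (nrow(gauss) > 0 && any(gauss$width <= 0)) {
    stop("Gaussian widths must be positive")
  }
  if (is.null(domain_guard)) {
    domain_guard <- 10 * max(1, max(abs(basin_centers)))
  }
  structure(
    list(poly = as.numeric(poly), gauss = gauss, q = q,
         phi_center = phi_center, phi_width = phi_width, kT = kT,
         basin_centers = sort(as.numeric(basin_centers)),
         domain_guard = domain_guard),
    class = "surrogate_potential"
  )
}

#' Symmetric double-well surrogate
#'
#' \eqn{U(x) = h\,((x/x_0)^2 - 1)^2 + q\,\phi(x)} with minima at
#' \eqn{\pm x_0} and a barrier of exactly `h` (in kT) at \eqn{x = 0} when
#' `q = 0`. The charge coupling \eqn{\phi} is centered on the barrier top,
#' so for a stiff system the induced barrier shift equals
#' \eqn{q\,[\phi(0) - \phi(x_0)] \approx q}.
#'
#' @param barrier barrier height in kT for the unperturbed system.
#' @param x0 half-separation of the two minima.
#' @param q spectator charge.
#' @param phi_width width of the charge coupling Gaussian.
#' @param kT thermal energy.
#' @return a `surrogate_potential`.
#' @export
double_well <- function(barrier = 10, x0 = 1, q = 0, phi_width = 0.25,
                        kT = 1) {
  stopifnot(barrier > 0, x0 > 0)
  # h * (x^2/x0^2 - 1)^2 = h - 2h x^2/x0^2 + h x^4/x0^4
  poly <- c(barrier, 0, -2 * barrier / x0^2, 0, barrier / x0^4)
  surrogate_potential(poly = poly, q = q, phi_center = 0,
                      phi_width = phi_width, kT = kT,
                      basin_centers = c(-x0, x0))
}

#' Multi-state surrogate with RS/TS1/INT/TS2/PS topology
#'
#' Three Gaussian wells on a soft polynomial confinement produce the
#' five-state topology of a two-step reaction: reactant (RS), first
#' transition state (TS1), intermediate (INT), second transition state
#' (TS2), product (PS). Well depths control the barriers seen from RS;
#' defaults give barriers in the 10-20 kT range. The spectator charge
#' couples at the second barrier (between INT and PS) by default.
#'
#' @param centers basin positions for RS, INT, PS.
#' @param depths well depths in kT (positive numbers).
#' @param well_width common Gaussian well width.
#' @param confinement quartic confinement coefficient.
#' @param q,phi_center,phi_width spectator-charge coupling, by default at
#'   the TS2 region midway between INT and PS.
#' @param kT thermal energy.
#' @return a `surrogate_potential`.
#' @export
triple_well <- function(centers = c(-2, 0, 2), depths = c(14, 4, 12),
                        well_width = 0.35, confinement = 0.05,
                        q = 0, phi_center = NULL, phi_width = 0.25,
                        kT = 1) {
  stopifnot(length(centers) == 3, length(depths) == 3, all(depths > 0))
  if (is.null(phi_center)) phi_center <- mean(centers[2:3])
  gauss <- data.frame(height = -depths, center = centers,
                      width = well_width)
  surrogate_potential(poly = c(0, 0, 0, 0, confinement), gauss = gauss,
                      q = q, phi_center = phi_center,
                      phi_width = phi_width, kT = kT,
                      basin_centers = centers)
}

#' Evaluate a surrogate potential
#'
#' @param pot a `surrogate_potential`.
#' @param x numeric vector of positions.
#' @return potential energy at `x` (reduced units), vectorized.
#' @export
potential_energy <- function(pot, x) {
  stopifnot(inherits(pot, "surrogate_potential"))
  u <- outer(x, seq_along(pot$poly) - 1, `^`) %*% pot$poly
  u <- drop(u)
  if (nrow(pot$gauss) > 0) {
    for (j in seq_len(nrow(pot$gauss))) {
      g <- pot$gauss[j, ]
      u <- u + g$height * exp(-(x - g$center)^2 / (2 * g$width^2))
    }
  }
  if (pot$q != 0) u <- u + pot$q * charge_coupling(pot, x)
  u
}

#' Charge-coupling function of a surrogate potential
#'
#' @param pot a `surrogate_potential`.
#' @param x positions.
#' @return \eqn{\phi(x)}, the dimensionless coupling profile.
#' @export
charge_coupling <- function(pot, x) {
  exp(-(x - pot$phi_center)^2 / (2 * pot$phi_width^2))
}

#' Force (negative gradient) of a surrogate potential
#'
#' @inheritParams potential_energy
#' @return \eqn{-dU/dx} at `x`.
#' @export
potential_force <- function(pot, x) {
  k <- seq_along(pot$poly) - 1
  du <- drop(outer(x, pmax(k - 1, 0), `^`) %*% (pot$poly * k))
  if (nrow(pot$gauss) > 0) {
    for (j in seq_len(nrow(pot$gauss))) {
      g <- pot$gauss[j, ]
      du <- du - g$height * (x - g$center) / g$width^2 *
        exp(-(x - g$center)^2 / (2 * g$width^2))
    }
  }
  if (pot$q != 0) {
    du <- du - pot$q * (x - pot$phi_center) / pot$phi_width^2 *
      charge_coupling(pot, x)
  }
  -du
}

#' Exact free-energy profile of a surrogate potential by quadrature
#'
#' For the 1-D surrogate the marginal free energy along the coordinate is
#' exact: per grid bin, \eqn{F_i = -kT \log(\int_{bin_i} e^{-U/kT} dx /
#' \Delta x)}, integrated with composite Gauss-Legendre quadrature and
#' shifted so the minimum is zero. This is the ground truth that biased
#' estimates are audited against.
#'
#' @param pot a `surrogate_potential`.
#' @param grid strictly increasing numeric vector of bin centers; must
#'   cover every basin of the potential.
#' @param n_quad quadrature nodes per bin.
#' @return a [fes_profile()] with `sem = 0` and `n_replicates = 1`.
#' @export
exact_fes <- function(pot, grid, n_quad = 24) {
  stopifnot(inherits(pot, "surrogate_potential"), length(grid) >= 3,
            all(diff(grid) > 0))
  if (min(grid) > min(pot$basin_centers) ||
      max(grid) < max(pot$basin_centers)) {
    stop("grid does not cover all basins of the potential (coverage error)")
  }
  dx <- diff(grid)
  edges <- c(grid[1] - dx[1] / 2, grid + c(dx, dx[length(dx)]) / 2)
  gl <- gauss_legendre_nodes(n_quad)
  f <- vapply(seq_along(grid), function(i) {
    a <- edges[i]; b <- edges[i + 1]
    xs <- (b - a) / 2 * gl$nodes + (a + b) / 2
    w <- (b - a) / 2 * gl$weights
    z <- sum(w * exp(-potential_energy(pot, xs) / pot$kT))
    -pot$kT * log(z / (b - a))
  }, numeric(1))
  fes_profile(grid = grid, free_energy = f - min(f),
              sem = rep(0, length(grid)), n_replicates = 1L)
}

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1].
gauss_legendre_nodes <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}
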