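#' Pairwise-distance feature specification
#'
#' The CV input features are all pairwise distances between a small set
#' of reaction-center atoms, normalized by a rational switch function.
#' A 9-atom set yields \eqn{C(9,2) = 36} features (matching the first
#' layer of the acylation-stage network) and an 8-atom set
#' \eqn{C(8,2) = 28} (deacylation stage).
#'
#' @param atom_ids ordered vector of unique atom identifiers.
#' @param switch_r0 switch midpoint distance r0 (Angstrom), recycled per
#'   pair.
#' @param switch_n,switch_m switch exponents, `m > n > 0`; default
#'   (6, 12), the most common rational-switch convention.
#' @return an object of class `feature_spec` with the canonical pair
#'   index.
#' @export
feature_spec <- function(atom_ids, switch_r0 = 4, switch_n = 6,
                         switch_m = 12) {
  if (anyDuplicated(atom_ids)) stop("atom_ids must be unique")
  stopifnot(switch_m > switch_n, switch_n > 0, all(switch_r0 > 0))
  k <- length(atom_ids)
  if (k < 2) stop("need at least two atoms")
  pairs <- t(utils::combn(k, 2))
  structure(list(atom_ids = atom_ids,
                 pairs = data.frame(i = pairs[, 1], j = pairs[, 2],
                                    name = paste0(atom_ids[pairs[, 1]], "-",
                                                  atom_ids[pairs[, 2]])),
                 switch_r0 = rep_len(switch_r0, nrow(pairs)),
                 switch_n = switch_n, switch_m = switch_m,
                 n_features = nrow(pairs)),
            class = "feature_spec")
}

#' Raw pairwise distances for one frame
#'
#' @param positions matrix (atoms x 3) with rownames giving atom ids, or
#'   a data.frame with `atom_id`, `x`, `y`, `z`.
#' @param spec a [feature_spec()].
#' @return numeric vector of \eqn{C(k,2)} distances in canonical
#'   (i < j) order, named by atom pair.
#' @export
pairwise_distances <- function(positions, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  if (is.data.frame(positions)) {
    m <- as.matrix(positions[c("x", "y", "z")])
    rownames(m) <- positions$atom_id
    positions <- m
  }
  miss <- setdiff(as.character(spec$atom_ids), rownames(positions))
  if (length(miss) > 0) {
    stop("atoms missing from frame: ", paste(miss, collapse = ", "),
         " (lookup error)")
  }
  xyz <- positions[as.character(spec$atom_ids), , drop = FALSE]
  d <- vapply(seq_len(nrow(spec$pairs)), function(r) {
    sqrt(sum((xyz[spec$pairs$i[r], ] - xyz[spec$pairs$j[r], ])^2))
  }, numeric(1))
  stats::setNames(d, spec$pairs$name)
}

#' Rational switch normalization
#'
#' \deqn{s(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m}}
#' with the removable singularity at \eqn{r = r_0} filled by the limit
#' \eqn{n/m}. For \eqn{m > n} the function is continuous on
#' \eqn{[0, \infty)}, equals 1 at r = 0, strictly decreasing, and
#' bounded in (0, 1].
#'
#' @param r distance(s), non-negative.
#' @param r0 switch midpoint.
#' @param n,m exponents with `m > n > 0`.
#' @return dimensionless value(s) in (0, 1].
#' @export
switch_normalize <- function(r, r0 = 4, n = 6, m = 12) {
  if (any(r < 0)) stop("distances must be non-negative (argument error)")
  stopifnot(m > n, n > 0, all(r0 > 0))
  x <- r / r0
  out <- ifelse(abs(x - 1) < 1e-12, n / m, (1 - x^n) / (1 - x^m))
  out
}

#' Switch-normalized feature vector(s)
#'
#' Applies [switch_normalize()] per pair using the spec's r0 and
#' exponents.
#'
#' @param distances numeric vector (one frame) or matrix/data.frame
#'   (frames x features) of raw distances.
#' @param spec a [feature_spec()].
#' @return normalized features, same shape as the input.
#' @export
featurize <- function(distances, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  if (is.null(dim(distances))) {
    stopifnot(length(distances) == spec$n_features)
    return(switch_normalize(distances, spec$switch_r0, spec$switch_n,
                            spec$switch_m))
  }
  distances <- as.matrix(distances)
  stopifnot(ncol(distances) == spec$n_features)
  out <- distances
  for (j in seq_len(ncol(out))) {
    out[, j] <- switch_normalize(distances[, j], spec$switch_r0[j],
                                 spec$switch_n, spec$switch_m)
  }
  out
}

#' Training-hull walls on raw distances
#'
#' Biased sampling must stay inside the convex hull of the training
#' distances because the network CV extrapolates poorly. Per feature, a
#' lower and an upper harmonic wall are placed at the `low` and `high`
#' percentiles of the training distribution (linear interpolation
#' between order statistics). A constant feature yields coinciding
#' walls, kept with a warning.
#'
#' @param training data.frame or matrix of raw training distances
#'   (frames x features).
#' @param low,high percentile fractions, `0 < low < high < 1`; defaults
#'   0.005 and 0.995.
#' @param k force constant; default 20 (kcal/mol/A^2 in production
#'   units).
#' @return data.frame with columns `feature`, `lower`, `upper`, `k`.
#' @export
hull_walls <- function(training, low = 0.005, high = 0.995, k = 20) {
  stopifnot(low > 0, high < 1, low < high, k > 0)
  training <- as.matrix(training)
  if (nrow(training) == 0) stop("training table is empty")
  qs <- apply(training, 2, stats::quantile, probs = c(low, high),
              type = 7)
  if (any(qs[1, ] == qs[2, ])) {
    warning("degenerate (constant) feature: walls coincide")
  }
  data.frame(feature = colnames(training) %||%
               paste0("f", seq_len(ncol(training))),
             lower = unname(qs[1, ]), upper = unname(qs[2, ]), k = k,
             stringsAsFactors = FALSE)
}

#' Hull-wall energy of a frame
#'
#' @param distances raw distance vector for one frame.
#' @param walls wall table from [hull_walls()].
#' @return total harmonic wall energy; zero everywhere between the
#'   thresholds.
#' @export
hull_wall_energy <- function(distances, walls) {
  stopifnot(length(distances) == nrow(walls))
  lowv <- pmin(distances - walls$lower, 0)
  highv <- pmax(distances - walls$upper, 0)
  sum(0.5 * walls$k * (lowv^2 + highv^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
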