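#' Specification of a metastable reaction state
#'
#' Describes one metastable state of the reaction (RS, TS1, INT, TS2 or
#' PS) as a Gaussian ensemble in feature space: per-feature mean raw
#' distances and spreads, plus the integer class index used when training
#' the discriminant collective variable (0 = reactant-like,
#' 1 = intermediate-like, 2 = product-like). Only stable states carry
#' training classes; transition states are never part of training sets.
#'
#' @param label state name, one of `"RS"`, `"TS1"`, `"INT"`, `"TS2"`,
#'   `"PS"`.
#' @param feature_means numeric vector of mean raw distances (length
#'   units).
#' @param feature_sds numeric vector of distance spreads, same length as
#'   `feature_means`, all positive or zero.
#' @param class integer class index in `{0, 1, 2}`, or `NA` for
#'   transition states.
#' @return an object of class `state_spec`.
#' @export
state_spec <- function(label, feature_means, feature_sds, class = NA) {
  label <- match.arg(label, c("RS", "TS1", "INT", "TS2", "PS"))
  if (length(feature_means) != length(feature_sds)) {
    stop("feature_means and feature_sds must have identical length ",
         "(dimensionality error)")
  }
  if (any(feature_sds < 0)) stop("feature_sds must be non-negative")
  structure(list(label = label,
                 feature_means = as.numeric(feature_means),
                 feature_sds = as.numeric(feature_sds),
                 class = if (is.na(class)) NA_integer_ else as.integer(class)),
            class = "state_spec")
}

#' Default stable-state specifications for the surrogate system
#'
#' Deterministic three-state (RS / INT / PS) Gaussian ensembles over
#' `n_features` raw distances. Base distances span 2-6 length units (the
#' range typical of the heavy-atom pair distances used as CV inputs);
#' states are displaced by alternating per-feature shifts of
#' `separation` units so that the three classes are well separated
#' relative to the within-state spread `sd`. Used as the canonical
#' training conditions for discriminant-CV tests.
#'
#' @param n_features feature dimensionality (36 for the 9-atom stage,
#'   28 for the 8-atom stage).
#' @param separation per-feature between-state displacement.
#' @param sd within-state spread of each distance.
#' @return list of three `state_spec` objects with classes 0, 1, 2.
#' @export
surrogate_state_specs <- function(n_features = 36, separation = 0.6,
                                  sd = 0.1) {
  base <- 2 + 4 * (seq_len(n_features) - 1) / max(1, n_features - 1)
  dir <- rep_len(c(1, -1), n_features)
  list(
    state_spec("RS",  base,                       rep(sd, n_features), class = 0L),
    state_spec("INT", base + dir * separation,    rep(sd, n_features), class = 1L),
    state_spec("PS",  base + dir * 2 * separation, rep(sd, n_features), class = 2L)
  )
}

#' Generate state-labeled feature ensembles
#'
#' Draws `n_per_state` independent Gaussian feature vectors per state,
#' emulating the pooled unbiased sampling of the stable reaction states
#' that populates discriminant-CV training sets. With
#' `mode = "per_replica"` the draw is split into `n_replicas` blocks with
#' a `replica` column, mirroring sampling in several short independent
#' replicas; `"pooled"` (default) emits one block.
#'
#' @param specs list of [state_spec()] objects sharing one feature
#'   dimensionality.
#' @param n_per_state rows to generate per state (at least 2).
#' @param seed integer seed; identical seed and arguments give
#'   byte-identical tables.
#' @param mode `"pooled"` or `"per_replica"`.
#' @param n_replicas number of replicas when `mode = "per_replica"`.
#' @return data.frame with columns `state`, `class` (and `replica` in
#'   per-replica mode) followed by features `f1..fk` (raw distances).
#' @export
generate_state_ensembles <- function(specs, n_per_state, seed = 1L,
                                     mode = c("pooled", "per_replica"),
                                     n_replicas = 8L) {
  mode <- match.arg(mode)
  if (n_per_state < 2) stop("n_per_state must be at least 2 (argument error)")
  dims <- vapply(specs, function(s) length(s$feature_means), integer(1))
  if (length(unique(dims)) != 1) {
    stop("all state specs must share feature dimensionality ",
         "(dimensionality error)")
  }
  k <- dims[1]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- lapply(specs, function(s) {
    x <- matrix(stats::rnorm(n_per_state * k), n_per_state, k)
    x <- sweep(x, 2, s$feature_sds, `*`)
    x <- sweep(x, 2, s$feature_means, `+`)
    colnames(x) <- paste0("f", seq_len(k))
    df <- data.frame(state = s$label, class = s$class, x,
                     stringsAsFactors = FALSE)
    if (mode == "per_replica") {
      df <- cbind(df[1:2],
                  replica = rep_len(seq_len(n_replicas), n_per_state),
                  df[-(1:2)])
    }
    df
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
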