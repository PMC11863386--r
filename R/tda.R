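#' Targets for the discriminant-CV (TDA) loss
#'
#' Targeted discriminant analysis drives a network CV so that the CV
#' distribution of each metastable class matches a prescribed Gaussian:
#' reactant-like at -10, intermediate-like at 0, product-like at +10,
#' with widths 0.4, 0.3, 0.4. The narrow intermediate width sharpens
#' the barrier regions between classes.
#'
#' @param centers strictly increasing per-class CV targets.
#' @param sigmas positive per-class width targets, one per center.
#' @param alpha relative weight of the width term in the loss.
#' @return an object of class `tda_targets`.
#' @export
tda_targets <- function(centers = c(-10, 0, 10),
                        sigmas = c(0.4, 0.3, 0.4), alpha = 1) {
  stopifnot(length(centers) == length(sigmas), all(diff(centers) > 0),
            all(sigmas > 0), alpha >= 0)
  structure(list(centers = centers, sigmas = sigmas, alpha = alpha,
                 n_classes = length(centers)),
            class = "tda_targets")
}

#' Feed-forward network specification for the CV
#'
#' @param layer_widths integer vector, first entry the feature
#'   dimension, last entry 1 (e.g. `c(36, 72, 36, 1)` for a 36-feature
#'   stage, `c(28, 56, 28, 1)` for a 28-feature stage).
#' @param activation hidden nonlinearity; `"tanh"` or `"relu"`.
#' @param seed integer seed for weight initialization and the
#'   train/validation split.
#' @return an object of class `mlp_spec`.
#' @export
mlp_spec <- function(layer_widths, activation = c("tanh", "relu"),
                     seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(length(layer_widths) >= 2,
            layer_widths[length(layer_widths)] == 1,
            all(layer_widths >= 1))
  structure(list(layer_widths = as.integer(layer_widths),
                 activation = activation, seed = as.integer(seed)),
            class = "mlp_spec")
}

.mlp_init <- function(spec) {
  lw <- spec$layer_widths
  params <- list(W = list(), b = list())
  for (l in seq_len(length(lw) - 1)) {
    lim <- sqrt(6 / (lw[l] + lw[l + 1]))
    params$W[[l]] <- matrix(stats::runif(lw[l] * lw[l + 1], -lim, lim),
                            lw[l], lw[l + 1])
    params$b[[l]] <- rep(0, lw[l + 1])
  }
  params
}

.act <- function(z, activation) {
  if (activation == "tanh") tanh(z) else pmax(z, 0)
}
.act_grad <- function(a, activation) {
  if (activation == "tanh") 1 - a^2 else (a > 0) * 1
}

# forward pass; returns activations per layer and the CV output vector
.mlp_forward <- function(params, X, activation) {
  L <- length(params$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(X), length(params$b[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < L) .act(z, activation) else z
  }
  list(acts = acts, out = drop(acts[[L + 1]]))
}

#' TDA loss of grouped CV values
#'
#' \deqn{L = \sum_c (\mu_c - \tilde\mu_c)^2 +
#'       \alpha\,(\sigma_c - \tilde\sigma_c)^2}
#' with \eqn{\mu_c, \sigma_c} the batch mean and (sample) standard
#' deviation of the CV within class c. Zero iff every class batch
#' matches its target mean and sd; invariant to within-class
#' permutation of samples.
#'
#' @param cv numeric vector of CV values.
#' @param classes integer class labels aligned with `cv`; the sorted
#'   unique labels are matched to the targets in order.
#' @param targets a [tda_targets()].
#' @return non-negative scalar.
#' @export
tda_loss <- function(cv, classes, targets) {
  stopifnot(inherits(targets, "tda_targets"))
  lev <- sort(unique(classes))
  if (length(lev) != targets$n_classes) {
    stop("number of classes in the batch (", length(lev),
         ") does not match the targets (", targets$n_classes, ")")
  }
  loss <- 0
  for (i in seq_along(lev)) {
    s <- cv[classes == lev[i]]
    if (length(s) < 2) {
      stop("class ", lev[i], " has fewer than 2 samples (batch error)")
    }
    loss <- loss + (mean(s) - targets$centers[i])^2 +
      targets$alpha * (stats::sd(s) - targets$sigmas[i])^2
  }
  loss
}

# dL/ds_i for the TDA loss
.tda_loss_grad <- function(cv, classes, targets) {
  lev <- sort(unique(classes))
  g <- numeric(length(cv))
  for (i in seq_along(lev)) {
    idx <- which(classes == lev[i])
    s <- cv[idx]
    n <- length(s)
    mu <- mean(s); sg <- stats::sd(s)
    g[idx] <- 2 * (mu - targets$centers[i]) / n
    if (targets$alpha > 0 && sg > 0) {
      g[idx] <- g[idx] + 2 * targets$alpha * (sg - targets$sigmas[i]) *
        (s - mu) / ((n - 1) * sg)
    }
  }
  g
}

# loss and parameter gradients by backprop (used by the trainer and the
# finite-difference gradient check)
.tda_network_grads <- function(params, X, classes, targets, activation) {
  fw <- .mlp_forward(params, X, activation)
  loss <- tda_loss(fw$out, classes, targets)
  delta <- matrix(.tda_loss_grad(fw$out, classes, targets), ncol = 1)
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(fw$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(params$W[[l]])) *
        .act_grad(fw$acts[[l]], activation)
    }
  }
  list(loss = loss, gW = gW, gb = gb, out = fw$out)
}

#' Train a discriminant collective variable
#'
#' Full-batch Adam on the TDA loss over an 80/20 stratified
#' train/validation split. Inputs are standardized by the training-set
#' mean and sd; the constants are stored in the model so that deployment
#' is self-contained. Training stops when the validation loss falls
#' below `loss_threshold` (default 0.02, the conventional convergence
#' level for this loss) or when it fails to improve over `patience`
#' epochs (warning status). Deterministic given the spec seed.
#'
#' @param features matrix or data.frame (samples x features) of
#'   switch-normalized features.
#' @param classes integer class labels, one per row; at least 3 classes.
#' @param spec an [mlp_spec()]; first layer width must equal the feature
#'   dimension.
#' @param targets a [tda_targets()].
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param val_frac validation fraction.
#' @param loss_threshold early-stop validation loss.
#' @param patience epochs without validation improvement before
#'   early-stopping with a warning.
#' @return an object of class `cv_model` with `params`, `spec`,
#'   `targets`, `norm` (standardization constants), per-epoch `history`
#'   (`train`, `val`), and `status` (`"converged"` or `"plateau"`).
#' @export
train_cv <- function(features, classes, spec, targets = tda_targets(),
                     epochs = 3000L, lr = 0.01, val_frac = 0.2,
                     loss_threshold = 0.02, patience = 300L) {
  stopifnot(inherits(spec, "mlp_spec"), inherits(targets, "tda_targets"))
  X <- as.matrix(features)
  if (ncol(X) != spec$layer_widths[1]) {
    stop("feature dimension (", ncol(X), ") does not match the first ",
         "layer width (", spec$layer_widths[1], ") (configuration error)")
  }
  lev <- sort(unique(classes))
  if (length(lev) < 3 || length(lev) != targets$n_classes) {
    stop("need one class per target center (configuration error)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  # stratified split
  val_idx <- unlist(lapply(lev, function(l) {
    idx <- which(classes == l)
    sample(idx, max(2, round(val_frac * length(idx))))
  }))
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  mu <- colMeans(X[tr_idx, , drop = FALSE])
  sdv <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- classes[tr_idx]
  Xva <- Xs[val_idx, , drop = FALSE]; yva <- classes[val_idx]

  params <- .mlp_init(spec)
  mW <- lapply(params$W, function(w) w * 0); vW <- mW
  mb <- lapply(params$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist_tr <- hist_va <- numeric(0)
  best_val <- Inf; best_epoch <- 0L
  status <- "max_epochs"

  for (ep in seq_len(epochs)) {
    g <- .tda_network_grads(params, Xtr, ytr, targets, spec$activation)
    for (l in seq_along(params$W)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$gW[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$gb[[l]]^2
      mh <- mW[[l]] / (1 - b1^ep); vh <- vW[[l]] / (1 - b2^ep)
      params$W[[l]] <- params$W[[l]] - lr * mh / (sqrt(vh) + eps)
      mh <- mb[[l]] / (1 - b1^ep); vh <- vb[[l]] / (1 - b2^ep)
      params$b[[l]] <- params$b[[l]] - lr * mh / (sqrt(vh) + eps)
    }
    val <- tda_loss(.mlp_forward(params, Xva, spec$activation)$out, yva,
                    targets)
    hist_tr <- c(hist_tr, g$loss); hist_va <- c(hist_va, val)
    if (val < best_val - 1e-12) { best_val <- val; best_epoch <- ep }
    if (val < loss_threshold) { status <- "converged"; break }
    if (ep - best_epoch >= patience) {
      warning("validation loss plateaued above the convergence ",
              "threshold; early-stopping")
      status <- "plateau"
      break
    }
  }

  structure(list(params = params, spec = spec, targets = targets,
                 norm = list(mean = mu, sd = sdv),
                 history = data.frame(epoch = seq_along(hist_tr),
                                      train = hist_tr, val = hist_va),
                 class_levels = lev, status = status,
                 final_val_loss = hist_va[length(hist_va)]),
            class = "cv_model")
}

#' Evaluate a trained CV model
#'
#' Pure function of the stored weights: inputs are standardized with the
#' model's training constants and passed through the network. If class
#' labels are supplied, per-class mean and sd summaries are computed
#' exactly from the returned series.
#'
#' @param model a `cv_model` from [train_cv()].
#' @param features matrix or data.frame (samples x features).
#' @param classes optional labels for per-class summaries.
#' @return list with `values` (CV series) and, when labels are given,
#'   `summary` (data.frame class / mean / sd).
#' @export
evaluate_cv <- function(model, features, classes = NULL) {
  stopifnot(inherits(model, "cv_model"))
  X <- as.matrix(features)
  if (ncol(X) != model$spec$layer_widths[1]) {
    stop("feature dimension does not match the model")
  }
  Xs <- sweep(sweep(X, 2, model$norm$mean), 2, model$norm$sd, `/`)
  out <- .mlp_forward(model$params, Xs, model$spec$activation)$out
  res <- list(values = out)
  if (!is.null(classes)) {
    lev <- sort(unique(classes))
    res$summary <- data.frame(
      class = lev,
      mean = vapply(lev, function(l) mean(out[classes == l]), numeric(1)),
      sd = vapply(lev, function(l) stats::sd(out[classes == l]),
                  numeric(1)))
  }
  res
}

#' Save / load a CV model as a portable text file
#'
#' The model is serialized as JSON (weights, spec, normalization,
#' history) so it can be versioned and inspected.
#'
#' @param model a `cv_model`.
#' @param path file path.
#' @export
write_cv_model <- function(model, path) {
  stopifnot(inherits(model, "cv_model"))
  obj <- list(layer_widths = model$spec$layer_widths,
              activation = model$spec$activation,
              seed = model$spec$seed,
              W = lapply(model$params$W, function(w) unclass(w)),
              b = model$params$b,
              norm_mean = model$norm$mean, norm_sd = model$norm$sd,
              centers = model$targets$centers,
              sigmas = model$targets$sigmas, alpha = model$targets$alpha,
              history = model$history, status = model$status,
              class_levels = model$class_levels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
}

#' @rdname write_cv_model
#' @return for the reader, the restored `cv_model`.
#' @export
read_cv_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- mlp_spec(o$layer_widths, o$activation, o$seed)
  params <- list(W = lapply(o$W, as.matrix), b = lapply(o$b, as.numeric))
  structure(list(params = params, spec = spec,
                 targets = tda_targets(o$centers, o$sigmas, o$alpha),
                 norm = list(mean = o$norm_mean, sd = o$norm_sd),
                 history = as.data.frame(o$history),
                 class_levels = o$class_levels, status = o$status,
                 final_val_loss = utils::tail(o$history$val, 1)),
            class = "cv_model")
}
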