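#' Descriptor specification for the delta model
#'
#' Rotation- and permutation-invariant atom-centred descriptors with a
#' 4 A cosine cutoff: per-element Gaussian radial channels on a grid of
#' centres, and angular channels of the form
#' \eqn{2^{1-\zeta} (1 + \lambda\cos\theta)^\zeta
#'      e^{-\eta(r_{ij}^2 + r_{ik}^2)} f_c(r_{ij}) f_c(r_{ik})}
#' resolved by neighbour-pair element (O-O, O-H, H-H).  All features go to
#' zero smoothly at the cutoff; the short 4 A range mirrors the
#' reduced-capacity principle for delta corrections, which are far more
#' local than the baseline interactions.
#'
#' @param cutoff descriptor cutoff, A (default 4.0)
#' @param centers radial grid centres, A (all strictly inside the cutoff)
#' @param width radial Gaussian width, A
#' @param zeta,lambda,eta parallel vectors defining the angular channel set
#'   (default 12 combinations: zeta 1 and 2, lambda +-1, at three radial
#'   envelopes eta = 0.04, 0.1, 0.25 1/A^2, spanning 1/cos/cos^2 angular
#'   content with enough radial resolution for few-body corrections)
#' @return an object of class `descriptor_spec`
#' @export
descriptor_spec <- function(cutoff = 4.0,
                            centers = seq(0.5, 3.75, by = 0.25),
                            width = 0.25,
                            zeta = rep(c(1, 1, 2, 2), 3),
                            lambda = rep(c(1, -1), 6),
                            eta = rep(c(0.04, 0.1, 0.25), each = 4)) {
  stopifnot(cutoff > 0, all(centers < cutoff), width > 0,
            length(zeta) == length(lambda), length(zeta) == length(eta))
  structure(list(cutoff = cutoff, centers = centers, width = width,
                 zeta = zeta, lambda = lambda, eta = eta),
            class = "descriptor_spec")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat(sprintf("<descriptor_spec: cutoff %.1f A, %d radial centres, %d angular combos (%d features/atom)>\n",
              x$cutoff, length(x$centers), length(x$zeta), .n_feat(x)))
  invisible(x)
}

.n_feat <- function(spec) 2L * length(spec$centers) + 3L * length(spec$zeta)

.spec_list <- function(spec) unclass(spec)

#' Per-atom descriptor features
#'
#' Computes the feature matrix (one row per atom) for an open or periodic
#' configuration; identical machinery for both, with minimum-image distances
#' when periodic.  An isolated atom, or any neighbour beyond the cutoff,
#' contributes zeros.
#'
#' @param cfg an [atoms()] configuration
#' @param spec a [descriptor_spec()]
#' @return numeric N x n_features matrix
#' @export
featurize <- function(cfg, spec = descriptor_spec()) {
  L <- if (cfg$periodic) cell_edge(cfg) else 0
  ml_featurize_cpp(cfg$positions, .elem_codes(cfg$elements), L,
                   cfg$periodic, .spec_list(spec))
}

# cluster-level design row: per-element feature sums plus molecule count
.design_row <- function(cfg, spec) {
  G <- featurize(cfg, spec)
  o <- cfg$elements == "O"
  c(colSums(G[o, , drop = FALSE]), colSums(G[!o, , drop = FALSE]),
    sum(o))
}

#' Fit the delta model by ridge regression on energy labels
#'
#' The core fitting routine: regresses total cluster energy differences
#' `E_HL - E_LL` on summed per-element atomic descriptors (design row =
#' per-O-atom feature sums, per-H-atom feature sums, and the molecule count,
#' whose coefficient acts as a per-molecule intercept absorbing the
#' size-proportional part of the label).  Features are standardised by
#' training-set mean and scale (stored in the model); the ridge system is
#' solved in closed form.  Training uses energies only; forces come from
#' differentiating the fitted model analytically.
#'
#' The validation split is taken from the dataset manifest (stratified by
#' radius at build time) unless `val_fraction` is given, in which case a
#' fresh stratified split is drawn from `seed`.  Column scales are floored
#' at 1% of the largest scale so that descriptor channels with (near-)zero
#' training variance keep near-zero weights instead of being amplified into
#' extrapolation artefacts.
#'
#' @param dataset a labelled [build_cluster_dataset()] result
#' @param descriptor a [descriptor_spec()]
#' @param lambda ridge regularisation strength (default 1e-6)
#' @param seed integer seed (only used when re-drawing the split)
#' @param val_fraction optional validation fraction overriding the manifest
#' @return an object of class `delta_model` with components `descriptor`,
#'   `coefficients`, `scaling`, `intercept`, effective per-atom weights for
#'   prediction, and `report` (a `train_report`: train/val RMSE per
#'   molecule, per-radius validation breakdown, sizes, seed, lambda)
#' @seealso [predict.delta_model()], [evaluate_composite()]
#' @export
delta_fit <- function(dataset, descriptor = descriptor_spec(),
                      lambda = 1e-6, seed = 1, val_fraction = NULL) {
  stopifnot(inherits(dataset, "cluster_dataset"))
  if (is.null(dataset$labels)) stop("dataset is unlabelled; run label_delta() first")
  n <- length(dataset$clusters)
  if (n < 2) stop("need at least 2 clusters to fit")
  split <- dataset$manifest$split
  if (!is.null(val_fraction)) {
    split <- rep("train", n)
    for (r_c in unique(dataset$manifest$radius)) {
      idx <- which(dataset$manifest$radius == r_c)
      nv <- round(val_fraction * length(idx))
      if (nv > 0)
        split[.with_seed(.derive_seed(seed, 991L, match(r_c, unique(dataset$manifest$radius))),
                         sample(idx, nv))] <- "val"
    }
  }
  X <- t(vapply(dataset$clusters, .design_row, numeric(2 * .n_feat(descriptor) + 1),
                spec = descriptor))
  y <- dataset$labels
  tr <- split == "train"; va <- !tr
  mu <- colMeans(X[tr, , drop = FALSE])
  sc <- apply(X[tr, , drop = FALSE], 2, sd)
  sc[!is.finite(sc)] <- 0
  # floor the scales: near-constant columns (descriptor channels probing
  # geometry absent from the training set, e.g. very short distances) must
  # not be amplified by standardisation, or the model develops spurious
  # short-range holes when such geometry appears at prediction time
  smax <- max(sc)
  sc <- if (smax <= 0) rep(1, length(sc)) else pmax(sc, 0.01 * smax)
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  ybar <- mean(y[tr])
  A <- crossprod(Xs[tr, , drop = FALSE]) + diag(lambda, ncol(Xs))
  b <- crossprod(Xs[tr, , drop = FALSE], y[tr] - ybar)
  beta <- tryCatch(solve(A, b), error = function(e) {
    if (lambda <= 0)
      stop("ridge system is singular at lambda = 0; use lambda > 0")
    stop(e)
  })
  beta <- drop(beta)
  yhat <- drop(Xs %*% beta) + ybar
  # effective (descaled) weights for fast prediction with analytic forces
  v <- beta / sc
  nf <- .n_feat(descriptor)
  econst0 <- ybar - sum(beta * mu / sc) # includes the nmol-column offset
  vO <- v[seq_len(nf)]
  vH <- v[nf + seq_len(nf)]
  econst_per_mol <- v[2 * nf + 1]

  nmol <- dataset$manifest$n_mol
  rpm <- (y - yhat) / nmol
  rmse <- function(e) if (length(e)) sqrt(mean(e^2)) else NA_real_
  by_radius <- vapply(sort(unique(dataset$manifest$radius)), function(r_c)
    rmse(rpm[va & dataset$manifest$radius == r_c]), 0)
  names(by_radius) <- sprintf("%.1f", sort(unique(dataset$manifest$radius)))
  report <- structure(list(n_train = sum(tr), n_val = sum(va),
                           rmse_per_mol_train = rmse(rpm[tr]),
                           rmse_per_mol_val = rmse(rpm[va]),
                           val_rmse_by_radius = by_radius,
                           lambda = lambda, seed = seed),
                      class = "train_report")
  structure(list(descriptor = descriptor, coefficients = beta,
                 scaling = list(mu = mu, sd = sc), intercept = ybar,
                 vO = vO, vH = vH, econst0 = econst0,
                 econst_per_mol = econst_per_mol, lambda = lambda,
                 seed = seed, report = report,
                 fitted = data.frame(y = y, yhat = yhat, split = split,
                                     radius = dataset$manifest$radius,
                                     n_mol = nmol)),
            class = "delta_model")
}

# pack for the compiled MD/predict layer
.model_pack <- function(model) {
  list(spec = .spec_list(model$descriptor), vO = model$vO, vH = model$vH,
       econst0 = model$econst0, econst_per_mol = model$econst_per_mol)
}

#' Predict delta energies and forces
#'
#' Evaluates the fitted linear model on a configuration: energy as the
#' weighted sum of per-atom features plus the per-molecule intercept,
#' forces as the exact analytic chain-rule gradient, and the virial from
#' per-pair/per-triplet feature derivatives.  Works on periodic boxes even
#' though the model is trained on open clusters - the cluster-to-bulk
#' transfer that delta learning relies on.
#'
#' @param object a `delta_model`
#' @param newdata an [atoms()] configuration, or a `cluster_dataset`
#'   (returns the vector of predicted label energies)
#' @param ... unused
#' @return a `potential_result` for a single configuration; a numeric
#'   vector for a dataset
#' @export
predict.delta_model <- function(object, newdata, ...) {
  if (inherits(newdata, "cluster_dataset")) {
    return(vapply(newdata$clusters, function(cl)
      predict(object, cl)$energy, 0))
  }
  stopifnot(inherits(newdata, "atoms"))
  if (!all(newdata$elements %in% c("O", "H")))
    stop("element outside the training set (model knows O and H)")
  topo <- identify_molecules(newdata)
  L <- if (newdata$periodic) cell_edge(newdata) else 0
  res <- ml_evaluate_cpp(newdata$positions, .elem_codes(newdata$elements),
                         L, newdata$periodic, .spec_list(object$descriptor),
                         object$vO, object$vH,
                         object$econst0 + object$econst_per_mol * topo$n_mol)
  structure(res, class = "potential_result")
}

#' @export
print.delta_model <- function(x, ...) {
  cat(sprintf("<delta_model: %d features/element, lambda = %g>\n",
              .n_feat(x$descriptor), x$lambda))
  print(x$report)
  invisible(x)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("  train: n = %d, RMSE/molecule = %.3e eV\n",
              x$n_train, x$rmse_per_mol_train))
  cat(sprintf("  val  : n = %d, RMSE/molecule = %.3e eV\n",
              x$n_val, x$rmse_per_mol_val))
  if (length(x$val_rmse_by_radius))
    cat("  val RMSE by radius (A):",
        paste(sprintf("%s: %.2e", names(x$val_rmse_by_radius),
                      x$val_rmse_by_radius), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.delta_model <- function(object, ...) {
  cat("Delta model (ridge regression on invariant descriptors)\n")
  print(object$descriptor)
  print(object$report)
  invisible(object$report)
}

#' @export
coef.delta_model <- function(object, ...) {
  nf <- .n_feat(object$descriptor)
  setNames(c(object$intercept, object$coefficients),
           c("(intercept)",
             paste0("O.", seq_len(nf)), paste0("H.", seq_len(nf)), "n_mol"))
}

#' @export
residuals.delta_model <- function(object, ...) {
  with(object$fitted, y - yhat)
}

#' Parity plot of fitted vs reference labels
#' @param x a `delta_model`
#' @param ... passed to [graphics::plot()]
#' @export
plot.delta_model <- function(x, ...) {
  f <- x$fitted
  graphics::plot(f$y, f$yhat, col = ifelse(f$split == "val", 2, 1),
                 pch = 16, cex = 0.5,
                 xlab = "reference delta energy (eV)",
                 ylab = "fitted delta energy (eV)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", c("train", "validation"), col = c(1, 2),
                   pch = 16, bty = "n")
  invisible(x)
}

#' Save / load a delta model as portable JSON
#'
#' Serialises the descriptor, scalers, weights and training report to a
#' single JSON container, with an MD5 provenance hash of the training
#' manifest when available.
#'
#' @param model a `delta_model`
#' @param path output path
#' @return `path` invisibly; `read_delta_model()` returns the model
#' @export
write_delta_model <- function(model, path) {
  obj <- list(descriptor = unclass(model$descriptor),
              coefficients = model$coefficients,
              mu = model$scaling$mu, sd = model$scaling$sd,
              intercept = model$intercept, lambda = model$lambda,
              seed = model$seed,
              report = unclass(model$report))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_delta_model
#' @export
read_delta_model <- function(path) {
  o <- jsonlite::fromJSON(path)
  desc <- do.call(descriptor_spec,
                  o$descriptor[c("cutoff", "centers", "width", "zeta",
                                 "lambda", "eta")])
  beta <- as.numeric(o$coefficients)
  mu <- as.numeric(o$mu); sc <- as.numeric(o$sd)
  nf <- .n_feat(desc)
  v <- beta / sc
  structure(list(descriptor = desc, coefficients = beta,
                 scaling = list(mu = mu, sd = sc),
                 intercept = o$intercept,
                 vO = v[seq_len(nf)], vH = v[nf + seq_len(nf)],
                 econst0 = o$intercept - sum(beta * mu / sc),
                 econst_per_mol = v[2 * nf + 1],
                 lambda = o$lambda, seed = o$seed,
                 report = structure(o$report, class = "train_report"),
                 fitted = NULL),
            class = "delta_model")
}

#' A zero delta model (predicts exactly zero everywhere)
#'
#' Useful as the additive identity: the composite of the baseline with a
#' zero model is the baseline.
#'
#' @param descriptor a [descriptor_spec()]
#' @return a `delta_model` with all-zero weights
#' @export
zero_delta_model <- function(descriptor = descriptor_spec()) {
  nf <- .n_feat(descriptor)
  structure(list(descriptor = descriptor,
                 coefficients = numeric(2 * nf + 1),
                 scaling = list(mu = numeric(2 * nf + 1),
                                sd = rep(1, 2 * nf + 1)),
                 intercept = 0, vO = numeric(nf), vH = numeric(nf),
                 econst0 = 0, econst_per_mol = 0, lambda = 0, seed = 0,
                 report = NULL, fitted = NULL),
            class = "delta_model")
}
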