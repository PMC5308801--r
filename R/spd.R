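# Covariance descriptors and affine-invariant geometry on the SPD manifold.
#
# A trial's spatial covariance C = (1/Nt)(X - Xbar)(X - Xbar)' captures its
# second-order kinematics independently of duration and starting posture.
# SPD matrices are handled as points of a Riemannian manifold: distances use
# the affine-invariant metric, averaging uses the log-Euclidean mean, and
# classification works in the tangent space at that mean.

# ---- low-level symmetric-matrix functional calculus ----

# Eigendecomposition of a (nominally) symmetric matrix, with an asymmetry
# guard: asymmetry beyond tolerance is an error, never silently fixed.
sym_eig <- function(a, tol = 1e-8, what = "matrix") {
  scale <- max(abs(a), 1e-300)
  if (max(abs(a - t(a))) > tol * scale) {
    abort(paste0(what, " is not symmetric within tolerance"),
          class = "riemsway_numeric_error")
  }
  eigen((a + t(a)) / 2, symmetric = TRUE)
}

# f(A) for symmetric A via eigendecomposition; fname used in error messages.
spd_fun <- function(a, f, fname, require_pos = TRUE, what = "matrix") {
  e <- sym_eig(a, what = what)
  if (require_pos && any(e$values <= 0)) {
    abort(sprintf("%s has a non-positive eigenvalue (min %.3e); cannot take %s",
                  what, min(e$values), fname),
          class = "riemsway_numeric_error")
  }
  v <- e$vectors
  v %*% (f(e$values) * t(v))
}

spd_logm <- function(a, what = "matrix") spd_fun(a, log, "Log", TRUE, what)
spd_expm <- function(a, what = "matrix") spd_fun(a, exp, "Exp", FALSE, what)
spd_power <- function(a, p, what = "matrix") {
  spd_fun(a, function(x) x^p, sprintf("power %.2g", p), TRUE, what)
}

is_spd <- function(a, tol = 1e-10) {
  is.matrix(a) && nrow(a) == ncol(a) &&
    max(abs(a - t(a))) <= tol * max(abs(a), 1e-300) &&
    min(eigen((a + t(a)) / 2, symmetric = TRUE, only.values = TRUE)$values) > 0
}

# ---- covariance estimation ----

#' Spatial covariance of a trial
#'
#' Estimates `C = (1/Nt) (X - Xbar)(X - Xbar)'` with the biased 1/Nt
#' normalisation, after removing each channel's mean (so the descriptor is
#' independent of the subject's starting posture).  An optional shrinkage
#' term `shrinkage * (trace(C)/N) * I` keeps near-constant channels (e.g.
#' crossed arms) from producing zero eigenvalues, which the matrix
#' logarithm cannot tolerate.
#'
#' @param x A channels x frames numeric matrix, or a trial table, in which
#'   case a `cov` list-column is added.
#' @param shrinkage Nonnegative diagonal-loading fraction (default 0 for
#'   the bare estimator; model-fitting functions default to `1e-6`).
#' @return A symmetric N x N matrix, or the trial table with a `cov`
#'   list-column.
#' @examples
#' x <- matrix(rnorm(3 * 100), 3)
#' estimate_covariance(x)
#' @export
estimate_covariance <- function(x, shrinkage = 0) {
  if (is.data.frame(x)) {
    x$cov <- purrr::map(x$samples, estimate_covariance, shrinkage = shrinkage)
    return(x)
  }
  if (!is.matrix(x) || ncol(x) < 2) {
    abort("Need a matrix with at least 2 frames (columns)",
          class = "riemsway_input_error")
  }
  if (shrinkage < 0) {
    abort("shrinkage must be >= 0", class = "riemsway_input_error")
  }
  nt <- ncol(x)
  xc <- x - rowMeans(x)
  cc <- tcrossprod(xc) / nt
  cc <- (cc + t(cc)) / 2
  if (shrinkage > 0) {
    n <- nrow(cc)
    cc <- cc + shrinkage * (sum(diag(cc)) / n) * diag(n)
  } else {
    lam_min <- min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values)
    if (lam_min <= 0) {
      warn(sprintf(
        "covariance is not positive definite (min eigenvalue %.3e); consider shrinkage > 0",
        lam_min))
      attr(cc, "spd") <- FALSE
    }
  }
  dimnames(cc) <- list(rownames(x), rownames(x))
  cc
}

# ---- metric ----

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `sqrt(sum(log(lambda_i)^2))` over the eigenvalues `lambda_i` of
#' `solve(c1) %*% c2`.  The metric is invariant under any common invertible
#' channel transform `V`: `d(V C1 V', V C2 V') = d(C1, C2)`, which makes
#' downstream classification robust to camera placement, subject height and
#' body proportions.  Computed through the symmetric whitened form
#' `c1^{-1/2} c2 c1^{-1/2}` for numerical stability.
#'
#' @param c1,c2 SPD matrices of equal dimension.
#' @return Nonnegative scalar distance.
#' @examples
#' riemann_distance(diag(2), diag(c(4, 4)))  # sqrt(2) * log(4)
#' @export
riemann_distance <- function(c1, c2) {
  if (!is.matrix(c1) || !is.matrix(c2) || any(dim(c1) != dim(c2))) {
    abort("Dimension mismatch between SPD matrices",
          class = "riemsway_input_error")
  }
  w <- spd_power(c1, -0.5, what = "first matrix")
  m <- w %*% c2 %*% w
  lam <- sym_eig(m, what = "whitened matrix")$values
  if (any(lam <= 0)) {
    abort("second matrix is not positive definite (non-positive eigenvalue)",
          class = "riemsway_numeric_error")
  }
  sqrt(sum(log(lam)^2))
}

#' Log-Euclidean mean of SPD matrices
#'
#' `Exp(mean(Log(C_i)))`: the exponential of the arithmetic mean of matrix
#' logarithms, a fast surrogate for the Karcher mean used as the tangent
#' space reference point.
#'
#' @param mats Non-empty list of SPD matrices with a common dimension.
#' @return An SPD matrix.
#' @export
logeuclid_mean <- function(mats) {
  if (!is.list(mats) || length(mats) == 0) {
    abort("Need a non-empty list of SPD matrices",
          class = "riemsway_input_error")
  }
  logs <- purrr::map(mats, spd_logm)
  spd_expm(Reduce(`+`, logs) / length(logs))
}

# ---- tangent space ----

# Row-major upper-triangle vectorization with unit weight on the diagonal
# and sqrt(2) off the diagonal, so the Euclidean norm of the vector equals
# the Frobenius norm of the symmetric matrix.
upper_vec <- function(s) {
  n <- nrow(s)
  w <- matrix(sqrt(2), n, n); diag(w) <- 1
  mask <- lower.tri(s, diag = TRUE)   # of t(s): row-major upper of s
  (t(s) * t(w))[mask]
}

# Inverse of upper_vec (used for round-trip checks and exports).
upper_unvec <- function(v) {
  n <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9) {
    abort("Vector length is not N(N+1)/2", class = "riemsway_input_error")
  }
  n <- round(n)
  s <- matrix(0, n, n)
  s[lower.tri(s, diag = TRUE)] <- v
  s <- t(s)
  off <- upper.tri(s)
  s[off] <- s[off] / sqrt(2)
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  s
}

#' Project an SPD matrix to the tangent space of a reference point
#'
#' Computes the tangent matrix `S = Log(Cref^{-1/2} C Cref^{-1/2})` and
#' vectorizes its upper triangle with weight 1 on the diagonal and sqrt(2)
#' off it, so `||s||_2` equals the Riemannian distance from `C` to the
#' reference.
#'
#' @param c An SPD matrix.
#' @param reference The reference SPD matrix, or a fitted tangent model
#'   (see [fit_tangent_model()]) whose cached whitener is reused.
#' @return Numeric vector of length `N(N+1)/2`.
#' @export
tangent_project <- function(c, reference) {
  w <- if (inherits(reference, "tangent_model")) {
    if (any(dim(c) != dim(reference$reference))) {
      abort("Dimension mismatch with the model reference",
            class = "riemsway_input_error")
    }
    reference$inverse_sqrt_reference
  } else {
    if (any(dim(c) != dim(reference))) {
      abort("Dimension mismatch with the reference",
            class = "riemsway_input_error")
    }
    spd_power(reference, -0.5, what = "reference")
  }
  s <- spd_logm(w %*% c %*% w, what = "whitened matrix")
  upper_vec(s)
}

#' Fit a tangent-space feature model
#'
#' The feature pipeline for a set of trials: (1) estimate each trial's
#' spatial covariance, (2) take the log-Euclidean mean of those covariances
#' as the reference point, (3) project every covariance to the tangent
#' space at the reference, (4) vectorize.  The returned model carries the
#' reference (and its cached inverse square root) so held-out trials can be
#' projected into the same feature space without refitting.
#'
#' @param trials A trial table; for MK2 data optionally restricted first
#'   via `subset`.
#' @param subset Optional joint subset applied with [select_channels()]
#'   (`NULL` keeps the channels as they are; use it for KFP trials).
#' @param shrinkage Covariance diagonal loading (default `1e-6`).
#' @return An object of class `tangent_model` with elements `reference`,
#'   `inverse_sqrt_reference`, `shrinkage`, `subset`, `channel_labels`, and
#'   `features`, the trials-by-coordinates matrix of tangent vectors.
#' @export
fit_tangent_model <- function(trials, subset = NULL, shrinkage = 1e-6) {
  if (nrow(trials) < 1) {
    abort("Need at least one trial", class = "riemsway_input_error")
  }
  if (!is.null(subset)) trials <- select_channels(trials, subset)
  labs <- rownames(trials$samples[[1]])
  ok <- purrr::map_lgl(trials$samples, ~ identical(rownames(.x), labs))
  if (!all(ok)) {
    abort("Trials do not share a common channel layout",
          class = "riemsway_input_error")
  }
  covs <- purrr::map(trials$samples, estimate_covariance,
                     shrinkage = shrinkage)
  reference <- logeuclid_mean(covs)
  w <- spd_power(reference, -0.5, what = "reference")
  feats <- do.call(rbind, purrr::map(covs, function(ci) {
    upper_vec(spd_logm(w %*% ci %*% w, what = "whitened covariance"))
  }))
  structure(
    list(reference = reference, inverse_sqrt_reference = w,
         shrinkage = shrinkage, subset = subset, channel_labels = labs,
         features = feats, meta = trials[, c("subject", "task", "condition",
                                             "device")]),
    class = "tangent_model")
}

#' @export
print.tangent_model <- function(x, ...) {
  n <- nrow(x$reference)
  cat(sprintf("Tangent feature model: %d channels -> %d coordinates, %d trials\n",
              n, n * (n + 1) / 2, nrow(x$features)))
  cat(sprintf("  shrinkage %.1e, subset %s\n", x$shrinkage,
              x$subset %||% "(as provided)"))
  invisible(x)
}

#' Project trials with a fitted tangent model
#'
#' @param object A `tangent_model`.
#' @param trials A trial table with the model's channel layout (the model's
#'   joint subset is applied automatically).
#' @param ... Unused.
#' @return Matrix of tangent vectors, one row per trial.
#' @export
predict.tangent_model <- function(object, trials, ...) {
  if (!is.null(object$subset)) trials <- select_channels(trials, object$subset)
  covs <- purrr::map(trials$samples, estimate_covariance,
                     shrinkage = object$shrinkage)
  do.call(rbind, purrr::map(covs, tangent_project, reference = object))
}

#' Tidy tangent features
#'
#' @param x A `tangent_model`.
#' @param ... Unused.
#' @return A tibble: trial metadata plus one column per tangent coordinate.
#' @export
tidy.tangent_model <- function(x, ...) {
  f <- tibble::as_tibble(x$features, .name_repair = ~ paste0("s", seq_along(.x)))
  dplyr::bind_cols(x$meta, f)
}

#' Export tangent features as CSV with a JSON sidecar
#'
#' Writes one row per trial (metadata + tangent coordinates) and a sidecar
#' `<path>.json` recording the subset, shrinkage and reference matrix so
#' the feature space can be reconstructed.
#'
#' @param model A `tangent_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(model, path) {
  readr::write_csv(tidy(model), path, progress = FALSE)
  side <- list(subset = model$subset %||% "as-provided",
               shrinkage = model$shrinkage,
               channel_labels = model$channel_labels,
               reference = model$reference)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
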