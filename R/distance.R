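# Pairwise Riemannian distance matrices and 2-D embeddings for cluster
# inspection.

#' Pairwise Riemannian distances between trial covariances
#'
#' Computes the affine-invariant distance between every pair of trial
#' covariances.  Each trial's inverse square root is cached so a K-trial
#' dataset costs K eigendecompositions plus one per pair.
#'
#' @param trials A trial table (single device or an explicit subset).
#' @param subset Optional joint subset for MK2 trials.
#' @param shrinkage Covariance diagonal loading (default `1e-6`).
#' @return An object of class `sway_dist`: `values` (symmetric K x K
#'   matrix, zero diagonal) and `labels` (trial metadata tibble).
#' @export
pairwise_distances <- function(trials, subset = NULL, shrinkage = 1e-6) {
  if (nrow(trials) < 2) {
    abort("Need at least two trials", class = "riemsway_input_error")
  }
  if (!is.null(subset)) trials <- select_channels(trials, subset)
  covs <- purrr::map(trials$samples, estimate_covariance,
                     shrinkage = shrinkage)
  k <- length(covs)
  ws <- purrr::map(covs, spd_power, p = -0.5)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    wi <- ws[[i]]
    for (j in (i + 1):k) {
      lam <- sym_eig(wi %*% covs[[j]] %*% wi, what = "whitened matrix")$values
      d[i, j] <- d[j, i] <- sqrt(sum(log(pmax(lam, 1e-300))^2))
    }
  }
  structure(list(values = d,
                 labels = trials[, c("subject", "task", "condition",
                                     "device")]),
            class = "sway_dist")
}

#' @export
print.sway_dist <- function(x, ...) {
  cat(sprintf("Riemannian distance matrix over %d trials (mean off-diagonal %.3f)\n",
              nrow(x$values), mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Write a distance matrix as CSV
#' @param dm A `sway_dist`.
#' @param path Output path; rows/columns labelled `subject|task|condition`.
#' @return `path`, invisibly.
#' @export
write_distances_csv <- function(dm, path) {
  lab <- paste(dm$labels$subject, dm$labels$task, dm$labels$condition,
               sep = "|")
  out <- tibble::as_tibble(dm$values, .name_repair = ~lab)
  out <- dplyr::bind_cols(tibble::tibble(trial = lab), out)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' 2-D t-SNE embedding of a Riemannian distance matrix
#'
#' Runs t-SNE on the precomputed distance matrix (exact gradients, so small
#' K is fine).  Coordinates are for visual inspection only; nothing
#' downstream depends on them beyond cluster membership.
#'
#' @param dm A `sway_dist` from [pairwise_distances()].
#' @param perplexity t-SNE perplexity; the default 30 is capped at
#'   `(K - 1) / 3`.  An explicit perplexity too large for K is an error.
#' @param seed RNG seed for the embedding initialisation.
#' @param max_iter Gradient-descent iterations (default 500).
#' @return A tibble of class `sway_embedding`: trial metadata plus
#'   `dim1`, `dim2`.
#' @export
embed_2d <- function(dm, perplexity = NULL, seed = 1, max_iter = 500) {
  k <- nrow(dm$values)
  cap <- (k - 1) / 3
  if (is.null(perplexity)) {
    perplexity <- min(30, cap)
  } else if (k <= 3 * perplexity) {
    abort(sprintf("K = %d is too small for perplexity %g (need K > 3*perplexity)",
                  k, perplexity),
          class = "riemsway_input_error")
  }
  if (!requireNamespace("Rtsne", quietly = TRUE)) {
    abort("embed_2d needs the Rtsne package", class = "riemsway_input_error")
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(dm$values, is_distance = TRUE, dims = 2,
                      perplexity = perplexity, theta = 0,
                      max_iter = max_iter, pca = FALSE, verbose = FALSE)
  out <- dm$labels
  out$dim1 <- fit$Y[, 1]
  out$dim2 <- fit$Y[, 2]
  class(out) <- c("sway_embedding", class(out))
  out
}
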