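# Shared fixtures, built in code.  Random draws always sit behind an
# explicit seed set by the caller or here.

# Random SPD matrix with eigenvalues bounded away from zero.
rand_spd <- function(n) {
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n + 0.5 * diag(n)
}

# Random orthogonal matrix.
rand_orth <- function(n) qr.Q(qr(matrix(rnorm(n * n), n)))

# Brute-force spatial covariance: explicit double loop over channel pairs,
# independent of the matrix-algebra implementation path.
brute_cov <- function(x) {
  n <- nrow(x); nt <- ncol(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      mi <- sum(x[i, ]) / nt
      mj <- sum(x[j, ]) / nt
      out[i, j] <- sum((x[i, ] - mi) * (x[j, ] - mj)) / nt
    }
  }
  out
}

# A small paired dataset reused across test files (cached per session).
.fixture_env <- new.env(parent = emptyenv())

small_config <- function() {
  synthetic_config(n_subjects = 4, n_tasks = 3, frames = 80,
                   template_separation = 2, seed = 11)
}

small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_dataset(small_config())
  }
  .fixture_env$small
}

small_mk2 <- function() dplyr::filter(small_dataset(), device == "MK2")

# A minimal MK2 trial table built directly from a matrix.
toy_mk2 <- function(x, subject = "S01", task = 1, condition = 1) {
  sway_trials(subject, task, condition, "MK2", list(x))
}
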