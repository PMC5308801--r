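# Synthetic paired-device generator.
#
# Emulates the statistical structure the pipeline assumes: per-task
# covariance templates, a condition effect that inflates variance in a
# low-dimensional "sway subspace" (so conditions are not separable by total
# variance alone), a per-subject affine transform (scale x rotation, the
# robustness case for the affine-invariant metric), AR(1) temporal
# smoothness with unit stationary variance, and a noisy 600 Hz COP channel
# read out from the mid-spine trajectory.

#' Synthetic dataset configuration
#'
#' Defaults mirror the seated balance protocol: 12 subjects x 6 tasks x 3
#' postural conditions, 10-second skeleton trials (300 frames at 30 Hz)
#' paired with 600 Hz force-platform traces.
#'
#' @param n_subjects,n_tasks,n_conditions Design counts.
#' @param frames Skeleton frames per trial (default 300, i.e. 10 s).
#' @param mk2_rate_hz,kfp_rate_hz Sampling rates (30 and 600 Hz).
#' @param ar_coefficient AR(1) coefficient of the latent sources in
#'   `[0, 1)`; innovations are scaled by `sqrt(1 - phi^2)` so the
#'   stationary variance is exactly 1 and the population covariance of a
#'   trial equals its mixing Gram matrix.
#' @param condition_effect Variance multipliers of the sway subspace, one
#'   per condition, non-decreasing (default `c(1, 1.5, 2.25)`).
#' @param subject_transform_scale Magnitude of the per-subject random
#'   scale/rotation (default 0.1; 0 disables it).
#' @param cop_noise_sd SD of the Gaussian noise added to the COP read-out
#'   in meters (default 0.2).
#' @param template_separation Minimum pairwise Riemannian distance between
#'   task templates (default 4).
#' @param sway_dim Dimension of the sway subspace the condition effect acts
#'   on (default 6).
#' @param template_rank Rank of the random factor in each task template
#'   (default 6).
#' @param seed Master seed; every trial derives its own stream from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 12, n_tasks = 6, n_conditions = 3,
                             frames = 300, mk2_rate_hz = 30,
                             kfp_rate_hz = 600, ar_coefficient = 0.95,
                             condition_effect = c(1, 1.5, 2.25),
                             subject_transform_scale = 0.1,
                             cop_noise_sd = 0.2, template_separation = 4,
                             sway_dim = 6, template_rank = 6, seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_tasks = as.integer(n_tasks),
              n_conditions = as.integer(n_conditions),
              frames = as.integer(frames), mk2_rate_hz = mk2_rate_hz,
              kfp_rate_hz = kfp_rate_hz, ar_coefficient = ar_coefficient,
              condition_effect = condition_effect,
              subject_transform_scale = subject_transform_scale,
              cop_noise_sd = cop_noise_sd,
              template_separation = template_separation,
              sway_dim = as.integer(sway_dim),
              template_rank = as.integer(template_rank),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_subjects, n_tasks, n_conditions, frames, sway_dim) < 1))
      abort("counts must be positive", class = "riemsway_input_error")
    if (ar_coefficient < 0 || ar_coefficient >= 1)
      abort("ar_coefficient must lie in [0, 1)",
            class = "riemsway_input_error")
    if (length(condition_effect) != n_conditions || any(condition_effect < 1))
      abort("condition_effect needs one multiplier >= 1 per condition",
            class = "riemsway_input_error")
    if (subject_transform_scale < 0 || cop_noise_sd < 0 ||
        template_separation <= 0)
      abort("scales must be nonnegative and template_separation positive",
            class = "riemsway_input_error")
  })
  structure(cfg, class = "synthetic_config")
}

# Number of MK2 channels the generator emits (upper-body joint set).
sim_channels <- function() mk2_channel_labels("upper16")

#' Per-task covariance templates
#'
#' Each template is `B_k B_k' + I` with `B_k` a random N x r factor; all
#' factors are scaled up jointly until every pairwise Riemannian distance
#' is at least `template_separation` (error after 100 doublings).
#'
#' @param config A [synthetic_config()].
#' @return List of `n_tasks` SPD matrices (48 x 48 for the default
#'   upper-body channel set).
#' @export
make_task_templates <- function(config) {
  n <- length(sim_channels())
  set.seed(config$seed)
  bs <- purrr::map(seq_len(config$n_tasks),
                   ~ matrix(rnorm(n * config$template_rank), n))
  scale <- 1
  for (attempt in seq_len(100)) {
    tpl <- purrr::map(bs, ~ tcrossprod(scale * .x) + diag(n))
    if (config$n_tasks < 2) return(tpl)
    dmin <- min(utils::combn(config$n_tasks, 2, function(ij) {
      riemann_distance(tpl[[ij[1]]], tpl[[ij[2]]])
    }))
    if (dmin >= config$template_separation) return(tpl)
    scale <- scale * 1.25
  }
  abort("template separation unattainable in 100 attempts",
        class = "riemsway_generation_error")
}

# Deterministic per-trial seed stream: master seed plus a trial counter,
# kept inside 32-bit integer range.
trial_seed <- function(config, counter) {
  as.integer((as.numeric(config$seed) * 100003 + counter * 7919) %% 2147483647)
}

# Population-level pieces shared by all trials: templates, sway basis,
# per-subject transforms, per-joint offsets.  All drawn from the master
# seed (after the template draw, which consumes its own stream).
sim_population <- function(config) {
  templates <- make_task_templates(config)
  n <- length(sim_channels())
  set.seed(config$seed + 1L)
  u <- qr.Q(qr(matrix(rnorm(n * config$sway_dim), n)))  # sway basis
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  vs <- purrr::map(subjects, function(s) {
    if (config$subject_transform_scale == 0) return(diag(n))
    a <- matrix(rnorm(n * n), n)
    skew <- (a - t(a)) / sqrt(2 * n)           # unit-ish Frobenius scale
    rot <- expm_series(config$subject_transform_scale * skew)
    exp(rnorm(1, 0, config$subject_transform_scale)) * rot
  })
  names(vs) <- subjects
  joints <- joint_subset("upper16")
  offsets <- cbind(rnorm(length(joints), 0, 0.3),
                   rnorm(length(joints), 0.8, 0.3),
                   rnorm(length(joints), 2.7, 0.1))
  offset_vec <- as.vector(t(offsets))           # joint-major x,y,z
  # mixing square roots per (task, condition):
  # L = C_k^{1/2} (I + (sqrt(gamma_c) - 1) U U')
  sq <- purrr::map(templates, spd_power, p = 0.5)
  mix <- purrr::map(seq_len(config$n_tasks), function(k) {
    purrr::map(seq_len(config$n_conditions), function(cc) {
      g <- config$condition_effect[cc]
      sq[[k]] %*% (diag(n) + (sqrt(g) - 1) * tcrossprod(u))
    })
  })
  list(templates = templates, sway_basis = u, subjects = subjects,
       transforms = vs, offset = offset_vec, mix = mix)
}

# Matrix exponential of a skew-symmetric generator (yields a rotation),
# by scaling-and-squaring with a Taylor core; ample for these magnitudes.
expm_series <- function(a) {
  s <- max(0, ceiling(log2(max(1e-300, norm(a, "F")))) + 4)
  x <- a / 2^s
  term <- diag(nrow(a)); out <- term
  for (k in 1:12) {
    term <- term %*% x / k
    out <- out + term
  }
  for (i in seq_len(s)) out <- out %*% out
  out
}

# One MK2 trial's latent AR(1) sources and mixed signal.
sim_mk2_samples <- function(config, mixing, transform, offset, frames) {
  n <- nrow(mixing)
  phi <- config$ar_coefficient
  z <- matrix(rnorm(n * frames), n, frames)
  if (phi > 0) {
    innov <- sqrt(1 - phi^2)               # stationary variance exactly 1
    for (t in 2:frames) z[, t] <- phi * z[, t - 1] + innov * z[, t]
  }
  x <- transform %*% (mixing %*% z) + offset
  rownames(x) <- sim_channels()
  x
}

#' Generate a paired synthetic dataset
#'
#' For every (subject, task, condition) cell one MK2 trial is drawn as
#' `V_s L_{k,c} z(t) + offset`, where `z` is AR(1) with unit stationary
#' variance, `L_{k,c} L_{k,c}' = C_k^{1/2} D_c C_k^{1/2}` inflates the sway
#' subspace by the condition multiplier, and `V_s` is the subject's fixed
#' scale/rotation.  The paired KFP trial reads out the SpineMid lateral and
#' depth channels, linearly interpolated to 600 Hz, plus independent
#' Gaussian noise.  Each trial consumes its own derived seed, so any single
#' trial is reproducible in isolation.
#'
#' @param config A [synthetic_config()].
#' @return A trial table with `2 * n_subjects * n_tasks * n_conditions`
#'   rows (both devices, paired by metadata).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("config must come from synthetic_config()",
          class = "riemsway_input_error")
  }
  pop <- sim_population(config)
  grid <- expand.grid(condition = seq_len(config$n_conditions),
                      task = seq_len(config$n_tasks),
                      subject = pop$subjects, stringsAsFactors = FALSE)
  spine_rows <- c("SpineMid_x", "SpineMid_z")
  rows <- purrr::pmap(grid, function(condition, task, subject) {
    counter <- which(pop$subjects == subject[[1]])
    i <- (counter - 1) * config$n_tasks * config$n_conditions +
      (task - 1) * config$n_conditions + condition
    set.seed(trial_seed(config, i))
    xm <- sim_mk2_samples(config, pop$mix[[task]][[condition]],
                          pop$transforms[[subject]], pop$offset,
                          config$frames)
    # COP: linear read-out of the mid-spine horizontal-plane trajectory,
    # upsampled by linear interpolation, plus sensor noise.
    t30 <- (seq_len(config$frames) - 1) / config$mk2_rate_hz
    nk <- config$frames * (config$kfp_rate_hz / config$mk2_rate_hz)
    t600 <- (seq_len(nk) - 1) / config$kfp_rate_hz
    xk <- rbind(
      approx(t30, xm[spine_rows[1], ], xout = t600, rule = 2)$y,
      approx(t30, xm[spine_rows[2], ], xout = t600, rule = 2)$y)
    xk <- xk + rnorm(length(xk), 0, config$cop_noise_sd)
    rownames(xk) <- .KFP_CHANNELS
    dplyr::bind_rows(
      sway_trials(subject, task, condition, "MK2", list(xm),
                  rate = config$mk2_rate_hz),
      sway_trials(subject, task, condition, "KFP", list(xk),
                  rate = config$kfp_rate_hz))
  })
  out <- dplyr::bind_rows(rows)
  validate_trials(out)
  out
}

#' Generator self-test: covariance convergence
#'
#' Generates one long MK2 trial and compares its empirical covariance to
#' the analytic population covariance `V_s L L' V_s'`.  The deviation is
#' the largest absolute elementwise error relative to the largest absolute
#' entry of the analytic matrix.
#'
#' @param config A [synthetic_config()].
#' @param long_frames Trial length (default 50000).
#' @return Maximum relative elementwise deviation (scalar).
#' @export
empirical_convergence_check <- function(config, long_frames = 50000) {
  pop <- sim_population(config)
  mixing <- pop$mix[[1]][[1]]
  v <- pop$transforms[[1]]
  set.seed(trial_seed(config, 0))
  x <- sim_mk2_samples(config, mixing, v, pop$offset, long_frames)
  emp <- estimate_covariance(x)
  truth <- v %*% tcrossprod(mixing) %*% t(v)
  max(abs(emp - truth)) / max(abs(truth))
}

#' Write a synthetic dataset to disk
#'
#' Emits one CSV per trial in the package dialects, a `manifest.csv`, and
#' the generating configuration as `config.json`.
#'
#' @param trials A trial table (typically from [generate_dataset()]).
#' @param dir Output directory (created if needed).
#' @param config Optional [synthetic_config()] echoed to `config.json`.
#' @return The manifest path, invisibly.
#' @export
write_dataset_csv <- function(trials, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::map_chr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    fn <- sprintf("%s_t%d_c%d_%s.csv", tr$subject, tr$task, tr$condition,
                  tolower(tr$device))
    write_trial_csv(tr, file.path(dir, fn))
    fn
  })
  man <- tibble::tibble(file = files, subject = trials$subject,
                        task = trials$task, condition = trials$condition,
                        device = trials$device)
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(man, mp, progress = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(mp)
}
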