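# Agreement between the depth camera's trunk centroids and the force
# platform's center of pressure.  The 600 Hz COP trace is block-averaged to
# the 30 Hz skeleton rate, both series are standardized, and per-trial
# Pearson r and RMSE are computed per mapped axis pair.

# Default axis correspondence: the camera's lateral (x) axis pairs with the
# platform's X, the camera's depth (z) axis with the platform's Y; the
# vertical (y) axis has no COP counterpart.
.DEFAULT_AXIS_MAP <- c(x = "cop_x", z = "cop_y")

#' Block-average a trial down to a lower sampling rate
#'
#' Non-overlapping block means; the source rate must be an integer multiple
#' of the target and any trailing partial block is dropped.
#'
#' @param trials A trial table.
#' @param target_rate_hz Target sampling rate in Hz.
#' @return The trial table resampled.
#' @export
block_downsample <- function(trials, target_rate_hz) {
  trials$samples <- purrr::map2(trials$samples, trials$rate, function(x, r) {
    fac <- r / target_rate_hz
    if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
      abort(sprintf("rate %g is not an integer multiple of target %g",
                    r, target_rate_hz),
            class = "riemsway_input_error")
    }
    fac <- as.integer(round(fac))
    if (fac == 1L) return(x)
    nblk <- ncol(x) %/% fac
    idx <- rep(seq_len(nblk), each = fac)
    out <- t(apply(x[, seq_len(nblk * fac), drop = FALSE], 1,
                   function(row) tapply(row, idx, mean)))
    out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), NULL))
    out
  })
  trials$rate <- target_rate_hz
  trials
}

#' Correlate one skeletal joint against the center of pressure
#'
#' The COP trial is block-averaged to the skeleton rate and both series are
#' truncated to their common length, mean-centered and divided by their
#' standard deviation; Pearson r and RMSE are then computed for each mapped
#' axis pair.
#'
#' @param mk2 One-row trial table, device MK2.
#' @param kfp One-row trial table, device KFP, same (subject, task,
#'   condition).
#' @param joint Joint name (default `"SpineMid"`).
#' @param axis_map Named character vector mapping skeleton axes to COP
#'   channels; default `c(x = "cop_x", z = "cop_y")`.
#' @return Tibble with one row per axis: `axis`, `cop_channel`, `r`, `rmse`,
#'   `n` (frames compared).
#' @export
correlate_pair <- function(mk2, kfp, joint = "SpineMid",
                           axis_map = .DEFAULT_AXIS_MAP) {
  stopifnot(nrow(mk2) == 1, nrow(kfp) == 1)
  if (mk2$device != "MK2" || kfp$device != "KFP") {
    abort("correlate_pair expects an MK2 trial and a KFP trial",
          class = "riemsway_input_error")
  }
  kfp <- block_downsample(kfp, mk2$rate)
  xm <- mk2$samples[[1]]
  xk <- kfp$samples[[1]]
  nt <- min(ncol(xm), ncol(xk))
  purrr::imap(axis_map, function(cop_ch, ax) {
    ch <- paste0(joint, "_", ax)
    if (!ch %in% rownames(xm)) {
      abort(paste0("Joint channel not present: ", ch),
            class = "riemsway_lookup_error")
    }
    a <- xm[ch, seq_len(nt)]
    b <- xk[cop_ch, seq_len(nt)]
    if (sd(a) == 0 || sd(b) == 0) {
      abort(sprintf("zero-variance channel (%s or %s): correlation undefined",
                    ch, cop_ch),
            class = "riemsway_numeric_error")
    }
    a <- (a - mean(a)) / sd(a)
    b <- (b - mean(b)) / sd(b)
    tibble::tibble(axis = ax, cop_channel = cop_ch, r = cor(a, b),
                   rmse = sqrt(mean((a - b)^2)), n = nt)
  }) |> dplyr::bind_rows()
}

#' Benchmark a paired dataset
#'
#' For every (subject, task, condition) with both an MK2 and a KFP trial,
#' computes per-axis agreement for the requested joints, averages each
#' subject's r over the pooled conditions, and summarises per (task, joint,
#' axis) as mean and SD across subjects.  Unpaired trials are skipped with
#' a warning.
#'
#' @param trials A trial table containing both devices.
#' @param joints Joints to benchmark (default the three trunk centroids
#'   `SpineMid`, `Neck`, `Head`).
#' @param axis_map See [correlate_pair()].
#' @param conditions Optional condition subset to restrict to (default all,
#'   pooled).
#' @return A tibble of class `sway_benchmark`: `task`, `joint`, `axis`,
#'   `mean_r`, `sd_r`, `mean_rmse`, `n` (contributing subjects).  The
#'   per-trial values are attached as attribute `"per_trial"`.
#' @export
benchmark_dataset <- function(trials, joints = c("SpineMid", "Neck", "Head"),
                              axis_map = .DEFAULT_AXIS_MAP,
                              conditions = NULL) {
  if (!is.null(conditions)) trials <- trials[trials$condition %in% conditions, ]
  mk2 <- trials[trials$device == "MK2", ]
  kfp <- trials[trials$device == "KFP", ]
  key <- function(d) paste(d$subject, d$task, d$condition, sep = "|")
  paired <- intersect(key(mk2), key(kfp))
  orphans <- setdiff(union(key(mk2), key(kfp)), paired)
  if (length(orphans) > 0) {
    warn(paste0(length(orphans), " unpaired trial(s) skipped: ",
                paste(head(orphans, 3), collapse = "; "),
                if (length(orphans) > 3) " ..." else ""))
  }
  per_trial <- purrr::map(paired, function(k) {
    m <- mk2[key(mk2) == k, ]
    f <- kfp[key(kfp) == k, ]
    purrr::map(joints, function(j) {
      correlate_pair(m, f, joint = j, axis_map = axis_map) |>
        dplyr::mutate(subject = m$subject, task = m$task,
                      condition = m$condition, joint = j, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- per_trial |>
    dplyr::group_by(.data$task, .data$joint, .data$axis, .data$subject) |>
    dplyr::summarise(r = mean(.data$r), rmse = mean(.data$rmse),
                     .groups = "drop") |>
    dplyr::group_by(.data$task, .data$joint, .data$axis) |>
    dplyr::summarise(mean_r = mean(.data$r),
                     sd_r = if (dplyr::n() > 1) sd(.data$r) else 0,
                     mean_rmse = mean(.data$rmse), n = dplyr::n(),
                     .groups = "drop")
  attr(out, "per_trial") <- per_trial
  class(out) <- c("sway_benchmark", class(out))
  out
}

#' Wide agreement table
#'
#' Reshapes a benchmark report to one row per task and one
#' `"<Joint> (<AXIS>)"` column per joint-axis pair, each cell formatted
#' `mean ± sd`.
#'
#' @param report A `sway_benchmark` report.
#' @return A tibble in the wide layout.
#' @export
benchmark_table <- function(report) {
  report |>
    dplyr::mutate(
      col = paste0(.data$joint, " (", toupper(.data$axis), ")"),
      cell = sprintf("%.2f ± %.2f", .data$mean_r, .data$sd_r)) |>
    dplyr::select("task", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell") |>
    dplyr::arrange(.data$task)
}

#' Tidy per-trial benchmark values
#' @param x A `sway_benchmark` report.
#' @param ... Unused.
#' @return The long per-trial tibble behind the summary.
#' @export
tidy.sway_benchmark <- function(x, ...) attr(x, "per_trial")
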