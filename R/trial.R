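# Trial container: a tibble with one row per recording and the numeric
# signal held in a list-column of channels-by-frames matrices.  Keeping the
# container a plain tibble means the whole dplyr/tidyr vocabulary applies.

#' Build a trial table
#'
#' A trial table holds one multivariate recording per row: metadata columns
#' (`subject`, `task`, `condition`, `device`, `rate`) plus a `samples`
#' list-column of numeric matrices, channels x frames, with channel labels
#' as rownames.  All user-facing functions in the package take and return
#' this shape so pipelines compose with the pipe.
#'
#' @param subject Character vector of subject identifiers.
#' @param task Integer task labels (1-6 in the seated balance protocol).
#' @param condition Integer postural-condition labels (1 = both feet down,
#'   2 = one foot up, 3 = both feet up).
#' @param device `"MK2"` (skeletal tracking, 30 Hz) or `"KFP"`
#'   (force-platform center of pressure, 600 Hz).
#' @param samples List of channels x frames numeric matrices with rownames
#'   giving channel labels (`"<Joint>_<axis>"` for MK2, `"cop_x"`/`"cop_y"`
#'   for KFP).
#' @param rate Sampling rate in Hz; defaults to 30 for MK2 and 600 for KFP.
#' @return A tibble with one row per trial.
#' @examples
#' x <- matrix(rnorm(2 * 50), 2, dimnames = list(c("cop_x", "cop_y"), NULL))
#' sway_trials("S01", 1L, 1L, "KFP", list(x))
#' @export
sway_trials <- function(subject, task, condition, device, samples,
                        rate = NULL) {
  device <- toupper(device)
  if (is.null(rate)) rate <- ifelse(device == "KFP", 600, 30)
  out <- tibble::tibble(
    subject = as.character(subject),
    task = as.integer(task),
    condition = as.integer(condition),
    device = device,
    rate = as.numeric(rate),
    samples = samples
  )
  validate_trials(out)
  out
}

# Internal: checks the trial-table contract and errors with a clear message.
validate_trials <- function(trials, require_clean = FALSE) {
  needed <- c("subject", "task", "condition", "device", "rate", "samples")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("Not a trial table; missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "riemsway_input_error")
  }
  bad_dev <- setdiff(unique(trials$device), c("MK2", "KFP"))
  if (length(bad_dev) > 0) {
    abort(paste0("Unknown device token(s): ", paste(bad_dev, collapse = ", ")),
          class = "riemsway_format_error")
  }
  for (i in seq_len(nrow(trials))) {
    x <- trials$samples[[i]]
    if (!is.matrix(x) || !is.numeric(x)) {
      abort(sprintf("samples[[%d]] is not a numeric matrix", i),
            class = "riemsway_input_error")
    }
    if (ncol(x) < 2) {
      abort(sprintf("trial %d has fewer than 2 frames", i),
            class = "riemsway_input_error")
    }
    if (is.null(rownames(x))) {
      abort(sprintf("samples[[%d]] lacks channel labels (rownames)", i),
            class = "riemsway_input_error")
    }
    if (trials$device[i] == "KFP" && !identical(rownames(x), .KFP_CHANNELS)) {
      abort(sprintf("KFP trial %d must have channels cop_x, cop_y", i),
            class = "riemsway_format_error")
    }
    if (require_clean && anyNA(x)) {
      abort(sprintf("trial %d contains missing values after cleaning", i),
            class = "riemsway_quality_error")
    }
  }
  key <- paste(trials$subject, trials$task, trials$condition, trials$device)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (subject, task, condition, device) key: ",
                 key[duplicated(key)][1]),
          class = "riemsway_validation_error")
  }
  invisible(trials)
}

# Internal: joints present in an MK2 trial, in channel order.
trial_joints <- function(x) {
  labs <- rownames(x)
  unique(sub("_[xyz]$", "", labs))
}
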