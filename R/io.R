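# CSV dialects and frame cleaning.
#
# MK2 trial file: header `frame,time_s,<Joint>_x,<Joint>_y,<Joint>_z,...`
# KFP trial file: header `sample,time_s,cop_x,cop_y`
# Manifest:       header `file,subject,task,condition,device`

#' Read a single trial from CSV
#'
#' Parses one recording in the package's device dialect and attaches the
#' metadata that the file itself does not carry.  The time column is used
#' only to validate monotonicity and is then discarded; channel order
#' follows the header.
#'
#' @param path Path to a trial CSV.
#' @param subject,task,condition Metadata for the recording.
#' @param device `"MK2"` or `"KFP"`.
#' @param joints For MK2 files, the joint set the file is expected to carry
#'   (a subset name or character vector, see [joint_subset()]); `NULL`
#'   infers the joints from the header and only checks x/y/z completeness.
#' @param units `"m"` (default) or `"mm"`; millimeter input is converted to
#'   meters at ingest.
#' @return A one-row trial table (see [sway_trials()]).
#' @export
read_trial_csv <- function(path, subject, task, condition,
                           device = c("MK2", "KFP"), joints = NULL,
                           units = c("m", "mm")) {
  device <- match.arg(device)
  units <- match.arg(units)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "riemsway_input_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA", "NaN"))
  index_col <- if (device == "MK2") "frame" else "sample"
  if (!identical(names(df)[1:2], c(index_col, "time_s"))) {
    abort(sprintf("Malformed %s header: expected leading columns %s,time_s, found %s",
                  device, index_col, paste(names(df)[1:2], collapse = ",")),
          class = "riemsway_format_error")
  }
  tvec <- df$time_s
  if (any(diff(tvec[!is.na(tvec)]) <= 0)) {
    abort("time_s is not strictly increasing",
          class = "riemsway_validation_error")
  }
  chan_names <- setdiff(names(df), c(index_col, "time_s"))
  if (device == "KFP") {
    if (!identical(chan_names, .KFP_CHANNELS)) {
      abort(paste0("Malformed KFP header: expected cop_x,cop_y, found ",
                   paste(chan_names, collapse = ",")),
            class = "riemsway_format_error")
    }
  } else {
    expected <- if (is.null(joints)) {
      mk2_channel_labels(unique(sub("_[xyz]$", "", chan_names)))
    } else {
      mk2_channel_labels(joints)
    }
    missing_ch <- setdiff(expected, chan_names)
    if (length(missing_ch) > 0) {
      abort(paste0("Malformed MK2 header: missing channel ", missing_ch[1]),
            class = "riemsway_format_error")
    }
    chan_names <- expected
  }
  x <- t(as.matrix(df[, chan_names, drop = FALSE]))
  if (units == "mm") x <- x / 1000
  storage.mode(x) <- "double"
  sway_trials(subject, task, condition, device, list(x))
}

#' Write a trial back to CSV
#'
#' Inverse of [read_trial_csv()]; emits the same dialect, with frame/sample
#' indices 0-based and time in seconds reconstructed from the sampling rate.
#'
#' @param trial A one-row trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(nrow(trial) == 1)
  x <- trial$samples[[1]]
  nt <- ncol(x)
  idx <- seq_len(nt) - 1L
  lead <- tibble::tibble(idx = idx, time_s = idx / trial$rate)
  names(lead)[1] <- if (trial$device == "MK2") "frame" else "sample"
  df <- dplyr::bind_cols(lead, tibble::as_tibble(t(x)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Clean missing frames
#'
#' Markerless tracking drops joints intermittently.  Interior gaps are
#' filled per channel by linear interpolation; frames at the start or end
#' that cannot be interpolated are dropped.  A channel missing more than
#' `max_missing_fraction` of its frames is a data-quality error.
#'
#' @param trials A trial table.
#' @param max_missing_fraction Maximum tolerated per-channel missing
#'   fraction before interpolation (default 0.5).
#' @return The trial table with gap-free samples.
#' @export
clean_frames <- function(trials, max_missing_fraction = 0.5) {
  trials$samples <- purrr::imap(trials$samples, function(x, i) {
    if (!anyNA(x)) return(x)
    frac <- rowMeans(is.na(x))
    if (any(frac > max_missing_fraction)) {
      ch <- rownames(x)[which.max(frac)]
      abort(sprintf(
        "trial %s: channel %s is %.0f%% missing (threshold %.0f%%)",
        i, ch, 100 * max(frac), 100 * max_missing_fraction),
        class = "riemsway_quality_error")
    }
    nt <- ncol(x)
    filled <- t(apply(x, 1, function(row) {
      ok <- !is.na(row)
      if (all(ok)) return(row)
      approx(which(ok), row[ok], xout = seq_len(nt), rule = 1)$y
    }))
    keep <- colSums(is.na(filled)) == 0
    # leading/trailing frames only: interior frames are always filled
    filled <- filled[, keep, drop = FALSE]
    rownames(filled) <- rownames(x)
    filled
  })
  validate_trials(trials, require_clean = TRUE)
  trials
}

#' Select a joint subset from MK2 trials
#'
#' Restricts every MK2 trial to the channels of the requested joints,
#' ordered joint-major (x, y, z per joint).  KFP trials are rejected.
#'
#' @param trials A trial table (all rows MK2).
#' @param subset A subset name (`"full25"`, `"upper16"`, `"spine4"`) or a
#'   character vector of joint names.
#' @return The trial table with reduced channel sets.
#' @export
select_channels <- function(trials, subset) {
  if (any(trials$device != "MK2")) {
    abort("select_channels applies to MK2 trials only",
          class = "riemsway_input_error")
  }
  labels <- mk2_channel_labels(subset)
  trials$samples <- purrr::map(trials$samples, function(x) {
    missing_ch <- setdiff(labels, rownames(x))
    if (length(missing_ch) > 0) {
      abort(paste0("Joint not present in trial: ",
                   sub("_[xyz]$", "", missing_ch[1])),
            class = "riemsway_lookup_error")
    }
    x[labels, , drop = FALSE]
  })
  trials
}

#' Load a dataset from a manifest
#'
#' The manifest CSV has columns `file,subject,task,condition,device`; paths
#' are resolved relative to the manifest's directory.  Every trial is read,
#' cleaned with [clean_frames()], and indexed; a duplicate
#' (subject, task, condition, device) key is an error.
#'
#' @param path Manifest CSV path.
#' @param max_missing_fraction Passed to [clean_frames()].
#' @param units Passed to [read_trial_csv()].
#' @return A trial table with one row per manifest entry.
#' @export
read_manifest <- function(path, max_missing_fraction = 0.5,
                          units = c("m", "mm")) {
  units <- match.arg(units)
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("file", "subject", "task", "condition", "device")
  if (!all(needed %in% names(man))) {
    abort(paste0("Manifest must have columns ", paste(needed, collapse = ",")),
          class = "riemsway_format_error")
  }
  if (nrow(man) == 0) {
    warn("Empty manifest: returning an empty trial table")
    return(sway_trials(character(), integer(), integer(), character(),
                       list()))
  }
  bad_dev <- setdiff(unique(toupper(man$device)), c("MK2", "KFP"))
  if (length(bad_dev) > 0) {
    abort(paste0("Unknown device token(s): ", paste(bad_dev, collapse = ", ")),
          class = "riemsway_format_error")
  }
  base <- dirname(path)
  rows <- purrr::pmap(man, function(file, subject, task, condition, device) {
    fp <- if (file.exists(file)) file else file.path(base, file)
    read_trial_csv(fp, subject, task, condition, toupper(device),
                   units = units)
  })
  trials <- dplyr::bind_rows(rows)
  trials <- clean_frames(trials, max_missing_fraction)
  validate_trials(trials, require_clean = TRUE)
  trials
}
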