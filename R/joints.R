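# Kinect-2 joint vocabulary and the named channel subsets.

.KINECT25 <- c(
  "SpineBase", "SpineMid", "Neck", "Head",
  "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
  "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
  "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
  "HipRight", "KneeRight", "AnkleRight", "FootRight",
  "SpineShoulder", "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight"
)

# Every joint at or above SpineMid: trunk, head and both arms (16 joints).
.UPPER16 <- c(
  "SpineMid", "SpineShoulder", "Neck", "Head",
  "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
  "HandTipLeft", "ThumbLeft",
  "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
  "HandTipRight", "ThumbRight"
)

# Spinal column, caudal to cranial; order is part of the contract.
.SPINE4 <- c("SpineMid", "SpineShoulder", "Neck", "Head")

#' Named joint subsets of the Kinect-2 skeleton
#'
#' The depth camera tracks 25 inferred joint centroids.  Balance analysis
#' from a seated position uses the upper body only (everything at or above
#' the mid-spine, 16 joints) or just the 4 spinal-column centroids, so that
#' classification reflects postural sway rather than leg placement.
#'
#' @param subset One of `"full25"`, `"upper16"`, `"spine4"`, or a character
#'   vector of joint names (returned as-is after validation).
#' @return Character vector of joint names, in canonical order.
#' @examples
#' joint_subset("spine4")
#' length(joint_subset("upper16"))
#' @export
joint_subset <- function(subset) {
  if (length(subset) == 1 && subset %in% c("full25", "upper16", "spine4")) {
    return(switch(subset, full25 = .KINECT25, upper16 = .UPPER16,
                  spine4 = .SPINE4))
  }
  bad <- setdiff(subset, .KINECT25)
  if (length(bad) > 0) {
    abort(paste0("Unknown joint name(s): ", paste(bad, collapse = ", ")),
          class = "riemsway_lookup_error")
  }
  subset
}

#' Channel labels for a set of joints
#'
#' Channels are laid out joint-major: the x, y, z coordinate of each joint
#' in turn, labelled `"<Joint>_<axis>"`.
#'
#' @inheritParams joint_subset
#' @return Character vector of length `3 * length(joints)`.
#' @examples
#' head(mk2_channel_labels("spine4"), 6)
#' @export
mk2_channel_labels <- function(subset) {
  joints <- joint_subset(subset)
  as.vector(t(outer(joints, c("x", "y", "z"), paste, sep = "_")))
}

.KFP_CHANNELS <- c("cop_x", "cop_y")
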