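#' Activity vocabulary
#'
#' The protocol records six fall types and five activities of daily living
#' (ADLs) per subject. Fall activities begin with `FALL_`, ADLs with `ADL_`;
#' the binary class used throughout classification is derived from that
#' prefix.
#'
#' @return character vector of the eleven activity codes.
#' @export
#' @examples
#' activity_levels()
activity_levels <- function() {
  c("FALL_FORWARD", "FALL_BACKWARD", "FALL_RIGHT", "FALL_LEFT",
    "FALL_ROT_CW", "FALL_ROT_CCW",
    "ADL_WALK", "ADL_CLAP", "ADL_MOVE_OBJECT", "ADL_TIE_SHOES", "ADL_SIT")
}

#' Binary class of an activity
#'
#' @param activity character vector of activity codes (see [activity_levels()]).
#' @return character vector of `"FALL"` or `"ADL"`.
#' @export
#' @examples
#' binary_label(c("FALL_LEFT", "ADL_WALK"))
binary_label <- function(activity) {
  bad <- !activity %in% activity_levels()
  if (any(bad))
    stop_wf("argument", "unknown activity: %s",
            paste(unique(activity[bad]), collapse = ", "))
  ifelse(startsWith(activity, "FALL_"), "FALL", "ADL")
}

is_fall_activity <- function(activity) startsWith(activity, "FALL_")
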