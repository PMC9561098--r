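#' Sensor layout of the instrumented buttock models
#'
#' Both buttock models carry 12 surface force sensors placed at 6 axisymmetric
#' locations on the elastomer shell and 3 internal pressure sensors mounted on
#' the rigid substructure. Surface sensors 1 and 2 sit below the medial
#' protuberances (ischial-tuberosity analogs), 7 and 8 below the lateral
#' protuberances (trochanter analogs), and 9 and 10 below the medio-posterior
#' protuberance; these six are the "bony" set used by the redistribution
#' parameter. Sensors 3/4 (rearward), 5/6 (lateral, off-substructure) and
#' 11/12 (forward) are the non-bony complement. The three internal channels
#' are labelled by role only: `I1` (medial element), `I2` (second instrumented
#' substructure element), `I3` (coccyx analog); the internal-pressure
#' parameter uses their sum, never their individual roles.
#'
#' @return An object of class `sensor_layout`: a list with components
#'   `surface_ids` (integer 1..12), `bony_ids`, `nonbony_ids`,
#'   `axisymmetric_pairs` (list of 6 integer pairs) and `internal_ids`
#'   (character, `I1`..`I3`).
#' @examples
#' layout <- default_layout()
#' layout$bony_ids
#' @export
default_layout <- function() {
  layout <- structure(
    list(
      surface_ids = 1:12,
      bony_ids = c(1L, 2L, 7L, 8L, 9L, 10L),
      nonbony_ids = c(3L, 4L, 5L, 6L, 11L, 12L),
      axisymmetric_pairs = list(
        c(1L, 2L), c(3L, 4L), c(5L, 6L),
        c(7L, 8L), c(9L, 10L), c(11L, 12L)
      ),
      internal_ids = c("I1", "I2", "I3")
    ),
    class = "sensor_layout"
  )
  validate_layout(layout)
  layout
}

#' The two buttock models
#'
#' Cushions are evaluated with two compliant buttock models: an elliptical
#' profile representing typical buttock tissue bulk, and a trigonometric
#' (more peaked) profile representing reduced tissue bulk with more prominent
#' bony loading.
#'
#' @return Character vector `c("elliptical", "trigonometric")`.
#' @export
buttock_models <- function() c("elliptical", "trigonometric")

validate_layout <- function(layout) {
  s <- layout$surface_ids
  b <- layout$bony_ids
  nb <- layout$nonbony_ids
  if (length(s) != 12L) cb_stop("surface_ids must contain 12 channels")
  if (length(b) != 6L || anyDuplicated(c(b, nb)) ||
      !setequal(c(b, nb), s)) {
    cb_stop("bony_ids and nonbony_ids must partition surface_ids with |bony| = 6")
  }
  pairs <- layout$axisymmetric_pairs
  flat <- unlist(pairs)
  if (length(pairs) != 6L || !setequal(flat, s) || anyDuplicated(flat)) {
    cb_stop("axisymmetric_pairs must cover each surface channel exactly once")
  }
  for (p in pairs) {
    roles <- p %in% b
    if (roles[1] != roles[2]) {
      cb_stop("an axisymmetric pair may not mix bony and non-bony channels")
    }
  }
  if (length(layout$internal_ids) != 3L) cb_stop("internal_ids must contain 3 channels")
  invisible(layout)
}

#' Axisymmetric partner of a surface channel
#'
#' Each buttock location is instrumented with a left/right pair of sensors;
#' the partner's reading stands in for a channel flagged as an outlier.
#'
#' @param channel Integer surface channel id.
#' @param layout A `sensor_layout`.
#' @return The integer id of the paired channel.
#' @export
axisymmetric_partner <- function(channel, layout = default_layout()) {
  channel <- as.integer(channel)
  for (p in layout$axisymmetric_pairs) {
    if (channel %in% p) return(p[p != channel])
  }
  cb_stop(sprintf("channel %s is not a surface channel", channel))
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("Buttock-model sensor layout\n")
  cat("  surface channels: ", paste(x$surface_ids, collapse = " "), "\n", sep = "")
  cat("  bony set (redistribution numerator): ",
      paste(x$bony_ids, collapse = " "), "\n", sep = "")
  cat("  axisymmetric pairs: ",
      paste(vapply(x$axisymmetric_pairs, paste, "", collapse = "-"),
            collapse = ", "), "\n", sep = "")
  cat("  internal channels: ", paste(x$internal_ids, collapse = " "), "\n", sep = "")
  invisible(x)
}

# internal: errors carry a class so the CLI can map validation failures to exit 2
cb_stop <- function(msg, class = "cushionbench_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}
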