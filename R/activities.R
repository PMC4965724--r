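#' Activity catalogue: 24 grips/movements plus neutral/rest
#'
#' The 25-class label set used throughout the package. Eight action groups are
#' each anchored by a base grip (hammer, tip pinch, 3-jaw chuck, key, scissors,
#' door knob, jar lid, ball) with one to three follow-on movements; the 25th
#' class is the neutral/rest posture `NR`, shared by all groups.
#'
#' @return A data frame with columns `group_no`, `group`, `code`, `description`
#'   and logical `is_grip` (base grip engaged at the start of a repetition).
#'   Row order defines the canonical class order used for confusion matrices
#'   and deterministic argmax tie-breaking.
#' @export
#' @examples
#' activity_table()
activity_table <- function() {
  tab <- data.frame(
    group_no = c(rep(1L, 4), rep(2L, 3), rep(3L, 3), rep(4L, 3), rep(5L, 3),
                 rep(6L, 3), rep(7L, 3), rep(8L, 2), NA_integer_),
    group = c(rep("hammer", 4), rep("tip pinch", 3), rep("3-jaw chuck", 3),
              rep("key", 3), rep("scissors", 3), rep("door knob", 3),
              rep("jar lid", 3), rep("ball", 2), "all"),
    code = c("HG", "HR", "HGR", "HL",
             "TPG", "TPR", "TPL",
             "3JCG", "3JCR", "3JCL",
             "KG", "KTS", "KTP",
             "SCG", "SCO", "SCC",
             "DKG", "DKS", "DKP",
             "JLG", "JLS", "JLP",
             "BG", "BSQ",
             "NR"),
    description = c(
      "hammer grip", "hammer raise", "hammer grip - raised pos.",
      "hammer lower",
      "tip pinch grip", "tip pinch raise", "tip pinch lower",
      "3-jaw chuck grip", "3-jaw chuck raise", "3-jaw chuck lower",
      "key grip", "key turn - supination", "key turn - pronation",
      "scissors grip", "scissors open", "scissors close",
      "door knob grip", "door knob turn - supination",
      "door knob turn - pronation",
      "jar lid grip", "jar lid turn - supination", "jar lid turn - pronation",
      "ball grip", "ball squeeze",
      "neutral/rest"),
    stringsAsFactors = FALSE
  )
  tab$is_grip <- tab$code %in% c("HG", "TPG", "3JCG", "KG", "SCG", "DKG",
                                 "JLG", "BG")
  tab
}

#' Canonical 25 class codes
#'
#' @return Character vector of the 25 activity codes in canonical order
#'   (`NR` last).
#' @export
activity_codes <- function() activity_table()$code

#' Names of the eight action groups
#'
#' @return Character vector of the eight group names, in protocol order.
#' @export
action_groups <- function() {
  unique(activity_table()$group[!is.na(activity_table()$group_no)])
}

# Internal: validate a vector of label codes, error on anything outside the 25.
check_codes <- function(codes) {
  bad <- setdiff(unique(as.character(codes)), activity_codes())
  if (length(bad) > 0L) {
    stop("unknown activity code(s): ", paste(bad, collapse = ", "),
         "; valid codes are: ", paste(activity_codes(), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Sensor montage: ten wireless sensors on the acting arm and hand
#'
#' Eight sEMG sensors sit over forearm/upper-arm muscles and provide the
#' classification features; two accelerometer-only sensors sit on the hand's
#' posterior (base of thumb, base of little finger) and are used solely for
#' labeling movement onsets.
#'
#' @return Data frame with columns `sensor`, `location`, `abbrev`, `kind`.
#' @export
sensor_table <- function() {
  data.frame(
    sensor = 1:10,
    location = c("extensor digitorum", "extensor indicis",
                 "flexor carpi radialis", "flexor digitorum superficialis",
                 "flexor carpi ulnaris", "pronator quadratus",
                 "brachioradialis", "biceps brachii",
                 "base of the thumb (posterior)",
                 "base of little finger (posterior)"),
    abbrev = c("ED", "EI", "FCR", "FDS", "FCU", "PQ", "Bra", "Bic",
               "thumb", "little"),
    kind = c(rep("EMG", 8), "ACC", "ACC"),
    stringsAsFactors = FALSE
  )
}
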