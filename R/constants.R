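# Controlled vocabularies shared across modules.

#' Behaviour change technique tags
#'
#' Twelve BCT tags drive message tailoring. Ten of them are
#' preference-tailored: users rate each on a three-point scale at baseline
#' and the resulting 1/5/10 scores weight message selection on the BCT
#' channel. The remaining two are channel-bound: `feedback_on_performance`
#' tags every step-feedback message and `provide_instruction` tags every
#' green-space prompt.
#'
#' @return Character vector of tag names.
#' @export
#' @examples
#' bct_preference_tags()
bct_preference_tags <- function() {
  c(
    "action_planning", "reward", "social_comparison", "consequences",
    "barrier_identification", "social_support", "social_approval",
    "goal_setting", "self_monitoring", "review_goals"
  )
}

#' @rdname bct_preference_tags
#' @export
bct_all_tags <- function() {
  c(bct_preference_tags(), "feedback_on_performance", "provide_instruction")
}

# internal fixed vocabularies
.categories <- c("STEP", "GEO", "BCT")
.green_space_types <- c("park", "forest", "walking_trail")
.strata <- c("LOW", "MID", "HIGH")
.weekdays <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
.slots <- c("morning", "evening")
.placeholders <- c("<name>", "<number>", "<green_space_type>")

# bitmask helpers for fast eligibility filtering
.weekday_bits <- stats::setNames(bitwShiftL(1L, 0:6), .weekdays)
.slot_bits <- stats::setNames(c(1L, 2L), .slots)

.weekday_mask <- function(days) {
  vapply(days, function(d) {
    if (length(d) == 0L) sum(.weekday_bits) else sum(.weekday_bits[d])
  }, integer(1), USE.NAMES = FALSE)
}

#' Green-space types
#'
#' The three green-space categories the geofence distinguishes; the matched
#' type is substituted into contextual prompt text.
#'
#' @return Character vector `c("park", "forest", "walking_trail")`.
#' @export
green_space_types <- function() .green_space_types

# display strings used when rendering <green_space_type>
.type_display <- c(
  park = "park", forest = "forest", walking_trail = "walking trail"
)

# weekday abbreviation of a Date on the fixed Mon..Sun cycle, independent of
# locale (simulation uses abstract local time)
.weekday_of <- function(date) {
  .weekdays[(as.integer(as.Date(date)) + 3L) %% 7L + 1L]
}
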