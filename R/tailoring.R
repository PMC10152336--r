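# The three elimination-based selection algorithms. Each successively
# filters the message library down to an eligible pool, draws, renders the
# placeholders, and returns a selection outcome carrying its trace. Empty
# pools are a logged non-event (reason NO_ELIGIBLE_MESSAGE), never an error:
# a coaching engine must not crash on a sparse library.

#' Weighted sampling without replacement
#'
#' Draws `min(k, n)` items by successive weighted draws: each draw picks an
#' item with probability proportional to the weights of the items still
#' remaining. This makes selection probability exactly proportional to
#' weight for the first draw and approximately so for subset inclusion when
#' the sampling fraction is small — which is how a preference score of 10
#' makes a message about ten times more likely to be chosen than a score
#' of 1. The order of selection is preserved in the result.
#'
#' @param ids Vector of item identifiers.
#' @param weights Positive numeric weights, same length as `ids`.
#' @param k Number of items to draw (at least 1).
#' @return A vector of `min(k, length(ids))` ids in selection order.
#' @export
#' @examples
#' set.seed(1)
#' weighted_subset(c("a", "b", "c"), c(10, 5, 1), k = 2)
weighted_subset <- function(ids, weights, k) {
  n <- length(ids)
  if (length(weights) != n) abort("ids and weights must have equal length")
  if (any(is.na(weights)) || any(weights <= 0)) {
    abort("all weights must be positive")
  }
  if (k < 1) abort("k must be at least 1")
  take <- min(k, n)
  # sample() performs successive draws proportional to remaining weights
  idx <- sample.int(n, size = take, replace = FALSE, prob = weights)
  ids[idx]
}

.outcome <- function(message_id = NULL, text = NULL, reason, trace) {
  structure(
    list(
      message_id = message_id, rendered_text = text,
      reason = reason, trace = trace
    ),
    class = "selection_outcome"
  )
}

#' @export
print.selection_outcome <- function(x, ...) {
  if (x$reason == "SELECTED") {
    cat("<selection_outcome> SELECTED", x$message_id, "\n ", x$rendered_text, "\n")
  } else {
    cat("<selection_outcome>", x$reason, "\n")
  }
  invisible(x)
}

#' @method as_tibble selection_outcome
#' @export
as_tibble.selection_outcome <- function(x, ...) {
  tibble(
    message_id = x$message_id %||% NA_character_,
    rendered_text = x$rendered_text %||% NA_character_,
    reason = x$reason,
    pool_size = x$trace$pool_size %||% NA_integer_
  )
}

# profile may be a one-row tibble or a named list; both index by [[ ]]
.profile_name <- function(profile) {
  nm <- profile[["first_name"]]
  if (is.null(nm) || is.na(nm) || !nzchar(nm)) {
    abort("profile must carry a nonempty first_name")
  }
  nm[[1]]
}

#' Select a step-feedback message
#'
#' Elimination: keep `STEP` templates, keep those whose stratum matches the
#' user's current performance stratum (or `ANY`), choose one uniformly, and
#' render with the user's first name and step count. When the step count is
#' stale (no synchronisation for the day) the engine treats the day as 0
#' steps, selects from the `LOW` pool, and the caller flags the delivery.
#'
#' @param lib A [message_library()].
#' @param profile One-row roster entry (or named list) with `first_name`.
#' @param steps Current cumulative step count for the day.
#' @param stale Logical: is the step count a stale fallback?
#' @param config An [engine_config()] (strata bounds).
#' @return A `selection_outcome`; reason `NO_ELIGIBLE_MESSAGE` on an empty
#'   pool.
#' @export
select_step_message <- function(lib, profile, steps, stale = FALSE,
                                config = engine_config()) {
  if (stale) steps <- 0L
  stratum <- as.character(classify_step_stratum(steps, config$strata_bounds))
  cat_col <- .subset2(lib, "category")
  str_col <- .subset2(lib, "stratum")
  pool <- which(cat_col == "STEP" & (str_col == stratum | str_col == "ANY"))
  trace <- list(channel = "STEP", stratum = stratum, pool_size = length(pool),
                stale_steps = stale)
  if (length(pool) == 0) return(.outcome(reason = "NO_ELIGIBLE_MESSAGE", trace = trace))
  i <- pool[sample.int(length(pool), 1L)]
  text <- render_message(.subset2(lib, "text")[i], .profile_name(profile),
                         number = steps)
  .outcome(.subset2(lib, "message_id")[i], text, "SELECTED", trace)
}

#' Select a green-space prompt
#'
#' Elimination: keep `GEO` templates, keep those matching the encountered
#' green-space type (or `ANY`), choose one uniformly, and render with the
#' user's first name and the type's display string.
#'
#' @inheritParams select_step_message
#' @param green_space_type One of `park`, `forest`, `walking_trail`.
#' @return A `selection_outcome`.
#' @export
select_geo_message <- function(lib, profile, green_space_type) {
  if (!green_space_type %in% .green_space_types) {
    abort(paste0("unknown green_space_type: ", green_space_type))
  }
  cat_col <- .subset2(lib, "category")
  gst_col <- .subset2(lib, "green_space_type")
  pool <- which(cat_col == "GEO" &
                  (gst_col == green_space_type | gst_col == "ANY"))
  trace <- list(channel = "GEO", green_space_type = green_space_type,
                pool_size = length(pool))
  if (length(pool) == 0) return(.outcome(reason = "NO_ELIGIBLE_MESSAGE", trace = trace))
  i <- pool[sample.int(length(pool), 1L)]
  text <- render_message(.subset2(lib, "text")[i], .profile_name(profile),
                         green_space_type = green_space_type)
  .outcome(.subset2(lib, "message_id")[i], text, "SELECTED", trace)
}

#' Select a preference-tailored (BCT) message
#'
#' Elimination then weighted subsetting: keep `BCT` templates relevant for
#' the weekday and slot, draw a subset of `k` (default 4) by successive
#' sampling proportional to the user's preference score for each template's
#' BCT (1, 5 or 10), then choose one of the subset uniformly — the final
#' uniform pick adds diversity to the delivered messages.
#'
#' @inheritParams select_step_message
#' @param slot `"morning"` or `"evening"`.
#' @param weekday Three-letter weekday `Mon`..`Sun`.
#' @return A `selection_outcome` whose trace records the eligible pool size
#'   and the subset ids.
#' @export
select_bct_message <- function(lib, profile, slot, weekday,
                               config = engine_config()) {
  if (!slot %in% .slots) abort(paste0("unknown slot: ", slot))
  if (!weekday %in% .weekdays) abort(paste0("unknown weekday: ", weekday))
  slot_bit <- .slot_bits[[slot]]
  wd_bit <- .weekday_bits[[weekday]]
  cat_col <- .subset2(lib, "category")
  pool <- which(cat_col == "BCT" &
                  bitwAnd(.subset2(lib, "slot_mask"), slot_bit) > 0L &
                  bitwAnd(.subset2(lib, "wd_mask"), wd_bit) > 0L)
  trace <- list(channel = "BCT", slot = slot, weekday = weekday,
                pool_size = length(pool))
  if (length(pool) == 0) return(.outcome(reason = "NO_ELIGIBLE_MESSAGE", trace = trace))
  tags <- .subset2(lib, "bct_tag")[pool]
  pref <- vapply(bct_preference_tags(), function(tg) {
    v <- profile[[paste0("bct_", tg)]]
    if (is.null(v)) abort(paste0("profile has no score for bct_", tg))
    as.numeric(v[[1]])
  }, numeric(1))
  w <- unname(pref[tags])
  ids <- .subset2(lib, "message_id")[pool]
  subset_ids <- weighted_subset(ids, w, k = config$bct_subset_k)
  trace$subset_ids <- subset_ids
  chosen <- subset_ids[sample.int(length(subset_ids), 1L)]
  i <- pool[match(chosen, ids)]
  text <- render_message(.subset2(lib, "text")[i], .profile_name(profile))
  .outcome(chosen, text, "SELECTED", trace)
}
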