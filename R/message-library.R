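#' Message library
#'
#' The unit of tailoring is a message template: a short coaching text
#' (target length roughly 20-30 words) tagged with its channel and the
#' constraints under which it is relevant. Three channels exist:
#'
#' * `STEP` — midday feedback on step count, tagged
#'   `feedback_on_performance`, restricted to a performance `stratum`
#'   (`LOW`/`MID`/`HIGH`) or `ANY`; may use the `<number>` placeholder.
#' * `GEO` — contextual prompts near green spaces, tagged
#'   `provide_instruction`, restricted to a `green_space_type`
#'   (`park`/`forest`/`walking_trail`) or `ANY`; may use
#'   `<green_space_type>`.
#' * `BCT` — morning/evening coaching tagged with one of the ten
#'   preference-tailored BCTs; may be restricted to weekdays and to the
#'   `morning`/`evening` slot.
#'
#' All templates may use `<name>`. `message_library()` validates a raw
#' template data frame and precomputes the bitmasks used by the selection
#' filters; `read_message_library()`/`write_message_library()` round-trip
#' the CSV interchange format (`message_id, category, bct_tag, stratum,
#' green_space_type, allowed_weekdays, allowed_slots, text`; empty cell =
#' ANY/default; weekdays pipe-joined `Mon|Tue|...`).
#'
#' @param templates Data frame with the columns above.
#' @return A `message_library` tibble (row order preserved).
#' @export
#' @examples
#' lib <- gen_message_library(per_pool = 1)
#' nrow(lib)
message_library <- function(templates) {
  df <- as_tibble(templates)
  need <- c("message_id", "category", "bct_tag", "stratum",
            "green_space_type", "allowed_weekdays", "allowed_slots", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("message library missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  df$stratum[blank(df$stratum)] <- "ANY"
  df$green_space_type[blank(df$green_space_type)] <- "ANY"
  df$allowed_weekdays[blank(df$allowed_weekdays)] <- paste(.weekdays, collapse = "|")
  df$allowed_slots[blank(df$allowed_slots)] <- paste(.slots, collapse = "|")

  if (nrow(df) == 0) abort("message library is empty")
  dup <- df$message_id[duplicated(df$message_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate message_id: ", paste(unique(dup), collapse = ", ")))
  }

  row_err <- function(i, msg) {
    abort(sprintf("message library row %d (%s): %s", i, df$message_id[i], msg))
  }
  wd_list <- strsplit(df$allowed_weekdays, "|", fixed = TRUE)
  slot_list <- strsplit(df$allowed_slots, "|", fixed = TRUE)
  for (i in seq_len(nrow(df))) {
    if (!df$category[i] %in% .categories) {
      row_err(i, paste0("unknown category '", df$category[i], "'"))
    }
    expected_tag <- switch(df$category[i],
      STEP = "feedback_on_performance",
      GEO = "provide_instruction",
      BCT = NULL
    )
    if (is.null(expected_tag)) {
      if (!df$bct_tag[i] %in% bct_preference_tags()) {
        row_err(i, paste0("unknown BCT tag '", df$bct_tag[i], "'"))
      }
    } else if (df$bct_tag[i] != expected_tag) {
      row_err(i, paste0(df$category[i], " templates must be tagged ", expected_tag))
    }
    if (df$category[i] == "STEP") {
      if (!df$stratum[i] %in% c(.strata, "ANY")) {
        row_err(i, paste0("unknown stratum '", df$stratum[i], "'"))
      }
    } else if (df$stratum[i] != "ANY") {
      row_err(i, "stratum applies to STEP templates only")
    }
    if (df$category[i] == "GEO") {
      if (!df$green_space_type[i] %in% c(.green_space_types, "ANY")) {
        row_err(i, paste0("unknown green_space_type '", df$green_space_type[i], "'"))
      }
    } else if (df$green_space_type[i] != "ANY") {
      row_err(i, "green_space_type applies to GEO templates only")
    }
    if (!all(wd_list[[i]] %in% .weekdays)) {
      row_err(i, "allowed_weekdays must be pipe-joined Mon..Sun")
    }
    if (!all(slot_list[[i]] %in% .slots)) {
      row_err(i, "allowed_slots must be pipe-joined morning|evening")
    }
    toks <- regmatches(df$text[i], gregexpr("<[^<>]*>", df$text[i]))[[1]]
    bad <- setdiff(toks, .placeholders)
    if (length(bad) > 0) {
      row_err(i, paste0("unknown placeholder ", paste(bad, collapse = ", ")))
    }
    if (df$category[i] != "GEO" && "<green_space_type>" %in% toks) {
      row_err(i, "<green_space_type> is allowed in GEO templates only")
    }
    if (df$category[i] != "STEP" && "<number>" %in% toks) {
      row_err(i, "<number> is allowed in STEP templates only")
    }
  }
  df$wd_mask <- .weekday_mask(wd_list)
  df$slot_mask <- vapply(slot_list, function(s) sum(.slot_bits[s]),
                         integer(1), USE.NAMES = FALSE)
  class(df) <- c("message_library", class(df))
  df
}

#' @rdname message_library
#' @param path CSV file path (UTF-8, header required).
#' @export
read_message_library <- function(path) {
  if (!file.exists(path)) abort(paste0("message file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  message_library(df)
}

#' @rdname message_library
#' @param lib A `message_library`.
#' @export
write_message_library <- function(lib, path) {
  out <- as_tibble(lib)
  out$wd_mask <- NULL
  out$slot_mask <- NULL
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Validate a message library
#'
#' Lints every template and checks pool coverage. Word counts outside the
#' house style of roughly 20-30 words are warnings, not errors (the bound is
#' approximate by design). Empty candidate pools are errors because they are
#' unselectable: every STEP stratum, every green-space type and every one of
#' the ten preference-tailored BCT tags must have at least one template
#' (`ANY` templates cover all strata/types).
#'
#' @param lib A [message_library()].
#' @param word_range Acceptable word-count range.
#' @return A `library_validation` object; `tidy()` gives the findings
#'   tibble (`level`, `message_id`, `issue`), `glance()` the counts.
#' @export
#' @examples
#' rep <- validate_library(gen_message_library(per_pool = 2))
#' glance(rep)
validate_library <- function(lib, word_range = c(20L, 30L)) {
  stopifnot(inherits(lib, "message_library"))
  wc <- vapply(strsplit(trimws(lib$text), "\\s+"), length, integer(1))
  findings <- tibble(
    level = character(), message_id = character(), issue = character()
  )
  off <- wc < word_range[1] | wc > word_range[2]
  if (any(off)) {
    findings <- bind_rows(findings, tibble(
      level = "WARNING",
      message_id = lib$message_id[off],
      issue = sprintf("word count %d outside [%d, %d]",
                      wc[off], word_range[1], word_range[2])
    ))
  }
  pool_err <- character()
  for (s in .strata) {
    if (!any(lib$category == "STEP" & lib$stratum %in% c(s, "ANY"))) {
      pool_err <- c(pool_err, paste0("no STEP template for stratum ", s))
    }
  }
  for (g in .green_space_types) {
    if (!any(lib$category == "GEO" & lib$green_space_type %in% c(g, "ANY"))) {
      pool_err <- c(pool_err, paste0("no GEO template for type ", g))
    }
  }
  for (b in bct_preference_tags()) {
    if (!any(lib$category == "BCT" & lib$bct_tag == b)) {
      pool_err <- c(pool_err, paste0("no BCT template tagged ", b))
    }
  }
  if (length(pool_err) > 0) {
    findings <- bind_rows(findings, tibble(
      level = "ERROR", message_id = NA_character_, issue = pool_err
    ))
  }
  structure(
    list(findings = findings, n_templates = nrow(lib), word_counts = wc),
    class = "library_validation"
  )
}

#' @export
print.library_validation <- function(x, ...) {
  n_err <- sum(x$findings$level == "ERROR")
  n_warn <- sum(x$findings$level == "WARNING")
  cat(sprintf("<library_validation> %d templates: %d coverage error(s), %d warning(s)\n",
              x$n_templates, n_err, n_warn))
  if (nrow(x$findings) > 0) print(x$findings, ...)
  invisible(x)
}

#' @method tidy library_validation
#' @export
tidy.library_validation <- function(x, ...) x$findings

#' @method glance library_validation
#' @export
glance.library_validation <- function(x, ...) {
  tibble(
    n_templates = x$n_templates,
    n_errors = sum(x$findings$level == "ERROR"),
    n_warnings = sum(x$findings$level == "WARNING"),
    median_words = stats::median(x$word_counts)
  )
}

#' Render a message template
#'
#' Substitutes the personalisation placeholders: `<name>` with the user's
#' first name, `<number>` with the step count (no thousands separators),
#' `<green_space_type>` with the display name of the matched green-space
#' type. Every placeholder present in the template must be supplied;
#' rendering is complete (no known token survives).
#'
#' @param text Template text (a single string).
#' @param first_name User's first name.
#' @param number Nonnegative integer, or `NULL` when the template has no
#'   `<number>`.
#' @param green_space_type Display string (or enum value) for
#'   `<green_space_type>`, or `NULL`.
#' @return The rendered string.
#' @export
#' @examples
#' render_message("So far you have taken <number> steps today, <name>.",
#'                first_name = "Anna", number = 4321)
render_message <- function(text, first_name, number = NULL,
                           green_space_type = NULL) {
  ctx <- list(
    "<name>" = first_name,
    "<number>" = if (!is.null(number)) format(number, scientific = FALSE, trim = TRUE),
    "<green_space_type>" = if (!is.null(green_space_type)) {
      if (green_space_type %in% names(.type_display)) {
        .type_display[[green_space_type]]
      } else {
        green_space_type
      }
    }
  )
  out <- text
  for (tok in .placeholders) {
    if (grepl(tok, out, fixed = TRUE)) {
      if (is.null(ctx[[tok]])) {
        abort(paste0("render_message: no value supplied for placeholder ", tok))
      }
      out <- gsub(tok, ctx[[tok]], out, fixed = TRUE)
    }
  }
  out
}
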