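# Per-subject, per-session dependent variables: %LLL preference, throughput
# (trials/min, pellets/min), timeout poking indices (persistence toward the
# LLL hole, restlessness toward the SS hole), and the experienced delivery
# probability and odds realized by each subject's own LLL choices.

#' Experienced delivery probability
#'
#' The delivery rate a subject actually realized on its LLL choices:
#' `100 * successful_LLL / total_LLL` (a percentage). Undefined (missing) when
#' the subject made no LLL choices.
#'
#' @param successful_LLL Number of LLL choices that were rewarded.
#' @param total_LLL Total LLL choices. Vectorized with `successful_LLL`.
#' @return Percentage in \[0, 100\], or `NA` where `total_LLL` is 0.
#' @export
#' @examples
#' experienced_probability(2, 8)  # 25
experienced_probability <- function(successful_LLL, total_LLL) {
  if (any(successful_LLL < 0) || any(total_LLL < 0) ||
      any(successful_LLL > total_LLL)) {
    stop("need 0 <= successful_LLL <= total_LLL", call. = FALSE)
  }
  ifelse(total_LLL > 0, 100 * successful_LLL / total_LLL, NA_real_)
}

#' Experienced odds
#'
#' Converts an experienced probability (percentage) to odds:
#' `(100 / experienced_p) - 1`. An experienced probability of 0 (LLL chosen
#' but never rewarded) has no finite odds; it yields `NA` with a warning, and
#' such sessions are excluded from the preference-odds fit.
#'
#' @param experienced_p Percentage in \[0, 100\] or `NA`; vectorized.
#' @return Non-negative odds, or `NA` for missing/zero input.
#' @export
#' @examples
#' experienced_odds(c(25, 100))  # 3, 0
experienced_odds <- function(experienced_p) {
  if (any(experienced_p < 0, na.rm = TRUE) ||
      any(experienced_p > 100, na.rm = TRUE)) {
    stop("experienced_p must lie in [0, 100]", call. = FALSE)
  }
  zero <- !is.na(experienced_p) & experienced_p == 0
  if (any(zero)) {
    warning(sum(zero), " session(s) with experienced p = 0: ",
            "odds undefined, set to missing", call. = FALSE)
  }
  ifelse(is.na(experienced_p) | zero, NA_real_, 100 / experienced_p - 1)
}

#' Reduce one subject-session's trials to session metrics
#'
#' @param records Trial records of a single subject-session (all rows must
#'   share `subject_id`, `session_index` and `p_set`). Zero rows are legal
#'   and yield a degenerate row with missing identifiers.
#' @param protocol A [protocol_config()]; the nominal session duration is the
#'   denominator of the per-minute rates.
#' @return One-row tibble: `subject_id`, `species`, `session_index`, `p_set`,
#'   `n_trials`, `pref_LLL` (%), `trials_per_min`, `pellets_per_min`,
#'   `persistence`, `restlessness`, `experienced_p` (%), `experienced_odds`.
#'   Zero-trial sessions have zero rates and missing per-trial fields.
#' @export
session_metrics <- function(records, protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (nrow(records) == 0) {
    id <- tibble::tibble(subject_id = NA_character_, species = NA_character_,
                         session_index = NA_integer_, p_set = NA_real_)
    return(session_metrics_row(id, records, protocol))
  }
  if (dplyr::n_distinct(records$subject_id) > 1 ||
      dplyr::n_distinct(records$session_index) > 1 ||
      dplyr::n_distinct(records$p_set) > 1) {
    stop("records mix subjects, sessions or p levels", call. = FALSE)
  }
  session_metrics_row(records[1, c("subject_id", "species", "session_index", "p_set")],
                      records, protocol)
}

# shared reducer; `id` carries the identifiers so n = 0 is representable
session_metrics_row <- function(id, records, protocol) {
  n <- nrow(records)
  minutes <- protocol$session_minutes
  if (n == 0) {
    return(tibble::tibble(
      subject_id = id$subject_id, species = id$species,
      session_index = id$session_index, p_set = id$p_set,
      n_trials = 0L, pref_LLL = NA_real_,
      trials_per_min = 0, pellets_per_min = 0,
      persistence = NA_real_, restlessness = NA_real_,
      experienced_p = NA_real_, experienced_odds = NA_real_
    ))
  }
  lll <- records$choice == "LLL"
  exp_p <- experienced_probability(sum(lll & records$delivered), sum(lll))
  tibble::tibble(
    subject_id = id$subject_id, species = id$species,
    session_index = id$session_index, p_set = id$p_set,
    n_trials = n,
    pref_LLL = 100 * sum(lll) / n,
    trials_per_min = n / minutes,
    pellets_per_min = sum(records$pellets) / minutes,
    persistence = sum(records$inadequate_LLL) / n,
    restlessness = sum(records$inadequate_SS) / n,
    experienced_p = exp_p,
    experienced_odds = suppressWarnings(experienced_odds(exp_p))
  )
}

#' Session metrics for a whole event log
#'
#' One [session_metrics()] row per (subject, session) present in the log,
#' sorted by subject then session.
#'
#' @param event_log Trial records as produced by [simulate_cohort()] or
#'   [read_event_log()].
#' @param protocol A [protocol_config()].
#' @return Tibble of session metrics.
#' @export
#' @examples
#' log <- simulate_cohort(demo_cohort("rat", 1), default_protocol("rat"), seed = 1)
#' cohort_metrics(log, default_protocol("rat"))
cohort_metrics <- function(event_log, protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (nrow(event_log) == 0) {
    return(session_metrics_row(empty_event_log(), empty_event_log(), protocol)[0, ])
  }
  groups <- dplyr::group_by(event_log, .data$subject_id, .data$session_index)
  out <- dplyr::group_modify(groups, function(df, key) {
    id <- tibble::tibble(subject_id = key$subject_id, species = df$species[1],
                         session_index = key$session_index, p_set = df$p_set[1])
    session_metrics_row(id, df, protocol)[, -c(1, 3)]
  })
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, .data$subject_id, .data$session_index)
  dplyr::relocate(out, "subject_id", "species", "session_index", "p_set")
}

#' Write / read a session-metrics table
#'
#' Delimited text mirroring the [session_metrics()] fields; missing values are
#' serialized as empty cells.
#'
#' @param metrics Session-metrics tibble.
#' @param path File path.
#' @return `read_metrics()` returns the metrics tibble.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::tibble(
    subject_id = as.character(raw$subject_id),
    species = as.character(raw$species),
    session_index = as.integer(raw$session_index),
    p_set = as.numeric(raw$p_set),
    n_trials = as.integer(raw$n_trials),
    pref_LLL = as.numeric(raw$pref_LLL),
    trials_per_min = as.numeric(raw$trials_per_min),
    pellets_per_min = as.numeric(raw$pellets_per_min),
    persistence = as.numeric(raw$persistence),
    restlessness = as.numeric(raw$restlessness),
    experienced_p = as.numeric(raw$experienced_p),
    experienced_odds = as.numeric(raw$experienced_odds)
  )
}
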