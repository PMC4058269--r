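# Task structure: reward specification, probability rarefaction schedule,
# session timing, and their analytic consequences (set odds, indifferent point).

#' Reward specification for the two-choice task
#'
#' Defines the pellet ranges of the small-and-sure (SS) and
#' large-and-luck-linked (LLL) options, together with the *nominal*
#' large/small fold-ratios used for indifference-zone arithmetic. The default
#' (1--2 vs 5--6 pellets) carries nominal ratios 3 and 5; the actual pellet
#' ratios (2.5--6 for the default ranges) are available through
#' [indifference_zone()]'s `nominal = FALSE`.
#'
#' @param small_min,small_max Pellet range of the SS option (positive integers).
#' @param large_min,large_max Pellet range of the LLL option.
#' @param nominal_ratio Length-2 numeric, the declared minimal and maximal
#'   large/small fold-ratios (default `c(3, 5)`).
#' @return An object of class `reward_spec`.
#' @export
#' @examples
#' reward_spec()
reward_spec <- function(small_min = 1L, small_max = 2L,
                        large_min = 5L, large_max = 6L,
                        nominal_ratio = c(3, 5)) {
  counts <- c(small_min, small_max, large_min, large_max)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("pellet counts must be positive integers", call. = FALSE)
  }
  if (!(small_min <= small_max && small_max < large_min && large_min <= large_max)) {
    stop("reward ranges must satisfy small_min <= small_max < large_min <= large_max",
         call. = FALSE)
  }
  if ((large_min + large_max) / (small_min + small_max) <= 1) {
    stop("mean large reward must exceed mean small reward", call. = FALSE)
  }
  if (length(nominal_ratio) != 2 || any(nominal_ratio <= 1) ||
      nominal_ratio[1] > nominal_ratio[2]) {
    stop("nominal_ratio must be two ratios > 1 in non-decreasing order",
         call. = FALSE)
  }
  structure(
    list(small_min = as.integer(small_min), small_max = as.integer(small_max),
         large_min = as.integer(large_min), large_max = as.integer(large_max),
         nominal_ratio = as.numeric(nominal_ratio)),
    class = "reward_spec"
  )
}

#' Probability rarefaction schedule
#'
#' The ordered sequence of set delivery probabilities `p` imposed across the
#' testing phase, with the number of consecutive sessions run at each level.
#'
#' @param p Strictly decreasing probabilities in (0, 1]; the default testing
#'   progression is 100%, 50%, 33%, 25%, 20%, 17%, 14%.
#' @param sessions_per_level Positive integer, recycled across levels.
#' @return A `probability_schedule`: a tibble with columns `p` and
#'   `sessions_per_level`.
#' @export
probability_schedule <- function(p = c(1, 0.50, 0.33, 0.25, 0.20, 0.17, 0.14),
                                 sessions_per_level = 1L) {
  if (any(p <= 0) || any(p > 1)) {
    stop("schedule probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (any(diff(p) >= 0)) {
    stop("schedule probabilities must be strictly decreasing", call. = FALSE)
  }
  spl <- as.integer(rep_len(sessions_per_level, length(p)))
  if (any(spl < 1)) stop("sessions_per_level must be positive", call. = FALSE)
  out <- tibble::tibble(p = as.numeric(p), sessions_per_level = spl)
  class(out) <- c("probability_schedule", class(out))
  out
}

#' Assemble a full task protocol
#'
#' Bundles reward sizes, the probability schedule, session timing and the
#' inclusion rule into one configuration object. Use [default_protocol()] for
#' the rat and marmoset presets.
#'
#' @param species_label Free-text species label.
#' @param session_minutes Session duration in minutes (> 0).
#' @param timeout_seconds Post-choice timeout in seconds (>= 0); pokes during
#'   this window are recorded as "inadequate".
#' @param reward A [reward_spec()].
#' @param schedule A [probability_schedule()].
#' @param inclusion_threshold Percentage; subjects must prefer the large
#'   reward *strictly more* than this over the inclusion sessions (default 60).
#' @param inclusion_levels Set probabilities whose sessions enter the
#'   inclusion filter (default `c(1.0, 0.5)`, the two levels before the
#'   indifference zone); must be a subset of the schedule's levels.
#' @param first_test_session Sessions with index below this are treated as
#'   training and ignored by the preference-odds fit (default 1: all sessions
#'   in a log are testing sessions).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(species_label,
                            session_minutes,
                            timeout_seconds,
                            reward = reward_spec(),
                            schedule = probability_schedule(),
                            inclusion_threshold = 60,
                            inclusion_levels = c(1.0, 0.5),
                            first_test_session = 1L) {
  if (!inherits(reward, "reward_spec")) reward <- do.call(reward_spec, reward)
  if (!inherits(schedule, "probability_schedule")) {
    schedule <- do.call(probability_schedule, as.list(schedule))
  }
  if (session_minutes <= 0) stop("session_minutes must be > 0", call. = FALSE)
  if (timeout_seconds < 0) stop("timeout_seconds must be >= 0", call. = FALSE)
  if (!all(inclusion_levels %in% schedule$p)) {
    stop("inclusion_levels must be a subset of the schedule's p levels",
         call. = FALSE)
  }
  structure(
    list(species_label = as.character(species_label),
         session_minutes = as.numeric(session_minutes),
         timeout_seconds = as.numeric(timeout_seconds),
         reward = reward,
         schedule = schedule,
         inclusion_threshold = as.numeric(inclusion_threshold),
         inclusion_levels = as.numeric(inclusion_levels),
         first_test_session = as.integer(first_test_session)),
    class = "protocol_config"
  )
}

#' Species presets for the probabilistic-delivery task
#'
#' Returns the standard task parameterization for each species. Rats run one
#' 25-minute session per probability level with a 15-second timeout (7 testing
#' sessions); marmosets run three consecutive 5-minute sessions per level with
#' a 6-second timeout (21 testing sessions). Both use 1--2 vs 5--6 pellet
#' rewards and the rarefaction progression 100%, 50%, 33%, 25%, 20%, 17%, 14%,
#' and include subjects whose large-reward preference exceeds 60% over the
#' sessions at p = 100% and 50%.
#'
#' @param species_label `"rat"` or `"marmoset"`.
#' @return A [protocol_config()].
#' @export
#' @examples
#' default_protocol("rat")$schedule
default_protocol <- function(species_label) {
  presets <- c("rat", "marmoset")
  if (!is.character(species_label) || length(species_label) != 1 ||
      !species_label %in% presets) {
    stop("unknown species preset ", deparse(species_label),
         "; valid presets: ", paste(dQuote(presets, FALSE), collapse = ", "),
         call. = FALSE)
  }
  switch(species_label,
    rat = protocol_config("rat", session_minutes = 25, timeout_seconds = 15,
                          schedule = probability_schedule(sessions_per_level = 1L)),
    marmoset = protocol_config("marmoset", session_minutes = 5, timeout_seconds = 6,
                               schedule = probability_schedule(sessions_per_level = 3L))
  )
}

#' Odds implied by a set delivery probability
#'
#' Odds are the mean number of omitted large-reward deliveries before a
#' successful one: `odds = 1/p - 1`, with inverse `p = 1/(odds + 1)`.
#'
#' @param p Delivery probability (fraction in (0, 1]); vectorized.
#' @return Non-negative odds.
#' @export
#' @examples
#' set_odds(c(1, 0.5, 0.2))  # 0, 1, 4
set_odds <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  1 / p - 1
}

#' Indifferent point of a reward ratio
#'
#' The delivery probability at which the expected payoff of the large
#' probabilistic reward equals the small certain one: the reciprocal of the
#' large/small reward ratio. A 5-fold ratio gives p = 20%, a 3-fold ratio
#' p = 33%.
#'
#' @param reward_ratio Large/small reward ratio (> 1); vectorized.
#' @return Probability fraction in (0, 1).
#' @export
#' @examples
#' indifferent_point(c(5, 3, 2))
indifferent_point <- function(reward_ratio) {
  if (!is.numeric(reward_ratio) || any(is.na(reward_ratio)) ||
      any(reward_ratio <= 1)) {
    stop("reward_ratio must be > 1 (the large reward must dominate)",
         call. = FALSE)
  }
  1 / reward_ratio
}

#' Indifference zone of a reward specification
#'
#' The interval of delivery probabilities spanned by the indifferent points of
#' the minimal and maximal reward fold-ratios. With the default nominal ratios
#' (3, 5) the zone is (0.20, 0.333...).
#'
#' @param reward A [reward_spec()].
#' @param nominal Use the declared nominal ratios (default) rather than the
#'   ratios of the actual pellet ranges (`large_min/small_max` to
#'   `large_max/small_min`).
#' @return Named numeric `c(p_low, p_high)`.
#' @export
indifference_zone <- function(reward = reward_spec(), nominal = TRUE) {
  if (!inherits(reward, "reward_spec")) stop("need a reward_spec", call. = FALSE)
  ratios <- if (nominal) {
    reward$nominal_ratio
  } else {
    c(reward$large_min / reward$small_max, reward$large_max / reward$small_min)
  }
  c(p_low = indifferent_point(ratios[2]), p_high = indifferent_point(ratios[1]))
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config> species:", x$species_label, "\n")
  cat("  session:", x$session_minutes, "min; timeout:", x$timeout_seconds, "s\n")
  cat("  rewards:", x$reward$small_min, "-", x$reward$small_max, "(SS) vs",
      x$reward$large_min, "-", x$reward$large_max, "(LLL)\n")
  cat("  schedule p:", paste(format(x$schedule$p), collapse = " "), "\n")
  cat("  sessions/level:", paste(x$schedule$sessions_per_level, collapse = " "),
      " (", sum(x$schedule$sessions_per_level), "testing sessions )\n")
  cat("  inclusion: mean %LLL >", x$inclusion_threshold, "at p =",
      paste(x$inclusion_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a protocol configuration file
#'
#' Serializes a [protocol_config()] to a human-editable YAML file and reads it
#' back losslessly.
#'
#' @param protocol A `protocol_config`.
#' @param path File path.
#' @return `read_protocol()` returns a `protocol_config`;
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol_config"))
  x <- list(
    species_label = protocol$species_label,
    session_minutes = protocol$session_minutes,
    timeout_seconds = protocol$timeout_seconds,
    reward = unclass(protocol$reward),
    schedule = list(p = protocol$schedule$p,
                    sessions_per_level = protocol$schedule$sessions_per_level),
    inclusion_threshold = protocol$inclusion_threshold,
    inclusion_levels = protocol$inclusion_levels,
    first_test_session = protocol$first_test_session
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  needed <- c("species_label", "session_minutes", "timeout_seconds",
              "reward", "schedule")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("protocol file ", path, " lacks fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  protocol_config(
    species_label = x$species_label,
    session_minutes = x$session_minutes,
    timeout_seconds = x$timeout_seconds,
    reward = do.call(reward_spec, x$reward),
    schedule = probability_schedule(unlist(x$schedule$p),
                                    unlist(x$schedule$sessions_per_level)),
    inclusion_threshold = x$inclusion_threshold %||% 60,
    inclusion_levels = unlist(x$inclusion_levels) %||% c(1.0, 0.5),
    first_test_session = x$first_test_session %||% 1L
  )
}
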