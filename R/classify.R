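# Phenotyping: inclusion filter, per-subject preference-odds slope, and the
# within-species median split into "gambler" vs "non-gambler".

#' Inclusion filter for one subject
#'
#' A subject is included when its mean %LLL preference over all sessions at
#' the inclusion probability levels (default p = 100% and 50%, the two levels
#' before the indifference zone) is *strictly* greater than the protocol's
#' threshold (default 60%). For protocols with replicate sessions per level
#' (marmoset) the mean runs over every replicate.
#'
#' @param metrics Session-metrics rows of a single subject.
#' @param protocol A [protocol_config()].
#' @return List with `included` (logical) and `reason` (`""` when included).
#' @export
include_subject <- function(metrics, protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (dplyr::n_distinct(metrics$subject_id) > 1) {
    stop("include_subject() expects one subject's metrics", call. = FALSE)
  }
  levels <- protocol$inclusion_levels
  absent <- setdiff(levels, metrics$p_set)
  if (length(absent)) {
    stop("subject ", metrics$subject_id[1],
         ": no sessions at inclusion level(s) p = ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  rows <- metrics[metrics$p_set %in% levels, ]
  m <- mean(rows$pref_LLL, na.rm = TRUE)
  if (is.nan(m)) {
    return(list(included = FALSE,
                reason = "no completed trials in inclusion sessions"))
  }
  if (m > protocol$inclusion_threshold) {
    list(included = TRUE, reason = "")
  } else {
    list(included = FALSE,
         reason = sprintf("mean %%LLL %.1f at p = {%s} not above %g",
                          m, paste(levels, collapse = ", "),
                          protocol$inclusion_threshold))
  }
}

#' Preference-odds slope of one subject
#'
#' Ordinary least-squares slope of per-session %LLL preference on
#' `log(experienced_odds + 1)` (base 10 by default, mirroring the spreadsheet
#' convention) over all usable testing-phase sessions. Sessions with missing
#' preference or missing experienced odds (no LLL choices, or LLL never
#' rewarded) are excluded and do not count toward `n_fit_points`. Sessions at
#' p = 100% contribute points at x = 0.
#'
#' @param metrics Session-metrics rows of a single subject.
#' @param log_base Base of the odds logarithm (default 10). Changing the base
#'   rescales every slope by the same factor and leaves median-split labels
#'   unchanged.
#' @param first_test_session Sessions with a smaller index are treated as
#'   training and ignored.
#' @return List with `slope` (% per log-unit) and `n_fit_points`.
#' @export
#' @examples
#' m <- tibble::tibble(subject_id = "s", pref_LLL = c(100, 70, 40),
#'                     experienced_odds = 10^c(0, 0.301, 0.602) - 1,
#'                     session_index = 1:3)
#' preference_odds_slope(m)$slope  # about -99.7
preference_odds_slope <- function(metrics, log_base = 10,
                                  first_test_session = 1L) {
  if (dplyr::n_distinct(metrics$subject_id) > 1) {
    stop("preference_odds_slope() expects one subject's metrics", call. = FALSE)
  }
  rows <- metrics[metrics$session_index >= first_test_session, ]
  usable <- !is.na(rows$pref_LLL) & !is.na(rows$experienced_odds)
  n <- sum(usable)
  if (n < 2) {
    stop("subject ", metrics$subject_id[1], ": only ", n,
         " usable session(s) for the preference-odds fit (need >= 2)",
         call. = FALSE)
  }
  x <- log(rows$experienced_odds[usable] + 1, base = log_base)
  y <- rows$pref_LLL[usable]
  if (stats::var(x) == 0) {
    stop("subject ", metrics$subject_id[1],
         ": experienced odds are constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]), n_fit_points = n)
}

#' Median split of fitted slopes into gambler / non-gambler
#'
#' Within each species, included subjects are split on the median of their
#' signed preference-odds slopes: slopes strictly below the median (steeper
#' decline) are labelled `non_gambler`, strictly above `gambler`. A subject
#' whose slope equals the median (odd cohorts) is assigned to the provisional
#' group its slope is closest to; closeness is the distance to the group's
#' mean slope by default, or to the nearest member with
#' `tie_rule = "nearest-neighbor"`. Exact equidistance resolves to
#' `non_gambler`. Excluded subjects pass through unlabelled.
#'
#' @param profiles Subject-profile tibble with columns `subject_id`,
#'   `species`, `included`, `slope` (see [classify_cohort()]).
#' @param tie_rule `"group-mean"` (default) or `"nearest-neighbor"`.
#' @return The profiles with a `strategy` column
#'   (`"gambler"`/`"non_gambler"`/`NA`).
#' @export
median_split <- function(profiles, tie_rule = c("group-mean", "nearest-neighbor")) {
  tie_rule <- match.arg(tie_rule)
  profiles$strategy <- NA_character_
  for (sp in unique(profiles$species)) {
    idx <- which(profiles$species == sp & profiles$included)
    slopes <- profiles$slope[idx]
    if (length(idx) < 2) {
      stop("species ", sp, ": need >= 2 included subjects for a median split",
           call. = FALSE)
    }
    if (dplyr::n_distinct(slopes) == 1) {
      stop("species ", sp,
           ": all slopes are equal; no separable subpopulations", call. = FALSE)
    }
    med <- stats::median(slopes)
    lab <- rep(NA_character_, length(slopes))
    lab[slopes < med] <- "non_gambler"
    lab[slopes > med] <- "gambler"
    at_median <- which(slopes == med)
    if (length(at_median)) {
      below <- slopes[slopes < med]
      above <- slopes[slopes > med]
      ref <- function(side, s) {
        if (!length(side)) return(Inf)
        if (tie_rule == "group-mean") abs(s - mean(side)) else min(abs(s - side))
      }
      for (i in at_median) {
        d_low <- ref(below, slopes[i])
        d_high <- ref(above, slopes[i])
        lab[i] <- if (d_high < d_low) "gambler" else "non_gambler"
      }
    }
    profiles$strategy[idx] <- lab
  }
  profiles
}

#' Classify a cohort from its session metrics
#'
#' Runs the full phenotyping procedure: the inclusion filter
#' ([include_subject()]), the per-subject preference-odds slope
#' ([preference_odds_slope()]) for included subjects, and the within-species
#' [median_split()]. The split is recomputed on included subjects only.
#'
#' @param metrics Session-metrics table from [cohort_metrics()].
#' @param protocol A [protocol_config()].
#' @param tie_rule Median-subject rule, see [median_split()].
#' @param pool_species Compute one pooled median split across species instead
#'   of the default within-species splits.
#' @return One profile row per subject: `subject_id`, `species`, `included`,
#'   `exclusion_reason`, `slope`, `n_fit_points`, `strategy`.
#' @export
#' @examples
#' protocol <- default_protocol("rat")
#' log <- simulate_cohort(demo_cohort("rat", 3), protocol, seed = 42)
#' classify_cohort(cohort_metrics(log, protocol), protocol)
classify_cohort <- function(metrics, protocol,
                            tie_rule = c("group-mean", "nearest-neighbor"),
                            pool_species = FALSE) {
  stopifnot(inherits(protocol, "protocol_config"))
  tie_rule <- match.arg(tie_rule)
  subjects <- unique(metrics$subject_id)
  rows <- lapply(subjects, function(id) {
    m <- metrics[metrics$subject_id == id, ]
    inc <- include_subject(m, protocol)
    if (inc$included) {
      fit <- preference_odds_slope(
        m, first_test_session = protocol$first_test_session)
      slope <- fit$slope
      n_fit <- fit$n_fit_points
    } else {
      slope <- NA_real_
      n_fit <- 0L
    }
    tibble::tibble(subject_id = id, species = m$species[1],
                   included = inc$included, exclusion_reason = inc$reason,
                   slope = slope, n_fit_points = as.integer(n_fit))
  })
  profiles <- dplyr::bind_rows(rows)
  if (pool_species) {
    pooled <- profiles
    pooled$species <- "pooled"
    profiles$strategy <- median_split(pooled, tie_rule = tie_rule)$strategy
  } else {
    profiles <- median_split(profiles, tie_rule = tie_rule)
  }
  profiles
}

#' Write / read a subject-profiles table
#'
#' @param profiles Profiles tibble from [classify_cohort()].
#' @param path File path.
#' @return `read_profiles()` returns the profiles tibble.
#' @export
write_profiles <- function(profiles, path) {
  out <- as.data.frame(profiles)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::tibble(
    subject_id = as.character(raw$subject_id),
    species = as.character(raw$species),
    included = as.logical(raw$included),
    exclusion_reason = ifelse(is.na(raw$exclusion_reason), "",
                              as.character(raw$exclusion_reason)),
    slope = as.numeric(raw$slope),
    n_fit_points = as.integer(raw$n_fit_points),
    strategy = as.character(raw$strategy)
  )
}
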