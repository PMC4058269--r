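# Synthetic cohorts: trial-level generation with the statistical structure the
# downstream analysis assumes, so every stage is testable without animal data.
#
# A synthetic subject's large-reward preference declines linearly in
# log10(odds + 1) of the SET probability; delivery is Bernoulli(p_set) per
# trial; free-operant trial counts are Poisson; inadequate pokes during the
# post-choice timeout are Poisson bursts whose rates depend on whether the
# trial was an omission.

#' Generative parameters of a synthetic subject
#'
#' @param subject_id Unique subject label.
#' @param species_label Species (used for protocol matching and grouping).
#' @param intercept_a Baseline %LLL preference at odds 0 (0--100).
#' @param slope_b Change in %LLL per unit log10(odds + 1); <= 0 for a
#'   declining preference. Steep (strongly negative) values produce
#'   non-gambler-like subjects, shallow values gambler-like ones.
#' @param rate_lambda Completed trials per minute at p = 100%.
#' @param rate_compensation_c Dimensionless >= 0: throughput inflation with
#'   rarefaction; the Poisson trial rate is
#'   `rate_lambda * (1 + c * log10(odds + 1))`.
#' @param persistence_rho Mean inadequate pokes toward the LLL hole per
#'   omission trial.
#' @param restlessness_rho Mean inadequate pokes toward the SS hole per
#'   omission trial.
#' @param background_rho Mean inadequate pokes toward each hole on rewarded
#'   trials.
#' @return One-row tibble of class `agent_params`.
#' @export
#' @examples
#' agent_params("r1", "rat", intercept_a = 100, slope_b = -90)
agent_params <- function(subject_id, species_label,
                         intercept_a = 100, slope_b = -50,
                         rate_lambda = 2.4, rate_compensation_c = 0,
                         persistence_rho = 0.5, restlessness_rho = 0.5,
                         background_rho = 0.2) {
  if (intercept_a < 0 || intercept_a > 100) {
    stop("intercept_a must lie in [0, 100]", call. = FALSE)
  }
  rates <- c(rate_lambda, rate_compensation_c, persistence_rho,
             restlessness_rho, background_rho)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  out <- tibble::tibble(
    subject_id = as.character(subject_id),
    species = as.character(species_label),
    intercept_a = as.numeric(intercept_a),
    slope_b = as.numeric(slope_b),
    rate_lambda = as.numeric(rate_lambda),
    rate_compensation_c = as.numeric(rate_compensation_c),
    persistence_rho = as.numeric(persistence_rho),
    restlessness_rho = as.numeric(restlessness_rho),
    background_rho = as.numeric(background_rho)
  )
  class(out) <- c("agent_params", class(out))
  out
}

#' Demonstration cohort of well-separated temperaments
#'
#' Builds a cohort of `n_per_group` shallow-slope ("flat", gambler-like,
#' b = -10) and `n_per_group` steep-slope (non-gambler-like, b = -90) agents,
#' all with perfect baseline preference (a = 100). Poke rates mirror the
#' qualitative patterns of the two phenotypes: flat agents keep seeking the
#' LLL hole after omissions (high persistence), steep agents divert to the SS
#' hole (high restlessness) and compensate throughput as the large reward is
#' rarefied. Trial rates give about 60 completed trials per session under the
#' species preset.
#'
#' @param species_label `"rat"` or `"marmoset"`.
#' @param n_per_group Agents per temperament group (default 6).
#' @param slope_flat,slope_steep Generative slopes of the two groups.
#' @return An `agent_params` tibble with `2 * n_per_group` rows.
#' @export
demo_cohort <- function(species_label = "rat", n_per_group = 6,
                        slope_flat = -10, slope_steep = -90) {
  protocol <- default_protocol(species_label)
  lambda <- 60 / protocol$session_minutes
  flat <- lapply(seq_len(n_per_group), function(i) {
    agent_params(sprintf("%s_flat_%02d", species_label, i), species_label,
                 intercept_a = 100, slope_b = slope_flat,
                 rate_lambda = lambda, rate_compensation_c = 0,
                 persistence_rho = 2, restlessness_rho = 0.5)
  })
  steep <- lapply(seq_len(n_per_group), function(i) {
    agent_params(sprintf("%s_steep_%02d", species_label, i), species_label,
                 intercept_a = 100, slope_b = slope_steep,
                 rate_lambda = lambda, rate_compensation_c = 0.5,
                 persistence_rho = 0.5, restlessness_rho = 2)
  })
  out <- dplyr::bind_rows(c(flat, steep))
  class(out) <- c("agent_params", class(out))
  out
}

# expected %LLL of an agent at a set probability (the generative clamp formula)
expected_preference <- function(intercept_a, slope_b, p_set) {
  pmin(pmax(intercept_a + slope_b * log10(set_odds(p_set) + 1), 0), 100)
}

#' Simulate one session of the task
#'
#' The number of completed trials is Poisson with mean
#' `rate_lambda * (1 + c * log10(odds + 1)) * session_minutes`. Each trial
#' independently chooses LLL with probability
#' `clamp(a + b * log10(odds + 1), 0, 100) / 100` (odds from the *set*
#' probability), delivers the large reward with probability `p_set`, draws
#' pellets uniformly on the configured range when delivered, and draws
#' Poisson inadequate-poke counts for each hole (omission rates on omission
#' trials, the background rate otherwise).
#'
#' @param agent A one-row [agent_params()].
#' @param protocol A [protocol_config()].
#' @param session_index Ordinal session number within the testing phase.
#' @param p_set Set delivery probability; must appear in the protocol schedule.
#' @param seed Integer seed; identical inputs give identical output. The
#'   caller's RNG state is left untouched.
#' @return A tibble of trial records with columns `subject_id`, `species`,
#'   `session_index`, `p_set`, `choice` (`"SS"`/`"LLL"`), `delivered`,
#'   `pellets`, `inadequate_SS`, `inadequate_LLL`. Zero-trial sessions yield
#'   zero rows (legal).
#' @export
simulate_session <- function(agent, protocol, session_index, p_set, seed) {
  stopifnot(inherits(protocol, "protocol_config"), nrow(agent) == 1)
  if (!p_set %in% protocol$schedule$p) {
    stop("p_set = ", p_set, " is not a level of the protocol schedule",
         call. = FALSE)
  }
  x <- log10(set_odds(p_set) + 1)
  withr::with_seed(as.integer(seed), {
    n <- stats::rpois(1, agent$rate_lambda *
                        (1 + agent$rate_compensation_c * x) *
                        protocol$session_minutes)
    if (n == 0) return(empty_event_log())
    pref <- expected_preference(agent$intercept_a, agent$slope_b, p_set) / 100
    lll <- stats::runif(n) < pref
    delivered <- !lll | stats::runif(n) < p_set
    rw <- protocol$reward
    pellets <- integer(n)
    pellets[!lll] <- sample(rw$small_min:rw$small_max, sum(!lll), replace = TRUE)
    hit <- lll & delivered
    pellets[hit] <- sample(rw$large_min:rw$large_max, sum(hit), replace = TRUE)
    omission <- lll & !delivered
    inadequate_LLL <- stats::rpois(n, ifelse(omission, agent$persistence_rho,
                                             agent$background_rho))
    inadequate_SS <- stats::rpois(n, ifelse(omission, agent$restlessness_rho,
                                            agent$background_rho))
    tibble::tibble(
      subject_id = agent$subject_id,
      species = agent$species,
      session_index = as.integer(session_index),
      p_set = as.numeric(p_set),
      choice = ifelse(lll, "LLL", "SS"),
      delivered = delivered,
      pellets = as.integer(pellets),
      inadequate_SS = as.integer(inadequate_SS),
      inadequate_LLL = as.integer(inadequate_LLL)
    )
  })
}

empty_event_log <- function() {
  tibble::tibble(
    subject_id = character(), species = character(),
    session_index = integer(), p_set = numeric(),
    choice = character(), delivered = logical(), pellets = integer(),
    inadequate_SS = integer(), inadequate_LLL = integer()
  )
}

# ordered (session_index, p_set) pairs of the testing schedule, replicates included
schedule_sessions <- function(protocol) {
  tibble::tibble(
    session_index = seq_len(sum(protocol$schedule$sessions_per_level)),
    p_set = rep(protocol$schedule$p, protocol$schedule$sessions_per_level)
  )
}

#' Simulate a full cohort through the testing schedule
#'
#' Runs [simulate_session()] for every agent over every scheduled session
#' (replicate sessions included, indexed 1..total in schedule order).
#' Per-(agent, session) seeds are drawn deterministically from the master
#' seed, so a given `(agents, protocol, seed)` triple always yields an
#' identical event log.
#'
#' @param agents An [agent_params()] tibble with distinct `subject_id`s.
#' @param protocol A [protocol_config()].
#' @param seed Master integer seed.
#' @return Event log: one tibble of trial records (see [simulate_session()]).
#' @export
#' @examples
#' log <- simulate_cohort(demo_cohort("rat", 2), default_protocol("rat"), seed = 1)
#' dplyr::count(log, subject_id, session_index)
simulate_cohort <- function(agents, protocol, seed) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (anyDuplicated(agents$subject_id)) {
    stop("duplicate subject_id in agents: ",
         paste(unique(agents$subject_id[duplicated(agents$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  sessions <- schedule_sessions(protocol)
  n_a <- nrow(agents)
  n_s <- nrow(sessions)
  seeds <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(.Machine$integer.max - 1L, n_a * n_s), nrow = n_a)
  })
  logs <- vector("list", n_a * n_s)
  k <- 0
  for (i in seq_len(n_a)) {
    for (j in seq_len(n_s)) {
      k <- k + 1
      logs[[k]] <- simulate_session(agents[i, ], protocol,
                                    sessions$session_index[j],
                                    sessions$p_set[j], seeds[i, j])
    }
  }
  dplyr::bind_rows(logs)
}

#' Write / read a trial-level event log
#'
#' Event logs are comma-separated UTF-8 text with a header row and columns
#' exactly `subject_id, species, session_index, p_set, choice, delivered,
#' pellets, inadequate_SS, inadequate_LLL` (`delivered` serialized as 0/1).
#' The reader validates every record and rejects rows violating the trial
#' invariants (an SS choice is always delivered; an omitted LLL trial earns
#' zero pellets; a delivered trial earns at least one) with row-numbered
#' diagnostics.
#'
#' @param records Event-log tibble as produced by [simulate_cohort()].
#' @param path File path.
#' @param protocol Optional [protocol_config()]; when supplied, pellet counts
#'   are additionally checked against the configured reward ranges.
#' @return `read_event_log()` returns the validated event log tibble;
#'   `write_event_log()` returns `path` invisibly.
#' @export
write_event_log <- function(records, path) {
  out <- as.data.frame(records)
  out$delivered <- as.integer(out$delivered)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

event_log_columns <- c("subject_id", "species", "session_index", "p_set",
                       "choice", "delivered", "pellets",
                       "inadequate_SS", "inadequate_LLL")

#' @rdname write_event_log
#' @export
read_event_log <- function(path, protocol = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(raw), event_log_columns)) {
    stop("malformed event-log header in ", path, ": expected columns ",
         paste(event_log_columns, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_event_log())
  fail <- function(rows, what) {
    stop("invalid event log ", path, ": ", what, " (data row",
         if (length(rows) > 1) "s", " ",
         paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) ", ...", ")", call. = FALSE)
  }
  rows <- seq_len(nrow(raw))
  if (!all(raw$delivered %in% c(0L, 1L))) {
    fail(rows[!raw$delivered %in% c(0L, 1L)], "delivered must be 0 or 1")
  }
  if (!all(raw$choice %in% c("SS", "LLL"))) {
    fail(rows[!raw$choice %in% c("SS", "LLL")], "choice must be SS or LLL")
  }
  counts <- c("session_index", "pellets", "inadequate_SS", "inadequate_LLL")
  for (col in counts) {
    bad <- !is.finite(raw[[col]]) | raw[[col]] < 0 | raw[[col]] != round(raw[[col]])
    if (any(bad)) fail(rows[bad], paste(col, "must be a non-negative integer"))
  }
  if (any(raw$p_set <= 0 | raw$p_set > 1)) {
    fail(rows[raw$p_set <= 0 | raw$p_set > 1], "p_set must lie in (0, 1]")
  }
  delivered <- raw$delivered == 1L
  bad <- raw$choice == "SS" & !delivered
  if (any(bad)) fail(rows[bad], "SS choices are always delivered")
  bad <- raw$choice == "LLL" & !delivered & raw$pellets != 0
  if (any(bad)) fail(rows[bad], "omitted LLL trials must earn 0 pellets")
  bad <- delivered & raw$pellets < 1
  if (any(bad)) fail(rows[bad], "delivered trials must earn at least 1 pellet")
  if (!is.null(protocol)) {
    rw <- protocol$reward
    bad <- raw$choice == "SS" &
      (raw$pellets < rw$small_min | raw$pellets > rw$small_max)
    if (any(bad)) fail(rows[bad], "SS pellets outside the configured range")
    bad <- raw$choice == "LLL" & delivered &
      (raw$pellets < rw$large_min | raw$pellets > rw$large_max)
    if (any(bad)) fail(rows[bad], "LLL pellets outside the configured range")
  }
  tibble::tibble(
    subject_id = as.character(raw$subject_id),
    species = as.character(raw$species),
    session_index = as.integer(raw$session_index),
    p_set = as.numeric(raw$p_set),
    choice = raw$choice,
    delivered = delivered,
    pellets = as.integer(raw$pellets),
    inadequate_SS = as.integer(raw$inadequate_SS),
    inadequate_LLL = as.integer(raw$inadequate_LLL)
  )
}

#' Write / read an agent-parameter table
#'
#' Plain CSV serialization of [agent_params()] rows, for scripting cohort
#' definitions outside R.
#'
#' @param agents An `agent_params` tibble.
#' @param path File path.
#' @return `read_agent_params()` returns an `agent_params` tibble.
#' @export
write_agent_params <- function(agents, path) {
  utils::write.csv(as.data.frame(agents), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_agent_params
#' @export
read_agent_params <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    agent_params(raw$subject_id[i], raw$species[i],
                 intercept_a = raw$intercept_a[i], slope_b = raw$slope_b[i],
                 rate_lambda = raw$rate_lambda[i],
                 rate_compensation_c = raw$rate_compensation_c[i],
                 persistence_rho = raw$persistence_rho[i],
                 restlessness_rho = raw$restlessness_rho[i],
                 background_rho = raw$background_rho[i])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("agent_params", class(out))
  out
}
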