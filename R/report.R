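# Group-level summaries (mean +/- SEM per species x strategy x p level) and
# the end-to-end pipeline driver.

summary_metrics <- c("pref_LLL", "persistence", "restlessness",
                     "trials_per_min", "pellets_per_min")

#' Group-level summary table
#'
#' For every species x strategy x set-probability cell, the across-subject
#' mean and SEM of each session metric. Replicate sessions at the same p
#' level (marmoset triplets) are averaged within subject first, so each
#' subject contributes one value per level; SEM is the sample SD over subject
#' means divided by `sqrt(n_subjects)`, and is missing for single-subject
#' groups.
#'
#' @param metrics Session-metrics table ([cohort_metrics()]).
#' @param profiles Subject profiles ([classify_cohort()]); only labelled
#'   subjects are summarized, and every labelled subject must appear in
#'   `metrics`.
#' @return Tibble with one row per species x strategy x p level:
#'   `n_subjects` plus `<metric>_mean` and `<metric>_sem` for `pref_LLL`,
#'   `persistence`, `restlessness`, `trials_per_min` and `pellets_per_min`.
#' @export
group_summary <- function(metrics, profiles) {
  labelled <- profiles[!is.na(profiles$strategy), ]
  missing <- setdiff(labelled$subject_id, metrics$subject_id)
  if (length(missing)) {
    stop("labelled subject(s) absent from metrics: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(
    metrics, labelled[, c("subject_id", "strategy")], by = "subject_id")
  per_subject <- dplyr::summarise(
    dplyr::group_by(joined, .data$species, .data$strategy,
                    .data$subject_id, .data$p_set),
    dplyr::across(dplyr::all_of(summary_metrics), ~mean(.x, na.rm = TRUE)),
    .groups = "drop")
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  out <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$species, .data$strategy, .data$p_set),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    dplyr::across(dplyr::all_of(summary_metrics),
                  list(mean = ~mean(.x, na.rm = TRUE), sem = sem)),
    .groups = "drop")
  dplyr::arrange(out, .data$species, .data$strategy, dplyr::desc(.data$p_set))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (optional) -> session metrics -> classification -> group
#' summary in one call, driven by a configuration list or YAML file with the
#' shape:
#'
#' ```yaml
#' protocol: rat            # "rat", "marmoset", or a protocol YAML path
#' simulate:                # either this block ...
#'   agents: demo           # "demo" or an agent-parameter CSV path
#'   seed: 1
#' log: path/to/events.csv  # ... or an existing event log
#' tie_rule: group-mean
#' ```
#'
#' When `out_dir` is given, all artifacts are written there as delimited text
#' (`event_log.csv`, `metrics.csv`, `profiles.csv`, `summary.csv`) together
#' with a run manifest (`manifest.yaml`: seed, configuration hash, package
#' and R versions, artifact hashes) that is identical across reruns of the
#' same configuration. Stage timings and warnings (excluded subjects,
#' missing-odds sessions) are reported via `message()`.
#'
#' @param config Configuration list or path to a YAML file.
#' @param out_dir Optional output directory (created if needed).
#' @return List with `event_log`, `metrics`, `profiles`, `summary`,
#'   `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(list(protocol = "rat",
#'                          simulate = list(agents = "demo", seed = 1)))
#' res$profiles
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$log) && is.null(config$simulate)) {
    stop("config must name either an input `log` or a `simulate` block",
         call. = FALSE)
  }
  protocol <- config$protocol %||% "rat"
  if (is.character(protocol)) {
    protocol <- if (protocol %in% c("rat", "marmoset")) {
      default_protocol(protocol)
    } else {
      read_protocol(protocol)
    }
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        message("[", name, "] warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    message(sprintf("[%s] done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  seed <- NULL
  if (!is.null(config$simulate)) {
    seed <- config$simulate$seed %||% 1L
    agents_spec <- config$simulate$agents %||% "demo"
    agents <- if (identical(agents_spec, "demo")) {
      demo_cohort(protocol$species_label)
    } else if (is.character(agents_spec)) {
      read_agent_params(agents_spec)
    } else {
      agents_spec
    }
    event_log <- stage("simulate", simulate_cohort(agents, protocol, seed))
  } else {
    event_log <- stage("read-log", read_event_log(config$log, protocol))
  }
  metrics <- stage("analyze", cohort_metrics(event_log, protocol))
  profiles <- stage("classify", classify_cohort(
    metrics, protocol, tie_rule = config$tie_rule %||% "group-mean"))
  excluded <- profiles$subject_id[!profiles$included]
  if (length(excluded)) {
    message("[classify] excluded subject(s): ", paste(excluded, collapse = ", "))
  }
  summary <- stage("summarize", group_summary(metrics, profiles))
  manifest <- list(
    package = "pdtask",
    package_version = as.character(utils::packageVersion("pdtask")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = rlang::hash(config),
    n_subjects = dplyr::n_distinct(event_log$subject_id),
    n_trials = nrow(event_log),
    artifact_hashes = list(
      event_log = rlang::hash(event_log),
      metrics = rlang::hash(metrics),
      profiles = rlang::hash(profiles),
      summary = rlang::hash(summary)
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_log(event_log, file.path(out_dir, "event_log.csv"))
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    write_profiles(profiles, file.path(out_dir, "profiles.csv"))
    utils::write.csv(as.data.frame(summary),
                     file.path(out_dir, "summary.csv"),
                     row.names = FALSE, na = "")
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(event_log = event_log, metrics = metrics, profiles = profiles,
       summary = summary, manifest = manifest)
}

#' Plot preference-odds curves
#'
#' Per-subject %LLL preference against log10(experienced odds + 1), colored
#' by phenotype when profiles are supplied. Visualization only; the numeric
#' tables are the analysis contract.
#'
#' @param metrics Session-metrics table.
#' @param profiles Optional subject profiles for phenotype coloring.
#' @return A ggplot object.
#' @export
plot_preference_odds <- function(metrics, profiles = NULL) {
  df <- metrics[!is.na(metrics$pref_LLL) & !is.na(metrics$experienced_odds), ]
  df$x <- log10(df$experienced_odds + 1)
  aes_line <- ggplot2::aes(x = .data$x, y = .data$pref_LLL,
                           group = .data$subject_id)
  p <- ggplot2::ggplot(df, aes_line)
  if (!is.null(profiles)) {
    df <- dplyr::left_join(df, profiles[, c("subject_id", "strategy")],
                           by = "subject_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$pref_LLL,
                                          group = .data$subject_id,
                                          color = .data$strategy))
  }
  p +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_smooth(ggplot2::aes(group = NULL), method = "lm",
                         formula = y ~ x, se = FALSE, linewidth = 1) +
    ggplot2::labs(x = "log10(experienced odds + 1)",
                  y = "LLL preference (%)",
                  color = "phenotype") +
    ggplot2::theme_minimal()
}
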