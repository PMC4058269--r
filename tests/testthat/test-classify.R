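protocol_rat <- default_protocol("rat")

test_that("inclusion requires strictly more than 60% preference before the zone", {
  base <- function(pref) {
    make_metrics("s1", p_set = c(1, 0.5, 0.33), pref_LLL = c(pref, pref, 10),
                 experienced_odds = c(0, 1, 2))
  }
  expect_true(include_subject(base(85), protocol_rat)$included)
  expect_true(include_subject(base(61), protocol_rat)$included)
  at_bound <- include_subject(base(60), protocol_rat)   # "more than 60%" is strict
  expect_false(at_bound$included)
  expect_match(at_bound$reason, "60")

  # only inclusion-level sessions count: poor later sessions are irrelevant
  expect_true(include_subject(base(100), protocol_rat)$included)

  # marmoset replicates all enter the mean
  marmoset <- default_protocol("marmoset")
  m <- make_metrics("m1", p_set = c(1, 1, 1, 0.5, 0.5, 0.5),
                    pref_LLL = c(90, 90, 90, 40, 40, 40),
                    experienced_odds = c(0, 0, 0, 1, 1, 1),
                    species = "marmoset")
  expect_true(include_subject(m, marmoset)$included)   # mean 65 > 60

  no_level <- make_metrics("s2", p_set = c(0.5, 0.33), pref_LLL = c(90, 80),
                           experienced_odds = c(1, 2))
  expect_error(include_subject(no_level, protocol_rat), "p = 1")
})

test_that("preference-odds slope equals the normal-equations oracle", {
  # hand-built example: equally spaced decline of 30% per 0.301 log-units
  x <- c(0, 0.301, 0.602)
  m <- make_metrics("s1", p_set = c(1, 0.5, 0.25), pref_LLL = c(100, 70, 40),
                    experienced_odds = 10^x - 1)
  fit <- preference_odds_slope(m)
  expect_equal(fit$slope, slope_oracle(x, c(100, 70, 40)), tolerance = 1e-12)
  expect_equal(fit$slope, -30 / 0.301, tolerance = 1e-9)   # -99.668
  expect_equal(fit$n_fit_points, 3L)

  # flat preference has zero slope; two points give the exact line
  flat <- make_metrics("s1", p_set = c(1, 0.5, 0.25), pref_LLL = c(80, 80, 80),
                       experienced_odds = c(0, 1, 3))
  expect_equal(preference_odds_slope(flat)$slope, 0)
  two <- make_metrics("s1", p_set = c(1, 0.2), pref_LLL = c(100, 40),
                      experienced_odds = c(0, 4))
  expect_equal(preference_odds_slope(two)$slope, -60 / log10(5))

  # randomized agreement with the independent oracle
  withr::with_seed(123, {
    for (i in 1:200) {
      n <- sample(3:12, 1)
      odds <- sort(stats::runif(n, 0, 8))
      pref <- pmin(pmax(stats::rnorm(n, 90 - 40 * log10(odds + 1), 15), 0), 100)
      m <- make_metrics("s", p_set = rep(0.5, n), pref_LLL = pref,
                        experienced_odds = odds, session_index = seq_len(n))
      expect_equal(preference_odds_slope(m)$slope,
                   slope_oracle(log10(odds + 1), pref), tolerance = 1e-9)
    }
  })
})

test_that("sessions with missing odds are dropped from the fit", {
  m <- make_metrics("s1", p_set = c(1, 0.5, 0.25, 0.14),
                    pref_LLL = c(100, 70, 40, 20),
                    experienced_odds = c(0, 1, NA, 6))
  fit <- preference_odds_slope(m)
  expect_equal(fit$n_fit_points, 3L)
  expect_equal(fit$slope,
               slope_oracle(log10(c(0, 1, 6) + 1), c(100, 70, 20)),
               tolerance = 1e-12)

  sparse <- make_metrics("s9", p_set = c(1, 0.5), pref_LLL = c(100, 70),
                         experienced_odds = c(0, NA))
  expect_error(preference_odds_slope(sparse), "s9.*usable")

  # training sessions below first_test_session are ignored
  with_training <- make_metrics("s1", p_set = c(1, 1, 0.5, 0.25),
                                pref_LLL = c(10, 100, 70, 40),
                                experienced_odds = c(0, 0, 1, 3),
                                session_index = c(0, 1, 2, 3))
  fit <- preference_odds_slope(with_training, first_test_session = 1L)
  expect_equal(fit$n_fit_points, 3L)
  expect_equal(fit$slope, slope_oracle(log10(c(0, 1, 3) + 1), c(100, 70, 40)))
})

test_that("median split labels steep slopes non-gambler and handles the median subject", {
  prof <- function(slopes, species = "rat") {
    tibble::tibble(subject_id = paste0("s", seq_along(slopes)),
                   species = species, included = TRUE,
                   exclusion_reason = "", slope = slopes,
                   n_fit_points = 7L)
  }
  even <- median_split(prof(c(-5, -10, -60, -80)))
  expect_equal(even$strategy, c("gambler", "gambler",
                                "non_gambler", "non_gambler"))

  # odd cohort: median subject (-40) is closer to the mean of the upper
  # provisional group (-5, distance 35) than the lower (-80, distance 40)
  odd <- median_split(prof(c(-5, -40, -80)))
  expect_equal(odd$strategy, c("gambler", "gambler", "non_gambler"))

  # nearest-neighbor rule can disagree with the group-mean rule
  nn <- median_split(prof(c(-10, -20, -42, -60, -100)),
                     tie_rule = "nearest-neighbor")
  gm <- median_split(prof(c(-10, -20, -42, -60, -100)))
  expect_equal(nn$strategy[3], "non_gambler")   # -60 is 18 away, -20 is 22
  expect_equal(gm$strategy[3], "gambler")       # mean(-10,-20)=-15: 27 vs 38

  expect_error(median_split(prof(c(-30, -30, -30))), "no separable")
  expect_error(median_split(prof(-30)), ">= 2")

  # splits are independent within species
  both <- dplyr::bind_rows(prof(c(-5, -80), "rat"),
                           prof(c(-200, -300), "marmoset"))
  both$subject_id <- paste0("s", 1:4)
  lab <- median_split(both)$strategy
  expect_equal(lab, c("gambler", "non_gambler", "gambler", "non_gambler"))
})

test_that("label assignment is invariant to the log base of the fit", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- 9
      odds <- replicate(n, sort(stats::runif(7, 0, 7)), simplify = FALSE)
      prefs <- replicate(n, pmin(pmax(
        stats::rnorm(7, 100 + stats::runif(1, -95, -5) * log10(1:7), 8),
        0), 100), simplify = FALSE)
      slopes10 <- vapply(seq_len(n), function(i) {
        m <- make_metrics(paste0("s", i), p_set = rep(0.5, 7),
                          pref_LLL = prefs[[i]], experienced_odds = odds[[i]])
        preference_odds_slope(m, log_base = 10)$slope
      }, numeric(1))
      slopes_e <- vapply(seq_len(n), function(i) {
        m <- make_metrics(paste0("s", i), p_set = rep(0.5, 7),
                          pref_LLL = prefs[[i]], experienced_odds = odds[[i]])
        preference_odds_slope(m, log_base = exp(1))$slope
      }, numeric(1))
      expect_equal(slopes_e, slopes10 / log(10), tolerance = 1e-9)
      prof <- tibble::tibble(subject_id = paste0("s", 1:n), species = "rat",
                             included = TRUE, exclusion_reason = "",
                             slope = slopes10, n_fit_points = 7L)
      prof_e <- prof
      prof_e$slope <- slopes_e
      expect_equal(median_split(prof_e)$strategy, median_split(prof)$strategy)
    }
  })
})

test_that("classify_cohort runs the whole procedure with provenance", {
  log <- simulate_cohort(demo_cohort("rat", 4), protocol_rat, seed = 21)
  metrics <- cohort_metrics(log, protocol_rat)
  profiles <- classify_cohort(metrics, protocol_rat)
  expect_equal(nrow(profiles), 8)
  expect_true(all(profiles$included))
  expect_setequal(unique(profiles$strategy), c("gambler", "non_gambler"))
  # generative temperament is recovered from the names
  expect_true(all(profiles$strategy[grepl("steep", profiles$subject_id)] ==
                    "non_gambler"))
  expect_true(all(profiles$strategy[grepl("flat", profiles$subject_id)] ==
                    "gambler"))
  expect_true(all(profiles$n_fit_points[profiles$included] >= 2))

  # pure function of its inputs
  expect_identical(profiles, classify_cohort(metrics, protocol_rat))

  # a subject failing the filter passes through unlabelled
  lazy <- make_metrics("rat_lazy", p_set = protocol_rat$schedule$p,
                       pref_LLL = c(50, 50, 40, 30, 30, 20, 20),
                       experienced_odds = set_odds(protocol_rat$schedule$p))
  profiles2 <- classify_cohort(dplyr::bind_rows(metrics, lazy), protocol_rat)
  lazy_row <- profiles2[profiles2$subject_id == "rat_lazy", ]
  expect_false(lazy_row$included)
  expect_match(lazy_row$exclusion_reason, "not above 60")
  expect_true(is.na(lazy_row$strategy))
  expect_true(is.na(lazy_row$slope))

  # profiles round-trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profiles2, path)
  expect_equal(read_profiles(path), profiles2)
})

test_that("pooled split uses one median across species", {
  prof_metrics <- function(id, species, slope) {
    # two exact points give slope exactly
    make_metrics(id, p_set = c(1, 0.5, 0.25), species = species,
                 pref_LLL = pmin(pmax(100 + slope * log10(c(1, 2, 4)), 0), 100),
                 experienced_odds = c(0, 1, 3))
  }
  m <- dplyr::bind_rows(
    prof_metrics("r1", "rat", -5), prof_metrics("r2", "rat", -20),
    prof_metrics("m1", "marmoset", -70), prof_metrics("m2", "marmoset", -95))
  pooled <- classify_cohort(m, protocol_rat, pool_species = TRUE)
  # pooled median is -45: both rats above, both marmosets below
  expect_equal(pooled$strategy[match(c("r1", "r2", "m1", "m2"),
                                     pooled$subject_id)],
               c("gambler", "gambler", "non_gambler", "non_gambler"))
  # the within-species split instead divides each pair
  within <- classify_cohort(m, protocol_rat)
  expect_equal(within$strategy[match(c("r1", "r2", "m1", "m2"),
                                     within$subject_id)],
               c("gambler", "non_gambler", "gambler", "non_gambler"))
})
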