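#' Assemble per-case program outcomes
#'
#' Joins the drone dispatch results onto the cohort's ground-EMS timeline.
#' The program's call-to-AED-attach time is the first AED to arrive: the
#' minimum of the drone and EMS attach times for dispatched cases, the EMS
#' attach time otherwise.
#'
#' @param cohort the included `ohca_cohort`.
#' @param dispatch a `dispatch_results` data.frame with one row per case.
#' @return data.frame of class `outcome_rows` with columns `case_id`,
#'   `ems_attach`, `uav_attach`, `dispatched`, `program_attach`,
#'   `pre_arrival` (drone strictly before EMS), `within5`, `within10`
#'   (program attach within 5/10 min of the call).
#' @export
assemble_outcomes <- function(cohort, dispatch) {
  m <- match(cohort$id, dispatch$case_id)
  if (any(is.na(m))) stop("every cohort case needs one dispatch result")
  ems <- cohort$t_aed_attach
  uav <- dispatch$uav_attach_time[m]
  disp <- dispatch$dispatched[m]
  program <- ifelse(disp, pmin(uav, ems), ems)
  out <- data.frame(case_id = cohort$id, ems_attach = ems, uav_attach = uav,
                    dispatched = disp, program_attach = program,
                    pre_arrival = disp & !is.na(uav) & uav < ems,
                    within5 = program <= 5, within10 = program <= 10)
  class(out) <- c("outcome_rows", "data.frame")
  out
}

#' Paired comparison of call-to-attach times
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences between
#' program and EMS attach times; zero differences are dropped, and an
#' all-zero difference vector returns p = 1 by convention. Exact p-values
#' are used for small untied samples, the normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y paired time vectors (minutes), equal length.
#' @return the two-sided p-value.
#' @export
paired_time_test <- function(x, y) {
  if (length(x) == 0) stop("no observations to compare")
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  exact <- length(d) < 50 && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value)
}

#' Paired comparison of success proportions
#'
#' McNemar-style test on the discordant pairs of a paired binary outcome
#' (e.g. AED attached within 5 min before vs after the drone program):
#' exact binomial when there are fewer than 25 discordant pairs, chi-square
#' with continuity correction otherwise. No discordant pairs returns p = 1.
#'
#' @param before,after logical vectors, equal length.
#' @return the two-sided p-value.
#' @export
paired_proportion_test <- function(before, after) {
  if (length(before) != length(after)) {
    stop("paired vectors must have equal length")
  }
  b <- sum(before & !after)
  c2 <- sum(!before & after)
  if (b + c2 == 0) return(1)
  if (b + c2 < 25) {
    stats::binom.test(b, b + c2, 0.5)$p.value
  } else {
    stats::mcnemar.test(matrix(c(0, b, c2, 0), 2, 2),
                        correct = TRUE)$p.value
  }
}

iqr_string <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

#' Summarize one scenario run
#'
#' Collapses per-case outcomes into the program's summary row: dispatch
#' count and rate, median (IQR) drone flight time over dispatched cases,
#' median (IQR) call-to-attach time over the whole included cohort, success
#' within 5 and 10 min, pre-arrival rate, and the paired tests against the
#' EMS-only baseline.
#'
#' @param outcomes an `outcome_rows` data.frame.
#' @param dispatch the matching `dispatch_results`.
#' @param scenario,pathway labels carried into the row.
#' @return a one-row data.frame.
#' @export
summarize_outcomes <- function(outcomes, dispatch, scenario = NA,
                               pathway = NA) {
  n <- nrow(outcomes)
  nd <- sum(outcomes$dispatched)
  ft <- dispatch$flight_time[dispatch$dispatched]
  data.frame(
    scenario = scenario, pathway = pathway, n = n,
    n_dispatched = nd, pct_dispatched = round(100 * nd / n, 1),
    flight_time = if (nd) iqr_string(ft) else NA_character_,
    call_to_attach = iqr_string(outcomes$program_attach),
    ems_call_to_attach = iqr_string(outcomes$ems_attach),
    median_call_to_attach = stats::median(outcomes$program_attach),
    n_within5 = sum(outcomes$within5),
    pct_within5 = round(100 * mean(outcomes$within5), 1),
    n_within10 = sum(outcomes$within10),
    pct_within10 = round(100 * mean(outcomes$within10), 1),
    n_pre_arrival = sum(outcomes$pre_arrival),
    pct_pre_arrival = round(100 * mean(outcomes$pre_arrival), 1),
    p_wilcoxon = paired_time_test(outcomes$program_attach,
                                  outcomes$ems_attach),
    p_mcnemar_within5 = paired_proportion_test(
      outcomes$ems_attach <= 5, outcomes$within5),
    p_mcnemar_within10 = paired_proportion_test(
      outcomes$ems_attach <= 10, outcomes$within10))
}

#' Scenario-by-pathway outcome table
#'
#' Runs the dispatch simulation for every requested scenario and pathway on
#' a fixed station set and tabulates the summary rows, mirroring the
#' program-vs-EMS comparison tables.
#'
#' @inheritParams simulate_program
#' @param models character vector of scenario models.
#' @param pathways character vector of pathways.
#' @param scenario_args named list of extra arguments passed to
#'   [scenario_config()] for every model.
#' @return data.frame with one row per scenario x pathway.
#' @export
outcome_summary_table <- function(cohort, stations, grid, weather,
                                  models = c("basic", "control_advanced",
                                             "flight_advanced",
                                             "flight_control_advanced"),
                                  pathways = c("euclidean", "topographic"),
                                  db = default_traversal_db(),
                                  scenario_args = list()) {
  rows <- list()
  for (pw in pathways) {
    for (mo in models) {
      sc <- do.call(scenario_config, c(list(model = mo), scenario_args))
      dr <- simulate_program(cohort, stations, grid, weather, sc,
                             pathway = pw, db = db)
      oc <- assemble_outcomes(cohort, dr)
      rows[[paste(pw, mo)]] <- summarize_outcomes(oc, dr, scenario = mo,
                                                  pathway = pw)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Median call-to-attach versus station count
#'
#' Re-runs the dispatch simulation for each allocation in a station-count
#' sweep and tabulates the median program call-to-attach time per scenario,
#' the curve showing how many stations a drone model needs before it beats
#' the ground EMS baseline. `k = 0` (no stations) reproduces the EMS-only
#' median.
#'
#' @inheritParams outcome_summary_table
#' @param allocations list of `allocation_result`s from [sweep_k()] (or a
#'   manually built list; an element with an empty selection encodes k = 0).
#' @param all_stations the full candidate data.frame the allocations index
#'   into.
#' @param pathway single pathway for the curve.
#' @return data.frame with columns `k`, `scenario`, `median_call_to_attach`.
#' @export
station_count_curves <- function(cohort, grid, weather, all_stations,
                                 allocations,
                                 models = c("basic", "control_advanced",
                                            "flight_advanced",
                                            "flight_control_advanced"),
                                 pathway = "topographic",
                                 db = default_traversal_db(),
                                 scenario_args = list()) {
  rows <- list()
  for (al in allocations) {
    sel <- all_stations[match(al$selected, all_stations$id), ,
                        drop = FALSE]
    for (mo in models) {
      sc <- do.call(scenario_config, c(list(model = mo), scenario_args))
      dr <- simulate_program(cohort, sel, grid, weather, sc,
                             pathway = pathway, db = db)
      oc <- assemble_outcomes(cohort, dr)
      rows[[paste(al$k, mo)]] <- data.frame(
        k = al$k, scenario = mo,
        median_call_to_attach = stats::median(oc$program_attach))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Plot station-count curves
#'
#' Line plot of median call-to-attach time against the number of operating
#' stations, one line per scenario. Requires ggplot2.
#'
#' @param curves output of [station_count_curves()].
#' @return a ggplot object.
#' @export
plot_station_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = k, y = median_call_to_attach,
                               colour = scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "operating drone stations",
                  y = "median call to AED attach (min)")
}

utils::globalVariables(c("k", "median_call_to_attach", "scenario"))
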