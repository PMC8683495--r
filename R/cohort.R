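#' Apply the cohort inclusion/exclusion cascade
#'
#' Removes records in a fixed order — age under the paediatric threshold,
#' arrest occurring in the ambulance during transport, missing AED-attach
#' time, missing arrest-recognition time — counting each record under the
#' first rule it trips, the convention in which registry exclusion cascades
#' are reported.
#'
#' @param records an `ohca_cohort` data.frame (see [generate_cohort()]).
#' @param age_threshold exclude cases with age strictly below this (years);
#'   default 8, the dose-attenuator recommendation boundary for paediatric
#'   defibrillation.
#' @return list with `included` (the retained cohort) and `report` (an
#'   `exclusion_report` with the per-rule counts).
#' @export
apply_exclusions <- function(records, age_threshold = 8) {
  n <- nrow(records)
  if (n == 0) {
    report <- exclusion_report(0L, 0L, 0L, 0L, 0L)
    return(list(included = records, report = report))
  }
  under <- records$age < age_threshold
  amb <- !under & records$in_ambulance_arrest
  attach <- !under & !amb & is.na(records$t_aed_attach)
  recog <- !under & !amb & !attach & is.na(records$t_recognition)
  keep <- !(under | amb | attach | recog)
  report <- exclusion_report(n, sum(under), sum(amb), sum(attach),
                             sum(recog))
  list(included = records[keep, , drop = FALSE], report = report)
}

#' Exclusion cascade report
#'
#' @param n_input,n_under_age,n_in_ambulance,n_missing_attach,n_missing_recognition
#'   integer counts; the included count is derived.
#' @return an `exclusion_report` list.
#' @export
exclusion_report <- function(n_input, n_under_age, n_in_ambulance,
                             n_missing_attach, n_missing_recognition) {
  excl <- n_under_age + n_in_ambulance + n_missing_attach +
    n_missing_recognition
  structure(list(n_input = as.integer(n_input),
                 n_under_age = as.integer(n_under_age),
                 n_in_ambulance = as.integer(n_in_ambulance),
                 n_missing_attach = as.integer(n_missing_attach),
                 n_missing_recognition = as.integer(n_missing_recognition),
                 n_included = as.integer(n_input - excl)),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("OHCA cohort exclusion cascade\n")
  cat(sprintf("  input records        %7d\n", x$n_input))
  cat(sprintf("  age under threshold  %7d\n", x$n_under_age))
  cat(sprintf("  arrest in ambulance  %7d\n", x$n_in_ambulance))
  cat(sprintf("  missing attach time  %7d\n", x$n_missing_attach))
  cat(sprintf("  missing recognition  %7d\n", x$n_missing_recognition))
  cat(sprintf("  included             %7d\n", x$n_included))
  invisible(x)
}

#' Read and write cohort tables and exclusion reports
#'
#' Cohorts round-trip as plain CSV with the documented column set;
#' exclusion reports as JSON.
#'
#' @param cohort an `ohca_cohort` data.frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("ohca_cohort", "data.frame")
  out
}

#' @rdname write_cohort_csv
#' @param report an `exclusion_report`.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
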