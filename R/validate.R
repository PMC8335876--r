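## Input validation shared by I/O, extraction and simulation.

#' Validate a single amplitude-frequency sweep
#'
#' A sweep is a data frame with numeric columns `freq_hz` (strictly
#' increasing, Hz) and `amp_db` (finite transmission amplitude, dB), with at
#' least 8 grid points. Optional metadata columns (`subject`, `time_h`,
#' `group`) are carried through untouched.
#'
#' @param sweep A data frame with columns `freq_hz` and `amp_db`.
#' @param min_points Minimum number of grid points required.
#' @return The sweep as a tibble, invisibly usable in pipes.
#' @export
validate_sweep <- function(sweep, min_points = 8L) {
  if (!is.data.frame(sweep)) {
    abort("`sweep` must be a data frame with columns `freq_hz` and `amp_db`.",
          class = "abcpe_error_validation")
  }
  missing_cols <- setdiff(c("freq_hz", "amp_db"), names(sweep))
  if (length(missing_cols) > 0) {
    abort(paste0("`sweep` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "abcpe_error_validation")
  }
  sweep <- as_tibble(sweep)
  if (nrow(sweep) < min_points) {
    abort(paste0("A sweep needs at least ", min_points,
                 " frequency points; got ", nrow(sweep), "."),
          class = "abcpe_error_validation")
  }
  if (anyNA(sweep$freq_hz) || any(diff(sweep$freq_hz) <= 0)) {
    abort("`freq_hz` must be strictly increasing with no missing values.",
          class = "abcpe_error_validation")
  }
  if (!all(is.finite(sweep$amp_db))) {
    abort("All `amp_db` values must be finite.",
          class = "abcpe_error_validation")
  }
  if ("time_h" %in% names(sweep) && any(sweep$time_h < 0)) {
    abort("`time_h` must be >= 0.", class = "abcpe_error_validation")
  }
  sweep
}

#' Validate a longitudinal cohort table
#'
#' A cohort is a long-format table with columns `subject`, `group`
#' (`"Exp"` or `"Con"`), `time_h`, `freq_hz`, `amp_db`: one row per subject,
#' time point and frequency. Checks that every subject has exactly one
#' baseline measurement at `time_h == 0`, that all records of a subject
#' share one frequency grid, and that every per-record sweep is valid.
#'
#' @param cohort A long-format cohort data frame.
#' @return The cohort as a tibble, sorted by subject, time and frequency.
#' @export
validate_cohort <- function(cohort) {
  required <- c("subject", "group", "time_h", "freq_hz", "amp_db")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "abcpe_error_validation")
  }
  cohort <- as_tibble(cohort) |>
    dplyr::arrange(.data$subject, .data$time_h, .data$freq_hz)

  bad_group <- setdiff(unique(cohort$group), c("Exp", "Con"))
  if (length(bad_group) > 0) {
    abort(paste0("`group` must be \"Exp\" or \"Con\"; found: ",
                 paste(bad_group, collapse = ", "), "."),
          class = "abcpe_error_validation")
  }
  if (any(cohort$time_h < 0)) {
    abort("`time_h` must be >= 0.", class = "abcpe_error_validation")
  }

  groups_per_subject <- cohort |>
    dplyr::distinct(.data$subject, .data$group) |>
    dplyr::count(.data$subject)
  if (any(groups_per_subject$n > 1)) {
    abort("Each subject must belong to exactly one group.",
          class = "abcpe_error_validation")
  }

  by_subject <- split(cohort, cohort$subject)
  for (subj in names(by_subject)) {
    sub <- by_subject[[subj]]
    times <- sort(unique(sub$time_h))
    if (!any(times == 0)) {
      abort(paste0("Subject \"", subj,
                   "\" has no baseline record at time_h == 0."),
            class = "abcpe_error_validation")
    }
    grids <- split(sub$freq_hz, sub$time_h)
    ref <- grids[[1]]
    same <- vapply(grids, function(g) {
      length(g) == length(ref) && all(g == ref)
    }, logical(1))
    if (!all(same)) {
      abort(paste0("Subject \"", subj,
                   "\" has records on different frequency grids."),
            class = "abcpe_error_validation")
    }
    validate_sweep(sub[sub$time_h == times[[1]],
                       c("freq_hz", "amp_db")])
  }
  cohort
}

#' Time-window definitions for the three study comparisons
#'
#' Windows are half-open on the left, in hours since the first measurement:
#' `full` is (0, 24], `early` is (0, 1], `acute` is (0, 6] and `chronic` is
#' (6, 24]. A record at exactly 6 h falls in the acute window. Baseline
#' records (`time_h == 0`) belong to no window: all five characteristic
#' parameters are identically zero there by construction, so including them
#' would inject degenerate zeros into both classes.
#'
#' @return A tibble with columns `window`, `t_min` (exclusive) and `t_max`
#'   (inclusive).
#' @export
#' @examples
#' phase_windows()
phase_windows <- function() {
  tibble(
    window = c("full", "early", "acute", "chronic"),
    t_min  = c(0, 0, 0, 6),
    t_max  = c(24, 1, 6, 24)
  )
}

#' Test window membership for measurement times
#'
#' @param time_h Numeric vector of measurement times in hours.
#' @param window One of `"full"`, `"early"`, `"acute"`, `"chronic"`.
#' @param windows Window definition table, by default [phase_windows()].
#' @return Logical vector: is each time inside the (t_min, t_max] interval?
#' @export
#' @examples
#' in_window(c(0, 0.5, 6, 6.5, 24), "acute")
in_window <- function(time_h, window, windows = phase_windows()) {
  row <- windows[windows$window == window, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown window \"", window, "\"."),
          class = "abcpe_error_config")
  }
  time_h > row$t_min & time_h <= row$t_max
}
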