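## Touchstone (.s2p) and cohort CSV I/O.
##
## Touchstone v1 only: an option line "# <unit> S <format> R <resistance>"
## followed by data lines with 9 numeric columns for a 2-port network
## (freq, then S11 S21 S12 S22 as value pairs, column order fixed by the
## standard). Formats RI (real/imaginary), MA (magnitude/angle) and DB
## (dB magnitude/angle) are accepted on read; DB is written.

.ts_unit_factor <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)

.parse_option_line <- function(line, path) {
  tokens <- toupper(strsplit(trimws(sub("^#", "", line)), "\\s+")[[1]])
  tokens <- tokens[tokens != ""]
  unit <- tokens[tokens %in% names(.ts_unit_factor)]
  fmt <- tokens[tokens %in% c("RI", "MA", "DB")]
  if (!"S" %in% tokens || length(fmt) != 1 || length(unit) > 1) {
    abort(paste0("Malformed Touchstone option line in ", path, ": \"",
                 line, "\"."),
          class = "abcpe_error_format")
  }
  list(unit = if (length(unit) == 1) unit else "GHZ", format = fmt)
}

#' Read an S-parameter sweep from a 2-port Touchstone file
#'
#' Parses a Touchstone v1 `.s2p` file and returns the amplitude of one
#' S-parameter (by default S21, the forward transmission coefficient) in
#' dB on a frequency grid in Hz, whatever the file's unit and numeric
#' format. RI and MA entries are converted as `20*log10(magnitude)`;
#' phase is discarded (the analysis is amplitude-only).
#'
#' @param path Path to a `.s2p` file.
#' @param port_pair Ordered integer pair `c(to, from)` selecting the
#'   S-parameter; `c(2, 1)` selects S21.
#' @param subject,time_h Optional metadata attached as columns.
#' @return A sweep tibble with columns `freq_hz` and `amp_db` (plus
#'   `subject`/`time_h` when supplied).
#' @export
read_touchstone <- function(path, port_pair = c(2L, 1L),
                            subject = NULL, time_h = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  opt_idx <- grep("^#", lines)
  if (length(opt_idx) == 0) {
    abort(paste0("No Touchstone option line (\"# ...\") found in ", path, "."),
          class = "abcpe_error_format")
  }
  opt <- .parse_option_line(lines[opt_idx[[1]]], path)
  data_lines <- lines[-opt_idx]
  fields <- strsplit(data_lines, "\\s+")
  n_fields <- lengths(fields)
  if (length(fields) == 0 || any(n_fields != 9)) {
    abort(paste0(path, " is not a 2-port Touchstone file: expected 9 ",
                 "columns per data line (freq + 4 S-parameter pairs)."),
          class = "abcpe_error_dimension")
  }
  values <- matrix(as.numeric(unlist(fields)), ncol = 9, byrow = TRUE)
  if (anyNA(values)) {
    abort(paste0("Non-numeric data entry in ", path, "."),
          class = "abcpe_error_format")
  }
  freq_hz <- values[, 1] * .ts_unit_factor[[opt$unit]]
  if (any(diff(freq_hz) <= 0)) {
    abort(paste0("Frequency column in ", path,
                 " is not strictly increasing."),
          class = "abcpe_error_validation")
  }
  ## v1 2-port column order: S11, S21, S12, S22
  slots <- list(`1,1` = 2:3, `2,1` = 4:5, `1,2` = 6:7, `2,2` = 8:9)
  key <- paste(port_pair, collapse = ",")
  if (!key %in% names(slots)) {
    abort("`port_pair` must be an ordered pair of port indices in {1, 2}.",
          class = "abcpe_error_dimension")
  }
  pair <- values[, slots[[key]], drop = FALSE]
  amp_db <- switch(opt$format,
    DB = pair[, 1],
    MA = 20 * log10(pair[, 1]),
    RI = 20 * log10(sqrt(pair[, 1]^2 + pair[, 2]^2))
  )
  out <- tibble(freq_hz = freq_hz, amp_db = amp_db)
  if (!is.null(subject)) out$subject <- subject
  if (!is.null(time_h)) out$time_h <- time_h
  validate_sweep(out, min_points = 1L)
}

#' Write a sweep to a 2-port Touchstone file
#'
#' Emits a Touchstone v1 `.s2p` file with option line `# HZ S DB R 50`.
#' The S21 slot carries `amp_db` with phase 0; the unmeasured S11, S12 and
#' S22 slots are written as a -200 dB placeholder (phase 0), documented
#' here rather than fabricated. Values are written with 15 significant
#' digits so a read-back reproduces them to well under 1e-6 dB.
#'
#' @param sweep A sweep data frame (`freq_hz`, `amp_db`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(sweep, path) {
  sweep <- validate_sweep(sweep, min_points = 1L)
  placeholder <- "-200 0"
  rows <- sprintf("%.15g %s %.15g 0 %s %s",
                  sweep$freq_hz, placeholder, sweep$amp_db,
                  placeholder, placeholder)
  writeLines(c("! 2-port S-parameter sweep (S21 amplitude only; other",
               "! parameters are -200 dB placeholders)",
               "# HZ S DB R 50", rows), path)
  invisible(path)
}

#' Read a longitudinal cohort from a long-format CSV
#'
#' Expects the header `subject,group,time_h,freq_hz,amp_db`, one row per
#' subject, time point and frequency. The table is validated: every
#' subject needs a baseline record at `time_h == 0` and a single frequency
#' grid shared across its time points.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble sorted by subject, time, frequency.
#' @export
read_cohort_csv <- function(path) {
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(),
      group = readr::col_character(),
      time_h = readr::col_double(),
      freq_hz = readr::col_double(),
      amp_db = readr::col_double()
    )
  )
  validate_cohort(cohort)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort_csv()]; the round trip is the identity on the
#' data model (subject, group, time, grid, amplitude).
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort[, c("subject", "group", "time_h",
                              "freq_hz", "amp_db")], path)
  invisible(path)
}

#' Read or write a cohort manifest (subject to group map)
#'
#' The manifest is a JSON object mapping subject identifiers to `"Exp"` or
#' `"Con"`.
#'
#' @param path Path to the JSON manifest.
#' @return `read_manifest_json`: a tibble with columns `subject`, `group`.
#' @export
read_manifest_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  manifest <- tibble(subject = names(raw),
                     group = unname(unlist(raw)))
  bad <- setdiff(unique(manifest$group), c("Exp", "Con"))
  if (length(bad) > 0) {
    abort(paste0("Manifest groups must be \"Exp\" or \"Con\"; found: ",
                 paste(bad, collapse = ", "), "."),
          class = "abcpe_error_validation")
  }
  manifest
}

#' @rdname read_manifest_json
#' @param cohort A cohort data frame (or any table with `subject`, `group`).
#' @export
write_manifest_json <- function(cohort, path) {
  map <- cohort |> dplyr::distinct(.data$subject, .data$group)
  jsonlite::write_json(as.list(setNames(map$group, map$subject)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a directory tree of Touchstone files
#'
#' Expects one subdirectory per subject, each holding one `.s2p` file per
#' time point named `t<time_h>.s2p` (e.g. `t0.s2p`, `t0.5.s2p`), plus a
#' `manifest.json` group map at the root — the layout written by
#' [write_cohort_touchstone()].
#'
#' @param dir Root directory.
#' @return A validated cohort tibble.
#' @export
read_cohort_touchstone <- function(dir) {
  manifest <- read_manifest_json(file.path(dir, "manifest.json"))
  records <- purrr::map(manifest$subject, function(subj) {
    files <- list.files(file.path(dir, subj), pattern = "\\.s2p$",
                        full.names = TRUE)
    purrr::map(files, function(f) {
      t_h <- as.numeric(sub("^t", "", sub("\\.s2p$", "", basename(f))))
      read_touchstone(f, subject = subj, time_h = t_h)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  records |>
    dplyr::left_join(manifest, by = "subject") |>
    validate_cohort()
}

#' @rdname read_cohort_touchstone
#' @param cohort A cohort data frame.
#' @export
write_cohort_touchstone <- function(cohort, dir) {
  cohort <- validate_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest_json(cohort, file.path(dir, "manifest.json"))
  cohort |>
    dplyr::group_by(.data$subject, .data$time_h) |>
    dplyr::group_walk(function(sweep, key) {
      subj_dir <- file.path(dir, key$subject)
      dir.create(subj_dir, showWarnings = FALSE)
      write_touchstone(sweep,
                       file.path(subj_dir,
                                 paste0("t", format(key$time_h), ".s2p")))
    })
  invisible(dir)
}
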