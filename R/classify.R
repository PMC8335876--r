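## Comparison definitions and Euclidean combination scoring.
##
## Three binary comparisons are studied:
##   detect_24h - experimental vs control subjects, all records in (0, 24] h
##   detect_1h  - the same contrast restricted to (0, 1] h (early detection)
##   phase      - within the experimental group, acute (0, 6] h vs chronic
##                (6, 24] h records
## The observation unit is one (subject, time point) measurement.

.comparison_ids <- c("detect_24h", "detect_1h", "phase")

#' Build labeled observations for one study comparison
#'
#' Attaches a binary class label to each extracted parameter vector
#' according to the comparison definition. For `detect_24h` and
#' `detect_1h` the positive class is the experimental group and the
#' negative class the control group, restricted to the full (0, 24] h or
#' early (0, 1] h window. For `phase` both classes come from the
#' experimental group: positives are acute-window records (0, 6] h,
#' negatives chronic-window records (6, 24] h. Baseline records never
#' appear (parameters are identically zero at t0 and are excluded
#' upstream).
#'
#' @param params Parameter table from [extract_series()] (columns
#'   `subject`, `group`, `time_h` and the five parameters).
#' @param comparison One of `"detect_24h"`, `"detect_1h"`, `"phase"`.
#' @param windows Window definitions, by default [phase_windows()].
#' @return The filtered parameter tibble with a `label` factor column
#'   (levels `"positive"`, `"negative"`) and a `comparison` column.
#' @export
build_observations <- function(params, comparison = .comparison_ids,
                               windows = phase_windows()) {
  comparison <- match.arg(comparison)
  required <- c("subject", "group", "time_h", abcpe_parameters())
  missing_cols <- setdiff(required, names(params))
  if (length(missing_cols) > 0) {
    abort(paste0("Parameter table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "abcpe_error_validation")
  }
  params <- as_tibble(params)
  obs <- switch(comparison,
    detect_24h = params |>
      dplyr::filter(in_window(.data$time_h, "full", windows)) |>
      dplyr::mutate(label = ifelse(.data$group == "Exp",
                                   "positive", "negative")),
    detect_1h = params |>
      dplyr::filter(in_window(.data$time_h, "early", windows)) |>
      dplyr::mutate(label = ifelse(.data$group == "Exp",
                                   "positive", "negative")),
    phase = params |>
      dplyr::filter(.data$group == "Exp") |>
      dplyr::filter(in_window(.data$time_h, "full", windows)) |>
      dplyr::mutate(label = ifelse(in_window(.data$time_h, "acute", windows),
                                   "positive", "negative"))
  )
  obs$label <- factor(obs$label, levels = c("positive", "negative"))
  obs$comparison <- comparison
  counts <- table(obs$label)
  if (any(counts == 0)) {
    abort(paste0("Comparison \"", comparison, "\" has an empty class (",
                 paste(names(counts)[counts == 0], collapse = ", "),
                 "); check groups and time windows."),
          class = "abcpe_error_config")
  }
  dplyr::arrange(obs, .data$subject, .data$time_h)
}

#' Score observations on a combination of characteristic parameters
#'
#' For a combination of two or more parameters, each parameter is first
#' mapped to \[-1, 1\] by dividing by its pooled maximum absolute value
#' over *all* observations (both classes together, so that a single
#' threshold acts on one common scale), and the score is the Euclidean
#' norm of the mapped values. A single-parameter combination is scored on
#' the raw, unmapped parameter value. If a parameter is identically zero
#' across all observations its pooled maximum is zero; it then contributes
#' zero to every score and a warning is issued.
#'
#' @param observations Labeled observations from [build_observations()].
#' @param combination Character vector, a non-empty subset of
#'   `abcpe_parameters()`.
#' @return The observations tibble with a `score` column added; the
#'   combination and the pooled norms are attached as attributes
#'   `"combination"` and `"norms"`.
#' @export
map_and_score <- function(observations, combination) {
  combination <- as.character(combination)
  bad <- setdiff(combination, abcpe_parameters())
  if (length(combination) == 0 || length(bad) > 0 ||
      anyDuplicated(combination)) {
    abort("`combination` must be a non-empty, duplicate-free subset of abcpe_parameters().",
          class = "abcpe_error_config")
  }
  obs <- as_tibble(observations)
  if (nrow(obs) == 0) {
    abort("No observations to score.", class = "abcpe_error_config")
  }
  if (length(combination) == 1) {
    obs$score <- obs[[combination]]
    norms <- setNames(NA_real_, combination)
  } else {
    values <- as.matrix(obs[, combination, drop = FALSE])
    norms <- apply(abs(values), 2, max)
    zero <- norms == 0
    if (any(zero)) {
      warn(paste0("Pooled max|.| is zero for: ",
                  paste(combination[zero], collapse = ", "),
                  "; these parameters contribute 0 to every score."))
    }
    scale <- ifelse(zero, 1, norms) # zero-variance column maps to all zeros
    mapped <- sweep(values, 2, scale, "/")
    obs$score <- sqrt(rowSums(mapped^2))
  }
  attr(obs, "combination") <- combination
  attr(obs, "norms") <- norms
  obs
}

#' All non-empty combinations of the five characteristic parameters
#'
#' Enumerates the 31 non-empty subsets of `abcpe_parameters()` in table
#' order: the 5 singles, 10 doubles, 10 triples, 5 quadruples and the one
#' quintuple, each subset in canonical parameter order.
#'
#' @return A named list of 31 character vectors; names collapse the
#'   members with `"+"` (e.g. `"gamma+delta+rho"`).
#' @export
#' @examples
#' length(param_combinations())
param_combinations <- function() {
  pars <- abcpe_parameters()
  combos <- unlist(
    lapply(seq_along(pars),
           function(k) combn(pars, k, simplify = FALSE)),
    recursive = FALSE
  )
  setNames(combos, vapply(combos, paste, "", collapse = "+"))
}

#' Evaluate every parameter combination for one comparison
#'
#' Runs [map_and_score()] and [roc_analysis()] for each of the 31
#' non-empty parameter subsets and tabulates the results the way the
#' combination tables are usually laid out: grouped by combination size,
#' with the AUC at full precision and rounded to two significant digits,
#' and the sensitivity/specificity at the Youden operating point.
#'
#' @param params Parameter table from [extract_series()], or labeled
#'   observations from [build_observations()] (then `comparison` must
#'   match).
#' @param comparison One of `"detect_24h"`, `"detect_1h"`, `"phase"`.
#' @param windows Window definitions, by default [phase_windows()].
#' @return A 31-row tibble: `combination`, `size`, `auc` (max-oriented),
#'   `auc_2sig`, `auc_raw` (increasing orientation, useful for null
#'   calibration where a max-oriented area is biased above 0.5),
#'   `sensitivity`, `specificity`, `threshold`, `orientation`, sorted by
#'   size then canonical order.
#' @export
evaluate_all_combinations <- function(params,
                                      comparison = .comparison_ids,
                                      windows = phase_windows()) {
  comparison <- match.arg(comparison)
  obs <- if ("label" %in% names(params)) {
    if (!all(params$comparison == comparison)) {
      abort("`params` already carries labels for a different comparison.",
            class = "abcpe_error_config")
    }
    as_tibble(params)
  } else {
    build_observations(params, comparison, windows)
  }
  combos <- param_combinations()
  purrr::imap(combos, function(combo, name) {
    scored <- map_and_score(obs, combo)
    roc <- roc_analysis(scored$score, scored$label)
    tibble(
      combination = name,
      size = length(combo),
      auc = roc$auc,
      auc_2sig = signif(roc$auc, 2),
      auc_raw = roc$auc_raw,
      sensitivity = roc$optimal$sensitivity,
      specificity = roc$optimal$specificity,
      threshold = roc$optimal$threshold,
      orientation = roc$orientation
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$size)
}
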