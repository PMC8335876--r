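## A small parameter table covering both groups and all windows, built
## directly (no sweeps needed at this layer).
make_params <- function(n_exp = 3, n_con = 2,
                        times = setdiff(seq(0, 24, by = 0.5), 0),
                        effect = 1) {
  subjects <- c(sprintf("E%d", seq_len(n_exp)), sprintf("C%d", seq_len(n_con)))
  groups <- rep(c("Exp", "Con"), c(n_exp, n_con))
  tidyr::expand_grid(idx = seq_along(subjects), time_h = times) |>
    dplyr::mutate(
      subject = subjects[idx], group = groups[idx],
      drift = ifelse(group == "Exp", effect * time_h / 24, 0),
      alpha = -0.05 * drift + rnorm(dplyr::n(), 0, 0.005),
      beta = 0.01 * drift + rnorm(dplyr::n(), 0, 0.004),
      gamma = 0.2 * drift + rnorm(dplyr::n(), 0, 0.01),
      delta = -0.1 * drift + rnorm(dplyr::n(), 0, 0.005),
      rho = -0.12 * drift + rnorm(dplyr::n(), 0, 0.005)
    ) |>
    dplyr::select(subject, group, time_h, alpha, beta, gamma, delta, rho)
}

test_that("observation counts follow the cohort design for each comparison", {
  set.seed(61)
  params <- make_params(n_exp = 10, n_con = 4)
  obs24 <- build_observations(params, "detect_24h")
  expect_equal(sum(obs24$label == "positive"), 10 * 48)
  expect_equal(sum(obs24$label == "negative"), 4 * 48)

  ## 30-min sampling leaves two rounds of data within the first hour
  obs1 <- build_observations(params, "detect_1h")
  expect_equal(sum(obs1$label == "positive"), 10 * 2)
  expect_equal(sum(obs1$label == "negative"), 4 * 2)
  expect_setequal(unique(obs1$time_h), c(0.5, 1))

  phase <- build_observations(params, "phase")
  expect_true(all(phase$group == "Exp"))
  expect_equal(sum(phase$label == "positive"), 10 * 12)  # (0, 6] h
  expect_equal(sum(phase$label == "negative"), 10 * 36)  # (6, 24] h
  expect_equal(unique(phase$label[phase$time_h == 6]), factor("positive",
               levels = c("positive", "negative")))
})

test_that("an empty class after windowing is a configuration error", {
  set.seed(62)
  con_only <- make_params(n_exp = 1, n_con = 2) |>
    dplyr::filter(group == "Con")
  expect_error(build_observations(con_only, "phase"),
               class = "abcpe_error_config")
  expect_error(build_observations(con_only, "detect_24h"),
               class = "abcpe_error_config")
})

test_that("Euclidean scores follow the hand-evaluated mapping", {
  obs <- tibble::tibble(
    subject = c("a", "b", "c"), group = c("Exp", "Exp", "Con"),
    time_h = 1:3,
    alpha = c(0.5, 1.0, -1.0), beta = c(-0.3, 0.6, 0.1),
    gamma = 0, delta = 0, rho = 0,
    label = factor(c("positive", "positive", "negative"),
                   levels = c("positive", "negative")))
  scored <- map_and_score(obs, c("alpha", "beta"))
  ## pooled max|alpha| = 1.0, pooled max|beta| = 0.6
  expect_equal(attr(scored, "norms"), c(alpha = 1.0, beta = 0.6))
  expect_equal(scored$score[1], sqrt(0.25 + 0.25), tolerance = 1e-12)
  expect_equal(scored$score[2], sqrt(2), tolerance = 1e-12) # both at max
  mapped <- cbind(obs$alpha / 1.0, obs$beta / 0.6)
  expect_true(all(abs(mapped) <= 1))
  expect_true(all(scored$score >= 0 & scored$score <= sqrt(2) + 1e-12))
})

test_that("an all-zero parameter vector scores 0 for any multi-combination", {
  obs <- tibble::tibble(alpha = c(0, 0.4), beta = c(0, -0.2),
                        gamma = c(0, 0.1), delta = c(0, 0.3),
                        rho = c(0, 0.2),
                        label = factor(c("negative", "positive"),
                                       levels = c("positive", "negative")))
  for (combo in list(c("alpha", "beta"), c("gamma", "delta", "rho"),
                     abcpe_parameters())) {
    expect_equal(map_and_score(obs, combo)$score[1], 0)
  }
})

test_that("single-parameter combinations are scored on the raw value", {
  set.seed(63)
  obs <- make_params(n_exp = 2, n_con = 1) |>
    (\(p) build_observations(p, "detect_24h"))()
  scored <- map_and_score(obs, "gamma")
  expect_equal(scored$score, obs$gamma)
})

test_that("a zero pooled maximum contributes zero with a warning", {
  obs <- tibble::tibble(alpha = c(0.2, -0.4), beta = c(0, 0),
                        label = factor(c("positive", "negative"),
                                       levels = c("positive", "negative")),
                        gamma = 0, delta = 0, rho = 0)
  expect_warning(scored <- map_and_score(obs, c("alpha", "beta")), "beta")
  expect_equal(scored$score, abs(obs$alpha / 0.4))
})

test_that("invalid combinations are rejected", {
  obs <- tibble::tibble(alpha = 1, label = factor("positive",
                        levels = c("positive", "negative")))
  expect_error(map_and_score(obs, character()), class = "abcpe_error_config")
  expect_error(map_and_score(obs, c("alpha", "alpha")),
               class = "abcpe_error_config")
  expect_error(map_and_score(obs, "sigma"), class = "abcpe_error_config")
})

test_that("the combination lattice has 31 subsets split 5/10/10/5/1", {
  combos <- param_combinations()
  expect_length(combos, 31)
  sizes <- table(lengths(combos))
  expect_equal(unname(c(sizes)), c(5, 10, 10, 5, 1))
  expect_true("gamma+delta+rho" %in% names(combos))
  expect_false(anyDuplicated(names(combos)) > 0)
})

test_that("evaluate_all_combinations tabulates all 31 subsets", {
  set.seed(64)
  params <- make_params()
  tbl <- evaluate_all_combinations(params, "detect_24h")
  expect_equal(nrow(tbl), 31)
  expect_equal(unname(c(table(tbl$size))), c(5, 10, 10, 5, 1))
  expect_true(all(tbl$auc >= 0.5 & tbl$auc <= 1))
  expect_true(all(tbl$sensitivity >= 0 & tbl$sensitivity <= 1))
  expect_true(all(tbl$specificity >= 0 & tbl$specificity <= 1))
  expect_equal(tbl$auc_2sig, signif(tbl$auc, 2))
})

test_that("identical classes yield chance-level AUC for every combination", {
  set.seed(65)
  base <- make_params(n_exp = 1, n_con = 1, effect = 0)
  ## mirror the Exp subject's rows into the Con subject: identical multisets
  exp_rows <- base[base$group == "Exp", ]
  con_rows <- dplyr::mutate(exp_rows, subject = "C1", group = "Con")
  params <- dplyr::bind_rows(exp_rows, con_rows)
  tbl <- evaluate_all_combinations(params, "detect_24h")
  expect_true(all(abs(tbl$auc - 0.5) < 1e-12))
})

test_that("mapped magnitudes can only grow when an observation is removed", {
  set.seed(66)
  obs <- make_params(n_exp = 2, n_con = 2) |>
    (\(p) build_observations(p, "detect_24h"))()
  scored_full <- map_and_score(obs, c("gamma", "delta"))
  norms_full <- attr(scored_full, "norms")
  drop_one <- obs[-which.max(abs(obs$gamma)), ]
  norms_drop <- attr(map_and_score(drop_one, c("gamma", "delta")), "norms")
  expect_true(all(norms_drop <= norms_full + 1e-15))
})
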