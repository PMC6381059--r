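# small synthetic record sets built in code
fake_records <- function(task, srt, type, levels = NULL) {
  n <- length(srt)
  out <- tibble::tibble(
    trial_id = seq_len(n), task = rep_len(task, n),
    stimulus_side = "right", srt = srt,
    direction = ifelse(type == "correct_anti", "left", "right"),
    saccade_type = rep_len(type, n)
  )
  if (!is.null(levels)) {
    for (nm in names(levels)) out[[nm]] <- levels[[nm]]
  }
  out
}

test_that("summary statistics match direct computation", {
  r <- fake_records("pro", c(100, 150, 200, 250), "regular_pro")
  s <- summarize_behavior(r)
  expect_equal(s$count, 4L)
  expect_equal(s$percent, 100)
  expect_equal(s$median_srt, 175)
  expect_equal(s$mean_srt, 175)
  expect_equal(s$sd_srt, sd(c(100, 150, 200, 250)))
  # single record: median = mean = value, sd = 0
  s1 <- summarize_behavior(fake_records("pro", 190, "regular_pro"))
  expect_equal(s1$median_srt, 190)
  expect_equal(s1$mean_srt, 190)
  expect_equal(s1$sd_srt, 0)
  # percents use per-task denominators
  r2 <- dplyr::bind_rows(
    fake_records("pro", rep(190, 3), "regular_pro"),
    fake_records("pro", 120, "express_pro"),
    fake_records("anti", rep(250, 2), "correct_anti")
  )
  s2 <- summarize_behavior(r2)
  expect_equal(s2$percent[s2$saccade_type == "regular_pro"], 75)
  expect_equal(s2$percent[s2$saccade_type == "express_pro"], 25)
  expect_equal(s2$percent[s2$saccade_type == "correct_anti"], 100)
})

test_that("sample skewness agrees with a brute-force third moment", {
  set.seed(5)
  x <- rexp(200) * 30 + 150
  n <- length(x)
  g1 <- (sum((x - mean(x))^3) / n) / ((sum((x - mean(x))^2) / n))^1.5
  adj <- g1 * sqrt(n * (n - 1)) / (n - 2)
  expect_equal(sample_skewness(x), adj, tolerance = 1e-12)
  expect_true(is.na(sample_skewness(c(1, 2))))
  expect_true(is.na(sample_skewness(rep(3, 10))))
})

test_that("histograms conserve counts and respect the express window", {
  set.seed(8)
  srt <- sample(90:450, 300, replace = TRUE)
  r <- fake_records("pro", srt, ifelse(srt <= 138, "express_pro",
                                       "regular_pro"))
  h <- srt_histogram(r)
  expect_equal(sum(h$count), 300L)
  agg <- tapply(h$count, h$saccade_type, sum)
  expect_equal(unname(agg["express_pro"]), sum(srt <= 138))
  # cumulative curves are non-decreasing and end at the type percentages
  for (tp in unique(h$saccade_type)) {
    cp <- h$cum_pct[h$saccade_type == tp]
    expect_true(all(diff(cp) >= 0))
    expect_equal(max(cp), 100 * sum(r$saccade_type == tp) / 300)
  }
  # an all-express set puts mass only in bins covering 90-138 ms
  re <- fake_records("pro", sample(90:138, 50, replace = TRUE), "express_pro")
  he <- srt_histogram(re)
  expect_true(all(he$bin_start[he$count > 0] >= 90))
  expect_true(all(he$bin_start[he$count > 0] <= 138))
  expect_error(srt_histogram(r, bin_ms = 0))
})

test_that("median shift equals a brute-force subgroup computation", {
  set.seed(13)
  lv <- sample(c("small", "medium", "large"), 30, replace = TRUE)
  srt <- round(rnorm(30, 200, 30)) + 40 * (lv == "large")
  r <- fake_records("pro", srt, "regular_pro",
                    levels = list(onset_delay_level = lv))
  ms <- median_shift(r, "onset_delay", "regular_pro")
  expect_equal(ms$median_shift,
               median(srt[lv == "large"]) - median(srt[lv == "small"]))
  # a level subgroup that never occurs is an error
  r0 <- fake_records("pro", rep(c(180, 200), 15), "regular_pro",
                     levels = list(onset_delay_level = rep("medium", 30)))
  expect_error(median_shift(r0, "onset_delay", "regular_pro"),
               "empty level subgroup")
  r1 <- fake_records("pro", rep(200, 30), "regular_pro",
                     levels = list(onset_delay_level = lv))
  expect_equal(median_shift(r1, "onset_delay", "regular_pro")$median_shift, 0)
  expect_error(median_shift(r, "not_an_attribute"))
})

test_that("cohens_d is the shift over the behaviour spread", {
  expect_equal(cohens_d(37, 22.45), 1.65, tolerance = 0.005)
  expect_equal(cohens_d(0, 10), 0)
  expect_lt(cohens_d(-12, 10), 0)
  expect_error(cohens_d(10, 0))
})

test_that("kruskal_wallis matches an independent rank-based computation", {
  brute_h <- function(groups) {
    x <- unlist(groups)
    n <- length(x)
    rk <- rank(x)
    h <- 12 / (n * (n + 1)) *
      sum(vapply(split(rk, rep(seq_along(groups), lengths(groups))),
                 function(r) length(r) * (mean(r) - (n + 1) / 2)^2,
                 numeric(1)))
    # tie correction
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  expect_equal(kruskal_wallis(list(1:3, 4:6, 7:9))$H,
               brute_h(list(1:3, 4:6, 7:9)), tolerance = 1e-8)
  set.seed(21)
  for (i in 1:50) {
    g <- lapply(1:3, function(j) sample(50:80, sample(4:12, 1),
                                        replace = TRUE))
    expect_equal(kruskal_wallis(g)$H, brute_h(g), tolerance = 1e-8)
  }
  # rank-based: invariant under monotone transforms
  g <- list(c(1, 5, 9), c(2, 3, 11), c(4, 8, 10))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, exp))$H,
               tolerance = 1e-10)
  # identical groups: H = 0
  expect_equal(kruskal_wallis(list(1:5, 1:5, 1:5))$H, 0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 5)))$H, 0)
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 5)))$p, 1)
})

test_that("selection chi-square equals the direct goodness-of-fit formula", {
  lv <- c(rep("small", 100), rep("medium", 100), rep("large", 400))
  r <- fake_records("pro", rep(120, 600), "express_pro",
                    levels = list(vp_max_level = lv))
  cs <- selection_chi_square(r, "vp_max", "express_pro")
  expect_equal(cs$chi2, 300) # (100-200)^2/200 * 2 + (400-200)^2/200
  expect_equal(cs$p, pchisq(300, 2, lower.tail = FALSE))
  # uniform thirds: chi2 = 0, p = 1
  r0 <- fake_records("pro", rep(120, 300), "express_pro",
                     levels = list(vp_max_level = rep(c("small", "medium",
                                                        "large"), 100)))
  cs0 <- selection_chi_square(r0, "vp_max", "express_pro")
  expect_equal(cs0$chi2, 0)
  expect_equal(cs0$p, 1)
})

test_that("the difference curve accumulates correct minus error percent", {
  r <- dplyr::bind_rows(
    fake_records("anti", c(100, 110, 150), "express_error"),
    fake_records("anti", c(250, 260, 300, 380), "correct_anti"),
    fake_records("anti", c(180, 210, 220), "regular_error")
  )
  curve <- anti_difference_curve(r)
  expect_equal(curve$time[1], 0)
  expect_equal(nrow(curve), 100)
  expect_equal(curve$diff[1], 0)
  # final value equals overall %correct - %error
  expect_equal(curve$diff[nrow(curve)], 100 * (4 - 6) / 10)
  # early errors drag the curve below zero in the express window
  expect_lt(curve$diff[curve$time == 114], 0)
  expect_error(anti_difference_curve(fake_records("pro", 200, "regular_pro")))
})

test_that("override time follows the minimum-then-rise rule", {
  # hand-traced toy curve: global minimum at the first -6, first rise of at
  # least 1 occurs at the -5.5 -> -4.2 transition
  toy <- tibble::tibble(time = seq(0, 36, by = 6),
                        diff = c(0, -5, -6, -6, -5.5, -4.2, -3.0))
  expect_equal(voluntary_override_time(toy), 30)
  # monotone recovery: the first jump >= 1 after the minimum wins
  toy2 <- tibble::tibble(time = seq(0, 30, by = 6),
                         diff = c(0, -4, -3.8, -2.5, -1, 0.5))
  expect_equal(voluntary_override_time(toy2), 18)
  # a curve that never recovers has no override time
  toy3 <- tibble::tibble(time = seq(0, 18, by = 6),
                         diff = c(0, -2, -2.5, -2.4))
  expect_true(is.na(voluntary_override_time(toy3)))
})

test_that("early-late ratio counts regular errors in closed windows", {
  r <- fake_records("anti", c(rep(150, 30), rep(230, 10)), "regular_error")
  expect_equal(early_late_ratio(r), 3)
  # window edges are inclusive
  r2 <- fake_records("anti", c(140, 199, 200, 259), "regular_error")
  expect_equal(early_late_ratio(r2), 1)
  r3 <- fake_records("anti", rep(150, 5), "regular_error")
  expect_true(is.na(early_late_ratio(r3))) # empty late window
})
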