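# exclusions, transforms, ANOVA (vs two independent oracles), effect
# sizes and simple effects

make_records <- function(rates, n_trials = 100) {
  do.call(rbind, lapply(seq_along(rates), function(i) {
    bad <- round(rates[i] * n_trials)
    data.frame(participant = sprintf("P%02d", i),
               enhancement = "absent", illumination = "ambient",
               viewing = "monoscopic", quadrant = "TL",
               response = c(rep("TR", bad), rep("TL", n_trials - bad)),
               correct = c(rep(FALSE, bad), rep(TRUE, n_trials - bad)),
               rt_ms = 1000)
  }))
}

test_that("participant exclusion implements the mean + 4 SD rule", {
  equal <- make_records(rep(0.05, 10))
  expect_identical(exclude_participants(equal)$removed, character(0))
  rates <- c(rep(0.03, 29), 0.60)
  ex <- exclude_participants(make_records(rates))
  # direct computation: 0.60 > mean + 4 SD of the 30 rates
  expect_gt(0.60, mean(rates) + 4 * sd(rates))
  expect_identical(ex$removed, "P30")
  expect_identical(length(unique(ex$records$participant)), 29L)
  expect_error(exclude_participants(make_records(c(0.1, 0.1))), "at least 3")
  expect_error(exclude_participants(make_records(numeric(0))), "no trial")
})

test_that("trial filtering logs exact percentages", {
  rec <- make_records(rep(0, 4))
  fl <- filter_trials(rec)
  expect_identical(nrow(fl$records), nrow(rec))
  expect_equal(fl$log$pct_no_response, 0)
  expect_equal(fl$log$pct_incorrect, 0)
  rec$response[1] <- "none"; rec$correct[1] <- FALSE
  rec$response[2:4] <- "BR"; rec$correct[2:4] <- FALSE
  fl <- filter_trials(rec)
  expect_equal(fl$log$pct_no_response, 100 * 1 / 400)
  expect_equal(fl$log$pct_incorrect, 100 * 3 / 400)
  expect_identical(nrow(fl$records), 396L)
})

test_that("reciprocal transform, screen and collapse behave", {
  rec <- simulate_experiment(null_observer_model(trial_sd = 0), 4,
                             master_seed = 1)
  rec <- filter_trials(rec)$records
  cl <- reciprocal_transform_and_screen(rec)
  expect_s3_class(cl, "camo_clean")
  expect_identical(nrow(cl$cells), 4L * 8L)
  # reciprocal arithmetic on known values: 500 ms -> 2 /s, 2000 -> 0.5 /s
  known <- rec[rec$participant %in% c("P01", "P02"), ]
  known$rt_ms <- ifelse(known$enhancement == "present", 500, 2000)
  clk <- reciprocal_transform_and_screen(known)
  expect_equal(unique(clk$cells$mean_recip[clk$cells$enhancement ==
                                             "present"]), 2)
  expect_equal(unique(clk$cells$mean_recip[clk$cells$enhancement ==
                                             "absent"]), 0.5)
  # identical RTs: no outliers, all cell means equal
  same <- rec; same$rt_ms <- 1234
  cls <- reciprocal_transform_and_screen(same)
  expect_identical(cls$log$n_outliers_removed, 0L)
  expect_equal(unique(cls$cells$mean_recip), 1 / 1.234)
  expect_error(reciprocal_transform_and_screen(transform(rec, rt_ms = 0)),
               "positive")
})

test_that("null data give zero effect SS and F", {
  Y <- matrix(rep(rnorm(5), 8), nrow = 5)  # all 8 cells equal per subject
  tab <- rm_anova_2x2x2(Y)
  expect_true(all(tab$SS < 1e-20))
  expect_true(all(tab$F == 0))
})

test_that("ANOVA matches the explicit contrast-coding oracle", {
  set.seed(12)
  for (n in c(3, 5, 10)) {
    Y <- matrix(rnorm(n * 8, 2, 0.5), n, 8)
    tab <- rm_anova_2x2x2(Y)
    oracle <- anova_contrast_oracle(Y)
    expect_equal(tab$SS, oracle$SS, tolerance = 1e-10)
    expect_equal(tab$SS_error, oracle$SS_error, tolerance = 1e-10)
    # decomposition closes: all components add to the total corrected SS
    expect_equal(sum(tab$SS) + sum(tab$SS_error) +
                   attr(tab, "ss_subjects"),
                 sum((Y - mean(Y))^2), tolerance = 1e-10)
    expect_true(all(tab$df_error == n - 1))
  }
})

test_that("ANOVA F and p match stats::aov with an Error term", {
  set.seed(21)
  n <- 8
  Y <- matrix(rnorm(n * 8, 1, 0.3), n, 8)
  tab <- rm_anova_2x2x2(Y)
  # expand.grid varies subj fastest, then A, B, C: exactly the layout of
  # as.vector(Y) with columns in expand.grid(A, B, C) order
  d <- expand.grid(subj = factor(1:n), A = factor(1:2), B = factor(1:2),
                   C = factor(1:2))
  d$y <- as.vector(Y)
  fit <- summary(stats::aov(y ~ A * B * C + Error(subj / (A * B * C)),
                            data = d))
  fs <- unlist(lapply(fit[-1], function(s) s[[1]]["F value"][[1]][1]))
  expect_equal(tab$F, unname(fs), tolerance = 1e-8)
})

test_that("generalized eta squared follows the stated formula", {
  tab <- data.frame(SS = 1, SS_error = 1)
  attr(tab, "ss_subjects") <- 1
  expect_equal(generalized_eta_squared(tab), 1 / 3)
  tab0 <- data.frame(SS = 0, SS_error = 1)
  attr(tab0, "ss_subjects") <- 1
  expect_equal(generalized_eta_squared(tab0), 0)
  # property: within [0, 1] on random data
  set.seed(5)
  for (k in 1:5) {
    t2 <- rm_anova_2x2x2(matrix(rnorm(48), 6, 8))
    expect_true(all(t2$ges >= 0 & t2$ges <= 1))
    expect_lte(sum(t2$SS), sum((attr(t2, "ss_total"))))
  }
})

test_that("simple effects match the paired-t oracle", {
  rec <- simulate_experiment(observer_model(), 5, master_seed = 3)
  cl <- reciprocal_transform_and_screen(filter_trials(rec)$records)
  se <- simple_effects(cl)
  expect_identical(nrow(se), 4L)
  # oracle for the first contrast via stats::t.test on condition means
  cells <- cl$cells
  mono <- cells[cells$viewing == "monoscopic", ]
  agg <- aggregate(mean_recip ~ participant + enhancement, mono, mean)
  x <- agg$mean_recip[agg$enhancement == "present"]
  y <- agg$mean_recip[agg$enhancement == "absent"]
  tt <- stats::t.test(x, y, paired = TRUE)
  expect_equal(se$t[1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(se$p[1], tt$p.value, tolerance = 1e-10)
  expect_equal(se$d_z[1], mean(x - y) / sd(x - y), tolerance = 1e-10)
  expect_identical(se$df[1], 4L)
  # t sign is consistent with the transformed-scale difference
  expect_equal(sign(se$t), sign(se$mean_diff_recip))
})

test_that("degenerate simple effects warn or return zero", {
  cells <- expand.grid(participant = sprintf("P%d", 1:4),
                       enhancement = c("absent", "present"),
                       illumination = c("ambient", "directional"),
                       viewing = c("monoscopic", "stereoscopic"),
                       stringsAsFactors = FALSE)
  cells$mean_recip <- 0.5
  cells$mean_rt_ms <- 2000
  expect_warning(se <- simple_effects(cells), "zero variance")
  expect_equal(se$t[1], 0)
  expect_equal(se$d_z[1], 0)
})

test_that("the full pipeline runs and reports coherently", {
  rec <- simulate_experiment(observer_model(), 12, master_seed = 9)
  res <- analyze_trials(rec)
  expect_s3_class(res$anova, "camo_anova")
  expect_identical(nrow(res$anova), 7L)
  expect_output(print(res), "repeated-measures ANOVA")
  f <- withr::local_tempfile(fileext = ".json")
  write_results_json(res, f)
  expect_true(jsonlite::validate(readLines(f)))
})
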