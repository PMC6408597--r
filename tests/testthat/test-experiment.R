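# design enumeration and the synthetic observer

test_that("a session is a balanced 320-trial factorial", {
  s <- enumerate_session(1)
  expect_identical(nrow(s), 320L)
  cells <- table(s$enhancement, s$illumination, s$viewing)
  expect_true(all(cells == 40))
  # each (texture, quadrant) pair appears once per condition cell
  full <- table(s$enhancement, s$illumination, s$viewing, s$quadrant,
                s$texture_id)
  expect_true(all(full == 1))
})

test_that("different seeds shuffle the same multiset of specs", {
  a <- enumerate_session(1)
  b <- enumerate_session(2)
  cols <- c("enhancement", "illumination", "viewing", "quadrant",
            "texture_id")
  key <- function(d) sort(do.call(paste, d[cols]))
  expect_identical(key(a), key(b))
  expect_false(identical(do.call(paste, a[cols]), do.call(paste, b[cols])))
  expect_identical(a, enumerate_session(1))
})

test_that("noise-free observer reproduces baseline + deltas exactly", {
  m <- observer_model(subject_sd = 0, trial_sd = 0, error_rate = 0,
                      lapse_rate = 0)
  s <- enumerate_session(3)
  rec <- simulate_participant(s, m, participant_seed = 1)
  expect_true(all(rec$correct))
  mono_enh <- s$viewing == "monoscopic" & s$enhancement == "present" &
    s$illumination == "directional"
  ref <- s$viewing == "stereoscopic" & s$enhancement == "absent" &
    s$illumination == "directional"
  expect_equal(unique(rec$rt_ms[ref]), m$baseline_rt)
  expect_equal(unique(rec$rt_ms[mono_enh]),
               m$baseline_rt + m$deltas$enh_mono + m$deltas$mono_base)
})

test_that("degenerate error and lapse rates behave", {
  s <- enumerate_session(4)
  all_wrong <- simulate_participant(s, observer_model(error_rate = 0.999999,
                                                      lapse_rate = 0), 2)
  expect_true(all(!all_wrong$correct))
  expect_true(all(all_wrong$response != s$quadrant))
  lapsed <- simulate_participant(s, observer_model(lapse_rate = 0.999999), 3)
  expect_true(all(lapsed$response == "none"))
  expect_true(all(is.na(lapsed$rt_ms)))
})

test_that("records are internally consistent and deterministic", {
  s <- enumerate_session(5)
  rec <- simulate_participant(s, observer_model(), 7)
  expect_identical(rec, simulate_participant(s, observer_model(), 7))
  none <- rec$response == "none"
  expect_identical(is.na(rec$rt_ms), none)
  expect_identical(rec$correct, rec$response == rec$quadrant & !none)
})

test_that("simulated cell means recover the configured monoscopic cost", {
  m <- observer_model()
  rec <- simulate_experiment(m, 29, master_seed = 11)
  mono <- rec$viewing == "monoscopic" & !is.na(rec$rt_ms)
  per <- tapply(rec$rt_ms[mono], list(rec$participant[mono],
                                      rec$enhancement[mono]), mean)
  diffs <- per[, "present"] - per[, "absent"]
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - m$deltas$enh_mono), 2 * se + 30)
})

test_that("quadrant classification matches brute force, ties go top-left", {
  b <- c(40, 30)
  expect_identical(quadrant_of(c(5, 5), b), "TR")
  expect_identical(quadrant_of(c(-5, -5), b), "BL")
  expect_identical(quadrant_of(c(0, 0), b), "TL")
  set.seed(6)
  for (k in 1:50) {
    p <- c(runif(1, -20, 20), runif(1, -15, 15))
    want <- if (p[2] >= 0) (if (p[1] <= 0) "TL" else "TR") else
      (if (p[1] <= 0) "BL" else "BR")
    expect_identical(quadrant_of(p, b), want)
  }
  expect_error(quadrant_of(c(100, 0), b))
})

test_that("trial CSV round trip and column mapping work", {
  f <- withr::local_tempfile(fileext = ".csv")
  rec <- simulate_participant(enumerate_session(6), observer_model(), 1)
  write_trials_csv(rec, f)
  back <- read_trials_csv(f)
  expect_equal(back$rt_ms, rec$rt_ms)
  expect_identical(back$correct, rec$correct)
  # foreign dialect via mapping
  alien <- rec
  names(alien)[names(alien) == "rt_ms"] <- "RT"
  names(alien)[names(alien) == "participant"] <- "subj"
  alien$correct <- NULL
  write.csv(alien, f, row.names = FALSE)
  back2 <- read_trials_csv(f, mapping = c(participant = "subj",
                                          rt_ms = "RT"))
  expect_identical(back2$correct, rec$correct)
  expect_error(read_trials_csv(f, mapping = c(rt_ms = "nope")), "nope")
})

test_that("build_trial_scene assembles a coherent reduced-scale trial", {
  spec <- enumerate_session(8)[1, ]
  tr <- build_trial_scene(spec, n_leaves = 60,
                          params = scene_params(bounds = c(16, 12)),
                          tex_params = texture_params(width = 256,
                                                      height = 64,
                                                      sigma = 20))
  expect_identical(tr$texture$enhanced, spec$enhancement == "present")
  expect_identical(tr$rig$mode, spec$viewing)
  expect_identical(tr$light$kind, spec$illumination)
  expect_identical(quadrant_of(c(tr$layout$snake$x, tr$layout$snake$y),
                               tr$layout$params$bounds),
                   spec$quadrant)
})
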