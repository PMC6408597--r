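# Factorial design enumeration, per-trial scene assembly, and the
# synthetic observer standing in for human participants.

qlevels <- c("TL", "TR", "BL", "BR")

#' Enumerate one session of the factorial design
#'
#' The full session crosses edge enhancement (absent/present),
#' illumination (ambient/directional), viewing (monoscopic/
#' stereoscopic), target quadrant (4) and snake texture (10): 320
#' trials, shuffled uniformly; each trial carries a derived seed for
#' its scene generation.
#'
#' @param master_seed integer seed controlling the shuffle and the
#'   per-trial seeds.
#' @return data.frame of 320 `TrialSpec` rows: enhancement,
#'   illumination, viewing, quadrant, texture_id, trial_seed.
#' @export
enumerate_session <- function(master_seed = 1) {
  specs <- expand.grid(
    enhancement = c("absent", "present"),
    illumination = c("ambient", "directional"),
    viewing = c("monoscopic", "stereoscopic"),
    quadrant = qlevels,
    texture_id = 1:10,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(master_seed, {
    specs <- specs[sample.int(nrow(specs)), , drop = FALSE]
    specs$trial_seed <- sample.int(.Machine$integer.max - 1L, nrow(specs))
  })
  rownames(specs) <- NULL
  specs
}

#' Synthetic observer model
#'
#' Reaction times are additive on the millisecond scale: a baseline,
#' a subject random intercept, condition shifts parameterised by the
#' study's printed mean differences, and right-skewed (lognormal,
#' mean-centred) trial noise; responses lapse to no-response with
#' probability `lapse_rate`, are incorrect with probability
#' `error_rate`, and times exceeding `timeout` become no-responses.
#'
#' @param baseline_rt mean RT (ms) in the fastest reference cell
#'   (stereoscopic, directional, unenhanced).
#' @param deltas named list of additive shifts in ms: `enh_mono` /
#'   `enh_stereo` (enhancement cost under each viewing), `amb_mono` /
#'   `amb_stereo` (ambient-light cost under each viewing), `mono_base`
#'   (monoscopic cost for unenhanced targets).
#' @param subject_sd between-subject intercept SD (ms).
#' @param trial_sd within-cell noise SD (ms).
#' @param trial_shape lognormal shape (sdlog) of the trial noise.
#' @param error_rate probability of an incorrect quadrant response.
#' @param lapse_rate probability of a no-response trial.
#' @param timeout response deadline in ms (default 20000).
#' @return a list of class `camo_observer`.
#' @export
observer_model <- function(baseline_rt = 2000,
                           deltas = list(enh_mono = 436.39,
                                         enh_stereo = 96.40,
                                         amb_mono = 540.75,
                                         amb_stereo = 309.97,
                                         mono_base = 100),
                           subject_sd = 300, trial_sd = 500,
                           trial_shape = 0.5, error_rate = 0.0354,
                           lapse_rate = 0.0107, timeout = 20000) {
  stopifnot(subject_sd >= 0, trial_sd >= 0, trial_shape > 0,
            error_rate >= 0, error_rate < 1, lapse_rate >= 0,
            lapse_rate < 1, timeout > 0)
  structure(list(baseline_rt = baseline_rt, deltas = deltas,
                 subject_sd = subject_sd, trial_sd = trial_sd,
                 trial_shape = trial_shape, error_rate = error_rate,
                 lapse_rate = lapse_rate, timeout = timeout),
            class = "camo_observer")
}

#' Null observer (all condition effects zero)
#'
#' @param ... overrides passed to [observer_model()].
#' @return a `camo_observer` with all deltas 0.
#' @export
null_observer_model <- function(...) {
  observer_model(deltas = list(enh_mono = 0, enh_stereo = 0, amb_mono = 0,
                               amb_stereo = 0, mono_base = 0), ...)
}

# additive condition shift for each trial spec row
condition_delta <- function(specs, deltas) {
  mono <- specs$viewing == "monoscopic"
  enh <- specs$enhancement == "present"
  amb <- specs$illumination == "ambient"
  ifelse(enh, ifelse(mono, deltas$enh_mono, deltas$enh_stereo), 0) +
    ifelse(amb, ifelse(mono, deltas$amb_mono, deltas$amb_stereo), 0) +
    ifelse(mono, deltas$mono_base, 0)
}

# mean-centred lognormal noise with SD = trial_sd and shape sdlog
trial_noise <- function(n, trial_sd, sdlog) {
  if (trial_sd == 0) return(numeric(n))
  m <- trial_sd / sqrt(exp(sdlog^2) - 1)
  rlnorm(n, log(m) - sdlog^2 / 2, sdlog) - m
}

#' Simulate one participant's session
#'
#' @param specs trial specs from [enumerate_session()].
#' @param model a [observer_model()].
#' @param participant_seed integer seed (intercept, noise, errors).
#' @param participant_id label for the output (default `"P1"`).
#' @return data.frame of `TrialRecord` rows: participant, the spec
#'   columns, response, correct, rt_ms (NA iff response is "none").
#' @export
simulate_participant <- function(specs, model, participant_seed = 1,
                                 participant_id = "P1") {
  stopifnot(inherits(model, "camo_observer"))
  n <- nrow(specs)
  with_seed(participant_seed, {
    intercept <- rnorm(1, 0, model$subject_sd)
    rt <- model$baseline_rt + intercept +
      condition_delta(specs, model$deltas) +
      trial_noise(n, model$trial_sd, model$trial_shape)
    rt <- pmax(rt, 100)
    lapse <- runif(n) < model$lapse_rate
    err <- runif(n) < model$error_rate
    wrong <- vapply(specs$quadrant, function(q) {
      sample(setdiff(qlevels, q), 1)
    }, character(1))
    response <- ifelse(err, wrong, specs$quadrant)
    none <- lapse | rt > model$timeout
    response[none] <- "none"
    rt[none] <- NA_real_
    data.frame(participant = participant_id,
               specs[, c("enhancement", "illumination", "viewing",
                         "quadrant", "texture_id")],
               response = response,
               correct = !is.na(response) & response == specs$quadrant &
                 response != "none",
               rt_ms = rt, row.names = NULL)
  })
}

#' Simulate a whole experiment
#'
#' Vectorised fast path over participants (trial order within a
#' participant is not shuffled here; the analysis is order-free). Each
#' participant gets a derived seed, a random intercept and independent
#' trial noise under the same observer model.
#'
#' @param model a [observer_model()].
#' @param n_participants number of observers (the study analyses 29).
#' @param master_seed integer seed.
#' @return data.frame of all trial records.
#' @export
simulate_experiment <- function(model, n_participants = 29,
                                master_seed = 1) {
  stopifnot(inherits(model, "camo_observer"), n_participants >= 1)
  cells <- expand.grid(
    enhancement = c("absent", "present"),
    illumination = c("ambient", "directional"),
    viewing = c("monoscopic", "stereoscopic"),
    quadrant = qlevels,
    texture_id = 1:10,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nt <- nrow(cells)
  n <- nt * n_participants
  specs <- cells[rep(seq_len(nt), n_participants), , drop = FALSE]
  pid <- sprintf("P%02d", rep(seq_len(n_participants), each = nt))
  with_seed(master_seed, {
    intercept <- rep(rnorm(n_participants, 0, model$subject_sd), each = nt)
    rt <- model$baseline_rt + intercept +
      condition_delta(specs, model$deltas) +
      trial_noise(n, model$trial_sd, model$trial_shape)
    rt <- pmax(rt, 100)
    lapse <- runif(n) < model$lapse_rate
    err <- runif(n) < model$error_rate
    # uniform over the three wrong quadrants
    qi <- match(specs$quadrant, qlevels)
    shift <- sample.int(3, n, replace = TRUE)
    wrong <- qlevels[((qi - 1 + shift) %% 4) + 1]
    response <- ifelse(err, wrong, specs$quadrant)
    none <- lapse | rt > model$timeout
    response[none] <- "none"
    rt[none] <- NA_real_
    data.frame(participant = pid, specs, response = response,
               correct = response == specs$quadrant & !none,
               rt_ms = rt, row.names = NULL)
  })
}

#' Classify a position into a screen quadrant
#'
#' Quadrants are defined by the signs of the centred coordinates; for a
#' snake the body centroid is used. Exact midline/centre positions
#' break towards the top-left (left if `x <= 0`, top if `y >= 0`).
#'
#' @param position `c(x, y)` in cm, centred coordinates.
#' @param bounds scene bounds (width, height) in cm; positions must lie
#'   within.
#' @return one of `"TL"`, `"TR"`, `"BL"`, `"BR"`.
#' @export
quadrant_of <- function(position, bounds = scene_params()$bounds) {
  stopifnot(abs(position[1]) <= bounds[1] / 2,
            abs(position[2]) <= bounds[2] / 2)
  left <- position[1] <= 0
  top <- position[2] >= 0
  if (top) (if (left) "TL" else "TR") else (if (left) "BL" else "BR")
}

#' Build the stimulus ingredients for one trial
#'
#' Generates the trial's texture (shared across trials by
#' `texture_id`), drops the leaf litter, places the snake in the
#' specified quadrant, and returns the layout together with the camera
#' rig and light implied by the trial's viewing and illumination
#' conditions. Rendering (via [render_trial()]) is decoupled so the
#' statistics pipeline can run without images.
#'
#' @param spec one row of [enumerate_session()] output.
#' @param palette a [camo_palette()].
#' @param params a [scene_params()].
#' @param n_leaves leaf count (default 4500; reduce for speed).
#' @param tex_params a [texture_params()]; its seed is replaced by
#'   `texture_id` so the ten textures are shared across trials.
#' @param rig_template a [camera_rig()]; its mode is replaced by the
#'   trial's viewing condition.
#' @return list with `layout`, `texture`, `rig`, `light`, `spec`.
#' @export
build_trial_scene <- function(spec, palette = generate_synthetic_palette(),
                              params = scene_params(), n_leaves = 4500,
                              tex_params = texture_params(),
                              rig_template = camera_rig()) {
  tex_params$seed <- spec$texture_id
  pair <- select_base_colors(palette, seed = spec$texture_id)
  texture <- compose_texture(tex_params, pair,
                             enhanced = spec$enhancement == "present")
  layout <- drop_leaves(n_leaves, params, palette, seed = spec$trial_seed)
  layout <- place_snake(layout, build_snake_mesh(texture = texture),
                        seed = spec$trial_seed + 1L,
                        quadrant = spec$quadrant)
  rig <- rig_template
  rig$mode <- spec$viewing
  light <- light_model(spec$illumination)
  list(layout = layout, texture = texture, rig = rig, light = light,
       spec = spec)
}

#' Write / read trial records as CSV
#'
#' The on-disk schema is one row per trial with header `participant,
#' enhancement, illumination, viewing, quadrant, texture_id, response,
#' correct, rt_ms`. `read_trials_csv` can ingest foreign files given a
#' `mapping` from this schema to the file's column names; `correct` is
#' recomputed from `response` and `quadrant` when absent.
#'
#' @param records data.frame of trial records.
#' @param path file path.
#' @param mapping optional named character vector, e.g.
#'   `c(participant = "subj", rt_ms = "RT")`.
#' @return the records (read) or `path` invisibly (write).
#' @export
write_trials_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path, mapping = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (ours in names(mapping)) {
      if (!mapping[[ours]] %in% names(d)) {
        stop("mapped column not in file: ", mapping[[ours]])
      }
      names(d)[names(d) == mapping[[ours]]] <- ours
    }
  }
  need <- c("participant", "enhancement", "illumination", "viewing",
            "quadrant", "response", "rt_ms")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"correct" %in% names(d)) {
    d$correct <- d$response == d$quadrant & d$response != "none"
  }
  d$correct <- as.logical(d$correct)
  d$rt_ms <- as.numeric(d$rt_ms)
  d
}
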