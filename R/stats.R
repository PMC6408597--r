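# Analysis pipeline: participant/trial exclusions, reciprocal
# transform with outlier screen, collapse to cell means, fully
# within-subjects 2x2x2 ANOVA with generalized eta squared, and
# simple-effects paired t-tests.

factor_cols <- c("enhancement", "illumination", "viewing")

#' Exclude participants by error rate
#'
#' A single pass removes every participant whose error rate (proportion
#' of trials not answered correctly, no-responses counted as errors)
#' exceeds the across-participant mean by more than four standard
#' deviations.
#'
#' @param records trial records (see [simulate_participant()]).
#' @return list with `records` (retained rows), `removed` (ids),
#'   `threshold` and `rates` (named error rates).
#' @export
exclude_participants <- function(records) {
  if (is.null(records) || !NROW(records)) stop("no trial records")
  rates <- tapply(!records$correct, records$participant, mean)
  if (length(rates) < 3) stop("need at least 3 participants")
  thr <- mean(rates) + 4 * sd(rates)
  removed <- names(rates)[rates > thr]
  list(records = records[!records$participant %in% removed, , drop = FALSE],
       removed = removed, threshold = thr, rates = rates)
}

#' Remove no-response and incorrect trials
#'
#' Percentages are reported against the trial count entering this stage
#' (after participant exclusion, before any trial removal).
#'
#' @param records trial records after [exclude_participants()].
#' @return list with `records` and `log` (counts and percentages of
#'   no-response and incorrect trials).
#' @export
filter_trials <- function(records) {
  n0 <- nrow(records)
  none <- records$response == "none"
  incorrect <- !none & !records$correct
  list(records = records[!none & !incorrect, , drop = FALSE],
       log = list(n_total = n0,
                  n_no_response = sum(none),
                  pct_no_response = 100 * sum(none) / n0,
                  n_incorrect = sum(incorrect),
                  pct_incorrect = 100 * sum(incorrect) / n0))
}

#' Reciprocal transform, outlier screen and collapse to cell means
#'
#' Each retained trial is transformed to `1 / RT` in 1/seconds;
#' transformed values more than three standard deviations from the
#' pooled grand mean are flagged and removed (the study's screen, which
#' detected none). Data are then collapsed over texture and quadrant to
#' per-participant means in the eight design cells, on both the
#' transformed and the millisecond scale.
#'
#' @param records filtered trial records (positive `rt_ms` throughout).
#' @return object of class `camo_clean`: list with `cells` (data.frame
#'   participant, enhancement, illumination, viewing, mean_recip,
#'   mean_rt_ms, n) and `log` (outliers removed, flagged participants
#'   with empty cells, if any).
#' @export
reciprocal_transform_and_screen <- function(records) {
  if (any(is.na(records$rt_ms)) || any(records$rt_ms <= 0)) {
    stop("all retained trials must have positive RTs")
  }
  recip <- 1 / (records$rt_ms / 1000)
  mu <- mean(recip); s <- sd(recip)
  out <- if (is.na(s) || s == 0) rep(FALSE, length(recip)) else
    abs(recip - mu) > 3 * s
  records <- records[!out, , drop = FALSE]
  recip <- recip[!out]
  cells <- aggregate(cbind(mean_recip = recip,
                           mean_rt_ms = records$rt_ms),
                     by = records[, c("participant", factor_cols)],
                     FUN = mean)
  counts <- aggregate(list(n = recip),
                      by = records[, c("participant", factor_cols)],
                      FUN = length)
  cells$n <- counts$n
  # flag participants missing any of the 8 cells
  tab <- table(cells$participant)
  flagged <- names(tab)[tab < 8]
  if (length(flagged)) {
    warning("participants with empty design cells dropped: ",
            paste(flagged, collapse = ", "))
    cells <- cells[!cells$participant %in% flagged, , drop = FALSE]
  }
  structure(list(cells = cells,
                 log = list(n_outliers_removed = sum(out),
                            flagged_empty_cells = flagged)),
            class = "camo_clean")
}

# camo_clean (or compatible data.frame) -> [n, 2, 2, 2] array of the
# given value column, dims: participant x enhancement x illumination x
# viewing, level order as in the design enumeration
cells_to_array <- function(cells, value = "mean_recip") {
  if (inherits(cells, "camo_clean")) cells <- cells$cells
  ids <- sort(unique(cells$participant))
  lv <- list(enhancement = c("absent", "present"),
             illumination = c("ambient", "directional"),
             viewing = c("monoscopic", "stereoscopic"))
  Y <- array(NA_real_, c(length(ids), 2, 2, 2),
             dimnames = c(list(ids), lv))
  idx <- cbind(match(cells$participant, ids),
               match(cells$enhancement, lv$enhancement),
               match(cells$illumination, lv$illumination),
               match(cells$viewing, lv$viewing))
  Y[idx] <- cells[[value]]
  if (any(is.na(Y))) stop("incomplete participant x cell matrix")
  Y
}

#' Fully within-subjects 2x2x2 repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for a complete n x 8 design:
#' subjects, three main effects, three two-way and one three-way
#' interaction, each tested against its own subject-by-effect error
#' term with (1, n - 1) degrees of freedom. Effect sizes are
#' generalized eta squared.
#'
#' @param cell_means a `camo_clean` object, or an n x 8 matrix whose
#'   columns follow `expand.grid` order over (enhancement,
#'   illumination, viewing), or an [n, 2, 2, 2] array.
#' @param value which cell statistic to analyse when a `camo_clean` is
#'   given (default the reciprocal-transformed means).
#' @return object of class `camo_anova`: data.frame with one row per
#'   effect (SS, df, SS_error, df_error, F, p, ges), with the subject
#'   SS and n as attributes.
#' @export
rm_anova_2x2x2 <- function(cell_means, value = "mean_recip") {
  Y <- if (inherits(cell_means, "camo_clean")) {
    cells_to_array(cell_means, value)
  } else if (is.matrix(cell_means)) {
    stopifnot(ncol(cell_means) == 8)
    array(cell_means, c(nrow(cell_means), 2, 2, 2))
  } else if (is.array(cell_means) && length(dim(cell_means)) == 4) {
    cell_means
  } else {
    stop("cell_means must be a camo_clean, an n x 8 matrix or an array")
  }
  n <- dim(Y)[1]
  if (n < 2) stop("need at least 2 participants")

  # marginal means; indices: i subject, a/b/c the three factors
  M <- mean(Y)
  Mi <- apply(Y, 1, mean)
  Ma <- apply(Y, 2, mean); Mb <- apply(Y, 3, mean); Mc <- apply(Y, 4, mean)
  Mab <- apply(Y, c(2, 3), mean)
  Mac <- apply(Y, c(2, 4), mean)
  Mbc <- apply(Y, c(3, 4), mean)
  Mabc <- apply(Y, c(2, 3, 4), mean)
  Mia <- apply(Y, c(1, 2), mean)
  Mib <- apply(Y, c(1, 3), mean)
  Mic <- apply(Y, c(1, 4), mean)
  Miab <- apply(Y, c(1, 2, 3), mean)
  Miac <- apply(Y, c(1, 2, 4), mean)
  Mibc <- apply(Y, c(1, 3, 4), mean)

  ctr <- function(m) m - M
  intx2 <- function(Mxy, Mx, My) {  # two-way residual (2 x 2)
    sweep(sweep(Mxy, 1, Mx), 2, My) + M
  }
  Iab <- intx2(Mab, Ma, Mb); Iac <- intx2(Mac, Ma, Mc)
  Ibc <- intx2(Mbc, Mb, Mc)
  Iabc <- Mabc
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    Iabc[a, b, cc] <- Mabc[a, b, cc] - Mab[a, b] - Mac[a, cc] -
      Mbc[b, cc] + Ma[a] + Mb[b] + Mc[cc] - M
  }

  ss_subj <- 8 * sum(ctr(Mi)^2)
  ss_main <- c(4 * n * sum(ctr(Ma)^2), 4 * n * sum(ctr(Mb)^2),
               4 * n * sum(ctr(Mc)^2))
  ss_two <- c(2 * n * sum(Iab^2), 2 * n * sum(Iac^2), 2 * n * sum(Ibc^2))
  ss_three <- n * sum(Iabc^2)

  # subject-by-effect error terms: interaction of subject with each term
  err1 <- function(Mif, Mf) {  # (n x 2), (2)
    r <- sweep(sweep(Mif, 1, Mi), 2, Mf) + M
    4 * sum(r^2)
  }
  err_main <- c(err1(Mia, Ma), err1(Mib, Mb), err1(Mic, Mc))
  err2 <- function(Mixy, Mix, Miy, Ixy) {  # (n x 2 x 2) etc.
    s <- 0
    for (i in 1:n) for (a in 1:2) for (b in 1:2) {
      r <- Mixy[i, a, b] - Mix[i, a] - Miy[i, b] + Mi[i] - Ixy[a, b]
      s <- s + r^2
    }
    2 * s
  }
  err_two <- c(err2(Miab, Mia, Mib, Iab), err2(Miac, Mia, Mic, Iac),
               err2(Mibc, Mib, Mic, Ibc))
  ss_total <- sum((Y - M)^2)
  err_three <- ss_total - ss_subj - sum(ss_main) - sum(ss_two) -
    ss_three - sum(err_main) - sum(err_two)
  err_three <- max(err_three, 0)

  ss <- c(ss_main, ss_two, ss_three)
  err <- c(err_main, err_two, err_three)
  # SS indistinguishable from roundoff counts as a null effect
  tiny <- 1e-12 * max(ss_total, .Machine$double.eps)
  ss[ss <= tiny] <- 0
  err[err <= tiny] <- 0
  f <- ifelse(ss == 0, 0, ss / (err / (n - 1)))
  if (any(err == 0 & ss > 0)) {
    warning("zero error SS: F reported as infinite")
    f[err == 0 & ss > 0] <- Inf
  }
  p <- pf(f, 1, n - 1, lower.tail = FALSE)
  tab <- data.frame(
    effect = c("enhancement", "illumination", "viewing",
               "enhancement:illumination", "enhancement:viewing",
               "illumination:viewing",
               "enhancement:illumination:viewing"),
    SS = ss, df = 1L, SS_error = err, df_error = n - 1L, F = f, p = p)
  attr(tab, "ss_subjects") <- ss_subj
  attr(tab, "n") <- n
  attr(tab, "ss_total") <- ss_total
  class(tab) <- c("camo_anova", "data.frame")
  tab$ges <- generalized_eta_squared(tab)
  tab
}

#' Generalized eta squared for a fully within-subjects design
#'
#' For each effect, `SS_effect / (SS_effect + SS_subjects +
#' sum(all error SS))`: the Olejnik-Algina/Bakeman form in which every
#' subject-related variance component enters the denominator.
#'
#' @param table a `camo_anova` (needs columns `SS`, `SS_error` and the
#'   `ss_subjects` attribute).
#' @return numeric vector of per-effect effect sizes (NA if the
#'   denominator is zero).
#' @export
generalized_eta_squared <- function(table) {
  ss_subj <- attr(table, "ss_subjects")
  denom_common <- ss_subj + sum(table$SS_error)
  denom <- table$SS + denom_common
  ifelse(denom == 0, NA_real_, table$SS / denom)
}

#' @export
print.camo_anova <- function(x, ...) {
  cat(sprintf("2x2x2 repeated-measures ANOVA (n = %d)\n", attr(x, "n")))
  y <- as.data.frame(x)
  y$F <- round(y$F, 2); y$p <- signif(y$p, 3); y$ges <- signif(y$ges, 2)
  print(y[, c("effect", "F", "p", "ges")], row.names = FALSE)
  invisible(x)
}

default_contrasts <- function() {
  list(
    list(label = "enhancement effect, monoscopic viewing",
         factor = "enhancement", levels = c("present", "absent"),
         at = c(viewing = "monoscopic")),
    list(label = "enhancement effect, stereoscopic viewing",
         factor = "enhancement", levels = c("present", "absent"),
         at = c(viewing = "stereoscopic")),
    list(label = "illumination effect, monoscopic viewing",
         factor = "illumination", levels = c("ambient", "directional"),
         at = c(viewing = "monoscopic")),
    list(label = "illumination effect, stereoscopic viewing",
         factor = "illumination", levels = c("ambient", "directional"),
         at = c(viewing = "stereoscopic")))
}

#' Simple-effects paired t-tests
#'
#' Each contrast compares two levels of one factor at a fixed level of
#' another, collapsing each participant's cell means over the remaining
#' factor. Inference (t, p, Cohen's d) is on the reciprocal-transformed
#' scale; the mean difference is additionally reported in milliseconds
#' from the untransformed per-participant means. Two d conventions are
#' reported: `d_z` (mean difference over the SD of paired differences)
#' and `d_av` (mean difference over the average condition SD).
#'
#' @param clean a `camo_clean` from [reciprocal_transform_and_screen()].
#' @param contrasts list of contrast descriptors (label, factor,
#'   levels, at); defaults to the study's four simple effects.
#' @return data.frame of class `camo_simple`: label, mean_diff_ms,
#'   mean_diff_recip, t, df, p, d_z, d_av.
#' @export
simple_effects <- function(clean, contrasts = default_contrasts()) {
  cells <- if (inherits(clean, "camo_clean")) clean$cells else clean
  out <- lapply(contrasts, function(ct) {
    sub <- cells[cells[[names(ct$at)]] == ct$at, , drop = FALSE]
    if (!nrow(sub)) stop("contrast references absent cells: ", ct$label)
    agg <- aggregate(sub[, c("mean_recip", "mean_rt_ms")],
                     by = list(participant = sub$participant,
                               lev = sub[[ct$factor]]), FUN = mean)
    a <- agg[agg$lev == ct$levels[1], ]
    b <- agg[agg$lev == ct$levels[2], ]
    a <- a[order(a$participant), ]; b <- b[order(b$participant), ]
    stopifnot(identical(a$participant, b$participant))
    dr <- a$mean_recip - b$mean_recip
    dm <- a$mean_rt_ms - b$mean_rt_ms
    n <- length(dr)
    sdd <- sd(dr)
    if (is.na(sdd) || sdd == 0) {
      warning("zero variance of paired differences for: ", ct$label)
      t <- if (mean(dr) == 0) 0 else NA_real_
      p <- if (mean(dr) == 0) 1 else NA_real_
      dz <- if (mean(dr) == 0) 0 else NA_real_
    } else {
      t <- mean(dr) / (sdd / sqrt(n))
      p <- 2 * pt(abs(t), n - 1, lower.tail = FALSE)
      dz <- mean(dr) / sdd
    }
    sav <- sqrt((sd(a$mean_recip)^2 + sd(b$mean_recip)^2) / 2)
    dav <- if (is.na(sav) || sav == 0) dz else mean(dr) / sav
    data.frame(label = ct$label, mean_diff_ms = mean(dm),
               mean_diff_recip = mean(dr), t = t, df = n - 1L, p = p,
               d_z = dz, d_av = dav)
  })
  res <- do.call(rbind, out)
  class(res) <- c("camo_simple", "data.frame")
  res
}

#' Run the complete analysis pipeline
#'
#' Applies participant exclusion, trial filtering, the reciprocal
#' transform with outlier screen, the 2x2x2 repeated-measures ANOVA
#' with generalized eta squared, and the four simple-effects t-tests.
#'
#' @param records raw trial records (from the simulator,
#'   [read_trials_csv()], or a mapped external dataset).
#' @return object of class `camo_results`: list with `exclusions`,
#'   `trial_log`, `clean`, `anova`, `simple`.
#' @export
analyze_trials <- function(records) {
  ex <- exclude_participants(records)
  fl <- filter_trials(ex$records)
  clean <- reciprocal_transform_and_screen(fl$records)
  anova <- rm_anova_2x2x2(clean)
  simple <- simple_effects(clean)
  structure(list(exclusions = list(removed = ex$removed,
                                   threshold = ex$threshold,
                                   rates = ex$rates),
                 trial_log = fl$log,
                 screen_log = clean$log,
                 clean = clean, anova = anova, simple = simple),
            class = "camo_results")
}

#' @export
print.camo_results <- function(x, ...) {
  cat("Camouflage visual-search analysis\n")
  cat(sprintf("  participants removed (error rate > mean + 4 SD): %s\n",
              if (length(x$exclusions$removed))
                paste(x$exclusions$removed, collapse = ", ") else "none"))
  cat(sprintf("  trials removed: %.2f%% no-response, %.2f%% incorrect\n",
              x$trial_log$pct_no_response, x$trial_log$pct_incorrect))
  cat(sprintf("  transformed-scale outliers removed: %d\n",
              x$screen_log$n_outliers_removed))
  print(x$anova)
  cat("Simple effects (t on reciprocal scale, difference in ms):\n")
  y <- as.data.frame(x$simple)
  y$mean_diff_ms <- round(y$mean_diff_ms, 2)
  y$t <- round(y$t, 2); y$p <- signif(y$p, 3); y$d_z <- round(y$d_z, 2)
  print(y[, c("label", "mean_diff_ms", "t", "df", "p", "d_z")],
        row.names = FALSE)
  invisible(x)
}

#' Export analysis results as JSON
#'
#' @param results a `camo_results`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  obj <- list(exclusions = results$exclusions,
              trial_log = results$trial_log,
              screen_log = results$screen_log,
              anova = as.data.frame(results$anova),
              simple = as.data.frame(results$simple))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
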