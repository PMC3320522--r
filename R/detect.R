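#' Detect rupture-repair episodes across a set of courses
#'
#' One front end over the three detection criteria. For every course the
#' function derives the variability profile (intraindividual SD, and the
#' interindividual SD of the whole set), applies the requested criterion,
#' and — for the crisis-repair criterion — classifies each episode into the
#' five-pattern taxonomy. The per-course thresholds actually used are
#' recorded in the result's `log` so that threshold choices stay auditable.
#'
#' @param x An [course_set()], a single [course()], or a long-format data
#'   frame with columns `course_id`, `session`, `value`.
#' @param criterion `"crisis_repair"` (cumulative-decline rule,
#'   [detect_crisis_repair()]), `"strauss"` / `"strauss_modified"`
#'   (step rule, [detect_strauss()]), or `"stiles"` / `"stiles_modified"`
#'   (quadratic-trend residual rule, [detect_stiles()]).
#' @param multiplier Threshold in SD units (1 or 2); for the Stiles-type
#'   criterion this is the RMSE multiplier and defaults to 2.
#' @param threshold_source Which variability feeds the threshold (ignored
#'   by the Stiles-type criterion, which is intraindividual by
#'   construction). Criterion presets lock incompatible values: original
#'   Strauss forces `"inter_only"` and multiplier 1.
#' @param absolute_floor Pre-specified limit for the original Stiles
#'   preset.
#' @param sd_denom SD denominator convention, see [intra_sd()].
#' @param classify Attach pattern labels to crisis-repair episodes
#'   (default `TRUE`).
#' @return An object of class `"rre"`: a list with `episodes` (data
#'   frame), `excluded` (data frame of excluded courses and reasons),
#'   `log` (per-course thresholds), `criterion`, `multiplier`, `courses`,
#'   `fits` (Stiles-type fits, when applicable).
#' @examples
#' fx <- schematic_fixtures()
#' fit <- detect_episodes(fx, "crisis_repair", threshold_source = "intra_only")
#' fit
#' summary(fit)
#' @export
detect_episodes <- function(x,
                            criterion = c("crisis_repair", "strauss",
                                          "strauss_modified", "stiles",
                                          "stiles_modified"),
                            multiplier = NULL,
                            threshold_source = c("stricter", "intra_only",
                                                 "inter_only"),
                            absolute_floor = NULL,
                            sd_denom = c("n-1", "n"),
                            classify = TRUE) {
  criterion <- match.arg(criterion)
  threshold_source <- match.arg(threshold_source)
  sd_denom <- match.arg(sd_denom)
  courses <- as_course_set(x)
  if (is.null(multiplier))
    multiplier <- if (startsWith(criterion, "stiles")) 2 else 1

  out <- switch(
    criterion,
    crisis_repair = run_crisis(courses, multiplier, threshold_source,
                               sd_denom, classify),
    strauss = run_strauss(courses, strauss_config("original"), sd_denom),
    strauss_modified = run_strauss(
      courses,
      strauss_config("modified", multiplier = multiplier,
                     threshold_source = threshold_source),
      sd_denom),
    stiles = run_stiles(courses, stiles_config("original",
                                               rmse_multiplier = multiplier,
                                               absolute_floor = absolute_floor)),
    stiles_modified = run_stiles(courses,
                                 stiles_config("modified",
                                               rmse_multiplier = multiplier)))
  out$criterion <- criterion
  out$multiplier <- multiplier
  out$courses <- courses
  class(out) <- "rre"
  out
}

run_crisis <- function(courses, multiplier, mode, denom, classify) {
  inter <- inter_sd(courses, denom)
  eps <- list(); log <- list(); thr_by_course <- numeric(0L)
  for (cr in courses) {
    prof <- structure(list(intra = sd_values(cr$values, denom), inter = inter,
                           mode = mode, denom = denom),
                      class = "rre_profile")
    det <- detect_crisis_repair(cr, prof, multiplier)
    eps[[cr$course_id]] <- det$episodes
    thr_by_course[cr$course_id] <- det$threshold
    log[[cr$course_id]] <- data.frame(
      course_id = cr$course_id, intra_sd = prof$intra, inter_sd = inter,
      mode = mode,
      stricter = if (prof$intra >= inter) "intra" else "inter",
      multiplier = multiplier, threshold = det$threshold)
  }
  episodes <- do.call(rbind, c(eps, list(make.row.names = FALSE)))
  if (classify)
    episodes <- classify_episodes(episodes, courses, thr_by_course)
  list(episodes = episodes,
       excluded = data.frame(course_id = character(0L),
                             reason = character(0L)),
       log = do.call(rbind, c(log, list(make.row.names = FALSE))))
}

run_strauss <- function(courses, config, denom) {
  inter <- inter_sd(courses, denom)
  eps <- list(); log <- list(); excl <- list()
  for (cr in courses) {
    prof <- structure(list(intra = sd_values(cr$values, denom), inter = inter,
                           mode = config$threshold_source, denom = denom),
                      class = "rre_profile")
    det <- detect_strauss(cr, prof, config)
    eps[[cr$course_id]] <- det$episodes
    if (det$excluded)
      excl[[cr$course_id]] <- data.frame(course_id = cr$course_id,
                                         reason = det$reason)
    log[[cr$course_id]] <- data.frame(
      course_id = cr$course_id, intra_sd = prof$intra, inter_sd = inter,
      mode = config$threshold_source,
      stricter = if (prof$intra >= inter) "intra" else "inter",
      multiplier = config$multiplier, threshold = det$threshold)
  }
  list(episodes = do.call(rbind, c(eps, list(make.row.names = FALSE))),
       excluded = if (length(excl))
         do.call(rbind, c(excl, list(make.row.names = FALSE)))
       else data.frame(course_id = character(0L), reason = character(0L)),
       log = do.call(rbind, c(log, list(make.row.names = FALSE))),
       config = config)
}

run_stiles <- function(courses, config) {
  eps <- list(); log <- list(); excl <- list(); fits <- list()
  for (cr in courses) {
    fit <- stiles_fit(cr)
    det <- detect_stiles(cr, fit, config)
    fits[[cr$course_id]] <- fit
    if (det$excluded) {
      excl[[cr$course_id]] <- data.frame(course_id = cr$course_id,
                                         reason = det$reason)
    } else if (length(det$ruptures)) {
      eps[[cr$course_id]] <- data.frame(
        course_id = cr$course_id,
        session = det$ruptures,
        value = cr$values[det$ruptures],
        fitted = fit$fitted.values[det$ruptures])
    }
    log[[cr$course_id]] <- data.frame(
      course_id = cr$course_id,
      midtreatment_intercept = fit$coefficients[[1L]],
      slope = fit$coefficients[[2L]],
      curve = fit$coefficients[[3L]],
      rmse = fit$rmse,
      threshold = config$rmse_multiplier * fit$rmse,
      excluded = det$excluded)
  }
  list(episodes = if (length(eps))
    do.call(rbind, c(eps, list(make.row.names = FALSE)))
    else data.frame(course_id = character(0L), session = integer(0L),
                    value = numeric(0L), fitted = numeric(0L)),
    excluded = if (length(excl))
      do.call(rbind, c(excl, list(make.row.names = FALSE)))
    else data.frame(course_id = character(0L), reason = character(0L)),
    log = do.call(rbind, c(log, list(make.row.names = FALSE))),
    config = config, fits = fits)
}

#' @export
print.rre <- function(x, ...) {
  n_eps <- nrow(x$episodes)
  cat("Rupture-repair detection (criterion: ", x$criterion,
      ", multiplier ", x$multiplier, ")\n", sep = "")
  cat("  ", length(x$courses), " course(s): ", n_eps, " episode(s)/rupture(s), ",
      nrow(x$excluded), " course(s) excluded\n", sep = "")
  if (!is.null(x$episodes$pattern) && n_eps)
    cat("  patterns:",
        paste(names(table(x$episodes$pattern)[table(x$episodes$pattern) > 0]),
              table(x$episodes$pattern)[table(x$episodes$pattern) > 0],
              sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Summarise a detection run
#'
#' For crisis-repair runs returns the full pattern summary
#' ([summarize_episodes()]); for the other criteria a count block in the
#' shape of the comparison tables: total episodes, courses with at least
#' one episode, courses with none, excluded courses.
#'
#' @param object An `"rre"` object.
#' @param ... Unused.
#' @export
summary.rre <- function(object, ...) {
  counts <- data.frame(
    criterion = object$criterion,
    total_episodes = nrow(object$episodes),
    courses_with_episode = length(unique(object$episodes$course_id)),
    courses_without_episode = length(object$courses) -
      length(unique(object$episodes$course_id)) - nrow(object$excluded),
    excluded_courses = nrow(object$excluded))
  out <- list(counts = counts, excluded = object$excluded)
  if (!is.null(object$episodes$pattern))
    out$patterns <- summarize_episodes(object$episodes,
                                       n_courses = length(object$courses))
  class(out) <- "summary.rre"
  out
}

#' @export
print.summary.rre <- function(x, ...) {
  print(x$counts, row.names = FALSE)
  if (nrow(x$excluded)) {
    cat("Excluded courses:\n")
    print(x$excluded, row.names = FALSE)
  }
  if (!is.null(x$patterns)) print(x$patterns)
  invisible(x)
}

#' Plot course trajectories with detected episodes
#'
#' One panel per course: the session-rating trajectory with detected
#' episodes shaded (start to repair; open-ended for unrepaired episodes)
#' and, for Stiles-type runs, the fitted quadratic trend and the rupture
#' threshold curve.
#'
#' @param x An `"rre"` object.
#' @param courses Ids of the courses to plot (default: all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rre <- function(x, courses = names(x$courses), ...) {
  ids <- intersect(courses, names(x$courses))
  op <- graphics::par(mfrow = c(min(length(ids), 3L),
                                ceiling(length(ids) / 3)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (id in ids) {
    cr <- x$courses[[id]]
    graphics::plot(cr$sessions, cr$values, type = "b", pch = 16, cex = 0.6,
                   xlab = "session", ylab = "rating", main = id, ...)
    ep <- x$episodes[x$episodes$course_id == id, , drop = FALSE]
    if (!is.null(ep$start_session) && nrow(ep)) {
      for (i in seq_len(nrow(ep))) {
        to <- if (is.na(ep$repair_session[i])) max(cr$sessions)
        else ep$repair_session[i]
        graphics::rect(ep$start_session[i], min(cr$values), to,
                       max(cr$values), col = grDevices::adjustcolor(
                         if (isTRUE(ep$repaired[i])) "steelblue" else "firebrick",
                         alpha.f = 0.15), border = NA)
      }
    } else if (!is.null(ep$session) && nrow(ep)) {
      graphics::points(ep$session, ep$value, col = "firebrick", pch = 4,
                       cex = 1.4, lwd = 2)
    }
    if (!is.null(x$fits) && !is.null(x$fits[[id]])) {
      graphics::lines(cr$sessions, stats::fitted(x$fits[[id]]), col = "grey40")
      graphics::lines(cr$sessions, stats::fitted(x$fits[[id]]) -
                        x$config$rmse_multiplier * x$fits[[id]]$rmse,
                      col = "grey40", lty = 2)
    }
  }
  invisible(x)
}

#' Run several criteria on one data set and tabulate the counts
#'
#' Produces a comparison block with one column per criterion run: total
#' episodes, courses with at least one episode, courses with none, and
#' excluded courses.
#'
#' @param x Input accepted by [detect_episodes()].
#' @param runs Named list of argument lists for [detect_episodes()] (the
#'   name labels the column). The default compares the crisis-repair
#'   criterion at 1 and 2 SD with the original Stiles-type and
#'   Strauss-type rules.
#' @param absolute_floor Floor handed to original Stiles runs in the
#'   default set.
#' @return A data frame with one row per count and one column per run,
#'   plus attribute `"runs"` holding the `"rre"` objects.
#' @export
compare_criteria <- function(x,
                             runs = list(
                               crisis_repair_1sd = list(criterion = "crisis_repair",
                                                        multiplier = 1),
                               crisis_repair_2sd = list(criterion = "crisis_repair",
                                                        multiplier = 2),
                               stiles = list(criterion = "stiles"),
                               strauss = list(criterion = "strauss")),
                             absolute_floor = NULL) {
  courses <- as_course_set(x)
  fits <- lapply(runs, function(args) {
    if (identical(args$criterion, "stiles") && is.null(args$absolute_floor))
      args$absolute_floor <- absolute_floor
    do.call(detect_episodes, c(list(x = courses), args))
  })
  cols <- lapply(fits, function(f) {
    s <- summary(f)$counts
    c(total_episodes = s$total_episodes,
      courses_with_episode = s$courses_with_episode,
      courses_without_episode = s$courses_without_episode,
      excluded_courses = s$excluded_courses)
  })
  out <- as.data.frame(cols)
  attr(out, "runs") <- fits
  out
}
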