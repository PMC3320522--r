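#' Step template realising one crisis-repair pattern
#'
#' Returns the session-to-session differences of a noise-free episode of
#' the requested pattern, scaled to a detection threshold. The geometry is
#' chosen so that detection at `threshold` recovers the planted episode
#' exactly: every decline qualifies with a comfortable margin, slide steps
#' in `a`-subtypes stay below the jump size, jump steps reach it, and
#' intermediate repair steps stay outside the repair band so that the
#' planted repair length is the detected one.
#'
#' @param pattern One of `"1"`, `"2"`, `"3a"`, `"3b"`, `"4a"`, `"4b"`,
#'   `"5"`.
#' @param threshold Detection threshold the geometry is aimed at.
#' @param depth Total drop from start value to trough, in rating units.
#'   Defaults to a pattern-appropriate multiple of `threshold`.
#' @param decline_length Sessions from start to trough (for pattern 5: the
#'   first decline only).
#' @param repair_length Sessions from trough to repair.
#' @param jump_positions For `b`-subtypes, which decline steps carry the
#'   jump (default: the middle step).
#' @return Numeric vector of step differences summing to zero (the episode
#'   returns exactly to its start value).
#' @export
pattern_steps <- function(pattern, threshold,
                          depth = NULL, decline_length = NULL,
                          repair_length = NULL, jump_positions = NULL) {
  pattern <- match.arg(as.character(pattern), pattern_levels)
  thr <- threshold
  if (!is.numeric(thr) || thr <= 0)
    stop("threshold must be a positive number", call. = FALSE)

  if (pattern == "5") {
    L <- if (is.null(decline_length)) 1L else as.integer(decline_length)
    D <- if (is.null(depth)) 2.4 * thr else depth
    if (D < 1.6 * thr)
      stop("pattern 5 needs depth >= 1.6 * threshold per decline", call. = FALSE)
    dec1 <- rep(-D / L, L)
    partial <- 0.7 * thr
    if (D - partial <= thr)
      stop("pattern 5: partial recovery would already repair the episode",
           call. = FALSE)
    D2 <- 2.0 * thr
    return(c(dec1, partial, -D2, D + D2 - partial))
  }

  jumpy <- pattern %in% c("3b", "4b")
  L <- if (is.null(decline_length)) {
    if (pattern %in% c("1", "2")) 1L else 3L
  } else as.integer(decline_length)
  R <- if (is.null(repair_length)) {
    if (pattern %in% c("2", "4a", "4b")) 2L else 1L
  } else as.integer(repair_length)
  if (pattern %in% c("1", "2") && L != 1L)
    stop("patterns 1 and 2 have a one-session decline", call. = FALSE)
  if (pattern %in% c("3a", "3b", "4a", "4b") && L < 2L)
    stop("slide-in patterns need decline_length >= 2", call. = FALSE)
  if (pattern %in% c("1", "3a", "3b") && R != 1L)
    stop("jump-out patterns have a one-session repair", call. = FALSE)
  if (pattern %in% c("2", "4a", "4b") && R < 2L)
    stop("slide-out patterns need repair_length >= 2", call. = FALSE)

  if (is.null(depth)) {
    depth <- if (jumpy) 0.7 * thr * (L - 1L) + 1.7 * thr
    else max(0.75 * thr * L, 1.7 * thr + 0.7 * thr * (R - 1L))
    if (pattern == "1") depth <- 2 * thr
    if (pattern == "2") depth <- 1.7 * thr + 0.7 * thr * (R - 1L)
  }
  D <- depth
  if (D < thr)
    stop("depth must reach the threshold for the episode to qualify",
         call. = FALSE)

  if (jumpy) {
    J <- if (is.null(jump_positions)) ceiling(L / 2) else as.integer(jump_positions)
    if (any(J < 1L | J > L))
      stop("jump_positions must lie within the decline", call. = FALSE)
    k <- length(J)
    small <- 0.7 * thr
    jump <- (D - small * (L - k)) / k
    if (jump < thr)
      stop("depth too shallow for a jump of at least the threshold inside ",
           "a ", L, "-step slide", call. = FALSE)
    dec <- rep(-small, L)
    dec[J] <- -jump
  } else if (L == 1L) {
    dec <- -D
  } else {
    if (D / L >= thr)
      stop("slide-without-jump needs every step below the threshold; ",
           "increase decline_length or reduce depth", call. = FALSE)
    dec <- rep(-D / L, L)
  }

  if (R == 1L) {
    rep_steps <- D
  } else {
    inter <- 0.7 * thr
    if (D - inter * (R - 1L) <= thr)
      stop("depth too shallow for a ", R, "-session repair (intermediate ",
           "steps would already re-enter the repair band)", call. = FALSE)
    rep_steps <- c(rep(inter, R - 1L), D - inter * (R - 1L))
  }
  c(dec, rep_steps)
}

#' Describe a planted crisis-repair episode
#'
#' @inheritParams pattern_steps
#' @param start_session Last pre-decline session: the planted decline
#'   begins with the step out of this session.
#' @return A list of class `"planted_episode"`.
#' @seealso [generator_spec()], [generate_course()]
#' @export
planted_episode <- function(pattern, start_session,
                            depth = NULL, decline_length = NULL,
                            repair_length = NULL, jump_positions = NULL) {
  structure(list(pattern = match.arg(as.character(pattern), pattern_levels),
                 start_session = as.integer(start_session),
                 depth = depth, decline_length = decline_length,
                 repair_length = repair_length,
                 jump_positions = jump_positions),
            class = "planted_episode")
}

#' Specification of a synthetic therapy course
#'
#' Defines a reproducible course with planted crisis-repair episodes.
#' Episodes are carved into the flat baseline first and independent
#' Gaussian noise is added afterwards, so the ground truth stays geometric.
#' The defaults emulate the kind of data the detection criteria target:
#' courses of about 30 post-session affiliation-index ratings whose
#' per-course standard deviation is of order 40 on the index scale, the
#' variability being driven mostly by the episodes themselves with modest
#' measurement noise on top.
#'
#' @param n_sessions Number of sessions (default 30; use 200 for a
#'   long-course scenario).
#' @param baseline Pre-crisis level of the rating (default 100).
#' @param noise_sd SD of the additive Gaussian per-session noise (default
#'   4, i.e. a tenth of the default threshold).
#' @param target_course_sd Optional scale anchor: when supplied the noise
#'   SD is re-derived so that the empirical course SD converges to this
#'   value as the course grows (useful to reproduce per-course SDs of
#'   around 38-41).
#' @param planted List of [planted_episode()]s; spans must lie inside the
#'   course and must not overlap.
#' @param threshold_ref Detection threshold the planted geometry is scaled
#'   to (default 40).
#' @param seed Integer seed; identical spec and seed give identical data.
#' @param clamp Optional `c(lo, hi)` bounding the values, emulating a
#'   bounded questionnaire-derived index.
#' @param ar Optional AR(1) coefficient in `[0, 1)` for autocorrelated
#'   noise (session ratings are plausibly autocorrelated); 0 gives the
#'   independent-noise default.
#' @return A list of class `"generator_spec"`.
#' @export
generator_spec <- function(n_sessions = 30L, baseline = 100,
                           noise_sd = 4, target_course_sd = NULL,
                           planted = list(), threshold_ref = 40,
                           seed = 1L, clamp = NULL, ar = 0) {
  n_sessions <- as.integer(n_sessions)
  if (n_sessions < 3L) stop("n_sessions must be at least 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (ar < 0 || ar >= 1) stop("ar must lie in [0, 1)", call. = FALSE)
  if (inherits(planted, "planted_episode")) planted <- list(planted)
  spans <- lapply(planted, function(p) {
    steps <- pattern_steps(p$pattern, threshold_ref, p$depth,
                           p$decline_length, p$repair_length,
                           p$jump_positions)
    c(p$start_session, p$start_session + length(steps))
  })
  if (length(spans)) {
    ord <- order(vapply(spans, `[`, numeric(1L), 1L))
    planted <- planted[ord]; spans <- spans[ord]
    for (k in seq_along(spans)) {
      if (spans[[k]][1L] < 1L || spans[[k]][2L] > n_sessions)
        stop("planted episode ", k, " extends outside the course (sessions ",
             spans[[k]][1L], "-", spans[[k]][2L], ")", call. = FALSE)
      if (k > 1L && spans[[k]][1L] < spans[[k - 1L]][2L])
        stop("planted episodes ", k - 1L, " and ", k, " overlap", call. = FALSE)
    }
  }
  structure(list(n_sessions = n_sessions, baseline = baseline,
                 noise_sd = noise_sd, target_course_sd = target_course_sd,
                 planted = planted, threshold_ref = threshold_ref,
                 seed = as.integer(seed), clamp = clamp, ar = ar,
                 spans = spans),
            class = "generator_spec")
}

#' Generate a synthetic course with known ground truth
#'
#' @param spec A [generator_spec()].
#' @param course_id Id for the generated course.
#' @return A list with elements `course` (an [course()]) and `truth` (data
#'   frame with one row per planted episode: `start_session`,
#'   `trough_session`, `repair_session`, `pattern`, `depth`,
#'   `decline_length`, `repair_length`).
#' @examples
#' spec <- generator_spec(30, planted = planted_episode("1", 10), noise_sd = 0)
#' g <- generate_course(spec)
#' g$truth
#' @export
generate_course <- function(spec, course_id = "sim") {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_sessions
  v <- rep(spec$baseline, n)
  truth <- vector("list", length(spec$planted))
  for (k in seq_along(spec$planted)) {
    p <- spec$planted[[k]]
    steps <- pattern_steps(p$pattern, spec$threshold_ref, p$depth,
                           p$decline_length, p$repair_length,
                           p$jump_positions)
    path <- cumsum(c(0, steps))
    s0 <- p$start_session
    v[s0:(s0 + length(steps))] <- spec$baseline + path
    tr_off <- max(which(path == min(path)))
    truth[[k]] <- data.frame(start_session = s0,
                             trough_session = s0 + tr_off - 1L,
                             repair_session = s0 + length(steps),
                             pattern = p$pattern,
                             depth = -min(path),
                             decline_length = tr_off - 1L,
                             repair_length = length(steps) - tr_off + 1L)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
  else data.frame(start_session = integer(0L), trough_session = integer(0L),
                  repair_session = integer(0L), pattern = character(0L),
                  depth = numeric(0L), decline_length = integer(0L),
                  repair_length = integer(0L))
  sd_noise <- spec$noise_sd
  if (!is.null(spec$target_course_sd)) {
    geom_var <- stats::var(v)
    sd_noise <- sqrt(max(spec$target_course_sd^2 - geom_var, 0))
  }
  if (sd_noise > 0) {
    set.seed(spec$seed)
    e <- stats::rnorm(n, 0, sd_noise)
    if (spec$ar > 0) {
      # stationary AR(1) with marginal sd sd_noise
      e <- as.numeric(stats::filter(e * sqrt(1 - spec$ar^2), spec$ar,
                                    method = "recursive"))
    }
    v <- v + e
  }
  if (!is.null(spec$clamp))
    v <- pmin(pmax(v, spec$clamp[1L]), spec$clamp[2L])
  list(course = course(v, course_id = course_id), truth = truth)
}

#' Schematic fixture courses for the five patterns
#'
#' Five minimal noise-free courses, one per pattern, realised at a
#' detection threshold of 20 (attached as attribute `"threshold"`). Each
#' contains exactly one detectable crisis-repair episode; the fifth
#' contains two threshold-reaching declines separated by a direction
#' change, which merge into one complex episode.
#'
#' @return An [course_set()] of five courses named `pattern1` ...
#'   `pattern5`, with attribute `threshold`.
#' @export
schematic_fixtures <- function() {
  vals <- list(pattern1 = c(60, 20, 60, 60),
               pattern2 = c(60, 10, 35, 60),
               pattern3 = c(60, 45, 30, 60),
               pattern4 = c(60, 45, 30, 15, 30, 45),
               pattern5 = c(60, 30, 38, 10, 40, 60))
  cs <- course_set(lapply(names(vals), function(id) course(vals[[id]], id)))
  attr(cs, "threshold") <- 20
  cs
}

#' Restrict a course to a sparse measurement schedule
#'
#' Emulates study designs that rate only selected sessions (e.g. sessions
#' 2, 5, 10, 20, ...). The retained values are renumbered consecutively,
#' which is how a sparse design would present itself to the detection
#' criteria; the original session numbers are kept in attribute
#' `"schedule"`. Results on subsampled courses can be distorted: a gradual
#' multi-session slide may appear as a single jump.
#'
#' @param course An [course()].
#' @param schedule Increasing subset of the course's sessions (at least 3).
#' @return An [course()] with attribute `schedule`.
#' @export
subsample_schedule <- function(course, schedule) {
  course <- as_course(course)
  schedule <- as.integer(schedule)
  if (!all(schedule %in% course$sessions))
    stop("schedule contains sessions outside the course", call. = FALSE)
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly increasing", call. = FALSE)
  out <- course(course$values[schedule], course_id = course$course_id)
  attr(out, "schedule") <- schedule
  out
}

#' Simulate a study-like batch of courses
#'
#' Generates ten short courses of 29-35 sessions plus one 200-session long
#' course, with planted episodes drawn from the empirical pattern mix the
#' classifier targets (V-shapes and jump-bearing slides most common) and
#' per-course variability of order 40 on the index scale. Intended as a
#' realistic end-to-end input for the detection pipeline.
#'
#' @param seed Integer seed.
#' @param n_short Number of short courses (default 10).
#' @return A list with `courses` (an [course_set()] of the short courses),
#'   `long_course` (the 200-session course), `truth` (combined ground
#'   truth), `threshold_ref`.
#' @export
simulate_study_courses <- function(seed = 1L, n_short = 10L) {
  set.seed(seed)
  thr <- 40
  pat_pool <- c("1", "1", "1", "3b", "3b", "3a", "2", "4a", "4b", "5")
  make <- function(n, id, n_eps, course_seed) {
    pats <- sample(pat_pool, n_eps, replace = TRUE)
    planted <- list(); pos <- 2L
    for (p in pats) {
      steps <- pattern_steps(p, thr)
      len <- length(steps)
      if (pos + len + 1L > n) break
      planted[[length(planted) + 1L]] <- planted_episode(p, pos)
      pos <- pos + len + sample(2:4, 1L)
    }
    spec <- generator_spec(n, baseline = 100, noise_sd = 4,
                           planted = planted, threshold_ref = thr,
                           seed = course_seed)
    g <- generate_course(spec, course_id = id)
    g$truth <- cbind(course_id = rep(id, nrow(g$truth)), g$truth)
    g
  }
  lens <- sample(29:35, n_short, replace = TRUE)
  seeds <- sample.int(2^30, n_short + 1L)
  short <- lapply(seq_len(n_short), function(i)
    make(lens[i], sprintf("S%02d", i), n_eps = sample(2:4, 1L), seeds[i]))
  long <- make(200L, "L01", n_eps = 25L, seeds[n_short + 1L])
  truth <- do.call(rbind, c(lapply(short, `[[`, "truth"), list(long$truth)))
  list(courses = course_set(lapply(short, `[[`, "course")),
       long_course = long$course,
       truth = truth,
       threshold_ref = thr)
}
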