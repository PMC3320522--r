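#' Segment a course into maximal decline and incline runs
#'
#' The crisis-repair criterion reads a course as an alternating sequence of
#' maximal runs, obtained by summing session-to-session differences until
#' the direction changes. A decline run consists of downward and constant
#' steps (a constant value is not a direction change: sessions with
#' constant values belong to the rupture, not to the repair); an incline
#' run consists of strictly upward steps. Concatenating the runs reproduces
#' the course's step sequence.
#'
#' @param course An [course()] object or numeric vector.
#' @return A data frame with one row per run: `kind` (`"decline"` or
#'   `"incline"`), `start_session`, `end_session`, `cumulative_change`
#'   (signed sum of the run's step differences).
#' @examples
#' segment_runs(c(60, 55, 55, 40, 70))
#' @export
segment_runs <- function(course) {
  course <- as_course(course)
  v <- course$values
  n <- length(v)
  d <- v[-1L] - v[-n]
  r <- rle(d > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(kind = ifelse(r$values, "incline", "decline"),
             start_session = starts,
             end_session = ends + 1L,
             cumulative_change = v[ends + 1L] - v[starts])
}

# Lean scan over one value vector. Returns a matrix with one row per
# episode: start, trough, repair (NA when unrepaired), magnitude,
# n_declines (number of threshold-reaching declines inside the episode),
# leading_constant (1 when the opening decline run begins with constant
# steps attached to the rupture).
#
# Definitions implemented:
#  * a rupture opens when a decline run's cumulative drop from its local
#    start (the last session before its first strictly-down step) reaches
#    the threshold;
#  * while open, further decline runs extend the episode; the trough is the
#    last session attaining the running minimum; each decline run whose own
#    drop reaches the threshold increments n_declines (complex pattern);
#  * the episode is repaired at the first session with at least one upward
#    step since the trough whose value is back within the threshold of the
#    start value (reaching the start value always repairs);
#  * an episode still open at the last session is emitted unrepaired.
crisis_scan <- function(v, thr) {
  n <- length(v)
  d <- v[-1L] - v[-n]
  r <- rle(d > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  rows <- vector("list", 8L); nr <- 0L
  open <- FALSE
  st <- tr <- 0L; vs <- v_tr <- 0; ndec <- 0L; lead <- FALSE
  for (j in seq_len(k)) {
    s <- starts[j]; e <- ends[j]
    if (!r$values[j]) {                          # decline run: steps s..e
      neg <- which(d[s:e] < 0)
      if (!length(neg)) {                        # purely constant run
        if (open && v[e + 1L] <= v_tr) { tr <- e + 1L; v_tr <- v[tr] }
        next
      }
      ls <- s + neg[1L] - 1L                     # local start session
      drop <- v[ls] - v[e + 1L]                  # run minimum is its end
      if (!open) {
        if (drop >= thr) {
          open <- TRUE
          st <- ls; vs <- v[ls]
          tr <- e + 1L; v_tr <- v[tr]
          ndec <- 1L
          lead <- ls > s
        }
      } else {
        if (drop >= thr) ndec <- ndec + 1L
        if (v[e + 1L] <= v_tr) { tr <- e + 1L; v_tr <- v[tr] }
      }
    } else if (open) {                           # incline run: sessions s+1..e+1
      tt <- (s + 1L):(e + 1L)
      hit <- which(v[tt] >= vs - thr)
      if (length(hit)) {
        nr <- nr + 1L
        rows[[nr]] <- c(st, tr, tt[hit[1L]], vs - v_tr, ndec, lead)
        open <- FALSE
      }
    }
  }
  if (open) {
    nr <- nr + 1L
    rows[[nr]] <- c(st, tr, NA_real_, vs - v_tr, ndec, lead)
  }
  if (nr == 0L) return(matrix(numeric(0L), 0L, 6L))
  matrix(unlist(rows[seq_len(nr)]), nr, 6L, byrow = TRUE)
}

#' Detect crisis-repair episodes (cumulative-decline criterion)
#'
#' The criterion sums session-to-session differences until the direction
#' changes (see [segment_runs()]) and flags a rupture whenever the
#' cumulative drop of a decline reaches at least `multiplier` standard
#' deviations, the SD being chosen by the profile's mode (the stricter of
#' intra- and interindividual variability by default). Because whole
#' declines are summed rather than single steps, gradual downward trends
#' that no single-step rule can see are detected, and the beginning and end
#' of each decline are located exactly.
#'
#' An episode is repaired at the first subsequent session, after at least
#' one upward step, whose value is back within `multiplier` SD of the
#' value at the episode start (reaching or exceeding the start value always
#' repairs). If, before that happens, a further threshold-reaching decline
#' begins, the episode extends and becomes complex (classified pattern 5).
#' An episode still open at the end of the course is reported with
#' `repaired = FALSE`; no course is excluded.
#'
#' @param course An [course()] object.
#' @param profile A [variability_profile()].
#' @param multiplier Threshold in SD units, 1 or 2.
#' @return A list of class `"crisis_detection"`: `episodes` (data frame
#'   with columns `course_id`, `start_session`, `trough_session`,
#'   `repair_session`, `rupture_magnitude`, `decline_length`,
#'   `repair_length`, `repaired`, `n_declines`, `leading_constant`),
#'   `threshold`, `multiplier`.
#' @examples
#' crs <- course(c(60, 55, 50, 45, 40, 60), "A")
#' prof <- structure(list(intra = 15, inter = NA_real_, mode = "intra_only",
#'                        denom = "n-1"), class = "rre_profile")
#' detect_crisis_repair(crs, prof, multiplier = 1)$episodes
#' @export
detect_crisis_repair <- function(course, profile, multiplier = 1) {
  course <- as_course(course)
  if (!inherits(profile, "rre_profile"))
    stop("profile must be a variability_profile()", call. = FALSE)
  if (length(multiplier) != 1L || !multiplier %in% c(1, 2))
    stop("multiplier must be 1 or 2", call. = FALSE)
  thr <- profile_threshold(profile, multiplier)
  if (thr <= 0)
    stop("effective threshold is 0 (constant reference data); ",
         "no meaningful detection is possible", call. = FALSE)
  mat <- crisis_scan(course$values, thr)
  eps <- data.frame(course_id = rep(course$course_id, nrow(mat)),
                    start_session = as.integer(mat[, 1L]),
                    trough_session = as.integer(mat[, 2L]),
                    repair_session = as.integer(mat[, 3L]),
                    rupture_magnitude = mat[, 4L],
                    decline_length = as.integer(mat[, 2L] - mat[, 1L]),
                    repair_length = as.integer(mat[, 3L] - mat[, 2L]),
                    repaired = !is.na(mat[, 3L]),
                    n_declines = as.integer(mat[, 5L]),
                    leading_constant = mat[, 6L] > 0)
  structure(list(episodes = eps, threshold = thr, multiplier = multiplier,
                 profile = profile, course_id = course$course_id),
            class = "crisis_detection")
}

#' @export
print.crisis_detection <- function(x, ...) {
  cat("course ", x$course_id, ": ", nrow(x$episodes),
      " crisis-repair episode(s) at ", x$multiplier, " SD (threshold ",
      format(x$threshold, digits = 4), ")\n", sep = "")
  invisible(x)
}
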