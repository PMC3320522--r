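#' Construct a therapy course
#'
#' A course is one course of therapy represented as an ordered series of
#' post-session ratings (one real value per session, e.g. a weighted
#' affiliation index). Sessions are numbered 1, 2, ... with no gaps: the
#' detection criteria sum session-to-session differences, which is only
#' meaningful when every session was rated.
#'
#' @param values Numeric vector of per-session ratings, length at least 3
#'   (a V-shaped episode needs three points). All values must be finite.
#' @param course_id Identifier for the course (coerced to character).
#' @param sessions Session indices; must be consecutive integers starting
#'   at 1. Defaults to `seq_along(values)`.
#' @return An object of class `"rre_course"`: a list with elements
#'   `course_id`, `sessions` and `values`.
#' @seealso [course_set()], [read_courses()], [detect_episodes()]
#' @examples
#' crs <- course(c(60, 55, 50, 45, 40, 60), course_id = "A")
#' intra_sd(crs)
#' @export
course <- function(values, course_id = "course", sessions = seq_along(values)) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("a course needs at least 3 sessions, got ", length(values), call. = FALSE)
  if (!all(is.finite(values)))
    stop("course '", course_id, "' contains non-finite values", call. = FALSE)
  sessions <- as.integer(sessions)
  if (length(sessions) != length(values) ||
      !identical(sessions, seq_len(length(values))))
    stop("sessions must be consecutive integers 1, 2, ... with one value each; ",
         "course '", course_id, "' violates this (gaps or reordered sessions ",
         "are an input error; see read_courses(interpolate_gaps=))", call. = FALSE)
  structure(list(course_id = as.character(course_id)[1L],
                 sessions = sessions, values = values),
            class = "rre_course")
}

#' @export
print.rre_course <- function(x, ...) {
  cat("<course ", x$course_id, "> ", length(x$values), " sessions, sd ",
      format(intra_sd(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
length.rre_course <- function(x) length(x$values)

is_course <- function(x) inherits(x, "rre_course")

as_course <- function(x, course_id = "course") {
  if (is_course(x)) return(x)
  if (is.numeric(x)) return(course(x, course_id = course_id))
  stop("cannot interpret object of class '", class(x)[1L], "' as a course",
       call. = FALSE)
}

#' Bundle courses into a course set
#'
#' A course set is a collection of courses with distinct ids; it is the unit
#' from which interindividual variability (the mean of per-course standard
#' deviations) is derived.
#'
#' @param ... `rre_course` objects, or a single list of them.
#' @return An object of class `"rre_course_set"`: a list of courses named by
#'   their ids.
#' @examples
#' cs <- course_set(course(c(50, 40, 50), "A"), course(c(60, 20, 60), "B"))
#' inter_sd(cs)
#' @export
course_set <- function(...) {
  courses <- list(...)
  if (length(courses) == 1L && !is_course(courses[[1L]]) && is.list(courses[[1L]]))
    courses <- courses[[1L]]
  if (length(courses) == 0L)
    stop("a course set must contain at least one course", call. = FALSE)
  ok <- vapply(courses, is_course, logical(1L))
  if (!all(ok))
    stop("all elements must be course objects (see course())", call. = FALSE)
  ids <- vapply(courses, function(cr) cr$course_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate course ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(courses) <- ids
  structure(courses, class = "rre_course_set")
}

#' @export
print.rre_course_set <- function(x, ...) {
  ns <- vapply(x, length, integer(1L))
  cat("<course set> ", length(x), " courses, ",
      min(ns), "-", max(ns), " sessions\n", sep = "")
  invisible(x)
}

is_course_set <- function(x) inherits(x, "rre_course_set")

as_course_set <- function(x) {
  if (is_course_set(x)) return(x)
  if (is_course(x)) return(course_set(x))
  if (is.data.frame(x)) return(courses_from_df(x))
  stop("cannot interpret object of class '", class(x)[1L], "' as a course set",
       call. = FALSE)
}

courses_from_df <- function(df, interpolate_gaps = FALSE) {
  need <- c("course_id", "session", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$value))
    stop("column 'value' must be numeric", call. = FALSE)
  ids <- unique(as.character(df$course_id))
  courses <- lapply(ids, function(id) {
    sub <- df[as.character(df$course_id) == id, , drop = FALSE]
    sub <- sub[order(sub$session), , drop = FALSE]
    ses <- as.integer(sub$session)
    if (anyDuplicated(ses))
      stop("course '", id, "': duplicated session ",
           ses[duplicated(ses)][1L], call. = FALSE)
    val <- sub$value
    if (ses[1L] != 1L)
      stop("course '", id, "': sessions must start at 1", call. = FALSE)
    if (!identical(ses, seq_len(length(ses)))) {
      if (!interpolate_gaps)
        stop("course '", id, "': sessions are not consecutive (missing ",
             paste(setdiff(seq_len(max(ses)), ses), collapse = ", "),
             "); set interpolate_gaps = TRUE to fill linearly", call. = FALSE)
      full <- seq_len(max(ses))
      val <- stats::approx(ses, val, xout = full, method = "linear")$y
      ses <- full
      crs <- course(val, course_id = id, sessions = ses)
      attr(crs, "interpolated") <- TRUE
      return(crs)
    }
    course(val, course_id = id, sessions = ses)
  })
  course_set(courses)
}

#' Per-course and across-course variability
#'
#' `intra_sd()` is the intraindividual standard deviation: the SD of one
#' course's session values. `inter_sd()` is the interindividual standard
#' deviation in the sense used by the detection criteria: the arithmetic
#' mean of the per-course intraindividual SDs over a course set (not the SD
#' of the pooled values).
#'
#' @param course An `rre_course`.
#' @param course_set An `rre_course_set`.
#' @param denom Denominator convention: `"n-1"` (sample SD, default) or
#'   `"n"`. The criteria are insensitive to this choice for all but very
#'   short courses, but it is exposed so results can be matched against
#'   either convention.
#' @return A single non-negative number.
#' @examples
#' intra_sd(course(c(2, 4, 4, 4, 5, 5, 7, 9)))
#' @export
intra_sd <- function(course, denom = c("n-1", "n")) {
  course <- as_course(course)
  sd_values(course$values, match.arg(denom))
}

sd_values <- function(x, denom = "n-1") {
  n <- length(x)
  if (n < 2L) stop("need at least 2 values to compute an SD", call. = FALSE)
  s2 <- sum((x - mean(x))^2)
  sqrt(s2 / if (denom == "n") n else n - 1L)
}

#' @rdname intra_sd
#' @export
inter_sd <- function(course_set, denom = c("n-1", "n")) {
  course_set <- as_course_set(course_set)
  denom <- match.arg(denom)
  mean(vapply(course_set, function(cr) sd_values(cr$values, denom), numeric(1L)))
}

#' Effective detection threshold
#'
#' Combines intra- and interindividual variability into the threshold (in
#' rating units) that a decline must reach to count as a rupture.
#' `mode = "inter_only"` is the original Strauss convention (averaged SD
#' across courses); `mode = "stricter"` takes the larger of the two SDs,
#' which avoids overrating minor fluctuations in stable courses as well as
#' intraindividually insignificant declines in highly fluctuating courses;
#' `mode = "intra_only"` is the stand-alone convention used for a long
#' course analysed on its own, so that courses of very different lengths
#' are not merged into one reference value.
#'
#' @param intra Intraindividual SD (non-negative).
#' @param inter Interindividual SD (non-negative).
#' @param multiplier Threshold in SD units: 1 (lenient) or 2 (strict).
#' @param mode One of `"stricter"`, `"intra_only"`, `"inter_only"`.
#' @return `multiplier` times the selected SD.
#' @examples
#' effective_threshold(40, 38.69, 1, "stricter")   # 40
#' effective_threshold(30, 38.69, 2, "stricter")   # 77.38
#' @export
effective_threshold <- function(intra, inter,
                                multiplier = 1,
                                mode = c("stricter", "intra_only", "inter_only")) {
  mode <- match.arg(mode)
  if (!is.numeric(intra) || !is.numeric(inter) || intra < 0 || inter < 0)
    stop("intra and inter SDs must be non-negative numbers", call. = FALSE)
  if (!multiplier %in% c(1, 2))
    stop("multiplier must be 1 or 2", call. = FALSE)
  base <- switch(mode,
                 stricter = max(intra, inter),
                 intra_only = intra,
                 inter_only = inter)
  multiplier * base
}

#' Variability profile of a course within a course set
#'
#' Computes the intraindividual SD of `course`, the interindividual SD of
#' `course_set` (when given), and records which convention (`mode`) will be
#' used to turn them into a detection threshold. When `course_set` is `NULL`
#' the course is treated as stand-alone and the mode is forced to
#' `"intra_only"`.
#'
#' @inheritParams intra_sd
#' @inheritParams effective_threshold
#' @param course_set Reference course set for the interindividual SD, or
#'   `NULL` for a stand-alone course.
#' @return A list of class `"rre_profile"` with elements `intra`, `inter`,
#'   `mode`, `denom`.
#' @export
variability_profile <- function(course, course_set = NULL,
                                mode = c("stricter", "intra_only", "inter_only"),
                                denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  intra <- intra_sd(course, denom)
  if (is.null(course_set)) {
    mode <- "intra_only"
    inter <- NA_real_
  } else {
    mode <- match.arg(mode)
    inter <- inter_sd(course_set, denom)
    if (mode == "intra_only") inter <- inter  # recorded for the log even if unused
  }
  structure(list(intra = intra, inter = inter, mode = mode, denom = denom),
            class = "rre_profile")
}

#' @export
print.rre_profile <- function(x, ...) {
  cat("<variability profile> intra ", format(x$intra, digits = 4),
      ", inter ", format(x$inter, digits = 4), ", mode ", x$mode, "\n", sep = "")
  invisible(x)
}

profile_threshold <- function(profile, multiplier) {
  if (!multiplier %in% c(1, 2))
    stop("multiplier must be 1 or 2", call. = FALSE)
  inter <- if (is.na(profile$inter)) 0 else profile$inter
  if (profile$mode == "inter_only" && is.na(profile$inter))
    stop("profile has no interindividual SD but mode is 'inter_only'",
         call. = FALSE)
  effective_threshold(profile$intra, inter, multiplier, profile$mode)
}
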