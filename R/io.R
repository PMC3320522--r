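#' Read courses from a long-format CSV file
#'
#' Expects UTF-8 delimited text with a header row and columns `course_id`,
#' `session`, `value`: one row per rated session. Duplicate
#' (course, session) rows and non-consecutive session numbers are input
#' errors; missing sessions can optionally be filled by linear
#' interpolation, in which case the affected courses carry attribute
#' `interpolated = TRUE`.
#'
#' @param path Path to the CSV file.
#' @param sep Field separator (default comma).
#' @param interpolate_gaps Fill missing sessions by linear interpolation
#'   instead of rejecting the course (default `FALSE`).
#' @return An [course_set()].
#' @export
read_courses <- function(path, sep = ",", interpolate_gaps = FALSE) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  courses_from_df(df, interpolate_gaps = interpolate_gaps)
}

#' Write a course set as long-format CSV
#'
#' Inverse of [read_courses()]: values are written with full precision, so
#' a write/read round trip reproduces them exactly.
#'
#' @param x An [course_set()] or [course()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_courses <- function(x, path) {
  x <- as_course_set(x)
  df <- do.call(rbind, lapply(x, function(cr)
    data.frame(course_id = cr$course_id, session = cr$sessions,
               # %.17g survives a write/read round trip bit-exactly
               value = sprintf("%.17g", cr$values))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weighted affiliation index from interpersonal cluster scores
#'
#' Condenses per-session circumplex cluster scores (clusters 2-4 and 6-8 of
#' the octant model: the affiliative and disaffiliative octants) into one
#' warmth/affiliation value per record as a weighted sum. A high index
#' signifies an experience of affectionate interaction. No default weights
#' are shipped: published weighting schemes for the questionnaire vary, so
#' the weights are an explicit analysis input.
#'
#' @param scores Named numeric vector, or data frame / matrix with one row
#'   per record, holding cluster scores named `c2`, `c3`, `c4`, `c6`,
#'   `c7`, `c8`.
#' @param weights Named numeric vector with one weight per required
#'   cluster (same names).
#' @return Numeric vector with one index value per record.
#' @examples
#' w <- c(c2 = 1, c3 = 1, c4 = 1, c6 = -1, c7 = -1, c8 = -1)
#' affiliation_index(c(c2 = 10, c3 = 10, c4 = 10, c6 = 10, c7 = 10, c8 = 10), -w)
#' @export
affiliation_index <- function(scores, weights) {
  need <- c("c2", "c3", "c4", "c6", "c7", "c8")
  if (is.null(names(weights)) || !all(need %in% names(weights)))
    stop("weights must be named and cover clusters ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.vector(scores) && !is.list(scores))
    scores <- matrix(scores, 1L, dimnames = list(NULL, names(scores)))
  scores <- as.data.frame(scores)
  miss <- setdiff(need, colnames(scores))
  if (length(miss))
    stop("missing cluster score(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mat <- as.matrix(scores[, need, drop = FALSE])
  if (!is.numeric(mat))
    stop("cluster scores must be numeric", call. = FALSE)
  if (anyNA(mat))
    stop("cluster scores contain missing values", call. = FALSE)
  as.numeric(mat %*% weights[need])
}

#' Collapse per-record interpersonal ratings into per-session courses
#'
#' Takes a long table of questionnaire records — one row per course,
#' session, rating direction (patient about self vs. patient about
#' therapist) and focus (transitive vs. intransitive) with cluster scores
#' `c2 ... c8` — computes the weighted affiliation index of every record
#' and sums the indices of the records belonging to the same session into
#' one rating per session.
#'
#' @param df Data frame with columns `course_id`, `session`, cluster score
#'   columns `c2`, `c3`, `c4`, `c6`, `c7`, `c8`, and optionally
#'   `direction`/`focus` (any further grouping columns are simply summed
#'   over).
#' @param weights Passed to [affiliation_index()].
#' @return An [course_set()] of affiliation-index courses.
#' @export
intrex_to_courses <- function(df, weights) {
  need <- c("course_id", "session")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  idx <- affiliation_index(df, weights)
  agg <- stats::aggregate(idx,
                          by = list(course_id = df$course_id,
                                    session = df$session),
                          FUN = sum)
  names(agg)[3L] <- "value"
  courses_from_df(agg)
}

#' Write an episode table as CSV
#'
#' @param episodes Episode data frame (any of the criteria's outputs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  utils::write.csv(episodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
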