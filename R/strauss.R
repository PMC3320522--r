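#' Configuration of the Strauss-type decrease/increase rule
#'
#' The Strauss-type rule reads the course step by step: a rupture is a
#' single session-to-session decrease at least as large as the reference
#' SD, and a repair is a subsequent single-step increase of at least the
#' same reference SD. In the original form the reference is the
#' interindividual (averaged) SD with multiplier 1, and a course whose last
#' rupture remains unrepaired at the end of treatment is removed from the
#' analysis entirely. The modifications, each switchable here, are:
#' using both the 1-SD and the stricter 2-SD threshold
#' (`multiplier`), taking the stricter of intra- and interindividual SD
#' (`threshold_source = "stricter"`), dropping the end-unrepaired exclusion
#' (`drop_exclusion`), requiring the repair of a deep (>= 2 SD) rupture to
#' match its magnitude rather than a single 1-SD step
#' (`match_repair_to_rupture`), and counting a run of consecutive
#' threshold-reaching decreases as one rupture whose magnitude is the
#' aggregated sum (`aggregate_consecutive`).
#'
#' @param preset `"original"` or `"modified"`. The original preset locks
#'   `threshold_source = "inter_only"`, `multiplier = 1` and all
#'   modification flags off; the modified preset turns them all on.
#' @param threshold_source Which SD feeds the threshold; see
#'   [effective_threshold()].
#' @param multiplier 1 or 2 SD units.
#' @param drop_exclusion Keep (flagged) courses ending on an unrepaired
#'   rupture instead of discarding them.
#' @param match_repair_to_rupture Deep ruptures need commensurate repairs.
#' @param aggregate_consecutive Merge consecutive threshold-reaching
#'   decreases into one rupture.
#' @return A list of class `"strauss_config"`.
#' @export
strauss_config <- function(preset = c("original", "modified"),
                           threshold_source = NULL,
                           multiplier = NULL,
                           drop_exclusion = NULL,
                           match_repair_to_rupture = NULL,
                           aggregate_consecutive = NULL) {
  preset <- match.arg(preset)
  def <- function(x, orig, mod) if (is.null(x)) (if (preset == "original") orig else mod) else x
  threshold_source <- def(threshold_source, "inter_only", "stricter")
  multiplier <- def(multiplier, 1, 1)
  drop_exclusion <- def(drop_exclusion, FALSE, TRUE)
  match_repair_to_rupture <- def(match_repair_to_rupture, FALSE, TRUE)
  aggregate_consecutive <- def(aggregate_consecutive, FALSE, TRUE)
  if (preset == "original" &&
      (threshold_source != "inter_only" || multiplier != 1 ||
       drop_exclusion || match_repair_to_rupture || aggregate_consecutive))
    stop("the original Strauss preset fixes inter_only, multiplier 1 and all ",
         "modification flags off; use preset = 'modified' to change them",
         call. = FALSE)
  if (!multiplier %in% c(1, 2))
    stop("multiplier must be 1 or 2", call. = FALSE)
  if (!threshold_source %in% c("inter_only", "intra_only", "stricter"))
    stop("unknown threshold_source '", threshold_source, "'", call. = FALSE)
  structure(list(preset = preset,
                 threshold_source = threshold_source,
                 multiplier = multiplier,
                 drop_exclusion = isTRUE(drop_exclusion),
                 match_repair_to_rupture = isTRUE(match_repair_to_rupture),
                 aggregate_consecutive = isTRUE(aggregate_consecutive)),
            class = "strauss_config")
}

# Lean step-level scan.
# v: values; thr: rupture/repair threshold; base_sd: the 1-SD unit (used by
# the matched-repair rule to decide what "deep" means); returns a matrix with
# one row per rupture: start, trough, repair (NA if none), rupture_magnitude,
# repair_magnitude.
strauss_scan <- function(v, thr, base_sd = thr,
                         aggregate = FALSE, match_repair = FALSE) {
  n <- length(v)
  d <- v[-1L] - v[-n]
  hit <- -d >= thr                       # step i: session i -> i+1
  idx <- which(hit)
  if (!length(idx))
    return(matrix(numeric(0L), 0L, 5L))
  if (aggregate) {
    grp <- cumsum(c(1L, diff(idx) != 1L))
    starts <- tapply(idx, grp, min)
    ends <- tapply(idx, grp, max)
  } else {
    starts <- idx; ends <- idx
  }
  m <- length(starts)
  out <- matrix(NA_real_, m, 5L)
  for (k in seq_len(m)) {
    st <- starts[[k]]                    # rupture start session
    tr <- ends[[k]] + 1L                 # trough session
    mag <- v[st] - v[tr]
    # repair window: after the trough, before the next rupture's start step
    lim <- if (k < m) starts[[k + 1L]] else n
    rp <- NA_real_; rmag <- NA_real_
    if (tr < lim) {
      if (match_repair && mag >= 2 * base_sd) {
        cand <- (tr + 1L):lim
        ok <- which(v[cand] - v[tr] >= mag)
        if (length(ok)) { rp <- cand[ok[1L]]; rmag <- v[rp] - v[tr] }
      } else {
        cand <- tr:(lim - 1L)            # candidate repair steps
        ok <- which(d[cand] >= thr)
        if (length(ok)) { rp <- cand[ok[1L]] + 1L; rmag <- d[cand[ok[1L]]] }
      }
    }
    out[k, ] <- c(st, tr, rp, mag, rmag)
  }
  out
}

#' Detect rupture-repair episodes with the Strauss-type rule
#'
#' @param course An [course()] object.
#' @param profile A [variability_profile()] supplying the intra- and
#'   interindividual SDs; its mode must agree with
#'   `config$threshold_source`.
#' @param config A [strauss_config()].
#' @return A list of class `"strauss_detection"`: `episodes` (data frame
#'   with one row per rupture: `rupture_start_session`, `trough_session`,
#'   `repair_session`, `rupture_magnitude`, `repair_magnitude`,
#'   `repaired`), `excluded`, `reason`, `threshold`. Under the original
#'   preset a course ending on an unrepaired rupture is excluded and its
#'   episode table is emptied; under `drop_exclusion` the episodes are kept
#'   and the unrepaired rupture rows carry `repaired = FALSE`.
#' @examples
#' crs <- course(c(50, 50, 10, 50, 50), "A")
#' prof <- variability_profile(crs)  # stand-alone: intraindividual SD
#' detect_strauss(crs, prof, strauss_config("modified",
#'                                          threshold_source = "intra_only"))
#' @export
detect_strauss <- function(course, profile,
                           config = strauss_config("original")) {
  course <- as_course(course)
  if (!inherits(config, "strauss_config"))
    stop("config must be a strauss_config()", call. = FALSE)
  if (!inherits(profile, "rre_profile"))
    stop("profile must be a variability_profile()", call. = FALSE)
  if (config$threshold_source != profile$mode)
    stop("profile mode ('", profile$mode, "') does not match ",
         "config$threshold_source ('", config$threshold_source, "')",
         call. = FALSE)
  base_sd <- profile_threshold(profile, 1)
  thr <- config$multiplier * base_sd
  mat <- strauss_scan(course$values, thr, base_sd,
                      aggregate = config$aggregate_consecutive,
                      match_repair = config$match_repair_to_rupture)
  eps <- data.frame(course_id = rep(course$course_id, nrow(mat)),
                    rupture_start_session = as.integer(mat[, 1L]),
                    trough_session = as.integer(mat[, 2L]),
                    repair_session = as.integer(mat[, 3L]),
                    rupture_magnitude = mat[, 4L],
                    repair_magnitude = mat[, 5L],
                    repaired = !is.na(mat[, 3L]))
  excluded <- FALSE; reason <- NA_character_
  if (!config$drop_exclusion && nrow(eps) > 0L &&
      !eps$repaired[nrow(eps)]) {
    excluded <- TRUE
    reason <- "unrepaired rupture at end of treatment"
    eps <- eps[0L, , drop = FALSE]
  }
  structure(list(episodes = eps, excluded = excluded, reason = reason,
                 threshold = thr, config = config,
                 course_id = course$course_id),
            class = "strauss_detection")
}

#' @export
print.strauss_detection <- function(x, ...) {
  if (x$excluded) {
    cat("course ", x$course_id, ": excluded (", x$reason, ")\n", sep = "")
  } else {
    cat("course ", x$course_id, ": ", nrow(x$episodes),
        " rupture(s) at threshold ", format(x$threshold, digits = 4), "\n",
        sep = "")
  }
  invisible(x)
}
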