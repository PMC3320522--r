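#' Quadratic trend fit of a course (Stiles-type regression)
#'
#' Fits, by ordinary least squares, the rating on the centred session index
#' and its square: `value ~ (s - mid) + (s - mid)^2` with `mid = (n + 1)/2`.
#' The four parameters are the ones the Stiles-type rupture rule is built
#' on: the fitted value at midtreatment (intercept), the linear trend
#' (slope), the quadratic trend (curve), and the residual variability
#' (root-mean-square error, the typical deviation of the raw values from
#' the fitted parabola).
#'
#' @param course An [course()] object (or numeric vector) with at least 4
#'   sessions, so that at least one residual degree of freedom remains.
#' @param rmse_df Degrees of freedom for the RMSE: `"n-3"` (residual df
#'   after estimating three parameters, default) or `"n"` (plain mean
#'   square).
#' @return An object of class `"stiles_fit"` with components
#'   `coefficients` (named: `midtreatment_intercept`, `slope`, `curve`),
#'   `rmse`, `fitted.values`, `residuals`, `mid`, `n`.
#' @examples
#' fit <- stiles_fit(course(c(60, 58, 50, 30, 45, 55, 60, 62)))
#' coef(fit)
#' fit$rmse
#' @export
stiles_fit <- function(course, rmse_df = c("n-3", "n")) {
  course <- as_course(course)
  rmse_df <- match.arg(rmse_df)
  n <- length(course$values)
  if (n < 4L)
    stop("the quadratic fit needs at least 4 sessions, got ", n, call. = FALSE)
  mid <- (n + 1) / 2
  x <- course$sessions - mid
  X <- cbind(`midtreatment_intercept` = 1, slope = x, curve = x^2)
  ls <- stats::lm.fit(X, course$values)
  # clean numerical dust at 1e-9 (far below rating precision) so that an
  # exactly-zero trend or a zero residual is treated as zero by the rule
  coefs <- round(ls$coefficients, 9)
  fitted <- round(ls$fitted.values, 9)
  res <- round(ls$residuals, 9)
  df <- if (rmse_df == "n") n else n - 3L
  rmse <- round(sqrt(sum(res^2) / df), 9)
  structure(list(coefficients = coefs,
                 rmse = rmse,
                 fitted.values = fitted,
                 residuals = res,
                 mid = mid, n = n, rmse_df = rmse_df,
                 course_id = course$course_id),
            class = "stiles_fit")
}

#' @export
print.stiles_fit <- function(x, digits = 4, ...) {
  cat("Quadratic trend fit (course ", x$course_id, ", ", x$n, " sessions)\n",
      sep = "")
  print(round(x$coefficients, digits))
  cat("RMSE:", format(x$rmse, digits = digits),
      sprintf("(df = %s)\n", x$rmse_df))
  invisible(x)
}

#' @export
coef.stiles_fit <- function(object, ...) object$coefficients

#' @export
fitted.stiles_fit <- function(object, ...) object$fitted.values

#' @export
residuals.stiles_fit <- function(object, ...) object$residuals

#' Predicted trend values at given sessions
#'
#' @param object A [stiles_fit()] object.
#' @param sessions Session indices at which to evaluate the fitted parabola
#'   (default: the fitted sessions).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.stiles_fit <- function(object, sessions = seq_len(object$n), ...) {
  x <- sessions - object$mid
  b <- object$coefficients
  b[[1L]] + b[[2L]] * x + b[[3L]] * x^2
}

#' Configuration of the Stiles-type rupture rule
#'
#' The rule flags a session as a rupture when its value falls at least
#' `rmse_multiplier` times the RMSE below the fitted quadratic trend. The
#' original formulation adds four specifications: first and last sessions
#' never count; courses with a negative linear trend are excluded outright
#' (a deteriorating alliance is never considered repaired); a rupture value
#' must be lower than the previous session's value; and the value must fall
#' below a pre-specified absolute limit, so that small wobbles in very
#' stable, permanently high courses are not flagged. The modified preset
#' disregards the course-level exclusion and the absolute floor, so that
#' potentially unsuccessful courses are not removed from the analysis.
#'
#' @param preset `"original"` or `"modified"`.
#' @param rmse_multiplier Positive multiple of the RMSE (default 2).
#' @param absolute_floor The pre-specified limit. No published value
#'   exists; it must be supplied by the analyst under the original preset
#'   and is disabled under the modified preset.
#' @param exclude_first_last Drop candidate ruptures in session 1 or n.
#' @param exclude_negative_slope Exclude the whole course when the fitted
#'   slope is negative.
#' @param require_below_previous Require `value(s) < value(s - 1)`.
#' @return A list of class `"stiles_config"`.
#' @export
stiles_config <- function(preset = c("original", "modified"),
                          rmse_multiplier = 2,
                          absolute_floor = NULL,
                          exclude_first_last = TRUE,
                          exclude_negative_slope = NULL,
                          require_below_previous = TRUE) {
  preset <- match.arg(preset)
  if (is.null(exclude_negative_slope))
    exclude_negative_slope <- preset == "original"
  if (preset == "modified") absolute_floor <- NULL
  if (!is.numeric(rmse_multiplier) || rmse_multiplier <= 0)
    stop("rmse_multiplier must be a positive number", call. = FALSE)
  structure(list(preset = preset,
                 rmse_multiplier = rmse_multiplier,
                 absolute_floor = absolute_floor,
                 exclude_first_last = isTRUE(exclude_first_last),
                 exclude_negative_slope = isTRUE(exclude_negative_slope),
                 require_below_previous = isTRUE(require_below_previous)),
            class = "stiles_config")
}

# lean scan over one value vector; returns list(ruptures, excluded, reason)
stiles_scan <- function(v, pred, rmse, mult, floor_val,
                        excl_first_last, excl_neg_slope, below_prev, slope) {
  n <- length(v)
  if (excl_neg_slope && slope < 0)
    return(list(ruptures = integer(0L), excluded = TRUE,
                reason = "negative linear trend"))
  s <- which(v <= pred - mult * rmse)
  if (excl_first_last) s <- s[s != 1L & s != n]
  if (below_prev) s <- s[s > 1L & v[s] < v[s - 1L]]
  if (!is.null(floor_val)) s <- s[v[s] < floor_val]
  list(ruptures = s, excluded = FALSE, reason = NA_character_)
}

#' Detect ruptures with the Stiles-type rule
#'
#' Applies the residual-outlier rule of [stiles_config()] to a course. The
#' rule marks rupture sessions only: it has no explicit repair point, so
#' the result is a list of rupture session indices plus a course-level
#' exclusion verdict, not paired episodes.
#'
#' @param course An [course()] object.
#' @param fit A [stiles_fit()] for the same course (recomputed if missing).
#' @param config A [stiles_config()].
#' @return A list of class `"stiles_detection"` with components `ruptures`
#'   (integer session indices), `excluded` (logical), `reason`, `fit`, and
#'   `config`.
#' @examples
#' crs <- course(c(60, 60, 60, 60, 60, 10, 60, 60, 60, 60, 60))
#' detect_stiles(crs, config = stiles_config("original", absolute_floor = 50))
#' @export
detect_stiles <- function(course, fit = stiles_fit(course),
                          config = stiles_config("modified")) {
  course <- as_course(course)
  if (!inherits(config, "stiles_config"))
    stop("config must be a stiles_config()", call. = FALSE)
  if (fit$n != length(course$values))
    stop("fit and course have different lengths", call. = FALSE)
  if (config$preset == "original" && is.null(config$absolute_floor))
    stop("the original Stiles preset requires an absolute_floor; no published ",
         "value exists, so it must be chosen explicitly", call. = FALSE)
  res <- stiles_scan(course$values, fit$fitted.values, fit$rmse,
                     config$rmse_multiplier, config$absolute_floor,
                     config$exclude_first_last, config$exclude_negative_slope,
                     config$require_below_previous, fit$coefficients[[2L]])
  structure(c(res, list(fit = fit, config = config,
                        course_id = course$course_id)),
            class = "stiles_detection")
}

#' @export
print.stiles_detection <- function(x, ...) {
  if (x$excluded) {
    cat("course ", x$course_id, ": excluded (", x$reason, ")\n", sep = "")
  } else if (length(x$ruptures) == 0L) {
    cat("course ", x$course_id, ": no ruptures\n", sep = "")
  } else {
    cat("course ", x$course_id, ": rupture session(s) ",
        paste(x$ruptures, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
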