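pattern_levels <- c("1", "2", "3a", "3b", "4a", "4b", "5")

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify one crisis-repair episode into the five-pattern taxonomy
#'
#' The taxonomy distinguishes episodes by whether the deterioration and the
#' repair each comprise one session or more: pattern 1 ("jump in - jump
#' out", the simple V-shape), pattern 2 ("jump in - slide out"), pattern 3
#' ("slide in - jump out"), pattern 4 ("slide in - slide out") and pattern
#' 5 ("complex": two or more threshold-reaching declines separated by a
#' direction change before the repair). Slides (patterns 3 and 4) carry a
#' subtype: `b` when at least one single step inside the decline is itself
#' a jump (a step whose magnitude reaches the detection threshold), `a`
#' when the decline is gradual throughout. Repairs are not subdivided.
#'
#' An unrepaired episode (open at the end of the course) is labelled from
#' its decline shape alone — `1` for a one-session decline, `3a`/`3b` for a
#' slide — and is distinguished by its `repaired = FALSE` flag, not by a
#' separate class.
#'
#' @param episode One row of the episode table produced by
#'   [detect_crisis_repair()] (a list or one-row data frame with
#'   `start_session`, `trough_session`, `decline_length`, `repair_length`,
#'   `repaired`, `n_declines`).
#' @param course The [course()] the episode was detected on (used to test
#'   steps inside the decline against the jump threshold).
#' @param threshold The detection threshold the episode was found at; also
#'   used as the jump size defining subtype `b` (override via
#'   `jump_threshold`).
#' @param jump_threshold Step magnitude that counts as a jump inside a
#'   slide; defaults to `threshold`.
#' @return A single label, one of `"1"`, `"2"`, `"3a"`, `"3b"`, `"4a"`,
#'   `"4b"`, `"5"`.
#' @export
classify_episode <- function(episode, course, threshold,
                             jump_threshold = threshold) {
  course <- as_course(course)
  st <- episode$start_session
  tr <- episode$trough_session
  if (is.na(st) || is.na(tr) || st < 1L || tr > length(course$values) || st >= tr)
    stop("episode is inconsistent with the course (start ", st,
         ", trough ", tr, ")", call. = FALSE)
  if (!is.null(episode$n_declines) && !is.na(episode$n_declines) &&
      episode$n_declines >= 2L)
    return("5")
  dl <- episode$decline_length
  rl <- if (isTRUE(episode$repaired)) episode$repair_length else NA_integer_
  if (dl == 1L)
    return(if (is.na(rl) || rl == 1L) "1" else "2")
  steps <- diff(course$values[st:tr])
  jump <- any(-steps >= jump_threshold)
  base <- if (is.na(rl) || rl == 1L) "3" else "4"
  paste0(base, if (jump) "b" else "a")
}

#' Classify all episodes of a detection run
#'
#' Vectorised wrapper around [classify_episode()]: adds a `pattern` column
#' to an episode table.
#'
#' @param episodes Episode data frame (as from [detect_crisis_repair()]),
#'   possibly spanning several courses.
#' @param courses An [course_set()] (or single course) containing every
#'   course the episodes refer to.
#' @param threshold Either a single detection threshold or a named vector
#'   with one threshold per course id.
#' @inheritParams classify_episode
#' @return `episodes` with a `pattern` column (factor with levels
#'   `1, 2, 3a, 3b, 4a, 4b, 5`).
#' @export
classify_episodes <- function(episodes, courses, threshold,
                              jump_threshold = NULL) {
  courses <- as_course_set(courses)
  n <- nrow(episodes)
  pat <- character(n)
  for (i in seq_len(n)) {
    id <- as.character(episodes$course_id[i])
    if (!id %in% names(courses))
      stop("episode refers to unknown course '", id, "'", call. = FALSE)
    thr <- if (length(threshold) > 1L || !is.null(names(threshold)))
      threshold[[id]] else threshold
    jt <- if (is.null(jump_threshold)) thr else jump_threshold
    pat[i] <- classify_episode(as.list(episodes[i, ]), courses[[id]], thr, jt)
  }
  episodes$pattern <- factor(pat, levels = pattern_levels)
  episodes
}

#' Summarise classified crisis-repair episodes
#'
#' Produces the frequency distribution of the five patterns (with 3a/3b and
#' 4a/4b subtypes), the number of courses contributing at least one episode
#' of each pattern, and the length statistics of the episodes: histograms
#' of decline and repair lengths, and mean decline, repair and whole-episode
#' lengths in sessions. Complex episodes (pattern 5) are excluded from all
#' length calculations, and unrepaired episodes from the repair-length ones.
#' Percentages are rounded to one decimal, halves away from zero.
#'
#' @param episodes Classified episode table (see [classify_episodes()]).
#' @param n_courses Number of courses the episodes were detected over
#'   (defaults to the number of distinct course ids present; supply it
#'   explicitly so that courses without episodes are counted).
#' @return A list of class `"cre_summary"`: `counts`, `percentages`
#'   (per label and per pattern group), `courses_with_episode`,
#'   `decline_length_dist`, `repair_length_dist`, `mean_decline_length`,
#'   `mean_repair_length`, `mean_episode_length`, `n_episodes`,
#'   `n_courses`, `empty`.
#' @examples
#' # counts -> percentage arithmetic on a hand-made table
#' eps <- data.frame(course_id = "A", decline_length = 1, repair_length = 1,
#'                   repaired = TRUE, n_declines = 1,
#'                   pattern = factor("1", levels = c("1","2","3a","3b","4a","4b","5")))
#' summarize_episodes(eps)$percentages
#' @export
summarize_episodes <- function(episodes, n_courses = NULL) {
  if (is.null(episodes$pattern))
    stop("episodes must be classified first (see classify_episodes())",
         call. = FALSE)
  pat <- factor(as.character(episodes$pattern), levels = pattern_levels)
  counts <- table(pat)
  total <- sum(counts)
  grp <- c(`1` = counts[["1"]], `2` = counts[["2"]],
           `3` = counts[["3a"]] + counts[["3b"]],
           `3a` = counts[["3a"]], `3b` = counts[["3b"]],
           `4` = counts[["4a"]] + counts[["4b"]],
           `4a` = counts[["4a"]], `4b` = counts[["4b"]],
           `5` = counts[["5"]])
  pct <- if (total > 0) round_half_up(100 * grp / total, 1) else grp * 0
  cw <- vapply(names(grp), function(g) {
    sel <- if (g %in% c("3", "4"))
      startsWith(as.character(pat), g) else as.character(pat) == g
    length(unique(episodes$course_id[sel]))
  }, numeric(1L))
  simple <- as.character(pat) != "5"
  dl <- episodes$decline_length[simple]
  rl <- episodes$repair_length[simple & episodes$repaired]
  el <- (episodes$decline_length + episodes$repair_length)[simple & episodes$repaired]
  structure(list(counts = counts,
                 group_counts = grp,
                 percentages = pct,
                 courses_with_episode = cw,
                 decline_length_dist = table(factor(dl, levels = seq_len(max(dl, 1L)))),
                 repair_length_dist = table(factor(rl, levels = seq_len(max(rl, 1L)))),
                 mean_decline_length = if (length(dl)) mean(dl) else NA_real_,
                 mean_repair_length = if (length(rl)) mean(rl) else NA_real_,
                 mean_episode_length = if (length(el)) mean(el) else NA_real_,
                 n_episodes = total,
                 n_courses = if (is.null(n_courses))
                   length(unique(episodes$course_id)) else n_courses,
                 empty = total == 0L),
            class = "cre_summary")
}

#' @export
print.cre_summary <- function(x, ...) {
  cat("Crisis-repair episode summary: ", x$n_episodes, " episode(s) over ",
      x$n_courses, " course(s)\n", sep = "")
  if (x$empty) {
    cat("  (no episodes; percentages undefined, reported as 0)\n")
    return(invisible(x))
  }
  print(pattern_table(x))
  cat("mean decline length ", format(x$mean_decline_length, digits = 3),
      ", mean repair length ", format(x$mean_repair_length, digits = 3),
      ", mean episode length ", format(x$mean_episode_length, digits = 3),
      " sessions (complex episodes excluded)\n", sep = "")
  invisible(x)
}

#' Pattern-frequency table
#'
#' Lays a [summarize_episodes()] result out as a compact table: one column
#' per pattern (3 and 4 with their a/b subtypes), rows for total episode
#' counts, percentages, and courses with at least one episode.
#'
#' @param summary A `cre_summary`.
#' @return A data frame with row names `total`, `percent`,
#'   `courses_with_episode`.
#' @export
pattern_table <- function(summary) {
  stopifnot(inherits(summary, "cre_summary"))
  cols <- c("1", "2", "3", "3a", "3b", "4", "4a", "4b", "5")
  out <- rbind(total = summary$group_counts[cols],
               percent = summary$percentages[cols],
               courses_with_episode = summary$courses_with_episode[cols])
  out <- as.data.frame(out)
  names(out) <- c("P1", "P2", "P3", "P3a", "P3b", "P4", "P4a", "P4b", "complex")
  out
}
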