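classify_on <- function(values, thr) {
  crs <- course(values)
  det <- detect_crisis_repair(crs, make_profile(thr), 1)
  classify_episodes(det$episodes, crs, thr)
}

test_that("the five pattern definitions are honoured", {
  # jump in - jump out (V-shape)
  expect_identical(as.character(classify_on(c(60, 20, 60, 60), 20)$pattern), "1")
  # jump in - slide out
  expect_identical(as.character(classify_on(c(60, 10, 35, 60), 20)$pattern), "2")
  # slide in without a jump - jump out
  expect_identical(as.character(classify_on(c(60, 45, 30, 60), 20)$pattern), "3a")
  # slide in including a jump (middle step reaches the threshold) - jump out
  expect_identical(as.character(classify_on(c(60, 50, 25, 20, 60), 15)$pattern), "3b")
  # slide in - slide out, no jump
  expect_identical(as.character(classify_on(c(60, 45, 30, 15, 30, 45), 20)$pattern), "4a")
  # complex: two threshold-reaching declines before the repair
  expect_identical(as.character(classify_on(c(60, 30, 38, 10, 40, 60), 20)$pattern), "5")
})

test_that("an episode record with a two-session decline and repair is 4a", {
  # definition-table check on a hand-made episode (decline 2, repair 2,
  # every step below the threshold)
  crs <- course(c(60, 52, 44, 52, 60))
  ep <- list(start_session = 1L, trough_session = 3L, decline_length = 2L,
             repair_length = 2L, repaired = TRUE, n_declines = 1L)
  expect_identical(classify_episode(ep, crs, 15), "4a")
  # same shape with a jump inside the decline is 4b
  crs <- course(c(60, 55, 25, 40, 60))
  ep$trough_session <- 3L
  expect_identical(classify_episode(ep, crs, 15), "4b")
})

test_that("unrepaired episodes are labelled from their decline shape", {
  eps <- classify_on(c(60, 60, 20, 25), 30)
  expect_false(eps$repaired)
  expect_identical(as.character(eps$pattern), "1")
  eps <- classify_on(c(60, 45, 30, 15, 19), 40)
  expect_false(eps$repaired)
  expect_identical(as.character(eps$pattern), "3a")
})

test_that("classification is total, exclusive, and shift-invariant", {
  set.seed(141)
  for (i in 1:60) {
    v <- sample(seq(0, 100, 10), sample(5:35, 1), replace = TRUE)
    crs <- course(v)
    thr <- max(intra_sd(crs), 1)
    det <- detect_crisis_repair(crs, make_profile(thr), 1)
    eps <- classify_episodes(det$episodes, crs, thr)
    expect_false(anyNA(eps$pattern))
    shift <- course(v + 250)
    det2 <- detect_crisis_repair(shift, make_profile(thr), 1)
    eps2 <- classify_episodes(det2$episodes, shift, thr)
    expect_identical(as.character(eps$pattern), as.character(eps2$pattern))
    # complex label iff two or more qualifying declines
    expect_identical(eps$pattern == "5", eps$n_declines >= 2L)
  }
})

test_that("episode counts turn into the printed percentages", {
  # 12 + 2 + 17 (4, 13) + 3 (1, 2) + 1 = 35 episodes
  labs <- rep(c("1", "2", "3a", "3b", "4a", "4b", "5"),
              times = c(12, 2, 4, 13, 1, 2, 1))
  eps <- data.frame(course_id = rep_len(sprintf("C%02d", 1:9), length(labs)),
                    decline_length = 1L, repair_length = 1L, repaired = TRUE,
                    n_declines = 1L,
                    pattern = factor(labs, levels = c("1", "2", "3a", "3b",
                                                      "4a", "4b", "5")))
  s <- summarize_episodes(eps, n_courses = 10)
  expect_identical(s$n_episodes, 35L)
  expect_equal(unname(s$percentages[c("1", "2", "3", "4", "5")]),
               c(34.3, 5.7, 48.6, 8.6, 2.9))
  expect_equal(unname(s$percentages[c("3a", "3b", "4a", "4b")]),
               c(11.4, 37.1, 2.9, 5.7))
  tab <- pattern_table(s)
  expect_identical(unname(unlist(tab["total", c("P1", "P2", "P3", "P4", "complex")])),
                   c(12, 2, 17, 3, 1))
})

test_that("percentage rounding is half away from zero at one decimal", {
  r <- crisisrepair:::round_half_up
  expect_identical(r(2.85, 1), 2.9)
  expect_identical(r(2.84, 1), 2.8)
  expect_identical(r(c(34.285714, 5.714286, 48.571429) , 1), c(34.3, 5.7, 48.6))
})

test_that("an empty episode set summarises to zero counts with a flag", {
  eps <- data.frame(course_id = character(0), decline_length = integer(0),
                    repair_length = integer(0), repaired = logical(0),
                    n_declines = integer(0),
                    pattern = factor(character(0),
                                     levels = c("1", "2", "3a", "3b",
                                                "4a", "4b", "5")))
  s <- summarize_episodes(eps, n_courses = 4)
  expect_true(s$empty)
  expect_identical(sum(s$counts), 0L)
  expect_equal(sum(s$percentages), 0)
})

test_that("length accounting excludes complex episodes", {
  labs <- c("1", "3a", "5")
  eps <- data.frame(course_id = c("A", "A", "B"),
                    decline_length = c(1L, 3L, 6L),
                    repair_length = c(1L, 1L, 2L),
                    repaired = TRUE, n_declines = c(1L, 1L, 2L),
                    pattern = factor(labs, levels = c("1", "2", "3a", "3b",
                                                      "4a", "4b", "5")))
  s <- summarize_episodes(eps)
  expect_equal(s$mean_decline_length, 2)     # (1 + 3) / 2, pattern 5 excluded
  expect_equal(s$mean_repair_length, 1)
  expect_equal(s$mean_episode_length, 3)     # decline + repair for the simple pair
  expect_equal(s$mean_episode_length,
               s$mean_decline_length + s$mean_repair_length)
})

test_that("summarising a planted pattern mix recovers the planted counts", {
  thr <- 40
  specs <- c(rep("1", 5), rep("3b", 5))
  courses <- lapply(seq_along(specs), function(i) {
    spec <- generator_spec(20, planted = planted_episode(specs[i], 5),
                           noise_sd = 0, threshold_ref = thr, seed = i)
    generate_course(spec, course_id = paste0("G", i))$course
  })
  cs <- course_set(courses)
  all_eps <- do.call(rbind, lapply(courses, function(cr) {
    det <- detect_crisis_repair(cr, make_profile(thr), 1)
    classify_episodes(det$episodes, cr, thr)
  }))
  s <- summarize_episodes(all_eps, n_courses = 10)
  expect_identical(as.integer(s$counts[c("1", "3b")]), c(5L, 5L))
  expect_identical(s$n_episodes, 10L)
})
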