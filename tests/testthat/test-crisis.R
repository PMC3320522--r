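test_that("run segmentation follows the constant-value convention", {
  # one direction change
  runs <- segment_runs(c(60, 55, 50, 45, 40, 60))
  expect_identical(runs$kind, c("decline", "incline"))
  expect_identical(runs$start_session, c(1L, 5L))
  expect_identical(runs$end_session, c(5L, 6L))
  expect_equal(runs$cumulative_change, c(-20, 20))
  # an all-constant course is a single degenerate decline run
  runs <- segment_runs(c(50, 50, 50))
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$kind, "decline")
  expect_equal(runs$cumulative_change, 0)
  # a constant step inside a decline belongs to the decline
  runs <- segment_runs(c(60, 55, 55, 40, 70))
  expect_identical(runs$kind, c("decline", "incline"))
  expect_identical(runs$end_session, c(4L, 5L))
  expect_equal(runs$cumulative_change, c(-20, 30))
})

test_that("runs partition the course and reproduce its steps", {
  set.seed(91)
  for (i in 1:50) {
    v <- sample(seq(0, 100, 10), sample(3:30, 1), replace = TRUE)
    runs <- segment_runs(v)
    expect_identical(runs$start_session[1], 1L)
    expect_identical(runs$end_session[nrow(runs)], length(v))
    if (nrow(runs) > 1)
      expect_identical(runs$start_session[-1], runs$end_session[-nrow(runs)])
    expect_equal(sum(runs$cumulative_change), v[length(v)] - v[1])
    # decline runs never rise, incline runs always rise
    expect_true(all(runs$cumulative_change[runs$kind == "decline"] <= 0))
    expect_true(all(runs$cumulative_change[runs$kind == "incline"] > 0))
  }
})

test_that("a gradual slide invisible to single steps is one episode", {
  det <- detect_crisis_repair(course(c(60, 55, 50, 45, 40, 60)),
                              make_profile(15), 1)
  eps <- det$episodes
  expect_identical(nrow(eps), 1L)
  expect_identical(eps$start_session, 1L)
  expect_identical(eps$trough_session, 5L)
  expect_identical(eps$repair_session, 6L)
  expect_equal(eps$rupture_magnitude, 20)
  expect_identical(eps$decline_length, 4L)
  expect_identical(eps$repair_length, 1L)
  expect_true(eps$repaired)
})

test_that("single-step V and degenerate courses behave as defined", {
  eps <- detect_crisis_repair(course(c(60, 40, 60)), make_profile(15), 1)$episodes
  expect_identical(nrow(eps), 1L)
  expect_identical(c(eps$decline_length, eps$repair_length), c(1L, 1L))
  # constant course: cumulative decline 0 never reaches a positive threshold
  eps <- detect_crisis_repair(course(rep(70, 8)), make_profile(15), 1)$episodes
  expect_identical(nrow(eps), 0L)
})

test_that("repair needs an upward step and uses the inclusive band", {
  # recovery to exactly start - threshold repairs
  eps <- detect_crisis_repair(course(c(60, 10, 30, 30)), make_profile(30), 1)$episodes
  expect_identical(eps$repair_session, 3L)
  # a decline of exactly threshold depth is not repaired at its own trough
  eps <- detect_crisis_repair(course(c(60, 30, 30, 35)), make_profile(30), 1)$episodes
  expect_identical(nrow(eps), 1L)
  expect_identical(eps$trough_session, 3L)   # trailing constant joins the rupture
  expect_identical(eps$repair_session, 4L)
  expect_identical(eps$decline_length, 2L)
  # unrepaired at course end is reported, not dropped
  eps <- detect_crisis_repair(course(c(60, 20, 25)), make_profile(30), 1)$episodes
  expect_identical(nrow(eps), 1L)
  expect_false(eps$repaired)
  expect_true(is.na(eps$repair_session))
})

test_that("leading constants attach to the rupture and shift its start", {
  eps <- detect_crisis_repair(course(c(60, 60, 20, 60)), make_profile(30), 1)$episodes
  expect_identical(eps$start_session, 2L)
  expect_true(eps$leading_constant)
  expect_identical(eps$decline_length, 1L)
})

test_that("interrupted declines merge into one complex episode", {
  # two qualifying declines separated by a non-repairing partial recovery
  v <- c(60, 30, 38, 10, 40, 60)
  eps <- detect_crisis_repair(course(v), make_profile(20), 1)$episodes
  expect_identical(nrow(eps), 1L)
  expect_identical(eps$n_declines, 2L)
  expect_identical(eps$start_session, 1L)
  expect_identical(eps$trough_session, 4L)
  expect_identical(eps$repair_session, 5L)
  expect_equal(eps$rupture_magnitude, 50)
})

test_that("scan output equals the literal cumulative-decline oracle", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:25, 1)
    v <- sample(seq(0, 100, 20), n, replace = TRUE)
    thr <- sample(c(20, 40, 60), 1)
    m <- crisisrepair:::crisis_scan(v, thr)
    o <- oracle_crisis(v, thr)
    expect_identical(nrow(m), nrow(o))
    if (nrow(m)) {
      expect_equal(m[, c(1, 2, 4, 5)], o[, c(1, 2, 4, 5)], ignore_attr = TRUE)
      expect_equal(m[, 3], o[, 3], ignore_attr = TRUE)
    }
  }
})

test_that("episodes at 2 SD nest within episodes at 1 SD", {
  # nesting is by decline-run identity: the opening decline of every 2-SD
  # episode lies inside the span of some 1-SD episode (the narrower repair
  # band at 1 SD can merge neighbouring declines, so start sessions may
  # differ between the two runs)
  set.seed(111)
  for (i in 1:100) {
    v <- sample(seq(0, 100, 10), sample(5:35, 1), replace = TRUE)
    crs <- course(v)
    prof <- make_profile(intra_sd(crs) / 2)  # keep both thresholds reachable
    e1 <- detect_crisis_repair(crs, prof, 1)$episodes
    e2 <- detect_crisis_repair(crs, prof, 2)$episodes
    if (nrow(e2)) {
      expect_gt(nrow(e1), 0L)
      ends1 <- ifelse(is.na(e1$repair_session), length(v), e1$repair_session)
      for (k in seq_len(nrow(e2))) {
        expect_true(any(e1$start_session <= e2$start_session[k] &
                          ends1 >= e2$trough_session[k]))
      }
    }
  }
})

test_that("every Strauss-sized step lies inside a crisis-repair episode", {
  set.seed(121)
  for (i in 1:100) {
    v <- sample(seq(0, 100, 10), sample(5:35, 1), replace = TRUE)
    thr <- sample(c(30, 50), 1)
    d <- diff(v)
    big <- which(-d >= thr)
    eps <- crisisrepair:::crisis_scan(v, thr)
    ends <- ifelse(is.na(eps[, 3]), length(v), eps[, 3])
    for (s in big)
      expect_true(any(eps[, 1] <= s & ends >= s + 1))
  }
})

test_that("episode geometry is invariant under value shifts", {
  set.seed(131)
  for (i in 1:50) {
    v <- sample(seq(0, 100, 10), sample(5:30, 1), replace = TRUE)
    shift <- runif(1, -500, 500)
    a <- crisisrepair:::crisis_scan(v, 35)
    b <- crisisrepair:::crisis_scan(v + shift, 35)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("crisis-repair inputs are validated", {
  expect_error(detect_crisis_repair(course(c(60, 20, 60)), make_profile(20), 3),
               "multiplier")
  expect_error(detect_crisis_repair(course(c(60, 20, 60)), make_profile(0), 1),
               "threshold")
  expect_error(detect_crisis_repair(course(c(60, 20, 60)), list(intra = 5), 1),
               "profile")
})
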