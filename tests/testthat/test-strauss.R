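strauss_cfg <- function(match_repair_to_rupture = FALSE,
                        aggregate_consecutive = FALSE) {
  strauss_config("modified", threshold_source = "intra_only", multiplier = 1,
                 drop_exclusion = TRUE,
                 match_repair_to_rupture = match_repair_to_rupture,
                 aggregate_consecutive = aggregate_consecutive)
}

test_that("a single deep V gives one paired episode", {
  det <- detect_strauss(course(c(50, 50, 10, 50, 50)), make_profile(20),
                        strauss_cfg())
  eps <- det$episodes
  expect_identical(nrow(eps), 1L)
  expect_identical(eps$rupture_start_session, 2L)
  expect_identical(eps$trough_session, 3L)
  expect_identical(eps$repair_session, 4L)
  expect_equal(eps$rupture_magnitude, 40)
  expect_equal(eps$repair_magnitude, 40)
})

test_that("a strictly increasing course has no ruptures", {
  det <- detect_strauss(course(seq(10, 90, by = 10)), make_profile(20),
                        strauss_cfg())
  expect_identical(nrow(det$episodes), 0L)
  expect_false(det$excluded)
})

test_that("end-unrepaired courses are excluded originally, kept when modified", {
  v <- c(80, 30, 80, 80, 20)
  prof <- make_profile(10, inter = 30, mode = "inter_only")
  orig <- detect_strauss(course(v), prof, strauss_config("original"))
  expect_true(orig$excluded)
  expect_identical(nrow(orig$episodes), 0L)
  expect_match(orig$reason, "unrepaired")
  mod <- detect_strauss(course(v), make_profile(30), strauss_cfg())
  expect_identical(nrow(mod$episodes), 2L)
  expect_identical(mod$episodes$repaired, c(TRUE, FALSE))
  expect_identical(mod$episodes$rupture_start_session, c(1L, 4L))
  # an unrepaired rupture followed by a repaired one does not exclude
  v2 <- c(80, 40, 50, 10, 60)
  orig2 <- detect_strauss(course(v2), make_profile(10, 30, "inter_only"),
                          strauss_config("original"))
  expect_false(orig2$excluded)
  expect_identical(orig2$episodes$repaired, c(FALSE, TRUE))
})

test_that("matched repair demands the full rupture magnitude for deep ruptures", {
  v <- c(50, 26, 38, 50)
  base <- make_profile(10)
  plain <- detect_strauss(course(v), base, strauss_cfg())
  expect_identical(plain$episodes$repair_session, 3L)
  matched <- detect_strauss(course(v), base,
                            strauss_cfg(match_repair_to_rupture = TRUE))
  expect_identical(matched$episodes$repair_session, 4L)
  expect_equal(matched$episodes$repair_magnitude, 24)
  # a shallow (< 2 SD) rupture still repairs by a single 1-SD step
  v <- c(50, 35, 46, 48)
  matched <- detect_strauss(course(v), base,
                            strauss_cfg(match_repair_to_rupture = TRUE))
  expect_identical(matched$episodes$repair_session, 3L)
})

test_that("consecutive threshold-reaching decreases aggregate into one rupture", {
  v <- c(60, 45, 30, 60)
  sep <- detect_strauss(course(v), make_profile(15), strauss_cfg())
  expect_identical(nrow(sep$episodes), 2L)
  agg <- detect_strauss(course(v), make_profile(15),
                        strauss_cfg(aggregate_consecutive = TRUE))
  expect_identical(nrow(agg$episodes), 1L)
  expect_equal(agg$episodes$rupture_magnitude, 30)
  expect_identical(agg$episodes$trough_session, 3L)
  expect_identical(agg$episodes$repair_session, 4L)
  # sub-threshold decreases never aggregate into a rupture
  v <- c(60, 52, 44, 36, 60)
  agg <- detect_strauss(course(v), make_profile(15),
                        strauss_cfg(aggregate_consecutive = TRUE))
  expect_identical(nrow(agg$episodes), 0L)
})

test_that("scan output equals the literal step-rule oracle", {
  set.seed(61)
  for (i in 1:300) {
    n <- sample(3:20, 1)
    v <- sample(seq(0, 100, 20), n, replace = TRUE)
    thr <- sample(c(20, 40), 1)
    agg <- i %% 2 == 0; mr <- i %% 3 == 0
    m <- crisisrepair:::strauss_scan(v, thr, thr, agg, mr)
    o <- oracle_strauss(v, thr, thr, aggregate = agg, match_repair = mr)
    expect_identical(nrow(m), nrow(o))
    if (nrow(m)) {
      expect_equal(m[, 1:2], o[, 1:2], ignore_attr = TRUE)
      expect_equal(m[, 3], o[, 3], ignore_attr = TRUE)
      expect_equal(m[, 4], o[, 4], ignore_attr = TRUE)
    }
  }
})

test_that("episodes at 2 SD are a subset of episodes at 1 SD", {
  set.seed(71)
  for (i in 1:100) {
    v <- sample(seq(0, 100, 10), sample(5:35, 1), replace = TRUE)
    m1 <- crisisrepair:::strauss_scan(v, 15)
    m2 <- crisisrepair:::strauss_scan(v, 30)
    expect_true(all(m2[, 1] %in% m1[, 1]))
  }
})

test_that("aggregated rupture runs are maximal (never adjacent)", {
  set.seed(81)
  for (i in 1:100) {
    v <- sample(seq(0, 100, 25), sample(5:25, 1), replace = TRUE)
    m <- crisisrepair:::strauss_scan(v, 25, aggregate = TRUE)
    if (nrow(m) > 1)
      expect_true(all(m[-1, 1] > m[-nrow(m), 2]))
  }
})

test_that("strauss configuration and profile consistency are enforced", {
  expect_error(strauss_config("original", multiplier = 2), "original")
  expect_error(strauss_config("modified", multiplier = 3), "1 or 2")
  expect_error(detect_strauss(course(c(60, 10, 60)), make_profile(20),
                              strauss_config("original")),
               "does not match")
})
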