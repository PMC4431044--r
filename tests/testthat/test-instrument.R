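test_that("total score sums all applicable items for both variants", {
  expect_identical(total_score(uniform_rating("s", 1)), 11L)
  expect_identical(total_score(uniform_rating("s", 7)), 77L)
  expect_identical(total_score(uniform_rating("s", 7, has_control = FALSE)),
                   70L)
  # mixed responses
  r <- study_rating("s", setNames(c(1:7, 7:4), 1:11), TRUE)
  expect_identical(total_score(r), sum(c(1:7, 7:4)))
})

test_that("rating validation names the offending item and enforces completeness", {
  expect_error(study_rating("s", setNames(c(rep(4, 10), 9), 1:11), TRUE),
               "item 11")
  expect_error(study_rating("s", setNames(rep(4, 10), 1:10), TRUE),
               "missing response for item 11")
  # item 3 may be omitted only without a control group
  expect_silent(study_rating("s", setNames(rep(4, 10), setdiff(1:11, 3)),
                             FALSE))
  expect_error(study_rating("s", setNames(rep(4, 10), setdiff(1:11, 3)),
                            TRUE), "item 3")
  # item 3 present without control group: ignored with a warning at scoring
  r <- study_rating("s", setNames(rep(4, 11), 1:11), FALSE)
  expect_warning(sc <- total_score(r), "item 3")
  expect_identical(sc, 40L)
})

test_that("classification matches the published interval definitions", {
  wc <- cutpoint_scheme("with_control")
  expect_equal(as.character(classify(35, wc)), "low")
  expect_equal(as.character(classify(36, wc)), "moderate")
  expect_equal(as.character(classify(45, wc)), "moderate")
  expect_equal(as.character(classify(46, wc)), "high")
  nc <- cutpoint_scheme("without_control")
  expect_equal(as.character(classify(32, nc)), "low")
  expect_equal(as.character(classify(40, nc)), "moderate")
  expect_equal(as.character(classify(41, nc)), "high")
  expect_error(classify(10, wc), "achievable range")
  expect_error(classify(78, wc), "achievable range")
})

test_that("classify partitions each achievable range into three non-empty contiguous intervals", {
  for (variant in c("with_control", "without_control")) {
    sch <- cutpoint_scheme(variant)
    rng <- score_range(variant)
    cls <- classify(seq(rng[1], rng[2]), sch)
    expect_setequal(as.character(unique(cls)), c("low", "moderate", "high"))
    # ordered and contiguous: class index never decreases
    expect_true(all(diff(as.integer(cls)) >= 0))
  }
})

test_that("raising one response raises the total by exactly the difference", {
  set.seed(41)
  for (rep in 1:20) {
    vals <- sample(1:6, 11, replace = TRUE)
    r <- study_rating("s", setNames(vals, 1:11), TRUE)
    j <- sample(1:11, 1)
    bump <- sample(seq_len(7 - vals[j]), 1)
    vals2 <- vals; vals2[j] <- vals[j] + bump
    r2 <- study_rating("s", setNames(vals2, 1:11), TRUE)
    expect_identical(total_score(r2) - total_score(r), as.integer(bump))
  }
})

test_that("with- and without-control totals agree after removing item 3", {
  set.seed(42)
  for (rep in 1:20) {
    vals <- sample(1:7, 11, replace = TRUE)
    with_cg <- study_rating("s", setNames(vals, 1:11), TRUE)
    without <- study_rating("s", setNames(vals[-3], setdiff(1:11, 3)), FALSE)
    expect_identical(total_score(with_cg) - vals[3], total_score(without))
  }
})

test_that("batch scoring reports the class distribution", {
  # 8 low (score 33), 17 moderate (44), 5 high (55)
  ratings <- c(lapply(1:8, function(i) uniform_rating(paste0("L", i), 3)),
               lapply(1:17, function(i) uniform_rating(paste0("M", i), 4)),
               lapply(1:5, function(i) uniform_rating(paste0("H", i), 5)))
  out <- batch_score(ratings)
  expect_equal(nrow(out), 30)
  s <- attr(out, "summary")
  expect_equal(s$n, c(8L, 17L, 5L))
  expect_equal(s$percent, c(8, 17, 5) / 30 * 100, tolerance = 1e-12)
  expect_equal(round(s$percent, 1), c(26.7, 56.7, 16.7))
})

test_that("batch scoring handles the degenerate collections", {
  empty <- batch_score(list())
  expect_equal(nrow(empty), 0)
  expect_null(attr(empty, "summary"))
  one <- batch_score(list(uniform_rating("only", 6)))
  expect_equal(nrow(one), 1)
  s1 <- attr(one, "summary")
  expect_equal(s1$percent[s1$quality == as.character(one$quality)], 100)
  expect_equal(sum(s1$n), 1L)
  expect_error(batch_score(list(uniform_rating("a", 3), uniform_rating("a", 4))),
               "duplicate study_id")
})

test_that("item definitions satisfy the instrument invariants", {
  items <- qgenie_items()
  expect_identical(items$item_id, 1:11)
  expect_identical(which(items$requires_control_group), 3L)
  expect_true(all(nzchar(items$stem)))
})

test_that("cut-point schemes are validated", {
  expect_error(cutpoint_scheme("with_control", 45, 35), "strictly below")
  expect_error(cutpoint_scheme("with_control", 5, 45), "achievable range")
  custom <- cutpoint_scheme("with_control", 30, 50)
  expect_equal(as.character(classify(31, custom)), "moderate")
})
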