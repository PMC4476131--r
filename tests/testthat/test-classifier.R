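reg <- load_registry()

test_that("match_code compares phase exactly and codon within tolerance", {
  expect_true(match_code("88a", c("86a", "88a", "90a"), 0))
  expect_true(match_code("167a", "167a", 0))
  expect_false(match_code("167c", "167a", 2))  # letter mismatch never matches
  expect_true(match_code("165a", "167a", 2))
  expect_false(match_code("164a", "167a", 2))
  # approximate observation widens the window by 2
  expect_true(match_code("164a~", "167a", 2))
  expect_false(match_code("161a~", "167a", 2))
  expect_error(match_code("167a", "167a", -1))
})

test_that("printed signature sets classify to their groups", {
  expect_identical(classify(c("78c", "128c", "167a", "212c", "262c"),
                            reg)$group, "V1")
  expect_identical(classify(c("78c", "128c", "167a", "212c", "262c"),
                            reg)$subgroup, "V1b")
  v1a <- classify(c("85c", "78c", "128c", "167a", "212c", "262c"), reg)
  expect_identical(v1a$group, "V1")
  expect_identical(v1a$subgroup, "V1a")
  expect_identical(classify(c("67a", "123a", "192a", "238c", "307a"),
                            reg)$group, "V4")
  expect_identical(classify(c("192a", "225a", "300c"), reg)$group, "V6")
})

test_that("fish-specific gains are annotated, not penalized", {
  call <- classify(c("192a", "282b", "331c", "241c"), reg)
  expect_identical(call$group, "V2")
  expect_identical(unname(call$fish_specific_hits), "241c")
  expect_match(names(call$fish_specific_hits), "HCII")
  expect_length(call$extra, 0L)
  # score unchanged by the explained gain
  expect_equal(call$score, classify(c("192a", "282b", "331c"), reg)$score)
})

test_that("degenerate inputs give ambiguous or unclassified calls", {
  amb <- classify("192a", reg)
  expect_identical(amb$group, "ambiguous")
  expect_true(all(c("V2", "V4", "V6") %in% amb$candidates$group))
  expect_identical(classify(character(0), reg)$group, "unclassified")
})

test_that("a six-code set with no positional support falls through to V5", {
  codes <- c("10a", "20b", "30c", "40a", "50b", "60c")
  call <- classify(codes, reg)
  expect_identical(call$group, "V5")
  expect_true(call$v5_by_count)
  # with user-supplied V5 positions the call becomes positional
  reg5 <- load_registry(v5_positions = codes)
  pos <- classify(codes, reg5)
  expect_identical(pos$group, "V5")
  expect_false(pos$v5_by_count)
  expect_equal(pos$score, 6)
})

test_that("matched and missing partition the winning required set", {
  codes <- c("78c", "128c", "167a")
  call <- classify(codes, reg)
  expect_identical(call$group, "V1")
  expect_setequal(c(call$matched, call$missing),
                  c("78c", "128c", "167a", "212c", "262c"))
  expect_length(intersect(call$matched, call$missing), 0L)
  expect_length(intersect(call$extra, call$matched), 0L)
})

test_that("every registry signature round-trips with a full score", {
  for (g in c("V1", "V2", "V3", "V4", "V6")) {
    sig <- reg$signatures[[g]]
    codes <- vapply(sig$required, `[[`, "", 1L)
    call <- classify(codes, reg)
    expect_identical(call$group, g)
    expect_length(call$missing, 0L)
    expect_length(call$extra, 0L)
    expect_equal(call$score, length(sig$required))
  }
  # each V3 first-intron alternative matches
  for (alt in c("86a", "88a", "90a")) {
    rest <- vapply(Filter(function(x) length(x) == 1L,
                          reg$signatures$V3$required), `[[`, "", 1L)
    expect_identical(classify(c(alt, rest), reg)$group, "V3")
  }
})

test_that("dropping one required code costs exactly 1.5 and keeps the group", {
  for (g in c("V1", "V2", "V3", "V4", "V6")) {
    sig <- reg$signatures[[g]]
    if (length(sig$required) < 3L) next
    codes <- vapply(sig$required, `[[`, "", 1L)
    full <- classify(codes, reg)$score
    for (drop in seq_along(codes)) {
      call <- classify(codes[-drop], reg)
      expect_identical(call$group, g)
      expect_equal(call$score, full - 1.5)
    }
  }
})

test_that("matched count is non-decreasing in tolerance", {
  set.seed(31)
  for (i in 1:20) {
    codes <- random_code_set()
    prev <- -1L
    for (tol in 0:4) {
      call <- classify(codes, reg, tolerance = tol)
      n_matched <- max(0L, call$candidates$n_matched, length(call$matched))
      best <- if (nrow(call$candidates)) max(call$candidates$n_matched) else 0L
      expect_gte(best, prev)
      prev <- best
    }
  }
})

test_that("classification is deterministic", {
  codes <- c("192a", "282b", "331c", "241c", "5a")
  expect_identical(classify(codes, reg), classify(codes, reg))
})

test_that("unexplained codes are listed as extra and penalized", {
  call <- classify(c("192a", "282b", "331c", "150b"), reg)
  expect_identical(call$group, "V2")
  expect_identical(call$extra, "150b")
  expect_equal(call$score, 3 - 0.25)
})
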