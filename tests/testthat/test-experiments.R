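# Batch simulation, metrics and comparisons.

fake_record <- function(colour, decision_time, correct, where, horizon = 8L) {
  structure(list(
    condition = list(context = "happy", emotion = "happy", type = "unambiguous",
                     colour = colour, variant = "contextualising",
                     mode = "map", label = colour),
    seed = 1L, horizon = horizon, n_steps = length(where), where = where,
    decision_time = decision_time, correct = correct,
    reported = if (is.na(decision_time)) NA_character_ else "happy"
  ), class = "trial_record")
}

test_that("batches are sized and seeded reproducibly", {
  specs <- data.frame(context = c("happy", "sad"),
                      emotion = c("happy", "sad"),
                      type = "unambiguous",
                      variant = "contextualising",
                      mode = "map",
                      stringsAsFactors = FALSE)
  a <- run_batch(specs, n = 2L, master_seed = 10L)
  b <- run_batch(specs, n = 2L, master_seed = 10L)
  expect_length(a, 4L)
  expect_equal(vapply(a, function(r) r$seed, numeric(1)), 11:14)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$where, b[[i]]$where)
    expect_identical(a[[i]]$decision_time, b[[i]]$decision_time)
  }
})

test_that("decided blue trials report the context-consistent emotion", {
  specs <- data.frame(context = c("happy", "sad"),
                      emotion = c("sad", "happy"),
                      type = "ambiguous", variant = "contextualising",
                      mode = "map", stringsAsFactors = FALSE)
  recs <- run_batch(specs, n = 5L, master_seed = 100L)
  ctx <- vapply(recs, function(r) r$condition$context, character(1))
  rep_emo <- vapply(recs, function(r) r$reported, character(1))
  decided <- !vapply(recs, function(r) is.na(r$decision_time), logical(1))
  expect_true(all(decided))
  expect_true(all(rep_emo[decided] == ctx[decided]))
  # context-consistent but factually wrong: feedback is incorrect
  expect_true(all(!vapply(recs, function(r) isTRUE(r$correct), logical(1))))
})

test_that("metrics aggregate decision times and accuracy as defined", {
  one <- list(fake_record("green", 6L, TRUE, c(1L, 4L, 6L, 2L, 3L, 8L)))
  m1 <- compute_metrics(one)
  expect_equal(m1$mean_decision_time, 6)
  expect_equal(m1$accuracy, 1)
  expect_equal(m1$n_undecided, 0L)

  two <- c(one, list(fake_record("green", 4L, FALSE, c(1L, 2L, 3L, 9L))))
  m2 <- compute_metrics(two)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$mean_decision_time, 5)

  # undecided trials leave the accuracy denominator but are censored into
  # the overall decision-time summary
  three <- c(two, list(fake_record("green", NA_integer_, NA, rep(1L, 8L))))
  m3 <- compute_metrics(three)
  expect_equal(m3$accuracy, 0.5)
  expect_equal(m3$n_undecided, 1L)
  expect_equal(m3$mean_censored_time, mean(c(6, 4, 8)))

  undecided_only <- list(fake_record("grey", NA_integer_, NA, rep(1L, 8L)))
  m4 <- compute_metrics(undecided_only)
  expect_true(is.na(m4$accuracy))
  expect_equal(m4$n, 1L)
})

test_that("identical groups compare as indistinguishable", {
  recs <- list(fake_record("green", 6L, TRUE, c(1L, 8L)),
               fake_record("green", 5L, TRUE, c(1L, 8L)))
  cmp <- compare_conditions(recs, recs, n_boot = 200L, seed = 3L)
  expect_equal(cmp$diff, 0)
  expect_true(cmp$ci[1] <= 0 && cmp$ci[2] >= 0)
  # degenerate constant samples give a zero-width interval
  const <- list(fake_record("green", 6L, TRUE, c(1L, 8L)))
  cmp2 <- compare_conditions(const, const, n_boot = 50L, seed = 1L)
  expect_equal(unname(diff(cmp2$ci)), 0)
})

test_that("scan paths export in fixation order with scene semantics", {
  rec <- fake_record("green", 6L, TRUE, c(1L, 4L, 6L, 2L, 3L, 8L))
  df <- scanpath_export(list(rec))
  expect_equal(nrow(df), 6L)
  expect_equal(df$step, 1:6)
  expect_equal(df$location, c(1L, 4L, 6L, 2L, 3L, 8L))
  expect_equal(df$quadrant[1], "centre")
  expect_equal(df$quadrant[2], "top_right")
  expect_equal(df$feature[4], "eyes")
  empty <- scanpath_export(list())
  expect_equal(nrow(empty), 0L)
  expect_equal(fixation_histogram(list(rec)),
               c(1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L, 0L))
  expect_equal(sum(fixation_histogram(list(rec))), rec$n_steps)
})

test_that("the local viewer never seeks social cues though it tolerates them", {
  # with zero precision on the context-face locations these saccades carry
  # no epistemic value, so they are never strictly preferred: the first
  # fixations go to the target face, and the policy posterior never puts
  # more mass on a context-face location than on the blank centre
  lv <- task_agent("local_viewer")
  glob <- task_agent("global_viewer")
  p <- build_generative_process("happy", "happy", "ambiguous")
  for (seed in 1:8) {
    tr <- run_trial(p, lv, mode = "map", seed = seed)
    expect_true(all(tr$where[2:3] %in% 2:3))
    ok <- which(!is.na(tr$pi_post[1L, ]))
    for (t in ok) {
      expect_true(all(tr$pi_post[4:7, t] <= tr$pi_post[1L, t] + 1e-10))
    }
    # the global viewer resolves the context first instead
    tg <- run_trial(p, glob, mode = "map", seed = seed)
    expect_true(all(tg$where[2:3] %in% 4:7))
  }
})
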