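# Structure of the mental-state-attribution task.

test_that("the scene has 144 state combinations and 5/9/3-level outcome modalities", {
  m <- build_generative_model()
  expect_equal(unname(m$n_states), c(4L, 4L, 9L))
  expect_equal(prod(m$n_states), 144)
  expect_equal(unname(m$n_out), c(5L, 9L, 3L))
  for (i in 1:3) {
    expect_equal(ncol(as_lik <- matrix(m$A[[i]], nrow = m$n_out[i])), 144)
    expect_equal(colSums(as_lik), rep(1, 144), tolerance = 1e-12)
  }
  expect_equal(nrow(m$policies), 9L)
  expect_equal(m$C[[3L]], c(0, 0.5, -10), ignore_attr = TRUE)
  # uniform context prior: the two incoherent arrangements jointly carry 0.5
  expect_equal(m$D[[1L]], rep(0.25, 4), ignore_attr = TRUE)
  expect_equal(m$D[[3L]], c(1, rep(0, 8)), ignore_attr = TRUE)
})

test_that("ground-truth likelihoods encode faces, locations and feedback", {
  p <- build_generative_process("happy", "happy", "unambiguous")
  i <- p$context_index; j <- p$target_index
  expr <- expression_levels <- c("narrow_eyelids", "pulled_eyebrows",
                                 "exposed_teeth", "covered_teeth", "null")
  # unambiguous happy target: narrow eyelids at 2, exposed teeth at 3
  expect_equal(p$A[[1L]][match("narrow_eyelids", expr), i, j, 2L], 1)
  expect_equal(p$A[[1L]][match("exposed_teeth", expr), i, j, 3L], 1)
  # null expression at fixation and report locations
  for (l in c(1L, 8L, 9L)) expect_equal(p$A[[1L]][5L, i, j, l], 1)
  # feedback is tied to the true emotion: happy -> correct at 8, incorrect at 9
  expect_equal(p$A[[3L]][2L, i, j, 8L], 1)
  expect_equal(p$A[[3L]][3L, i, j, 9L], 1)
  for (l in 1:7) expect_equal(p$A[[3L]][1L, i, j, l], 1)
  # every ground-truth column is one-hot
  for (m in 1:3) {
    M <- matrix(p$A[[m]], nrow = p$n_out[m])
    expect_true(all(apply(M, 2, max) == 1))
  }
  # sad faces/ambiguous faces at the target locations
  ps <- build_generative_process("happy", "sad", "unambiguous")
  expect_equal(ps$A[[1L]][2L, ps$context_index, ps$target_index, 2L], 1)
  expect_equal(ps$A[[1L]][4L, ps$context_index, ps$target_index, 3L], 1)
  pa <- build_generative_process("happy", "sad", "ambiguous")
  expect_equal(pa$A[[1L]][2L, pa$context_index, pa$target_index, 2L], 1)
  expect_equal(pa$A[[1L]][3L, pa$context_index, pa$target_index, 3L], 1)
  expect_equal(pa$A[[3L]][2L, pa$context_index, pa$target_index, 9L], 1)
})

test_that("the incoherent contexts are mirror arrangements of one happy and one sad face", {
  pa <- build_generative_process("incoherent_a", "happy", "ambiguous")
  pb <- build_generative_process("incoherent_b", "happy", "ambiguous")
  ia <- pa$context_index; ib <- pb$context_index; j <- pa$target_index
  # locations 4/5 and 6/7 swap face emotions between the two arrangements
  expect_equal(pa$A[[1L]][, ia, j, 4L], pb$A[[1L]][, ib, j, 6L])
  expect_equal(pa$A[[1L]][, ia, j, 5L], pb$A[[1L]][, ib, j, 7L])
  expect_false(isTRUE(all.equal(pa$A[[1L]][, ia, j, 4L], pb$A[[1L]][, ib, j, 4L])))
})

test_that("the base model's likelihoods equal the generative process's exactly", {
  m <- build_generative_model()
  p <- build_generative_process("sad", "sad", "unambiguous")
  for (i in 1:3) expect_identical(m$A[[i]], p$A[[i]])
  # saccade transitions: action a maps every location to a
  for (a in 1:9) {
    expect_equal(m$B[[3L]][a, , a], rep(1, 9), ignore_attr = TRUE)
    expect_equal(colSums(m$B[[3L]][, , a]), rep(1, 9), tolerance = 1e-12)
  }
  expect_equal(m$B[[1L]][, , 4L], diag(4), ignore_attr = TRUE)
})

test_that("agent variants only reshape the facial-expression precisions", {
  base <- build_generative_model()
  nonctx <- make_agent_variant(base, "non_contextualising")
  expect_identical(nonctx$Abar, base$Abar)
  glob <- make_agent_variant(base, "global_viewer")
  expect_identical(glob$Abar, base$Abar)

  ctx <- make_agent_variant(base, "contextualising")
  # uniform columns exactly where the context-inconsistent ambiguous
  # mappings were down-weighted, at all face locations
  i_h <- 1L; i_s <- 2L; j_ha <- 3L; j_sa <- 4L
  for (l in 2:7) {
    expect_equal(ctx$Abar[[1L]][, i_h, j_sa, l], rep(0.2, 5),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(ctx$Abar[[1L]][, i_s, j_ha, l], rep(0.2, 5),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # ... and nowhere else
  changed <- abs(ctx$Abar[[1L]] - base$Abar[[1L]]) > 1e-12
  idx <- which(changed, arr.ind = TRUE)
  expect_true(all((idx[, 2] == i_h & idx[, 3] == j_sa) |
                  (idx[, 2] == i_s & idx[, 3] == j_ha)))
  expect_true(all(idx[, 4] %in% 2:7))
  # where and feedback mappings are untouched by every variant
  lv <- make_agent_variant(base, "local_viewer")
  for (v in list(ctx, nonctx, lv)) {
    expect_identical(v$Abar[[2L]], base$Abar[[2L]])
    expect_identical(v$Abar[[3L]], base$Abar[[3L]])
  }
  # local viewer: context-face columns uniform, target columns unchanged
  for (l in 4:7) {
    M <- matrix(lv$Abar[[1L]][, , , l], nrow = 5)
    expect_true(all(abs(M - 0.2) < 1e-12))
  }
  expect_equal(lv$Abar[[1L]][, , , 2L], base$Abar[[1L]][, , , 2L])
  expect_equal(lv$Abar[[1L]][, , , 3L], base$Abar[[1L]][, , , 3L])
  expect_error(make_agent_variant(base, "contextualising", z = -1),
               "non-negative")
})

test_that("the 16 condition cells are classified by congruence and coherence", {
  cells <- enumerate_conditions()
  expect_equal(nrow(cells), 16L)
  expect_equal(sum(cells$colour == "grey"), 8L)
  expect_equal(sum(cells$colour == "green"), 2L)
  expect_equal(sum(cells$colour == "red"), 2L)
  expect_equal(sum(cells$colour == "blue"), 4L)
  expect_equal(condition_colour("happy", "happy", "unambiguous"), "green")
  expect_equal(condition_colour("sad", "happy", "unambiguous"), "red")
  expect_equal(condition_colour("sad", "sad", "ambiguous"), "blue")
  expect_equal(condition_colour("incoherent_b", "sad", "unambiguous"), "grey")
  expect_error(build_generative_process("cheerful", "happy", "ambiguous"),
               "invalid")
})
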