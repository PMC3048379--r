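test_that("single-step arithmetic matches the recursion by hand", {
  p <- model_params(A = 1, B = 0.02, E = 1, K = 1, F = 0)
  trial <- list(block = "rotation_strategy", rotation_deg = -45,
                strategy_instructed = TRUE, feedback = TRUE)
  st <- list(x_hat = 0, s = 45)
  out <- step_model(st, p, trial, "feedthrough_fixed_strategy")
  expect_equal(out$record$target_error, 0)     # strategy cancels rotation
  expect_equal(out$record$aiming_error, -45)   # feedback far from the aim
  expect_equal(out$state$x_hat, -0.9)          # B * aiming error
  expect_equal(out$record$hand_angle, 45)

  # quiescent case: nothing happens without rotation or strategy
  q <- step_model(list(x_hat = 0, s = 0), p,
                  list(block = "baseline", rotation_deg = 0,
                       strategy_instructed = FALSE, feedback = TRUE),
                  "full_dynamic")
  expect_equal(q$record$target_error, 0)
  expect_equal(q$record$aiming_error, 0)
  expect_equal(unlist(q$state), c(x_hat = 0, s = 0))

  expect_error(model_params(A = 1.2), "\\[0, 1\\]")
  expect_error(model_params(B = -0.1), "\\[0, 1\\]")
})

test_that("simulate_model agrees with step_model trial-for-trial", {
  sched <- build_paper_schedule("AT")
  p <- group_params_default("AT")
  tr <- simulate_model(sched, p, "full_dynamic")
  st <- list(x_hat = 0, s = 0)
  prev_rot <- FALSE
  for (i in seq_len(nrow(sched))) {
    b <- sched$block[i]
    # block-entry strategy engagement is a schedule-level rule
    if (b == "rotation_strategy" && !prev_rot) st$s <- p$s_star
    prev_rot <- b == "rotation_strategy"
    out <- step_model(st, p, sched[i, ], "full_dynamic")
    st <- out$state
    expect_equal(out$record$target_error, tr$target_error[i],
                 tolerance = 1e-12, label = paste("trial", i))
  }
})

test_that("standard model adapts gradually and probes show the raw rotation", {
  sched <- fig_layout()
  p <- model_params(A = 1, B = 0.02, K = 1, F = 0)
  tr <- simulate_model(sched, p, "standard")
  e_rot <- tr$target_error[121:442]
  expect_equal(e_rot[1], -45)                      # naive internal model
  expect_true(all(diff(abs(e_rot)) < 0))           # monotone compensation
  expect_lt(abs(e_rot[length(e_rot)]), 1)
})

test_that("direct feedthrough gives immediate compensation; aiming-error drive produces drift", {
  sched <- fig_layout()
  p <- model_params(A = 1, B = 0.02, E = 1, K = 1, F = 0)
  green <- simulate_model(sched, p, "feedthrough_target_error")
  expect_equal(green$target_error[121:442], rep(0, 322))
  red <- simulate_model(sched, p, "feedthrough_fixed_strategy")
  expect_equal(red$target_error[121], 0)
  e_rot <- red$target_error[121:442]
  expect_true(all(diff(e_rot) > 0))                # drift toward the strategy
  # drift approaches the strategy magnitude on long runs
  long <- simulate_model(build_custom_schedule(c(rotation_strategy = 5000)),
                         p, "feedthrough_fixed_strategy")
  expect_equal(utils::tail(long$target_error, 1), 45, tolerance = 1e-3)
})

test_that("terminal drift scales with the availability weight K", {
  sched <- build_custom_schedule(c(rotation_strategy = 8000))
  terminal <- vapply(c(0.25, 0.5, 0.75, 1), function(k) {
    p <- model_params(A = 1, B = 0.02, E = 1, K = k, F = 0)
    utils::tail(simulate_model(sched, p,
                               "feedthrough_fixed_strategy_K")$target_error, 1)
  }, numeric(1))
  expect_equal(terminal, c(0.25, 0.5, 0.75, 1) * 45, tolerance = 1e-3)
  expect_true(all(diff(terminal) > 0))
})

test_that("with no instructed strategy every variant collapses to the standard model", {
  sched <- build_custom_schedule(c(baseline = 60, rotation_probe = 80,
                                   washout = 40))
  p <- model_params(A = 0.97, B = 0.05, E = 0.9, K = 0.4, F = 0.3)
  ref <- simulate_model(sched, p, "standard")
  for (v in c("feedthrough_target_error", "feedthrough_fixed_strategy",
              "feedthrough_fixed_strategy_K", "full_dynamic")) {
    tr <- simulate_model(sched, p, v)
    expect_identical(tr$target_error, ref$target_error, label = v)
    expect_identical(tr$x_hat, ref$x_hat, label = v)
  }
})

test_that("full certainty of a matched aim cancels the strategy from the error signal", {
  sched <- build_paper_schedule("AT")
  p <- model_params(A = 0.99, B = 0.02, E = 1, K = 1, F = 0)
  tr <- simulate_model(sched, p, "feedthrough_fixed_strategy")
  expect_equal(tr$aiming_error, sched$rotation_deg - tr$x_hat,
               tolerance = 1e-12)
})

test_that("no-feedback trials freeze both states", {
  sched <- build_paper_schedule("AT")
  p <- group_params_default("AT")
  tr <- simulate_model(sched, p, "full_dynamic")
  nf <- which(!sched$feedback)
  expect_equal(tr$x_hat[nf], rep(tr$x_hat[nf[1]], length(nf)))
  expect_equal(tr$s[nf], rep(0, length(nf)))
})

test_that("hand angle and target error differ by exactly the rotation", {
  sched <- build_paper_schedule("DAT")
  tr <- simulate_model(sched, group_params_default("DAT"), "full_dynamic")
  expect_equal(tr$hand_angle - tr$target_error, -sched$rotation_deg)
})

test_that("fixed points solve the steady-state equations", {
  # fixed strategy, full certainty: drift limit equals the strategy
  fp <- fixed_point(model_params(A = 1, B = 0.02, E = 1, K = 1, F = 0),
                    strategy = "fixed")
  expect_equal(fp$x_hat, -45)
  expect_equal(fp$e, 45)
  # no strategy: standard-model equilibrium e = r (1-A) / (1-A+B)
  p <- model_params(A = 0.95, B = 0.1, K = 0.5, F = 0.2)
  fp0 <- fixed_point(p, s_star = 0, strategy = "fixed")
  expect_equal(fp0$e, -45 * (1 - 0.95) / (1 - 0.95 + 0.1))
  # dynamic equilibrium matches a long simulation
  pAT <- group_params_default("AT")
  fpd <- fixed_point(pAT)
  long <- simulate_model(build_custom_schedule(c(rotation_strategy = 20000)),
                         pAT, "full_dynamic")
  expect_equal(utils::tail(long$target_error, 1), fpd$e, tolerance = 0.01)
  expect_equal(utils::tail(long$x_hat, 1), fpd$x_hat, tolerance = 0.01)
  # singular system is reported, not silently returned
  expect_error(fixed_point(model_params(A = 1, B = 0.02, E = 1, K = 0.5,
                                        F = 0)),
               "no finite equilibrium")
})

test_that("per-trial stepping matches the matrix-form recursion oracle", {
  # closed-form matrix powers after 64 strategy trials
  p <- group_params_default("AT")
  sched64 <- build_custom_schedule(c(rotation_strategy = 65))
  tr <- simulate_model(sched64, p, "full_dynamic")
  v <- matrix_power_state(p, 64)
  expect_equal(tr$x_hat[65], v[1], tolerance = 1e-9)
  expect_equal(tr$s[65], v[2], tolerance = 1e-9)

  # affine-map oracle across a mixed 500-trial schedule, all three groups
  sched <- build_custom_schedule(c(familiarization = 20, strategy_only = 30,
                                   baseline = 40, rotation_probe = 2,
                                   rotation_strategy = 320,
                                   no_feedback_aftereffect = 8,
                                   washout = 80))
  expect_equal(nrow(sched), 500)
  for (g in REF_GROUPS) {
    pg <- group_params_default(g)
    tr <- simulate_model(sched, pg, "full_dynamic")
    expect_equal(tr$target_error, matrix_oracle(sched, pg),
                 tolerance = 1e-9, label = g)
  }
})

test_that("trajectory export writes the contracted columns", {
  tr <- simulate_model(build_custom_schedule(c(baseline = 8)),
                       model_params(), "standard")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_named(back, c("index", "block", "x_hat", "s", "target_error",
                       "aiming_error", "hand_angle"))
  expect_equal(back$target_error, tr$target_error, tolerance = 1e-6)
})
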