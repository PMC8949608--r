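# Feedback controller: decision rule, instrument interaction, closed loop.

mk_state <- function(config, mode = "RUNNING") {
  s <- controller_state(config, settle_frames = 35)
  s$mode <- mode
  s
}

test_that("decision rule maps labels to actions under both policies", {
  cfg <- controller_config()  # toward-crossover, ladder 10/50/100/500/1000 kHz
  s <- mk_state(cfg); s$freq_hz <- 1e5
  expect_equal(decide("POSITIVE_DEP", 0.2, s, cfg)$action, "STEP_UP")
  expect_equal(decide("NEGATIVE_DEP", -0.2, s, cfg)$action, "STEP_DOWN")
  # and the target of the step is the next ladder rung
  inst <- mock_function_generator(1e5)
  s2 <- apply_action("STEP_UP", s, cfg, inst, 35)
  expect_equal(s2$freq_hz, 5e5)
  expect_equal(instrument_log(inst), "FREQ 500000")

  litcfg <- controller_config(step_policy = "algorithm1-literal")
  expect_equal(decide("POSITIVE_DEP", 0.2, s, litcfg)$action, "STEP_DOWN")
  expect_equal(decide("NEGATIVE_DEP", -0.2, s, litcfg)$action, "STEP_UP")
})

test_that("steps clamp at the ladder ends", {
  cfg <- controller_config()
  s <- mk_state(cfg); s$freq_hz <- min(cfg$ladder_hz)
  expect_equal(decide("NEGATIVE_DEP", -0.2, s, cfg)$action, "HOLD")
  s$freq_hz <- max(cfg$ladder_hz)
  expect_equal(decide("POSITIVE_DEP", 0.2, s, cfg)$action, "HOLD")
})

test_that("consecutive NO_DEP decisions accumulate and terminate", {
  cfg <- controller_config(not_move_threshold = 3)
  s <- mk_state(cfg)
  d1 <- decide("NO_DEP", 0, s, cfg)
  expect_equal(d1$action, "HOLD")
  d2 <- decide("NO_DEP", 0, d1$state, cfg)
  expect_equal(d2$action, "HOLD")
  d3 <- decide("NO_DEP", 0, d2$state, cfg)
  expect_equal(d3$action, "TERMINATE")
  # any DEP label resets the counter
  d <- decide("NO_DEP", 0, mk_state(cfg), cfg)
  d <- decide("POSITIVE_DEP", 0.2, d$state, cfg)
  expect_equal(d$state$not_move_count, 0L)
})

test_that("deciding during SETTLE is a contract violation", {
  cfg <- controller_config()
  s <- mk_state(cfg, mode = "SETTLE")
  expect_error(decide("NO_DEP", 0, s, cfg), "SETTLE")
})

test_that("stepping issues one command and enters SETTLE; holds issue none", {
  cfg <- controller_config()
  inst <- mock_function_generator(1e5)
  s <- mk_state(cfg); s$freq_hz <- 1e5
  s2 <- apply_action("STEP_UP", s, cfg, inst, 35)
  expect_equal(s2$mode, "SETTLE")
  expect_equal(s2$settle_remaining, 35L)
  expect_length(instrument_log(inst), 1)
  s3 <- apply_action("HOLD", s2, cfg, inst, 35)
  s3 <- apply_action("TERMINATE", s3, cfg, inst, 35)
  expect_length(instrument_log(inst), 1)
})

test_that("the instrument rejects malformed or out-of-range packets", {
  inst <- mock_function_generator(1e5, f_min = 1e4, f_max = 1e6)
  expect_error(send_command(inst, "FREQ 1e9"), "outside")
  expect_error(send_command(inst, "FREQUENCY 1000"), "malformed")
  expect_error(send_command(inst, "VOLT -3 VPP"), "amplitude")
  send_command(inst, "FREQ 500000")
  send_command(inst, "VOLT 2 VPP")
  expect_equal(inst$freq_hz, 5e5)
  expect_equal(inst$vpp, 2)
  expect_length(instrument_log(inst), 2)
})

test_that("at the exact crossover the loop terminates by not-move counting", {
  mat <- material_set()
  fx <- crossover_frequency(mat)
  cfg <- controller_config(ladder_hz = fx, start_freq_hz = fx,
                           not_move_threshold = 3)
  run <- run_closed_loop(mat, control = cfg, seed = 4)
  expect_equal(run$report$reason, "not_move")
  expect_true(all(run$history$label == "NO_DEP"))
  expect_equal(nrow(run$history), 3)
  # zero force -> zero slope -> never a frequency command
  expect_length(run$instrument_log, 0)
  expect_equal(run$n_steps, 0L)
})

test_that("no command is ever issued during SETTLE and counts match steps", {
  run <- run_closed_loop(material_set(), seed = 6)
  # one FREQ packet per STEP action, nothing else in the log
  n_step_actions <- sum(run$history$action %in% c("STEP_UP", "STEP_DOWN"))
  expect_equal(sum(grepl("^FREQ ", run$instrument_log)), n_step_actions)
  expect_equal(length(run$instrument_log), run$n_steps)
  # decisions (hence commands) only happen in RUNNING frames
  dec_frames <- run$history$frame
  tr <- run$trace
  expect_true(all(!is.na(tr$slope_b[tr$frame %in% dec_frames])))
  expect_true(all(is.na(tr$slope_b[tr$mode == "SETTLE" &
                                     !tr$frame %in% dec_frames])))
  # visited frequencies stay on the ladder
  expect_true(all(tr$freq_hz %in% run$config$control$ladder_hz))
})

test_that("the default noiseless run recovers the expected regime table", {
  run <- run_closed_loop(material_set(), seed = 2)
  g <- glance(run)
  expect_equal(g$pdep_max_hz, 5e5)
  expect_equal(g$ndep_min_hz, 1e6)
  expect_equal(g$reason, "converged")
  lt <- tidy(run)
  expect_equal(lt$label_final[lt$freq_hz == 5e5], "POSITIVE_DEP")
  expect_equal(lt$label_final[lt$freq_hz == 1e6], "NEGATIVE_DEP")
})

test_that("runs are reproducible for a fixed seed", {
  r1 <- run_closed_loop(material_set(), sim = sim_config(noise_on = TRUE),
                        seed = 9)
  r2 <- run_closed_loop(material_set(), sim = sim_config(noise_on = TRUE),
                        seed = 9)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$instrument_log, r2$instrument_log)
})

test_that("tidiers and plots expose the run", {
  run <- run_closed_loop(material_set(), seed = 1)
  expect_s3_class(tidy(run), "tbl_df")
  expect_equal(nrow(glance(run)), 1)
  p <- ggplot2::autoplot(run)
  expect_s3_class(p, "ggplot")
  p2 <- plot_cm_spectrum(material_set())
  expect_s3_class(p2, "ggplot")
})
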