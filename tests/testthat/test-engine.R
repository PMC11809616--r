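test_that("posture classification applies thresholds and hysteresis", {
  cfg <- posture_config(5, 5, hysteresis_deg = 0)
  expect_equal(classify_posture(0, 0, cfg, "IN"), "IN")
  expect_equal(classify_posture(6, 0, cfg, "IN"), "OUT")
  expect_equal(classify_posture(0, -6, cfg, "IN"), "OUT")
  expect_equal(classify_posture(5, 5, cfg, "IN"), "IN")  # strict exceedance

  cfg_h <- posture_config(5, 5, hysteresis_deg = 1)
  expect_equal(classify_posture(4.5, 0, cfg_h, "OUT"), "OUT")  # needs <= 4
  expect_equal(classify_posture(4.0, 0, cfg_h, "OUT"), "IN")
  expect_equal(classify_posture(4.5, 0, cfg_h, "IN"), "IN")
  expect_error(posture_config(5, 5, hysteresis_deg = 5),
               "hysteresis")
})

test_that("directives pick the dominant plane and the opposite direction", {
  cfg <- posture_config(5, 5)
  expect_equal(directive_for(8, 0, cfg), "LEAN_BACKWARD")
  expect_equal(directive_for(-8, 0, cfg), "LEAN_FORWARD")
  expect_equal(directive_for(0, 7, cfg), "LEAN_LEFT")
  expect_equal(directive_for(0, -7, cfg), "LEAN_RIGHT")
  expect_equal(directive_for(6, 6, cfg), "LEAN_BACKWARD")  # tie -> frontal
  cfg_asym <- posture_config(10, 5)
  expect_equal(directive_for(11, 6, cfg_asym), "LEAN_LEFT")  # larger ratio wins
  expect_error(directive_for(1, 1, cfg), "no directive needed")
})

test_that("the step rules force the documented event sequence", {
  cfg <- posture_config(5, 5, tolerance_s = 3)
  # quiet stage: initial green only
  run <- run_engine(angle_stream(0:10), cfg)
  expect_equal(vapply(run$events, `[[`, "", "kind"),
               c("MONITORING_STARTED", "COLOR_GREEN"))

  # deviation jumps to frontal 8 at t=10 and stays
  ang <- angle_stream(0:16, frontal = c(rep(0, 10), rep(8, 7)))
  run <- run_engine(ang, cfg)
  ev <- data.frame(t = vapply(run$events, `[[`, 0, "t"),
                   kind = vapply(run$events, `[[`, "", "kind"))
  expect_equal(ev$kind[ev$t == 10], c("COLOR_RED", "VIBRATION"))
  dir_ev <- run$events[ev$kind == "AUDIO_DIRECTIVE"]
  expect_equal(vapply(dir_ev, `[[`, 0, "t"), c(13, 16))
  expect_true(all(vapply(dir_ev, function(e) e$payload$key, "") ==
                  "LEAN_BACKWARD"))
  expect_equal(dir_ev[[1]]$payload$text, "please lean backward")

  # return to posture: green + congratulation, no further directives
  ang2 <- angle_stream(0:20, frontal = c(rep(0, 5), rep(8, 6), rep(0, 10)))
  run2 <- run_engine(ang2, cfg)
  kinds <- vapply(run2$events, `[[`, "", "kind")
  ts <- vapply(run2$events, `[[`, 0, "t")
  expect_equal(ts[kinds == "COLOR_GREEN"], c(0, 11))
  expect_equal(sum(kinds == "AUDIO_CONGRATULATION"), 1)
  expect_equal(ts[kinds == "AUDIO_CONGRATULATION"], 11)
})

test_that("praise fires after every full interval of continuous posture", {
  cfg <- posture_config(5, 5, praise_interval_s = 300)
  run <- run_engine(angle_stream(0:600), cfg)
  kinds <- vapply(run$events, `[[`, "", "kind")
  ts <- vapply(run$events, `[[`, 0, "t")
  expect_equal(ts[kinds == "AUDIO_PRAISE"], c(300, 600))

  # a brief excursion resets the praise clock
  f <- rep(0, 601); f[100:101] <- 9
  run2 <- run_engine(angle_stream(0:600, frontal = f), cfg)
  kinds2 <- vapply(run2$events, `[[`, "", "kind")
  ts2 <- vapply(run2$events, `[[`, 0, "t")
  expect_equal(ts2[kinds2 == "AUDIO_PRAISE"], 401)  # 300 s after return at 101
})

test_that("disabled channels never emit and colors strictly alternate", {
  silent <- posture_config(5, 5, vibration_enabled = FALSE,
                           audio_enabled = FALSE)
  set.seed(3)
  f <- cumsum(rnorm(400, 0, 2))
  run <- run_engine(angle_stream(seq_along(f), frontal = f), silent)
  kinds <- vapply(run$events, `[[`, "", "kind")
  expect_false(any(grepl("^AUDIO_", kinds)))
  expect_false(any(kinds == "VIBRATION"))
  colors <- kinds[grepl("^COLOR_", kinds)]
  expect_gt(length(colors), 2)
  expect_true(all(colors[-1] != colors[-length(colors)]))
  expect_equal(colors[1], "COLOR_GREEN")

  # audio on, vibration off
  cfg <- posture_config(5, 5, vibration_enabled = FALSE)
  run2 <- run_engine(angle_stream(0:10, frontal = c(rep(0, 5), rep(9, 6))),
                     cfg)
  kinds2 <- vapply(run2$events, `[[`, "", "kind")
  expect_false(any(kinds2 == "VIBRATION"))
  expect_true(any(kinds2 == "AUDIO_DIRECTIVE"))
})

test_that("no directive fires earlier than the tolerance after leaving posture", {
  for (tol in c(0, 2, 5)) {
    cfg <- posture_config(5, 5, tolerance_s = tol)
    set.seed(17 + tol)
    f <- cumsum(rnorm(300, 0, 2.5))
    run <- run_engine(angle_stream(seq_along(f) / 2, frontal = f), cfg)
    kinds <- vapply(run$events, `[[`, "", "kind")
    ts <- vapply(run$events, `[[`, 0, "t")
    last_red <- NA_real_
    for (i in seq_along(kinds)) {
      if (kinds[i] == "COLOR_RED") last_red <- ts[i]
      if (kinds[i] == "AUDIO_DIRECTIVE") {
        expect_gte(ts[i], last_red + tol)
      }
    }
  }
})

test_that("identical stream, config and seed give identical event lists", {
  cfg <- posture_config(5, 5, rng_seed = 42L)
  set.seed(9)
  f <- cumsum(rnorm(500, 0, 2))
  ang <- angle_stream(seq_along(f), frontal = f)
  r1 <- run_engine(ang, cfg)
  r2 <- run_engine(ang, cfg)
  expect_identical(r1$events, r2$events)
  # congratulation variants are drawn from the seeded generator
  v1 <- vapply(Filter(function(e) e$kind == "AUDIO_CONGRATULATION", r1$events),
               function(e) e$payload$key, "")
  expect_gt(length(v1), 1)
  r3 <- run_engine(ang, posture_config(5, 5, rng_seed = 43L))
  v3 <- vapply(Filter(function(e) e$kind == "AUDIO_CONGRATULATION", r3$events),
               function(e) e$payload$key, "")
  expect_false(identical(v1, v3))  # different seed, different variant order
})

test_that("control commands toggle monitoring and log settings changes", {
  cfg <- posture_config()
  st <- engine_state(cfg)
  expect_error(engine_step(st, 0, 0, 0, cfg), "engine paused")

  ctl <- engine_control(st, "play", 0, cfg)
  expect_true(ctl$state$monitoring)
  expect_equal(vapply(ctl$events, `[[`, "", "kind"),
               c("MONITORING_STARTED", "COLOR_GREEN"))

  ctl2 <- engine_control(ctl$state, "pause", 5, cfg)
  expect_false(ctl2$state$monitoring)
  expect_equal(ctl2$events[[1]]$kind, "MONITORING_PAUSED")

  ctl3 <- engine_control(ctl2$state, "update_settings", 6, cfg,
                         payload = list(tolerance_s = 5))
  expect_equal(ctl3$config$tolerance_s, 5)
  ev <- ctl3$events[[1]]
  expect_equal(ev$kind, "SETTINGS_CHANGED")
  expect_equal(ev$payload$changed$tolerance_s$old, 3)
  expect_equal(ev$payload$changed$tolerance_s$new, 5)

  expect_error(engine_control(st, "reboot", 0, cfg), "unknown command")
  expect_error(engine_control(st, "update_settings", 0, cfg,
                              payload = list(volume = 1)), "unknown setting")
})

test_that("config files read as JSON or key=value with flag overrides", {
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"frontal_threshold_deg": 8, "language": "es", "tolerance_s": 4}',
             js)
  cfg <- read_posture_config(js)
  expect_equal(cfg$frontal_threshold_deg, 8)
  expect_equal(cfg$language, "es")
  expect_equal(cfg$lateral_threshold_deg, 5)  # default retained

  kv <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("frontal_threshold_deg = 7", "vibration_enabled = false",
               "language = pt"), kv)
  cfg2 <- read_posture_config(kv, tolerance_s = 9)
  expect_equal(cfg2$frontal_threshold_deg, 7)
  expect_false(cfg2$vibration_enabled)
  expect_equal(cfg2$language, "pt")
  expect_equal(cfg2$tolerance_s, 9)  # flag override

  expect_error(read_posture_config(js, language = "de"), "unknown language")
})
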