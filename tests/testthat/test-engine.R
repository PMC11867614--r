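test_that("an idle step emits only a heartbeat record", {
  eng <- engine_init(fixture_settings())
  eng$running <- TRUE
  res <- engine_step(eng, 10, list())
  expect_length(res$outbox, 0)
  expect_equal(vapply(res$records, `[[`, character(1), "kind"), "heartbeat")
})

test_that("entering a non-operant reward zone opens the valve once per lap", {
  eng <- engine_init(fixture_settings(mode = "non_operant"))
  eng$running <- TRUE
  # move toward the zone at 1500 mm: 2600 ticks * 0.5 = 1300 mm -> outside
  res <- engine_step(eng, 10, list(message_packet("position", "delta",
                                                 list(ticks = 2600))))
  expect_length(res$outbox, 0)
  # 300 more ticks -> 1450 mm, inside
  res2 <- engine_step(res$engine, 20,
                      list(message_packet("position", "delta",
                                          list(ticks = 300))))
  routes <- vapply(res2$outbox, function(m) m$route[[1]], character(1))
  expect_true("valve" %in% routes)
  kinds <- vapply(res2$records, `[[`, character(1), "kind")
  expect_true("reward" %in% kinds)
  # staying in the zone does not re-trigger
  res3 <- engine_step(res2$engine, 30,
                      list(message_packet("position", "delta",
                                          list(ticks = 10))))
  expect_false(any(vapply(res3$outbox, function(m) m$route[[1]], character(1)) ==
                     "valve"))
  expect_equal(res3$engine$reward_count, 1L)
})

test_that("malformed inbound messages dead-letter and the step continues", {
  eng <- engine_init(fixture_settings())
  eng$running <- TRUE
  res <- engine_step(eng, 10, list("not a message",
                                   message_packet("bogus_route", "x")))
  kinds <- vapply(res$records, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "error"), 2)
  expect_equal(res$engine$dead_letters, 2L)
})

test_that("a closed-loop session balances context edges and rewards once per lap", {
  cfg <- fixture_cfg()
  rig <- virtual_rig(mouse_model(lick_rate_zone_hz = 60), cfg, 120000,
                     zones = list(zone(1500, 150)), seed = 11)
  log <- run_experiment(fixture_settings(scenes = TRUE), rig, 120000,
                        wall_clock = as.POSIXct("2026-01-01", tz = "UTC"))
  s <- load_session(log)
  eng <- attr(log, "engine")

  # sync first and last
  expect_equal(s$records$kind[1], "sync")
  expect_equal(s$records$kind[nrow(s$records)], "sync")

  # every context interval is closed
  expect_false(any(s$contexts$unclosed))
  starts <- sum(s$records$kind == "context_start")
  stops <- sum(s$records$kind == "context_stop")
  expect_equal(starts, stops)

  # exactly one reward per lap whose zone was traversed (operant,
  # guaranteed licking); the final partial lap may not reach the zone
  reward_laps <- sort(unlist(s$rewards$lap))
  expect_equal(anyDuplicated(reward_laps), 0L)
  expect_true(all(0:(eng$track$lap - 1L) %in% reward_laps))
  expect_equal(eng$reward_count, nrow(s$rewards))

  # scene messages alternate with lap parity
  scenes <- rig$display$log()
  sw <- scenes[scenes$action == "scene", ]
  expect_gt(nrow(sw), 5)
  expect_true(all(utils::head(sw$scene_id, -1) != utils::tail(sw$scene_id, -1)))
})

test_that("identical seeds give byte-identical behavior logs", {
  cfg <- fixture_cfg()
  run1 <- run_experiment(fixture_settings(), virtual_rig(mouse_model(), cfg,
                                                         30000, seed = 5),
                         30000, wall_clock = as.POSIXct("2026-01-01", tz = "UTC"))
  run2 <- run_experiment(fixture_settings(), virtual_rig(mouse_model(), cfg,
                                                         30000, seed = 5),
                         30000, wall_clock = as.POSIXct("2026-01-01", tz = "UTC"))
  expect_identical(readLines(run1), readLines(run2))
  run3 <- run_experiment(fixture_settings(), virtual_rig(mouse_model(), cfg,
                                                         30000, seed = 6),
                         30000, wall_clock = as.POSIXct("2026-01-01", tz = "UTC"))
  expect_false(identical(readLines(run1), readLines(run3)))
})

test_that("a failed sync acknowledgment aborts the run", {
  cfg <- fixture_cfg()
  rig <- virtual_rig(mouse_model(), cfg, 10000, seed = 1,
                     behavior_transport_factory = function(peer) {
                       transport_droplist(peer, drop = 1:100)
                     })
  expect_error(run_experiment(fixture_settings(), rig, 10000),
               class = "trackloop_run_error")
})

test_that("devices actuate on manual commands even when no experiment runs", {
  ctrl <- virtual_behavior_controller()
  tr <- transport_lossless(ctrl$peer)
  st <- send_with_ack(tr, message_packet("valve", "open",
                                         list(duration_ms = 50), id = 1))
  expect_true(st$acked)
  log <- ctrl$log()
  expect_equal(nrow(log), 1)
  expect_equal(log$duration_ms, 50)
})
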