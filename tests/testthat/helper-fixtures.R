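# Shared fixtures, built in code at load time.  Sizes are kept small so
# the whole suite runs quickly; the acceptance tests build their own
# larger fixtures.

fixture_cfg <- function() track_config(2000, 0.5, circular = TRUE)

fixture_settings <- function(mode = "operant", scenes = FALSE) {
  ctx <- list(
    list(id = "reward", mode = mode,
         zones = list(list(center_mm = 1500, radius_mm = 150)))
  )
  if (scenes) {
    ctx <- c(ctx, list(
      list(id = "sceneA",
           decorators = list(list(kind = "lap_parity", parity = "odd")),
           targets = list(list(route = list("display"), start_action = "scene",
                               payload = list(scene_id = "A")))),
      list(id = "sceneB",
           decorators = list(list(kind = "lap_parity", parity = "even")),
           targets = list(list(route = list("display"), start_action = "scene",
                               payload = list(scene_id = "B"))))
    ))
  }
  list(track = list(track_length_mm = 2000, scale_mm_per_tick = 0.5,
                    circular = TRUE),
       contexts = ctx)
}

# one modest synthetic suite reused by several test files (~20 laps,
# 30 cells); deterministic
local_suite <- local({
  suite <- NULL
  function() {
    if (is.null(suite)) {
      suite <<- make_benchmark_suite(seed = 99, n_cells = 30,
                                     duration_ms = 240000)
    }
    suite
  }
})

# random valid message generator for property tests
random_message <- function() {
  depth <- sample(1:3, 1)
  route <- sample(c("valve", "context", "position", "display", "tone"), depth,
                  replace = TRUE)
  payload <- list()
  n_fields <- sample(0:4, 1)
  for (i in seq_len(n_fields)) {
    payload[[paste0("k", i)]] <- switch(sample(1:4, 1),
      runif(1) * 100,
      paste(sample(letters, 5), collapse = ""),
      as.double(sample(1:1000, sample(1:5, 1))),
      sample(c(TRUE, FALSE), 1))
  }
  action <- if (runif(1) < 0.8) sample(c("start", "stop", "open"), 1) else NULL
  message_packet(route, action = action,
                 payload = payload,
                 id = sample(1:10000, 1), t_ms = sample(0:1e6, 1))
}
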