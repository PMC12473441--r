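test_that("default Borg risk table carries the documented scores", {
  rt <- posture_risk_table()
  expect_equal(unname(rt$scores),
               c(1, 10, 7, 7, 3, 8, 8, 9, 6, 7, 7, 4, 9, 10, 10, 10, 10, 8, 8))
  expect_equal(names(rt$scores), paste0("SP", 1:19))
  # mirrored posture pairs carry identical risk
  for (pair in list(c("SP3", "SP4"), c("SP6", "SP7"), c("SP10", "SP11"),
                    c("SP14", "SP15"), c("SP16", "SP17"), c("SP18", "SP19"))) {
    expect_equal(risk_score(rt, pair[1]), risk_score(rt, pair[2]))
  }
  expect_error(posture_risk_table(c(SP1 = 1)), "cover")
  expect_error(posture_risk_table(setNames(rep(11, 19), paste0("SP", 1:19))),
               "1, 10")
})

test_that("decay lookups reproduce the ruleset on boundary-adjacent durations", {
  # independent rule-by-rule oracle
  oracle <- function(posture, t_min) {
    if (posture == "SP1") {
      if (t_min <= 30) 0 else 0.005
    } else {
      if (t_min <= 0.5) 0 else 0.02
    }
  }
  for (p in c("SP1", "SP3", "SP12")) {
    for (t in c(29.999, 30, 30.001, 29.999 / 60, 30 / 60, 30.001 / 60,
                0, 0.2, 45, 120)) {
      expect_equal(decay_factor(p, t), oracle(p, t),
                   label = sprintf("%s @ %g min", p, t))
    }
  }
  expect_equal(decay_factor("SP1", 45), 0.005)
  expect_equal(decay_factor("SP1", 30), 0)
  expect_equal(decay_factor("SP3", 0.33), 0)
  expect_equal(decay_factor("SP3", 1), 0.02)
  expect_error(decay_factor("SP1", -1), "non-negative")
})

test_that("the upright context set is configurable", {
  rs <- decay_ruleset(upright_set = c("SP1", "SP5"))
  expect_equal(decay_factor("SP5", 10, rs), 0)
  expect_equal(decay_factor("SP5", 40, rs), 0.005)
  expect_equal(decay_factor("SP5", 10), 0.02)  # default: SP5 not upright
})

test_that("quality score matches the closed form and is monotone", {
  expect_equal(quality_score(1, 0, 10), 0.5)
  expect_equal(quality_score(10, 0.02, 60), 1 / 12.2)
  expect_equal(quality_score(7, 0.02, 45), 1 / 8.9)
  set.seed(50)
  S <- runif(1000, 1, 10); D <- runif(1000, 0, 0.05); T_ <- runif(1000, 0, 240)
  qs <- quality_score(S, D, T_)
  expect_equal(qs, 1 / (1 + S + D * T_), tolerance = 1e-12)
  expect_true(all(qs > 0 & qs <= 0.5))
  # monotonicity in each argument on the same grid
  eps <- 0.01
  expect_true(all(quality_score(S + eps, D, T_) <= qs))
  expect_true(all(quality_score(S, D + eps, T_) <= qs))
  expect_true(all(quality_score(S, D, T_ + eps) <= qs))
  expect_error(quality_score(0.5, 0, 1), ">= 1")
  expect_error(quality_score(2, -0.1, 1), "non-negative")
})

test_that("episode segmentation finds maximal runs with midpoint boundaries", {
  tl <- segment_episodes(0:59, rep("SP1", 60))
  expect_equal(nrow(tl), 1)
  expect_gte(tl$end[1] - tl$start[1], 59)
  tl2 <- segment_episodes(0:29, rep(c("SP1", "SP3", "SP1"), each = 10))
  expect_equal(tl2$posture, c("SP1", "SP3", "SP1"))
  expect_equal(tl2$start[2], 9.5)   # midpoint between samples 9 and 10
  expect_equal(tl2$end[2], 19.5)
  # consecutive episodes differ and tile the span
  expect_true(all(head(tl2$posture, -1) != tail(tl2$posture, -1)))
  expect_equal(tl2$start[-1], head(tl2$end, -1))
  expect_error(segment_episodes(c(0, 2, 1), c("A", "A", "A")), "increasing")
})

test_that("debouncing collapses alternating labels onto the majority run", {
  ts <- 0:20
  lab <- c(rep(c("SP1", "SP3"), 10), "SP1")  # SP1 holds the 11:10 majority
  tl <- segment_episodes(ts, lab, min_episode = 5)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$posture, "SP1")
  # debounce removes a single-sample blip entirely
  lab2 <- c(rep("SP1", 9), "SP2", rep("SP1", 10))
  tl2 <- segment_episodes(0:19, lab2, min_episode = 3)
  expect_equal(tl2$posture, "SP1")
  expect_equal(nrow(tl2), 1)
})

test_that("scoring a timeline applies the decay switch at the threshold", {
  # 20 min upright: flat at 0.5
  tl <- segment_episodes(seq(0, 1200, by = 10), rep("SP1", 121))
  s <- score_timeline(tl, step = 10)
  expect_true(all(abs(s$series$qs - 0.5) < 1e-12))
  # 40 min upright: flat for 30 min, strictly decreasing afterwards
  tl2 <- segment_episodes(seq(0, 2400, by = 10), rep("SP1", 241))
  s2 <- score_timeline(tl2, step = 10)
  qs <- s2$series$qs
  tt <- s2$series$time
  expect_true(all(abs(qs[tt <= 1800] - 0.5) < 1e-12))
  late <- qs[tt > 1800]
  expect_true(all(diff(late) < 0))
  expect_true(all(qs > 0 & qs <= 0.5))
  # non-upright: decay kicks in after 30 s
  tl3 <- segment_episodes(seq(0, 120, by = 1), rep("SP3", 121))
  s3 <- score_timeline(tl3, step = 1)
  expect_equal(s3$series$qs[s3$series$time == 10], 1 / 8)       # S=7, D=0
  expect_equal(s3$series$qs[s3$series$time == 60], 1 / (8 + 0.02))
})

test_that("session summaries report shares, episodes and weighted quality", {
  tl <- segment_episodes(seq(0, 3600, by = 60),
                         c(rep("SP1", 31), rep("SP3", 30)))
  s <- session_summary(tl)
  expect_equal(s$n_episodes, 2)
  expect_equal(sum(s$per_posture$percent), 100, tolerance = 1e-9)
  expect_equal(s$per_posture$percent[s$per_posture$posture == "SP1"], 50,
               tolerance = 2)
  expect_equal(s$longest_static$minutes, max(tl$duration_min))
  one <- segment_episodes(seq(0, 3600, by = 60), rep("SP1", 61))
  s1 <- session_summary(one)
  expect_equal(s1$per_posture$percent, 100)
  expect_equal(s1$n_episodes, 1)
  recs <- session_recommendations(tl)
  expect_true(any(grepl("Dominant posture", recs)))
  expect_true(any(grepl("exceeded", recs)))  # SP3 for ~30 min > 30 s rule
})

test_that("history JSON round-trips canonically", {
  expect_equal(render_history_json(segment_episodes(0, "SP1")[0, ]), "[]")
  tl <- segment_episodes(seq(0, 1200, by = 60),
                         c(rep("SP1", 11), rep("SP4", 10)))
  js <- render_history_json(tl)
  expect_match(js, "^\\[\\{\"posture\":\\[?\"SP1\"")
  expect_match(js, "T09:00:00Z")
  back <- read_history_json(js)
  expect_equal(back$posture, tl$posture)
  expect_equal(back$start, round(tl$start))
  expect_true(back$end[1] <= back$start[2])
  # write -> read -> write is byte-stable
  expect_identical(render_history_json(back), js)
})
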