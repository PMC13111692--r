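test_that("a single Elo update conserves points and matches closed forms", {
  cfg <- elo_config()
  # equal ratings: expectation one half, winner takes k/2
  upd <- elo_update(1000, 1000, cfg)
  expect_equal(unname(upd), c(1050, 950))
  # 200-point favourite wins: E_w = 1/(1 + 10^(-0.5))
  e_w <- 1 / (1 + 10^(-0.5))
  upd <- elo_update(1100, 900, cfg)
  expect_equal(upd[["winner"]], 1100 + 100 * (1 - e_w), tolerance = 1e-12)
  expect_equal(upd[["loser"]], 900 - 100 * (1 - e_w), tolerance = 1e-12)
  expect_equal(upd[["winner"]], 1124.0253, tolerance = 1e-4)
  # an upset moves ratings more than the expected result at the same gap
  upset <- elo_update(900, 1100, cfg)
  expect_gt(upset[["winner"]] - 900, upd[["winner"]] - 1100)
  # conservation
  expect_equal(sum(upd), 2000)
})

test_that("compute_elo matches an independent sequential hand computation", {
  ev <- make_events(winner_id = c("a", "a", "c", "b", "a"),
                    loser_id = c("b", "c", "b", "a", "c"),
                    day = 1:5)
  traj <- compute_elo(ev, roster = c("a", "b", "c"))
  # brute-force oracle: plain sequential loop written independently of the
  # package internals
  r <- c(a = 1000, b = 1000, c = 1000)
  for (i in 1:5) {
    w <- ev$winner_id[i]; l <- ev$loser_id[i]
    e_w <- 1 / (1 + 10^((r[[l]] - r[[w]]) / 400))
    r[[w]] <- r[[w]] + 100 * (1 - e_w)
    r[[l]] <- r[[l]] - 100 * (1 - e_w)
  }
  last <- traj[traj$date == max(traj$date), ]
  expect_equal(setNames(last$rating, last$individual_id)[names(r)], r)
  # intermediate day: rating after that day's last event, carried forward
  day3 <- traj[traj$date == as.Date("2020-02-04"), ]
  expect_equal(day3$rating[day3$individual_id == "a"],
               traj$rating[traj$date == as.Date("2020-02-03") &
                             traj$individual_id == "a"])
})

test_that("ratings are conserved on every day of the trajectory", {
  set.seed(42)
  ids <- letters[1:5]
  ev <- make_events(winner_id = sample(ids, 60, TRUE),
                    loser_id = sample(ids, 60, TRUE),
                    day = sort(sample(1:40, 60, TRUE)))
  ev <- ev[ev$winner_id != ev$loser_id, ]
  traj <- compute_elo(ev, roster = ids)
  daily_sum <- as.numeric(tapply(traj$rating, traj$date, sum))
  expect_equal(daily_sum, rep(5000, length(daily_sum)), tolerance = 1e-9)
})

test_that("an empty event log yields flat trajectories at the start rating", {
  ev <- make_events(character(0), character(0))
  traj <- compute_elo(ev, roster = c("a", "b"),
                      date_range = as.Date(c("2020-02-01", "2020-02-10")))
  expect_true(all(traj$rating == 1000))
  expect_equal(nrow(traj), 20L)
})

test_that("events naming unknown individuals are rejected", {
  ev <- make_events("a", "zz")
  expect_error(compute_elo(ev, roster = c("a", "b")), "outside the roster")
  expect_error(compute_elo(make_events("a", "a"), roster = "a"), "differ")
})

test_that("ordinal ranks are dense, ordered, and shift-invariant", {
  ev <- make_events(winner_id = c("a", "a", "a", "b"),
                    loser_id = c("b", "c", "b", "c"), day = 1:4)
  traj <- compute_elo(ev, roster = c("a", "b", "c"))
  rk <- ordinal_rank(traj, max(traj$date))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$individual_id[1], "a")
  # all tied at the start rating: everyone rank 1
  flat <- compute_elo(make_events(character(0), character(0)),
                      roster = c("a", "b", "c"),
                      date_range = as.Date(c("2020-02-01", "2020-02-02")))
  expect_equal(ordinal_rank(flat, as.Date("2020-02-01"))$rank, c(1, 1, 1))
  # adding a constant to all ratings preserves the rank table
  shifted <- traj; shifted$rating <- shifted$rating + 500
  rk2 <- ordinal_rank(shifted, max(traj$date))
  expect_equal(rk2$rank, rk$rank)
  expect_equal(rk2$individual_id, rk$individual_id)
  expect_error(ordinal_rank(traj, as.Date("1999-01-01")), "span")
})

test_that("conflict outcome predictability counts wins and losses in-window", {
  win <- function(n) rep("x", n); lose <- function(n) rep("x", n)
  mk <- function(w, l) make_events(winner_id = c(win(w), rep("o", l)),
                                   loser_id = c(rep("o", w), lose(l)),
                                   day = seq_len(w + l))
  window <- as.POSIXct(c("2020-02-01", "2020-03-01"), tz = "UTC")
  expect_equal(cop(mk(10, 0), "x", window)$score, 1.0)
  expect_equal(cop(mk(5, 5), "x", window)$score, 0.0)
  expect_equal(cop(mk(7, 3), "x", window)$score, 0.4)
  # swapping the win/loss labels leaves the score unchanged
  expect_equal(cop(mk(3, 7), "x", window)$score, 0.4)
  # no conflicts in the window: undefined, not zero
  empty <- cop(mk(7, 3), "x", window + 365 * 86400)
  expect_true(is.na(empty$score))
  expect_equal(empty$n_conflicts, 0L)
  # events outside the window are not counted
  ev <- mk(7, 3)
  narrow <- cop(ev, "x", c(ev$timestamp[1], ev$timestamp[5]))
  expect_equal(narrow$n_conflicts, 5L)
})

test_that("hierarchy measures align to chunk time spans", {
  ids <- c("a", "b")
  ev <- make_events("a", "b", day = 1)
  traj <- compute_elo(ev, roster = ids,
                      date_range = as.Date(c("2020-02-01", "2020-03-31")))
  # constant trajectory segment: mean equals the constant
  spans <- data.frame(individual_id = "a", chunk_index = 1L,
                      t_start = as.POSIXct("2020-02-10", tz = "UTC"),
                      t_end = as.POSIXct("2020-02-20", tz = "UTC"))
  al <- align_hierarchy_to_chunks(traj, ev, spans)
  expect_equal(al$mean_elo, 1050)
  expect_equal(al$n_days, 11L)
  # one-day chunk: the mean is that day's rating
  one <- spans; one$t_end <- one$t_start
  expect_equal(align_hierarchy_to_chunks(traj, ev, one)$mean_elo, 1050)
  # a linear ramp averages to its midpoint
  ramp <- data.frame(date = seq(as.Date("2020-02-01"), by = "day",
                                length.out = 101),
                     individual_id = "a",
                     rating = seq(1000, 1100, length.out = 101))
  rs <- data.frame(individual_id = "a", chunk_index = 1L,
                   t_start = as.POSIXct("2020-02-01", tz = "UTC"),
                   t_end = as.POSIXct("2020-05-11", tz = "UTC"))
  expect_equal(align_hierarchy_to_chunks(ramp, ev[0, ], rs)$mean_elo, 1050,
               tolerance = 0.01)
  # a span with no rating days is flagged missing
  off <- spans
  off$t_start <- as.POSIXct("2021-01-01", tz = "UTC")
  off$t_end <- as.POSIXct("2021-01-05", tz = "UTC")
  miss <- align_hierarchy_to_chunks(traj, ev, off)
  expect_true(is.na(miss$mean_elo))
  expect_equal(miss$n_days, 0L)
})

test_that("a strict linear dominance order is recovered by the final ratings", {
  ok <- sapply(1:20, function(s) {
    ids <- sprintf("m%d", 1:6)
    strength <- 6:1  # m1 strongest
    ev <- ptrank:::with_seed(s, {
      i <- sample.int(6, 100, replace = TRUE)
      j <- sample.int(5, 100, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      win <- ifelse(strength[i] > strength[j], i, j)
      los <- ifelse(strength[i] > strength[j], j, i)
      make_events(ids[win], ids[los], day = seq_len(100) / 5)
    })
    traj <- compute_elo(ev, roster = ids)
    rk <- ordinal_rank(traj, max(traj$date))
    identical(rk$individual_id, ids)
  })
  expect_gte(mean(ok), 0.95)
})
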