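# Unknown-activity filtering, the expert rules, and match-making scores.

mk_events <- function(names, minutes, person = "p1", location = "",
                      start = "2026-01-05 07:00:00") {
  activity_events(id = sprintf("e%02d", seq_along(names)), name = names,
                  time = as.POSIXct(start, tz = "UTC") + minutes * 60,
                  person = person, location = location)
}

test_that("unknown activities are diverted, never dropped", {
  ev <- mk_events(c("Walking", "door locking", "eating"), c(0, 1, 2))
  out <- filter_unknown(ev)
  expect_equal(out$known$name, c("Walking", "eating"))
  expect_equal(out$unknown$name, "door locking")
  expect_equal(nrow(out$known) + nrow(out$unknown), nrow(ev))
  empty <- mk_events(character(), numeric())
  out0 <- filter_unknown(empty)
  expect_equal(nrow(out0$known) + nrow(out0$unknown), 0)
})

test_that("the five rules fire on their trigger patterns", {
  # exercise: two distinct motion contents by one person in a session
  r1 <- apply_rules(mk_events(c("walking", "jumping"), c(0, 5)))
  expect_true(any(r1$decisions$kind == "high_level_activity" &
                    r1$decisions$payload == "Exercise"))
  # same content twice is not exercise
  r1b <- apply_rules(mk_events(c("walking", "walking"), c(0, 5)))
  expect_false(any(r1b$decisions$payload == "Exercise"))
  # contents in separate sessions do not combine
  r1c <- apply_rules(mk_events(c("walking", "jumping"), c(0, 45)))
  expect_false(any(r1c$decisions$payload == "Exercise"))

  # medicine: eating with no prior taking-medicine that day
  r2 <- apply_rules(mk_events(c("eating"), 0))
  expect_true(any(r2$decisions$kind == "reminder" &
                    r2$decisions$payload == "take medicine"))
  r2b <- apply_rules(mk_events(c("taking medicine", "eating"), c(0, 5)))
  expect_false(any(r2b$decisions$payload == "take medicine"))

  # TV off on reading while the TV is on
  r3 <- apply_rules(mk_events(c("watching TV", "reading"), c(0, 10)))
  expect_true(any(r3$decisions$payload == "turnOff(TV)"))
  r3b <- apply_rules(mk_events(c("reading"), 0))
  expect_false(any(r3b$decisions$payload == "turnOff(TV)"))

  # wrong movements: an unknown activity with no successor within timeout
  r4 <- apply_rules(mk_events(c("door jiggling"), 0))
  expect_true(any(r4$decisions$payload == "movements are wrong"))
  r4b <- apply_rules(mk_events(c("door jiggling", "walking"), c(0, 2)))
  expect_false(any(r4b$decisions$payload == "movements are wrong"))

  # lights on entering the kitchen or bedroom
  r5 <- apply_rules(mk_events(c("entering kitchen"), 0))
  expect_true(any(r5$decisions$payload == "turnOn(lights)"))

  # unsorted stream is a contract violation
  bad <- mk_events(c("eating", "walking"), c(5, 0))[c(2, 1), ]
  expect_error(apply_rules(bad), class = "harkit_contract_error")
})

test_that("knowledge-base gating makes decisions idempotent per day", {
  ev <- mk_events(c("entering kitchen", "eating", "watching TV", "reading",
                    "walking", "jumping"), c(0, 5, 10, 15, 20, 22))
  first <- apply_rules(ev)
  expect_gte(nrow(first$decisions), 3)
  replay <- apply_rules(ev, kb = first$kb)
  # reminders and high-level activities never double; device commands may
  # re-fire only if the replayed stream itself changes the device state
  expect_equal(sum(replay$decisions$kind %in%
                     c("reminder", "high_level_activity")), 0)
  expect_false(any(replay$decisions$payload == "turnOn(lights)"))
})

test_that("match-making pairs greedily within tolerance", {
  truth <- mk_events(c("eating", "walking", "reading"), c(0, 5, 10))
  m0 <- match_activities(truth, truth)
  expect_equal(nrow(m0$matched), 3)
  expect_equal(nrow(m0$unmatched_pred) + nrow(m0$unmatched_truth), 0)

  # a prediction outside tolerance stays unmatched on both sides
  off <- mk_events("eating", 10)
  m1 <- match_activities(off, mk_events("eating", 0), tolerance = 60)
  expect_equal(nrow(m1$matched), 0)
  expect_equal(nrow(m1$unmatched_pred), 1)
  expect_equal(nrow(m1$unmatched_truth), 1)

  # constructed 3 TP, 1 FP, 2 FN instance vs an exhaustive pairing oracle
  truth2 <- mk_events(c("eating", "walking", "reading", "sitting", "eating"),
                      c(0, 5, 10, 20, 30))
  pred2 <- mk_events(c("eating", "walking", "reading", "bathing"),
                     c(0.3, 5.2, 10.4, 12))
  m2 <- match_activities(pred2, truth2, tolerance = 60)
  expect_equal(nrow(m2$matched), 3)
  expect_equal(nrow(m2$unmatched_pred), 1)
  expect_equal(nrow(m2$unmatched_truth), 2)
  # oracle: maximum bipartite matching by exhaustive assignment search
  compat <- outer(seq_len(nrow(pred2)), seq_len(nrow(truth2)),
                  Vectorize(function(i, j)
                    tolower(pred2$name[i]) == tolower(truth2$name[j]) &&
                      abs(as.numeric(difftime(pred2$time[i], truth2$time[j],
                                              units = "secs"))) <= 60))
  best <- 0
  perms <- expand.grid(rep(list(0:nrow(truth2)), nrow(pred2)))
  for (r in seq_len(nrow(perms))) {
    asg <- as.integer(perms[r, ])
    nz <- asg[asg > 0]
    if (anyDuplicated(nz)) next
    ok <- all(vapply(seq_along(asg), function(i)
      asg[i] == 0 || compat[i, asg[i]], logical(1)))
    if (ok) best <- max(best, length(nz))
  }
  expect_equal(nrow(m2$matched), best)
})

test_that("precision/recall follow the flagged empty-denominator convention", {
  ev <- evaluate_matchmaking(3, 1, 2)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.6)
  perfect <- evaluate_matchmaking(4, 0, 0)
  expect_equal(c(perfect$precision, perfect$recall), c(1, 1))
  none <- evaluate_matchmaking(0, 0, 3)
  expect_true(none$precision_undefined)
  expect_equal(none$precision, 1.0)
  expect_equal(none$recall, 0)
})

test_that("the unknown filter never lowers match-making precision", {
  set.seed(50)
  cat <- activity_catalog()
  for (rep in 1:10) {
    n <- 12
    names_t <- sample(cat$known, n, replace = TRUE)
    minutes_t <- sort(runif(n, 0, 120))
    truth <- mk_events(names_t, minutes_t)
    # predictions: the truth jittered, plus out-of-catalog contamination
    keep <- runif(n) < 0.8
    contam <- paste("glitch", seq_len(6))
    pred_names <- c(names_t[keep], contam)
    pred_times <- c(minutes_t[keep] + runif(sum(keep), -0.3, 0.3),
                    runif(length(contam), 0, 120))
    ord <- order(pred_times)
    pred <- mk_events(pred_names[ord], pred_times[ord])
    score <- function(p) {
      m <- match_activities(p, truth, tolerance = 60)
      evaluate_matchmaking(m$matched, m$unmatched_pred, m$unmatched_truth)$precision
    }
    expect_gte(score(filter_unknown(pred, cat)$known), score(pred))
  }
})
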