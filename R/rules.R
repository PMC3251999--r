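# Executable context-aware activity manipulation: filter unknown
# activities, match predicted against true activity streams, and apply the
# expert rules that lift low-level activity events to high-level activities,
# reminders and device commands. A knowledge base gates obligations so that
# replaying a stream never duplicates a reminder; per-day flags reset at
# local midnight simply by being keyed on the calendar date.

#' Default catalog of expected activities
#'
#' Eighteen activities of daily living; anything else in a stream is an
#' unknown activity. Name matching is case-insensitive.
#'
#' @param known character vector of expected activity names.
#' @return object of class `activity_catalog`.
#' @export
activity_catalog <- function(known = c(
  "bending", "jacking", "jumping", "running", "skipping", "siding",
  "walking", "waving", "sitting", "eating", "having tea", "tooth brushing",
  "reading", "taking medicine", "taking bath", "entering kitchen",
  "entering bedroom", "watching tv")) {
  known <- tolower(known)
  check_that(length(known) >= 1, "catalog must be non-empty")
  structure(list(known = known), class = "activity_catalog")
}

#' Create an activity event stream
#'
#' @param id unique tokens. @param name activity names. @param time POSIXct
#'   (or parseable) timestamps. @param person subject ids. @param location
#'   room names. @param type category strings. @param consequent_action
#'   optional strings.
#' @return data frame of class `activity_events`, sorted by time.
#' @export
activity_events <- function(id, name, time, person = "p1", location = "",
                            type = "Motion", consequent_action = NA_character_) {
  time <- as.POSIXct(time, tz = "UTC")
  check_that(!any(is.na(time)), "unparseable time stamps")
  check_that(all(nzchar(name)), "event names must be non-empty")
  check_that(!any(duplicated(id)), "event ids must be unique")
  n <- length(name)
  ev <- data.frame(id = as.character(id), name = as.character(name),
                   type = rep_len(type, n), time = time,
                   person = rep_len(as.character(person), n),
                   location = rep_len(as.character(location), n),
                   consequent_action = rep_len(consequent_action, n),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$time, ev$id), ]
  rownames(ev) <- NULL
  class(ev) <- c("activity_events", "data.frame")
  ev
}

#' Divert unknown activities to a separate log
#'
#' Events whose name is not in the catalog are moved to the unknown log —
#' retained for later analysis, never dropped silently. Conserves events:
#' `nrow(known) + nrow(unknown) == nrow(input)`.
#'
#' @param events `activity_events` (or compatible data frame).
#' @param catalog `activity_catalog`.
#' @return list with `known` and `unknown` event streams.
#' @export
filter_unknown <- function(events, catalog = activity_catalog()) {
  is_known <- tolower(events$name) %in% catalog$known
  list(known = events[is_known, , drop = FALSE],
       unknown = events[!is_known, , drop = FALSE])
}

#' Create an empty knowledge base
#'
#' Holds per-day obligation flags (medicine taken/reminded, exercised),
#' device states (TV, lights per room) and the ids of already-handled
#' events; per-day flags are keyed by calendar date, so they reset at local
#' midnight.
#'
#' @param tv_on initial TV state.
#' @return object of class `knowledge_base`.
#' @export
knowledge_base <- function(tv_on = FALSE) {
  structure(list(medicine_taken = character(), medicine_reminded = character(),
                 exercised = character(), exercise_emitted = character(),
                 tv_on = tv_on, lights_on = character(),
                 rule4_done = character()),
            class = "knowledge_base")
}

#' Default rule configuration
#'
#' @param session_window_min sliding session window for the exercise rule
#'   (minutes, default 30).
#' @param rule4_timeout_min timeout after an unknown activity with no
#'   successor (minutes, default 5).
#' @param exercise_contents motion contents that count toward exercise.
#' @return list of class `ruleset`.
#' @export
default_ruleset <- function(session_window_min = 30, rule4_timeout_min = 5,
                            exercise_contents = c(
                              "bending", "jacking", "jumping", "running",
                              "skipping", "siding", "walking", "waving")) {
  structure(list(session_window_min = session_window_min,
                 rule4_timeout_min = rule4_timeout_min,
                 exercise_contents = tolower(exercise_contents)),
            class = "ruleset")
}

day_of <- function(time) format(time, "%Y-%m-%d", tz = "UTC")

#' Apply the expert rules to an event stream
#'
#' Walks a time-sorted stream and emits decisions:
#' * exercise: at least 2 distinct motion contents by one person within the
#'   session window emit the high-level activity `"Exercise"` (once per
#'   person and day);
#' * medicine: an eating event with no prior taking-medicine event that day
#'   emits the reminder `"take medicine"` (once per day; a taking-medicine
#'   event satisfies the obligation);
#' * TV: a reading event while the TV is on emits `"turnOff(TV)"`;
#' * wrong movements: an unknown activity with no successor event within
#'   the timeout emits the reminder `"movements are wrong"`;
#' * lights: entering the kitchen or bedroom emits `"turnOn(lights)"` when
#'   the room's lights are off.
#' Once an obligation is satisfied or a decision emitted, the knowledge
#' base is updated so that replaying the stream produces no duplicates.
#'
#' @param events time-sorted `activity_events`.
#' @param kb `knowledge_base` (updated copy returned).
#' @param rules `ruleset`.
#' @param catalog `activity_catalog` used to recognize unknown activities.
#' @return list with `decisions` (data frame `kind`, `payload`, `triggers`
#'   (list of event ids), `time`) and the updated `kb`.
#' @export
apply_rules <- function(events, kb = knowledge_base(),
                        rules = default_ruleset(),
                        catalog = activity_catalog()) {
  check_that(inherits(kb, "knowledge_base"), "kb must be a knowledge_base")
  if (nrow(events) > 1)
    check_that(!is.unsorted(events$time), "event stream must be time-sorted")
  dec <- list()
  emit <- function(kind, payload, triggers, time)
    dec[[length(dec) + 1L]] <<- data.frame(
      kind = kind, payload = payload,
      triggers = I(list(as.character(triggers))), time = time,
      stringsAsFactors = FALSE)
  n <- nrow(events)
  next_time <- if (n) c(events$time[-1], as.POSIXct(NA)) else as.POSIXct(character())
  for (i in seq_len(n)) {
    ev <- events[i, ]
    nm <- tolower(ev$name)
    day <- day_of(ev$time)
    known <- nm %in% catalog$known
    if (!known) {                                    # wrong-movements rule
      gap <- as.numeric(difftime(next_time[i], ev$time, units = "mins"))
      if ((is.na(gap) || gap > rules$rule4_timeout_min) &&
          !(ev$id %in% kb$rule4_done)) {
        emit("reminder", "movements are wrong", ev$id, ev$time)
        kb$rule4_done <- c(kb$rule4_done, ev$id)
      }
      next
    }
    if (nm %in% c("watching tv", "tv on")) kb$tv_on <- TRUE
    if (nm == "taking medicine") {
      kb$medicine_taken <- union(kb$medicine_taken, day)
    }
    if (nm == "eating" && !(day %in% kb$medicine_taken) &&
        !(day %in% kb$medicine_reminded)) {          # medicine rule
      emit("reminder", "take medicine", ev$id, ev$time)
      kb$medicine_reminded <- union(kb$medicine_reminded, day)
    }
    if (nm == "reading" && isTRUE(kb$tv_on)) {       # TV rule
      emit("device_command", "turnOff(TV)", ev$id, ev$time)
      kb$tv_on <- FALSE
    }
    if (nm %in% c("entering kitchen", "entering bedroom")) {   # lights rule
      room <- sub("entering ", "", nm)
      if (!(room %in% kb$lights_on)) {
        emit("device_command", "turnOn(lights)", ev$id, ev$time)
        kb$lights_on <- c(kb$lights_on, room)
      }
    }
    if (nm %in% rules$exercise_contents) {           # exercise rule
      key <- paste(day, ev$person, sep = "|")
      if (!(key %in% kb$exercise_emitted)) {
        win <- events$time >= ev$time - rules$session_window_min * 60 &
          events$time <= ev$time &
          events$person == ev$person &
          tolower(events$name) %in% rules$exercise_contents
        contents <- unique(tolower(events$name[win]))
        if (length(contents) >= 2) {
          emit("high_level_activity", "Exercise", events$id[win], ev$time)
          kb$exercised <- union(kb$exercised, day)
          kb$exercise_emitted <- c(kb$exercise_emitted, key)
        }
      }
    }
  }
  decisions <- if (length(dec)) do.call(rbind, dec) else
    data.frame(kind = character(), payload = character(),
               triggers = I(list()), time = as.POSIXct(character()),
               stringsAsFactors = FALSE)
  rownames(decisions) <- NULL
  list(decisions = decisions, kb = kb)
}

#' Match predicted against true activity events
#'
#' Greedy deterministic 1-to-1 matching: predicted events are visited in
#' time order and each is paired with the earliest unmatched true event of
#' equal (case-insensitive) name within the time tolerance.
#'
#' @param predicted,truth time-sorted event streams (need `name`, `time`,
#'   `id`).
#' @param tolerance matching window in seconds (default 60).
#' @return list with `matched` (data frame `pred_id`, `truth_id`, `dt`),
#'   `unmatched_pred`, `unmatched_truth` (event streams).
#' @export
match_activities <- function(predicted, truth, tolerance = 60) {
  for (s in list(predicted, truth))
    if (nrow(s) > 1) check_that(!is.unsorted(s$time), "streams must be time-sorted")
  used <- rep(FALSE, nrow(truth))
  pairs <- list()
  for (i in seq_len(nrow(predicted))) {
    cand <- which(!used &
                    tolower(truth$name) == tolower(predicted$name[i]) &
                    abs(as.numeric(difftime(truth$time, predicted$time[i],
                                            units = "secs"))) <= tolerance)
    if (length(cand)) {
      j <- cand[1]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        pred_id = predicted$id[i], truth_id = truth$id[j],
        dt = as.numeric(difftime(predicted$time[i], truth$time[j],
                                 units = "secs")),
        stringsAsFactors = FALSE)
    }
  }
  matched <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pred_id = character(), truth_id = character(), dt = numeric(),
               stringsAsFactors = FALSE)
  list(matched = matched,
       unmatched_pred = predicted[!predicted$id %in% matched$pred_id, , drop = FALSE],
       unmatched_truth = truth[!used, , drop = FALSE])
}

#' Precision and recall of the match-making phase
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. An empty
#' denominator is reported as 1.0 with the corresponding flag set
#' (documented convention: no predictions means no false alarms; no truth
#' means nothing missed).
#'
#' @param matched matched pairs (data frame or count).
#' @param unmatched_pred,unmatched_truth unmatched streams (or counts).
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `precision_undefined`, `recall_undefined`.
#' @export
evaluate_matchmaking <- function(matched, unmatched_pred, unmatched_truth) {
  cnt <- function(z) if (is.data.frame(z)) nrow(z) else as.integer(z)
  tp <- cnt(matched); fp <- cnt(unmatched_pred); fn <- cnt(unmatched_truth)
  check_that(tp >= 0 && fp >= 0 && fn >= 0, "counts must be nonnegative")
  pu <- tp + fp == 0; ru <- tp + fn == 0
  list(precision = if (pu) 1.0 else tp / (tp + fp),
       recall = if (ru) 1.0 else tp / (tp + fn),
       tp = tp, fp = fp, fn = fn,
       precision_undefined = pu, recall_undefined = ru)
}
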