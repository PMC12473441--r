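#' Borg CR-10 posture risk table
#'
#' Biomechanical-risk scores on the Borg CR-10 scale (1 = optimal, 10 =
#' most harmful) for the 19 postures. The defaults encode the package's
#' risk matrix (neutral upright 1; unsupported forward flexion 10; lateral
#' leans 7; leg crosses 8; reclined ankle-rest/leg-cross combinations 10;
#' trunk rotations 8; semi-recline 3; lounge 4). The scores are provisional
#' by design and user-editable.
#'
#' @param scores named numeric vector mapping `SP1`..`SP19` to scores in
#'   1..10; defaults as above. Mirrored posture pairs carry equal scores.
#' @return An object of class `posture_risk_table`.
#' @export
posture_risk_table <- function(scores = NULL) {
  default <- c(SP1 = 1, SP2 = 10, SP3 = 7, SP4 = 7, SP5 = 3, SP6 = 8,
               SP7 = 8, SP8 = 9, SP9 = 6, SP10 = 7, SP11 = 7, SP12 = 4,
               SP13 = 9, SP14 = 10, SP15 = 10, SP16 = 10, SP17 = 10,
               SP18 = 8, SP19 = 8)
  if (is.null(scores)) scores <- default
  need <- posture_codes()
  if (!all(need %in% names(scores))) {
    stop("risk table must cover all of SP1..SP19", call. = FALSE)
  }
  scores <- scores[need]
  if (any(scores < 1) || any(scores > 10)) {
    stop("Borg CR-10 scores must lie in [1, 10]", call. = FALSE)
  }
  structure(list(scores = scores), class = "posture_risk_table")
}

#' @rdname posture_risk_table
#' @param table a `posture_risk_table`.
#' @param posture posture code(s).
#' @export
risk_score <- function(table = posture_risk_table(), posture) {
  stopifnot(inherits(table, "posture_risk_table"))
  assert_posture_codes(posture, include_empty = FALSE)
  unname(table$scores[posture])
}

#' Decay-factor ruleset
#'
#' The duration-dependent penalty coefficient D of the quality score. The
#' default rules: an upright posture is free for its first 30 minutes and
#' decays at 0.005 beyond; a non-upright posture is tolerated for 30
#' seconds (brief adjustments) and decays at 0.02 beyond. Durations on the
#' boundary belong to the low-duration (zero-decay) rule. Thresholds are
#' stored in minutes.
#'
#' @param upright_threshold_min upright static-duration threshold, minutes.
#' @param upright_decay decay factor past the upright threshold.
#' @param other_threshold_min non-upright tolerance threshold, minutes.
#' @param other_decay decay factor past the non-upright threshold.
#' @param upright_set posture codes counted as upright context (default
#'   only SP1, the neutral spine posture).
#' @return An object of class `decay_ruleset` whose `rules` element lists
#'   the four (context, duration predicate, D) rules.
#' @export
decay_ruleset <- function(upright_threshold_min = 30, upright_decay = 0.005,
                          other_threshold_min = 0.5, other_decay = 0.02,
                          upright_set = "SP1") {
  stopifnot(upright_decay >= 0, other_decay >= 0,
            upright_threshold_min >= 0, other_threshold_min >= 0)
  assert_posture_codes(upright_set, include_empty = FALSE)
  rules <- data.frame(
    id = 1:4,
    context = c("upright", "upright", "not_upright", "not_upright"),
    duration = c(sprintf("T <= %g min", upright_threshold_min),
                 sprintf("T > %g min", upright_threshold_min),
                 sprintf("T <= %g min", other_threshold_min),
                 sprintf("T > %g min", other_threshold_min)),
    decay = c(0, upright_decay, 0, other_decay)
  )
  structure(list(rules = rules,
                 upright_threshold_min = upright_threshold_min,
                 upright_decay = upright_decay,
                 other_threshold_min = other_threshold_min,
                 other_decay = other_decay,
                 upright_set = upright_set),
            class = "decay_ruleset")
}

#' Decay factor for a held posture
#'
#' @param posture posture code (SP1..SP19).
#' @param T_min duration the posture has been maintained, minutes.
#' @param ruleset a [decay_ruleset()].
#' @return The decay factor D of the unique matching rule.
#' @examples
#' decay_factor("SP1", 45)   # upright past 30 min -> 0.005
#' decay_factor("SP3", 1/3)  # 20 s non-upright tolerance -> 0
#' @export
decay_factor <- function(posture, T_min, ruleset = decay_ruleset()) {
  stopifnot(inherits(ruleset, "decay_ruleset"))
  assert_posture_codes(posture, include_empty = FALSE)
  if (any(T_min < 0)) stop("duration must be non-negative", call. = FALSE)
  upright <- posture %in% ruleset$upright_set
  thr <- ifelse(upright, ruleset$upright_threshold_min,
                ruleset$other_threshold_min)
  dec <- ifelse(upright, ruleset$upright_decay, ruleset$other_decay)
  ifelse(T_min <= thr, 0, dec)
}

#' Sitting-quality score
#'
#' `QS = 1 / (1 + S + D * T)` where S is the posture's Borg CR-10 risk
#' score, T the held duration in minutes and D the context-dependent decay
#' factor. QS is a fraction in (0, 0.5]: the neutral posture scores 0.5
#' while fresh and every risk or duration penalty strictly lowers the
#' score.
#'
#' @param S Borg CR-10 risk score (>= 1).
#' @param D decay factor (>= 0).
#' @param T_min held duration in minutes (>= 0).
#' @return The quality score.
#' @examples
#' quality_score(S = 1, D = 0, T_min = 10)       # 0.5
#' quality_score(S = 10, D = 0.02, T_min = 60)   # 1/12.2
#' @export
quality_score <- function(S, D, T_min) {
  if (any(S < 1)) stop("Borg score S must be >= 1", call. = FALSE)
  if (any(D < 0) || any(T_min < 0)) {
    stop("decay factor and duration must be non-negative", call. = FALSE)
  }
  1 / (1 + S + D * T_min)
}

#' Segment a posture prediction stream into episodes
#'
#' Collapses an ordered (timestamp, posture) stream into maximal runs of
#' identical labels. Episode boundaries sit at the midpoint between
#' adjacent differing samples; the first and last episodes extend to the
#' stream ends. Runs shorter than `min_episode` seconds are debounced:
#' merged into the longer neighbouring episode, repeatedly, so isolated
#' misclassifications do not fragment the timeline.
#'
#' @param timestamps strictly increasing sample times, seconds.
#' @param postures posture code per sample.
#' @param min_episode debounce threshold in seconds (0 disables).
#' @return A `session_timeline`: data frame of `posture`, `start`, `end`
#'   and `duration_min`, with the source sampling period as an attribute.
#' @export
segment_episodes <- function(timestamps, postures, min_episode = 0) {
  stopifnot(length(timestamps) == length(postures), length(timestamps) > 0)
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  postures <- as.character(postures)
  r <- rle(postures)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1, head(ends_idx, -1) + 1)
  bounds <- function(si, ei) {
    start <- if (si == 1) timestamps[1] else
      (timestamps[si - 1] + timestamps[si]) / 2
    end <- if (ei == length(timestamps)) timestamps[ei] else
      (timestamps[ei] + timestamps[ei + 1]) / 2
    c(start, end)
  }
  ep <- t(mapply(bounds, starts_idx, ends_idx))
  tl <- data.frame(posture = r$values, start = ep[, 1], end = ep[, 2])
  if (min_episode > 0 && nrow(tl) > 1) {
    # per-episode sample support by label; merged episodes keep the tally so
    # the surviving label is the per-sample majority over the merged span
    support <- mapply(function(v, l) setNames(l, v), r$values, r$lengths,
                      SIMPLIFY = FALSE)
    start <- tl$start; end <- tl$end
    repeat {
      dur <- end - start
      short <- which(dur < min_episode)
      if (length(short) == 0 || length(dur) == 1) break
      i <- short[which.min(dur[short])]
      left <- if (i > 1) dur[i - 1] else -Inf
      right <- if (i < length(dur)) dur[i + 1] else -Inf
      j <- if (left >= right) i - 1L else i + 1L
      merged <- tapply(c(support[[i]], support[[j]]),
                       names(c(support[[i]], support[[j]])), sum)
      k <- min(i, j)
      support[[k]] <- merged
      start[k] <- min(start[i], start[j]); end[k] <- max(end[i], end[j])
      drop <- max(i, j)
      support <- support[-drop]; start <- start[-drop]; end <- end[-drop]
    }
    lab <- vapply(support, function(s) names(s)[which.max(s)], character(1))
    keep <- c(TRUE, lab[-1] != head(lab, -1))
    grp <- cumsum(keep)
    tl <- data.frame(posture = lab[keep],
                     start = as.numeric(tapply(start, grp, min)),
                     end = as.numeric(tapply(end, grp, max)))
    rownames(tl) <- NULL
  }
  tl$duration_min <- (tl$end - tl$start) / 60
  attr(tl, "sampling_period") <- stats::median(diff(timestamps))
  class(tl) <- c("session_timeline", class(tl))
  tl
}

#' Score a session timeline over time
#'
#' Walks each episode in steps of `step` seconds; at each step the elapsed
#' time T within the current episode sets the decay factor and the quality
#' score `QS = 1/(1+S+D*T)`. Holding the neutral posture is free (flat
#' QS = 0.5) until the upright threshold, after which the score decays;
#' non-upright postures start decaying after their 30-second tolerance.
#'
#' @param timeline a `session_timeline` from [segment_episodes()].
#' @param risk_table a [posture_risk_table()].
#' @param ruleset a [decay_ruleset()].
#' @param step evaluation step in seconds.
#' @return List with `series` (data frame `time`, `posture`, `qs`) and
#'   `episodes` (per-episode mean/min QS and final T).
#' @export
score_timeline <- function(timeline, risk_table = posture_risk_table(),
                           ruleset = decay_ruleset(), step = 1) {
  stopifnot(inherits(timeline, "session_timeline"), step > 0)
  series <- vector("list", nrow(timeline))
  episodes <- timeline
  episodes$mean_qs <- NA_real_
  episodes$min_qs <- NA_real_
  for (i in seq_len(nrow(timeline))) {
    tt <- seq(timeline$start[i], timeline$end[i], by = step)
    T_min <- (tt - timeline$start[i]) / 60
    S <- risk_score(risk_table, timeline$posture[i])
    D <- decay_factor(rep(timeline$posture[i], length(T_min)), T_min, ruleset)
    qs <- quality_score(S, D, T_min)
    series[[i]] <- data.frame(time = tt, posture = timeline$posture[i],
                              qs = qs)
    episodes$mean_qs[i] <- mean(qs)
    episodes$min_qs[i] <- min(qs)
  }
  list(series = do.call(rbind, series), episodes = episodes)
}

#' Session summary analytics
#'
#' Per-posture time totals and percentages, episode counts, the longest
#' static episode and the time-weighted mean quality score of the whole
#' session (QS integrated at `step`-second resolution and weighted by
#' time).
#'
#' @inheritParams score_timeline
#' @return List with `per_posture` (minutes and percentage per posture),
#'   `n_episodes`, `longest_static` (posture and minutes),
#'   `mean_qs` and `history` (the Fig-7-style list of posture/start/end
#'   records, seconds since session start).
#' @export
session_summary <- function(timeline, risk_table = posture_risk_table(),
                            ruleset = decay_ruleset(), step = 1) {
  stopifnot(inherits(timeline, "session_timeline"))
  dur <- timeline$duration_min
  per <- aggregate(dur, by = list(posture = timeline$posture), FUN = sum)
  names(per)[2] <- "minutes"
  per$percent <- 100 * per$minutes / sum(per$minutes)
  scored <- score_timeline(timeline, risk_table, ruleset, step = step)
  longest <- which.max(dur)
  list(per_posture = per[order(-per$minutes), ],
       n_episodes = nrow(timeline),
       longest_static = list(posture = timeline$posture[longest],
                             minutes = dur[longest]),
       mean_qs = mean(scored$series$qs),
       history = timeline[, c("posture", "start", "end")])
}

#' Historical posture timeline as JSON
#'
#' Serializes a timeline to the history interchange format: a JSON array of
#' `{posture, start, end}` objects in chronological order with ISO-8601
#' timestamps. The serialization is canonical (fixed field order, UTC,
#' whole-second precision), so write -> read -> write is byte-stable.
#'
#' @param timeline a `session_timeline`.
#' @param origin POSIXct session start used to anchor the relative episode
#'   times.
#' @return `render_history_json()` returns the JSON text;
#'   `read_history_json()` parses it back into a `session_timeline`.
#' @export
render_history_json <- function(timeline,
                                origin = as.POSIXct("2025-01-01 09:00:00",
                                                    tz = "UTC")) {
  stopifnot(inherits(timeline, "session_timeline"))
  if (nrow(timeline) == 0) return("[]")
  iso <- function(s) format(origin + round(s), "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  df <- data.frame(posture = timeline$posture,
                   start = iso(timeline$start), end = iso(timeline$end),
                   stringsAsFactors = FALSE)
  as.character(jsonlite::toJSON(df, auto_unbox = FALSE, pretty = FALSE))
}

#' @rdname render_history_json
#' @param text JSON text produced by `render_history_json()` (or the same
#'   format from another tool).
#' @export
read_history_json <- function(text,
                              origin = as.POSIXct("2025-01-01 09:00:00",
                                                  tz = "UTC")) {
  df <- jsonlite::fromJSON(text)
  if (length(df) == 0) {
    tl <- data.frame(posture = character(0), start = numeric(0),
                     end = numeric(0), duration_min = numeric(0))
    class(tl) <- c("session_timeline", class(tl))
    return(tl)
  }
  start <- as.numeric(difftime(as.POSIXct(df$start, tz = "UTC",
                                          format = "%Y-%m-%dT%H:%M:%SZ"),
                               origin, units = "secs"))
  end <- as.numeric(difftime(as.POSIXct(df$end, tz = "UTC",
                                        format = "%Y-%m-%dT%H:%M:%SZ"),
                             origin, units = "secs"))
  tl <- data.frame(posture = df$posture, start = start, end = end)
  tl$duration_min <- (tl$end - tl$start) / 60
  class(tl) <- c("session_timeline", class(tl))
  tl
}

#' Rule-based session recommendations
#'
#' A deterministic text summary of the analytics that downstream feedback
#' interfaces (or a language-model prompt) would consume: dominant posture,
#' longest static episode, and any episode held past its decay threshold.
#'
#' @inheritParams score_timeline
#' @return Character vector of human-readable findings.
#' @export
session_recommendations <- function(timeline,
                                    risk_table = posture_risk_table(),
                                    ruleset = decay_ruleset()) {
  stopifnot(inherits(timeline, "session_timeline"))
  s <- session_summary(timeline, risk_table, ruleset)
  top <- s$per_posture[1, ]
  out <- sprintf("Dominant posture: %s (%.1f min, %.0f%% of the session).",
                 top$posture, top$minutes, top$percent)
  out <- c(out, sprintf("Longest static episode: %s for %.1f min.",
                        s$longest_static$posture, s$longest_static$minutes))
  thr <- ifelse(timeline$posture %in% ruleset$upright_set,
                ruleset$upright_threshold_min, ruleset$other_threshold_min)
  over <- which(timeline$duration_min > thr)
  for (i in over) {
    out <- c(out, sprintf(
      "%s held %.1f min exceeded its %s threshold of %.1f min; consider a change of posture.",
      timeline$posture[i], timeline$duration_min[i],
      ifelse(timeline$posture[i] %in% ruleset$upright_set, "static-upright",
             "non-upright"),
      thr[i]))
  }
  if (s$mean_qs < 0.2) {
    out <- c(out, sprintf(
      "Mean sitting quality %.2f is low; favour the neutral upright posture with regular breaks.",
      s$mean_qs))
  }
  out
}
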