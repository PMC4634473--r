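# Destination posture of each transition label.
TRANSITION_DEST <- c(
  sit_stand = "stand", stand_sit = "sit", sit_lie = "lie",
  lie_sit = "sit", stand_lie = "lie", lie_stand = "stand"
)
TRANSITION_SRC <- c(
  sit_stand = "sit", stand_sit = "stand", sit_lie = "sit",
  lie_sit = "lie", stand_lie = "stand", lie_stand = "lie"
)

#' Posture occupancy timeline from classified transitions
#'
#' Replays a time-ordered sequence of classified transition events through a
#' three-state machine over sit / stand / lie, producing the per-state dwell
#' times and transition counts that summarise a subject's day.  Each event
#' moves the machine to the transition's destination posture at its
#' timestamp.  When an event's source posture disagrees with the current
#' state (a classification error upstream), the machine still adopts the
#' destination — the classifier's best estimate of the new posture — and
#' increments an inconsistency counter.  `no_movement` and `other_movement`
#' windows produce no timeline events.
#'
#' @param events Data frame with columns `time_s` (strictly increasing) and
#'   `label` (one of the six transition labels).  Rows with non-transition
#'   labels are dropped.
#' @param initial_state Posture at the start of the span: `"sit"`,
#'   `"stand"` or `"lie"`.
#' @param span Numeric length-2 vector `(t0, t1)`; all events must lie
#'   inside it.  Occupancy durations sum exactly to `t1 - t0`.
#' @return A `posture_timeline` object: list with `occupancy` (tibble of
#'   state and seconds), `transition_counts`, `segments` (state intervals),
#'   `n_inconsistent` and `span`.
#' @export
#' @examples
#' ev <- data.frame(time_s = c(10, 20), label = c("stand_sit", "sit_lie"))
#' posture_timeline(ev, initial_state = "stand", span = c(0, 30))
posture_timeline <- function(events, initial_state = c("stand", "sit", "lie"),
                             span) {
  initial_state <- match.arg(initial_state)
  stopifnot(length(span) == 2, span[2] >= span[1])
  events <- tibble::as_tibble(events)
  events <- events[events$label %in% TRANSITION_LABELS, ]
  if (nrow(events) > 1 && any(diff(events$time_s) < 0)) {
    abort("events must be in time order", class = "wristpose_ordering_error")
  }
  if (nrow(events) > 0 &&
      (min(events$time_s) < span[1] || max(events$time_s) > span[2])) {
    abort("events must lie within the span",
          class = "wristpose_parameter_error")
  }

  state <- initial_state
  t_prev <- span[1]
  n_inconsistent <- 0L
  seg_state <- character(0)
  seg_start <- numeric(0)
  seg_end <- numeric(0)

  for (i in seq_len(nrow(events))) {
    lab <- events$label[i]
    tt <- events$time_s[i]
    if (TRANSITION_SRC[[lab]] != state) n_inconsistent <- n_inconsistent + 1L
    seg_state <- c(seg_state, state)
    seg_start <- c(seg_start, t_prev)
    seg_end <- c(seg_end, tt)
    state <- TRANSITION_DEST[[lab]]
    t_prev <- tt
  }
  seg_state <- c(seg_state, state)
  seg_start <- c(seg_start, t_prev)
  seg_end <- c(seg_end, span[2])

  segments <- tibble::tibble(
    state = seg_state, start_s = seg_start, end_s = seg_end
  )
  occupancy <- purrr::map_dfr(c("sit", "stand", "lie"), function(s) {
    tibble::tibble(
      state = s,
      seconds = sum(segments$end_s[segments$state == s] -
                      segments$start_s[segments$state == s])
    )
  })
  counts <- purrr::map_dfr(TRANSITION_LABELS, function(lab) {
    tibble::tibble(label = lab, n = sum(events$label == lab))
  })

  structure(
    list(occupancy = occupancy, transition_counts = counts,
         segments = segments, n_inconsistent = n_inconsistent, span = span),
    class = "posture_timeline"
  )
}

#' @export
print.posture_timeline <- function(x, ...) {
  cat(sprintf("<posture_timeline> span %.1f-%.1f s, %d transitions (%d inconsistent)\n",
              x$span[1], x$span[2], sum(x$transition_counts$n),
              x$n_inconsistent))
  print(x$occupancy)
  invisible(x)
}

#' @describeIn posture_timeline Occupancy and transition counts as one tidy
#'   table.
#' @param x A `posture_timeline` object.
#' @param ... Unused.
#' @export
tidy.posture_timeline <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$occupancy, quantity = "occupancy_s",
                  value = .data$seconds, .keep = "unused") |>
      dplyr::rename(name = "state"),
    dplyr::mutate(x$transition_counts, quantity = "transition_count",
                  value = as.numeric(.data$n), .keep = "unused") |>
      dplyr::rename(name = "label")
  )
}

#' @describeIn posture_timeline Horizontal state band over the span, the
#'   daily summary view.
#' @param object A `posture_timeline` object.
#' @export
autoplot.posture_timeline <- function(object, ...) {
  ggplot2::ggplot(object$segments) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_s, xmax = .data$end_s,
      ymin = 0, ymax = 1, fill = .data$state
    )) +
    ggplot2::scale_fill_manual(values = c(
      sit = "#e2b007", stand = "#4daf4a", lie = "#377eb8"
    )) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "posture",
                  title = "Posture occupancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Daily posture summary table
#'
#' Splits classified transition events into calendar days (fixed-length
#' spans) and reports per-day state occupancy and transition counts — the
#' clinician-facing weekly view.
#'
#' @inheritParams posture_timeline
#' @param day_length_s Length of one day-span in seconds (default 86400).
#' @return Tibble with one row per day and state: `day`, `state`,
#'   `occupancy_s`, plus total transition count per day.
#' @export
summarize_days <- function(events, initial_state = "stand",
                           span = NULL, day_length_s = 86400) {
  events <- tibble::as_tibble(events)
  events <- events[events$label %in% TRANSITION_LABELS, ]
  span <- span %||% c(0, max(c(events$time_s, day_length_s)))
  n_days <- ceiling((span[2] - span[1]) / day_length_s)
  state <- initial_state
  out <- purrr::map_dfr(seq_len(n_days), function(d) {
    t0 <- span[1] + (d - 1) * day_length_s
    t1 <- min(t0 + day_length_s, span[2])
    ev <- events[events$time_s >= t0 & events$time_s < t1, ]
    tl <- posture_timeline(ev, initial_state = state, span = c(t0, t1))
    if (nrow(ev) > 0) {
      state <<- tail(tl$segments$state, 1)
    }
    dplyr::mutate(tl$occupancy, day = d, n_transitions = sum(tl$transition_counts$n),
                  .before = 1)
  })
  dplyr::rename(out, occupancy_s = "seconds")
}
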