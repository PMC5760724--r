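# Intervention policies. The interactive pop-up of a hybrid tracker is
# generalized to a decision contract: when the engine cannot resolve a frame
# on its own it emits an intervention request and the active policy answers
# with a decision. Requests:
#   kind = "no_maximum"  (nothing bright enough in the scan region;
#                         legal actions: stop, manual, gap)
#   kind = "overlap"     (>= 2 candidates in the scan region;
#                         legal actions: manual, linear_motion, pick_candidate)
# A decision is a list(action, manual_position = c(x, y), candidate_index).

intervention_request <- function(kind, track_id, frame, scan_region,
                                 candidates = list()) {
  if (kind == "no_maximum" && length(candidates) != 0L) {
    stop("no_maximum request carries no candidates", call. = FALSE)
  }
  if (kind == "overlap" && length(candidates) < 2L) {
    stop("overlap request needs >= 2 candidates", call. = FALSE)
  }
  structure(list(kind = kind, track_id = track_id, frame = frame,
                 scan_region = scan_region, candidates = candidates),
            class = "intervention_request")
}

intervention_decision <- function(action, manual_position = NULL,
                                  candidate_index = NULL) {
  if (action == "manual" && (is.null(manual_position) || length(manual_position) != 2L)) {
    stop("action 'manual' requires a (x, y) manual_position", call. = FALSE)
  }
  if (action == "pick_candidate" && is.null(candidate_index)) {
    stop("action 'pick_candidate' requires a candidate_index", call. = FALSE)
  }
  list(action = action, manual_position = manual_position,
       candidate_index = candidate_index)
}

legal_actions <- list(no_maximum = c("stop", "manual", "gap"),
                      overlap = c("manual", "linear_motion", "pick_candidate"))

check_decision <- function(request, decision) {
  if (!decision$action %in% legal_actions[[request$kind]]) {
    stop(sprintf("policy returned illegal action '%s' for a %s request (track %d, frame %d)",
                 decision$action, request$kind, request$track_id, request$frame),
         call. = FALSE)
  }
  decision
}

new_policy <- function(name, decide) {
  structure(list(name = name, decide = decide), class = "track_policy")
}

#' @export
print.track_policy <- function(x, ...) {
  cat(sprintf("intervention policy: %s\n", x$name)); invisible(x)
}

#' Automatic (hands-off) intervention policy
#'
#' Resolves every request without a human: a frame with no bright-enough
#' maximum becomes a gap, and a two-particle overlap is resolved by linear
#' extrapolation of the particle's previous velocity (falling back to the
#' candidate nearest the previous position while the track is too short to
#' have a velocity).
#'
#' @return A `track_policy`.
#' @export
policy_automatic <- function() {
  new_policy("automatic", function(request, track, config) {
    if (request$kind == "no_maximum") return(intervention_decision("gap"))
    pts <- track$points
    have_vel <- sum(is.finite(pts$x) & pts$status != "stopped") >= 2L
    if (have_vel) return(intervention_decision("linear_motion"))
    last <- last_localized_point(track)
    d <- vapply(request$candidates, function(cd) {
      (cd$col - last$x)^2 + (cd$row - last$y)^2
    }, numeric(1))
    intervention_decision("pick_candidate", candidate_index = which.min(d))
  })
}

#' Scripted intervention policy
#'
#' Replays pre-recorded decisions from a table with columns `frame`,
#' `track_id`, `action`, and optional `x`, `y` (required when
#' `action = "manual"`) and `candidate_index` (required for
#' `"pick_candidate"`). Together with a fixed movie and configuration this
#' makes a tracking run fully reproducible.
#'
#' @param decisions Data frame of decisions (e.g. from [read_decisions()]).
#'
#' @return A `track_policy`.
#' @export
policy_scripted <- function(decisions) {
  decisions <- as.data.frame(decisions)
  required <- c("frame", "track_id", "action")
  if (!all(required %in% names(decisions))) {
    stop("decisions table needs columns frame, track_id, action", call. = FALSE)
  }
  new_policy("scripted", function(request, track, config) {
    hit <- which(decisions$frame == request$frame &
                   decisions$track_id == request$track_id)
    if (length(hit) == 0L) {
      stop(sprintf("no scripted decision for track %d at frame %d (%s request)",
                   request$track_id, request$frame, request$kind), call. = FALSE)
    }
    row <- decisions[hit[1L], ]
    pos <- if (!is.null(row$x) && is.finite(row$x)) c(row$x, row$y) else NULL
    idx <- if (!is.null(row$candidate_index) && is.finite(row$candidate_index)) {
      as.integer(row$candidate_index)
    } else NULL
    intervention_decision(as.character(row$action), manual_position = pos,
                          candidate_index = idx)
  })
}

#' Ground-truth oracle policy (for validation)
#'
#' Answers every request from simulator ground truth: an invisible (blinked)
#' particle becomes a gap, a missed visible particle is re-seeded manually at
#' its true position, and an overlap is resolved by picking the candidate
#' nearest the true position. Only meaningful on synthetic movies.
#'
#' @param truth Ground-truth data frame from [simulate_movie()].
#' @param particle_ids Mapping from track id to truth `particle_id`; defaults
#'   to the identity (track i follows particle i).
#'
#' @return A `track_policy`.
#' @export
policy_oracle <- function(truth, particle_ids = NULL) {
  new_policy("oracle", function(request, track, config) {
    pid <- if (is.null(particle_ids)) request$track_id else particle_ids[request$track_id]
    row <- truth[truth$particle_id == pid & truth$frame == request$frame, ]
    if (nrow(row) != 1L) {
      stop(sprintf("oracle has no ground truth for particle %d at frame %d",
                   pid, request$frame), call. = FALSE)
    }
    if (request$kind == "no_maximum") {
      if (!row$visible) return(intervention_decision("gap"))
      return(intervention_decision("manual",
                                   manual_position = c(row$x_true, row$y_true)))
    }
    d <- vapply(request$candidates, function(cd) {
      (cd$col - row$x_true)^2 + (cd$row - row$y_true)^2
    }, numeric(1))
    intervention_decision("pick_candidate", candidate_index = which.min(d))
  })
}

#' Interactive console policy
#'
#' Minimal stand-in for a GUI prompt: prints the request and reads the action
#' (and coordinates, when manual) from the console. Only usable in an
#' interactive session; batch runs should use [policy_automatic()] or
#' [policy_scripted()].
#'
#' @return A `track_policy`.
#' @export
policy_interactive <- function() {
  new_policy("interactive", function(request, track, config) {
    if (!interactive()) {
      stop("interactive policy requires an interactive session", call. = FALSE)
    }
    cat(sprintf("track %d, frame %d: %s\n", request$track_id, request$frame,
                request$kind))
    if (length(request$candidates) > 0L) {
      for (i in seq_along(request$candidates)) {
        cd <- request$candidates[[i]]
        cat(sprintf("  candidate %d: (x=%d, y=%d), window mean %.2f\n",
                    i, cd$col, cd$row, cd$window_mean))
      }
    }
    cat(sprintf("actions: %s\n", paste(legal_actions[[request$kind]], collapse = ", ")))
    action <- trimws(readline("action> "))
    pos <- NULL; idx <- NULL
    if (action == "manual") {
      pos <- c(as.numeric(readline("x> ")), as.numeric(readline("y> ")))
    } else if (action == "pick_candidate") {
      idx <- as.integer(readline("candidate index> "))
    }
    intervention_decision(action, manual_position = pos, candidate_index = idx)
  })
}
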