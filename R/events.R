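# Event-chain assembly, ordering validation, and anesthesia-depth state
# labeling. The canonical event chain during induction/maintenance is
#   iso_start < theta_decay < delta_app < theta_disp < delta_disp
#             < strong_ies < gamma_rebound
# with every event time stored relative to tau_iso_start; the four protocol
# times (recording start/stop, anesthetic on/off) are absolute.

CHAIN_EVENTS <- c("tau_theta_decay", "tau_delta_app", "tau_theta_disp",
                  "tau_delta_disp", "tau_s", "tau_gamma")

#' Assemble the event-timestamp table for one recording
#'
#' Collects the outputs of the suppression, spectral and gamma analyses
#' into a single set of event timestamps; absent events stay `NA`.
#'
#' @param ies_sum From [ies_summary()].
#' @param prominence From [band_prominence_times()].
#' @param decay From [theta_decay()].
#' @param gamma From [detect_gamma_rebound()] (absolute onset; converted to
#'   a delay from `tau_iso_start` here). `NULL` when not computed.
#' @param rec The analyzed [ga_recording()] (protocol annotations).
#' @return An `event_times` list: absolute `tau_start_rec`,
#'   `tau_iso_start`, `tau_iso_stop`, `tau_rec_stop`, `tau_lom`, `tau_rom`;
#'   relative `tau_theta_decay`, `tau_delta_app`, `tau_theta_disp`,
#'   `tau_delta_disp`, `tau_ies1`, `tau_s`, `tau_gamma`.
#' @export
extract_event_chain <- function(ies_sum, prominence, decay, gamma, rec) {
  ann <- rec$annotations
  t0 <- ann$tau_iso_start %||% NA_real_
  structure(list(
    tau_start_rec = 0,
    tau_iso_start = t0,
    tau_iso_stop = ann$tau_iso_stop %||% NA_real_,
    tau_rec_stop = recording_duration(rec),
    tau_lom = ann$tau_lom %||% NA_real_,
    tau_rom = ann$tau_rom %||% NA_real_,
    tau_theta_decay = decay$tau_theta_decay,
    tau_delta_app = prominence$tau_delta_app,
    tau_theta_disp = prominence$tau_theta_disp,
    tau_delta_disp = prominence$tau_delta_disp,
    tau_ies1 = ies_sum$tau_ies1,
    tau_s = ies_sum$tau_s,
    tau_gamma = if (is.null(gamma) || is.na(gamma$tau_gamma)) NA_real_
                else gamma$tau_gamma - t0),
    class = "event_times")
}

#' @export
print.event_times <- function(x, ...) {
  cat("<event_times> (delays from tau_iso_start =", x$tau_iso_start, "s)\n")
  for (nm in c(CHAIN_EVENTS[1:4], "tau_ies1", CHAIN_EVENTS[5:6]))
    cat(sprintf("  %-16s %s\n", nm,
                if (is.na(x[[nm]])) "absent" else sprintf("%.1f s", x[[nm]])))
  invisible(x)
}

#' Validate the canonical event ordering
#'
#' Checks each adjacent inequality of the event chain among the PRESENT
#' events (absent events are skipped). Because the event times are
#' quantized on different window grids (20 s ratios, 30 s spectral frames),
#' an inequality only counts as violated when the later event precedes the
#' earlier one by more than `tol_s`.
#'
#' @param events An [extract_event_chain()] result.
#' @param tol_s Grid-quantization tolerance in seconds (one 20 s window).
#' @return List with `ordered` (logical) and `violations`
#'   (`data.frame` of offending pairs, zero rows when ordered).
#' @export
validate_order <- function(events, tol_s = 20) {
  nm <- c("tau_iso_start_rel", CHAIN_EVENTS)
  vals <- c(0, unlist(events[CHAIN_EVENTS], use.names = FALSE))
  pres <- which(!is.na(vals))
  viol <- data.frame(earlier = character(0), later = character(0),
                     gap_s = numeric(0), stringsAsFactors = FALSE)
  if (length(pres) >= 2) {
    for (k in 2:length(pres)) {
      i <- pres[k - 1]; j <- pres[k]
      if (vals[j] < vals[i] - tol_s)
        viol <- rbind(viol, data.frame(earlier = nm[i], later = nm[j],
                                       gap_s = vals[j] - vals[i]))
    }
  }
  list(ordered = nrow(viol) == 0, violations = viol)
}

#' Anesthesia state names
#' @export
ga_states <- function() c("Awake", "ThetaDecay", "ProminentDeltaTheta",
                          "ProminentDelta", "PreIES", "LightIES",
                          "StrongIES", "Movement", "GammaReboundMovement")

#' Allowed state-chart transitions
#'
#' Directed edge list of the anesthesia state chart (self-loops are always
#' allowed and not listed).
#'
#' @return `data.frame` with columns `from`, `to`.
#' @export
state_edges <- function() {
  e <- rbind(
    c("Awake", "ThetaDecay"),
    c("ThetaDecay", "ProminentDeltaTheta"),
    c("ProminentDeltaTheta", "ProminentDelta"),
    c("ProminentDelta", "PreIES"),
    c("ProminentDelta", "LightIES"),
    c("ProminentDelta", "Movement"),
    c("PreIES", "LightIES"),
    c("PreIES", "StrongIES"),
    c("PreIES", "Movement"),
    c("LightIES", "StrongIES"),
    c("LightIES", "Movement"),
    c("StrongIES", "GammaReboundMovement"),
    c("StrongIES", "Movement"),
    c("GammaReboundMovement", "Movement"))
  data.frame(from = e[, 1], to = e[, 2], stringsAsFactors = FALSE)
}

#' Label each window with an anesthesia state
#'
#' Decision cascade per 20 s window: before induction, `Awake`; after the
#' return of movement, `Movement` (or `GammaReboundMovement` while the
#' gamma rebound is active); windows inside a sustained strong-IES run,
#' `StrongIES`; `0 < IESSR <= 0.25` with delta prominent and theta not,
#' `LightIES`; both bands prominent, `ProminentDeltaTheta`; delta only,
#' `ProminentDelta`; theta only after induction, `ThetaDecay`; neither
#' band prominent and no IES, `PreIES`. Windows with missing flags get
#' `NA`.
#'
#' @param ratios A [power_ratios()] table (defines the 20 s grid).
#' @param prominence From [band_prominence_times()] on the same grid.
#' @param ies IES segment matrix.
#' @param events From [extract_event_chain()].
#' @param strong_thr,strong_persist_s Strong-IES definition.
#' @return `data.frame` with `center_s`, `state` (factor over
#'   [ga_states()]), `iessr`, `theta_prominent`, `delta_prominent`.
#' @export
label_states <- function(ratios, prominence, ies, events,
                         strong_thr = 0.25, strong_persist_s = 40) {
  centers <- ratios$center_s
  w <- stats::median(diff(centers))
  iessr <- vapply(centers, function(ct)
    overlap_duration(as_segments(ies), ct - w / 2, ct + w / 2) / w,
    numeric(1))
  t0 <- events$tau_iso_start
  rom <- events$tau_rom
  gamma_on <- !is.na(events$tau_gamma)
  gamma_start <- if (gamma_on) t0 + events$tau_gamma else Inf
  # windows belonging to any >= strong_persist_s run of high IES ratio
  high <- iessr > strong_thr
  runs <- runs_to_segments(high, 1 / w)   # in window-index time
  runs <- runs[segment_durations(runs) >= strong_persist_s, , drop = FALSE]
  in_strong <- vapply(seq_along(centers), function(i) {
    t <- (i - 0.5) * w
    nrow(runs) > 0 && any(t >= runs[, 1] & t < runs[, 2])
  }, logical(1))
  thp <- prominence$theta_prominent
  dep <- prominence$delta_prominent
  st <- character(length(centers))
  for (i in seq_along(centers)) {
    ct <- centers[i]
    st[i] <- if (is.na(thp[i]) || is.na(dep[i])) NA_character_
    else if (!is.na(t0) && ct < t0) "Awake"
    else if (!is.na(rom) && ct >= rom) {
      if (gamma_on && ct >= gamma_start) "GammaReboundMovement" else "Movement"
    }
    else if (in_strong[i]) "StrongIES"
    else if (iessr[i] > 0 && iessr[i] <= strong_thr && dep[i] && !thp[i])
      "LightIES"
    else if (thp[i] && dep[i]) "ProminentDeltaTheta"
    else if (dep[i]) "ProminentDelta"
    else if (thp[i]) "ThetaDecay"
    else "PreIES"
  }
  data.frame(center_s = centers,
             state = factor(st, levels = ga_states()),
             iessr = iessr, theta_prominent = thp, delta_prominent = dep)
}

#' Check that a labeled state sequence walks the state chart
#'
#' Collapses consecutive repeats (and skips missing windows) and verifies
#' every transition against [state_edges()].
#'
#' @param states A [label_states()] table.
#' @return List with `valid` and `bad_transitions` (`data.frame`).
#' @export
validate_state_path <- function(states) {
  s <- as.character(states$state)
  s <- s[!is.na(s)]
  s <- rle(s)$values
  edges <- state_edges()
  bad <- data.frame(from = character(0), to = character(0),
                    stringsAsFactors = FALSE)
  if (length(s) > 1) {
    for (k in 2:length(s)) {
      if (!any(edges$from == s[k - 1] & edges$to == s[k]))
        bad <- rbind(bad, data.frame(from = s[k - 1], to = s[k]))
    }
  }
  list(valid = nrow(bad) == 0, bad_transitions = bad)
}
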