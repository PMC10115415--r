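# Time-dependent scenarios: the transcription pulse that recruits RNA and
# Cyp33 into a pre-equilibrated MLL1/H3K4me3 system, single-component
# controls, and equilibrium parameter scans.

#' Construct a timed synthesis/decay scenario
#'
#' A scenario is a set of initial monomer totals plus a list of events. Each
#' event switches the active zeroth-order synthesis rates (uM/s, fed into the
#' free monomer) and first-order decay constants (s^-1, removing free monomer
#' only) from its time onward.
#'
#' @param initial_totals named monomer totals at t = 0, uM.
#' @param events list of events, each a list with `t_s` (event time, s),
#'   `synthesis` (named rates, uM/s) and `decay` (named rate constants,
#'   s^-1). Event times must be strictly increasing and positive.
#' @param t_end end of simulation, s.
#' @param pre_equilibrate equilibrate the initial totals before t = 0
#'   (otherwise start from free monomers only).
#' @return An object of class `scenario`.
#' @export
scenario <- function(initial_totals, events = list(), t_end = 3600,
                     pre_equilibrate = TRUE) {
  ts <- vapply(events, `[[`, numeric(1), "t_s")
  if (length(ts) && (any(diff(ts) <= 0) || any(ts <= 0)))
    stop("event times must be positive and strictly increasing", call. = FALSE)
  for (ev in events) {
    if (any(unlist(ev$synthesis) < 0) || any(unlist(ev$decay) < 0))
      stop("synthesis and decay rates must be non-negative", call. = FALSE)
  }
  if (length(ts) && t_end < max(ts)) stop("t_end precedes the last event")
  structure(list(initial_totals = initial_totals, events = events,
                 t_end = t_end, pre_equilibrate = isTRUE(pre_equilibrate)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> totals (%s), %d events, t_end %g s%s\n",
              paste(sprintf("%s=%g", names(x$initial_totals),
                            x$initial_totals), collapse = ", "),
              length(x$events), x$t_end,
              if (x$pre_equilibrate) ", pre-equilibrated" else ""))
  invisible(x)
}

# calibration cache: synthesis rates depend only on the network constants and
# pulse geometry, and solving them costs a handful of integrations
.calibration_cache <- new.env(parent = emptyenv())

# Solve the synthesis rates of R and C so each total peaks at `peak` uM at
# switch-off. Decay acts on free monomer only, so the effective loss rate
# depends on the bound fraction and the rates must be found numerically;
# fixed-point rescaling converges in a few rounds.
calibrate_pulse_rates <- function(network, initial_totals, peak, t_on, t_off,
                                  kdeg) {
  key <- paste(c(vapply(network$reactions, `[[`, numeric(1), "kd"),
                 network$reactions[[1]]$kon, initial_totals, peak, t_on,
                 t_off, kdeg), collapse = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)

  window <- t_off - t_on
  ksyn <- c(R = peak * kdeg / (1 - exp(-kdeg * window)),
            C = peak * kdeg / (1 - exp(-kdeg * window)))
  state0 <- equilibrate(network, initial_totals)
  total_of <- function(state, m) sum(network$conservation[[m]] * state)
  for (round in 1:12) {
    out <- integrate_network(network, state0,
                             times = seq(0, window, length.out = 25),
                             synthesis = ksyn, decay = c(R = kdeg, C = kdeg))
    final <- out[nrow(out), network$species]
    got <- c(R = total_of(final, "R"), C = total_of(final, "C"))
    if (max(abs(got / peak - 1)) < 1e-4) break
    ksyn <- ksyn * peak / got
  }
  .calibration_cache[[key]] <- ksyn
  ksyn
}

#' Transcription-pulse scenario of the chromatin switch
#'
#' The reference scenario: MLL1 reader and H3K4me3 tail equilibrated at 100 uM
#' each; at 5.6 min transcription starts, synthesising RNA and recruiting
#' Cyp33 (both with first-order decay at 0.005 s^-1 of the free species, and
#' synthesis rates calibrated so each total peaks at 100 uM); at 22 min
#' transcription stops and decay drains both back out of the system.
#'
#' @param params a [parameter_set()]; the network used for rate calibration
#'   is built from it.
#' @param components which monomers receive synthesis: both (`c("R", "C")`,
#'   the default), only RNA, or only Cyp33. Calibration always uses the
#'   two-component system, so single-component controls are identical except
#'   for the synthesis switched off.
#' @param initial_totals monomer totals equilibrated before the trigger, uM.
#' @param peak target maximum total per synthesised species, uM.
#' @param t_on,t_off transcription start and stop, s.
#' @param t_end end of simulation, s; long enough for the pulse to drain.
#' @param kdeg decay rate constant of free RNA and free Cyp33, s^-1.
#' @return A [scenario()] with two events (pulse on, pulse off).
#' @export
transcription_pulse_scenario <- function(params = default_parameter_set(),
                                         components = c("R", "C"),
                                         initial_totals = c(M = 100, H = 100),
                                         peak = 100, t_on = 336, t_off = 1320,
                                         t_end = 10800, kdeg = 0.005) {
  components <- match.arg(components, c("R", "C"), several.ok = TRUE)
  network <- build_network(params)
  ksyn <- calibrate_pulse_rates(network, initial_totals, peak, t_on, t_off,
                                kdeg)
  syn_on <- as.list(ksyn[components])
  decay <- list(R = kdeg, C = kdeg)
  scenario(initial_totals = initial_totals,
           events = list(
             list(t_s = t_on, synthesis = syn_on, decay = decay),
             list(t_s = t_off, synthesis = list(), decay = decay)),
           t_end = t_end, pre_equilibrate = TRUE)
}

#' Single- and two-component control scenarios
#'
#' The two-component pulse next to its controls where only RNA or only Cyp33
#' is synthesised (same calibrated rates and decay). Comparing the
#' active/repressive balance at switch-off across the three shows that both
#' components are required to tip the system into the repressive state.
#'
#' @inheritParams transcription_pulse_scenario
#' @return Named list of [scenario()] objects: `both`, `rna_only`,
#'   `cyp33_only`.
#' @export
control_scenarios <- function(params = default_parameter_set(), ...) {
  list(both = transcription_pulse_scenario(params, c("R", "C"), ...),
       rna_only = transcription_pulse_scenario(params, "R", ...),
       cyp33_only = transcription_pulse_scenario(params, "C", ...))
}

#' Partition the H3K4me3 pool into active and repressive states
#'
#' The transcriptionally active state counts the histone mark held by the
#' MLL1 reader, directly (`MH`) or within the ternary complex (`CMH`); the
#' repressive state counts the mark exposed to erasers: free (`H`) or
#' RNA-bound (`RH`). Every H-containing species must be assigned by the
#' classification, so user-extended networks fail loudly rather than
#' silently dropping mass.
#'
#' @param state named concentration vector over the network species, uM.
#' @param network the `reaction_network` the state belongs to.
#' @param classification list with character elements `active`, `repressive`
#'   and optionally `other`.
#' @return List with numeric elements `active`, `repressive`, `other` (uM of
#'   H equivalents).
#' @export
classify_state <- function(state, network,
                           classification = list(
                             active = c("MH", "CMH"),
                             repressive = c("H", "RH"),
                             other = character(0))) {
  h_weight <- network$conservation[["H"]]
  h_species <- network$species[h_weight > 0]
  assigned <- unlist(classification[c("active", "repressive", "other")])
  missing <- setdiff(h_species, assigned)
  if (length(missing))
    stop("H-containing species not assigned by the classification: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tally <- function(group) {
    sp <- intersect(classification[[group]], network$species)
    sum(h_weight[sp] * state[sp])
  }
  list(active = tally("active"), repressive = tally("repressive"),
       other = tally("other"))
}

#' Simulate a scenario
#'
#' Piecewise stiff integration between events, with each event's synthesis
#' and decay settings active until the next. Output is on a 1 s grid (plus
#' event times), with the active/repressive partition appended per time
#' point.
#'
#' @param network a `reaction_network`.
#' @param scen a [scenario()].
#' @param dt output resolution, s.
#' @return A data frame of class `trajectory`: `time_s`, one column per
#'   species (uM), then `active_uM`, `repressive_uM`, `other_uM`.
#' @export
simulate_scenario <- function(network, scen, dt = 1) {
  stopifnot(inherits(network, "reaction_network"), inherits(scen, "scenario"))
  unknown <- setdiff(names(scen$initial_totals), network$monomers)
  if (length(unknown))
    stop("scenario monomers not in network: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  state <- if (scen$pre_equilibrate) {
    equilibrate(network, scen$initial_totals)
  } else {
    s <- stats::setNames(rep(0, length(network$species)), network$species)
    s[names(scen$initial_totals)] <- scen$initial_totals
    s
  }

  bounds <- unique(c(0, vapply(scen$events, `[[`, numeric(1), "t_s"),
                     scen$t_end))
  bounds <- bounds[bounds <= scen$t_end]
  synthesis <- NULL
  decay <- NULL
  rows <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    if (i > 1L) {
      ev <- scen$events[[i - 1L]]
      synthesis <- if (length(ev$synthesis)) unlist(ev$synthesis) else NULL
      decay <- if (length(ev$decay)) unlist(ev$decay) else NULL
    }
    times <- unique(c(seq(bounds[i], bounds[i + 1L], by = dt),
                      bounds[i + 1L]))
    seg <- integrate_network(network, state, times, synthesis, decay)
    state <- seg[nrow(seg), network$species]
    if (!is.null(rows)) seg <- seg[-1L, , drop = FALSE]  # drop shared bound
    rows <- rbind(rows, seg)
  }

  conc <- rows[, network$species, drop = FALSE]
  part <- t(apply(conc, 1L, function(st)
    unlist(classify_state(st, network))))
  traj <- data.frame(time_s = rows[, "time"], conc,
                     active_uM = part[, "active"],
                     repressive_uM = part[, "repressive"],
                     other_uM = part[, "other"], check.names = FALSE)
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "network") <- network
  attr(traj, "scenario") <- scen
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over %g s, %d species\n",
              nrow(x), max(x$time_s),
              length(attr(x, "network")$species)))
  invisible(x)
}

#' Extract the state or partition at a given time
#'
#' @param traj a `trajectory`.
#' @param t time, s; the nearest stored time point is used.
#' @return `state_at()` returns the named species vector; `partition_at()`
#'   the classification list.
#' @export
state_at <- function(traj, t) {
  i <- which.min(abs(traj$time_s - t))
  sp <- attr(traj, "network")$species
  stats::setNames(as.numeric(traj[i, sp]), sp)
}

#' @rdname state_at
#' @export
partition_at <- function(traj, t) {
  classify_state(state_at(traj, t), attr(traj, "network"))
}

#' Total concentration of one monomer along a trajectory
#'
#' @param traj a `trajectory`.
#' @param monomer monomer label.
#' @return Numeric vector of totals (uM) per time point.
#' @export
monomer_total <- function(traj, monomer) {
  network <- attr(traj, "network")
  w <- network$conservation[[monomer]]
  if (is.null(w)) stop("unknown monomer ", monomer, call. = FALSE)
  as.numeric(as.matrix(traj[, network$species]) %*% w)
}

#' Equilibrium scan over one dissociation constant
#'
#' Rebuilds the network for each candidate value of a measured constant
#' (re-deriving the detailed-balance edge), equilibrates at the given totals
#' and reports the active/repressive partition. The derived `C:MH` edge is
#' refused.
#'
#' @param params a [parameter_set()].
#' @param pair_id measured pair to scan, e.g. `"R:H"`.
#' @param values candidate dissociation constants, uM.
#' @param totals named monomer totals, uM.
#' @return Data frame with columns `kd_uM`, `active_uM`, `repressive_uM`,
#'   `other_uM`, `repressive_fraction`.
#' @export
scan_kd <- function(params, pair_id, values, totals) {
  rows <- lapply(values, function(v) {
    ps <- set_constant(params, pair_id, v)
    net <- build_network(ps)
    part <- classify_state(equilibrate(net, totals), net)
    htot <- part$active + part$repressive + part$other
    data.frame(kd_uM = v, active_uM = part$active,
               repressive_uM = part$repressive, other_uM = part$other,
               repressive_fraction = if (htot > 0) part$repressive / htot
                                     else NA_real_)
  })
  do.call(rbind, rows)
}

#' Write a trajectory to CSV
#'
#' First column `time_s`, one column per species, then the partition columns.
#' Optional comment headers (`# key=value`) precede the table.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param comments named character vector written as `# name=value` lines.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(sprintf("# %s=%s", names(comments), comments), con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}
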