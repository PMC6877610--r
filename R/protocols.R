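#' Logarithmically spaced interval grid
#'
#' @param from,to grid endpoints (ms), both > 0.
#' @param per_decade points per decade (default 8).
#' @return increasing numeric vector including both endpoints.
#' @export
log_grid <- function(from, to, per_decade = 8) {
  stopifnot(from > 0, to > from)
  g <- 10^seq(log10(from), log10(to), by = 1 / per_decade)
  if (g[length(g)] < to * (1 - 1e-12)) g <- c(g, to)
  g
}

#' Voltage-clamp protocol presets
#'
#' Builds one of the six standard double/single-pulse voltage-clamp protocols:
#' \describe{
#'   \item{\code{activation}}{2 ms at -120 mV, then a 14 ms test step swept
#'     from -90 to +60 mV in 5 mV increments (31 sweeps).}
#'   \item{\code{deactivation}}{0.5 ms at -120 mV, 0.5 ms at -10 mV to open
#'     channels, then a 5 ms repolarization swept from -100 to -30 mV in
#'     10 mV steps (tail currents, 8 sweeps).}
#'   \item{\code{availability}}{500 ms conditioning swept from -120 to 0 mV
#'     in 5 mV steps, then a 20 ms test pulse at -10 mV (steady-state
#'     availability).}
#'   \item{\code{fast_repriming}}{30 ms conditioning pulse (P1) at -20 mV,
#'     a recovery interval at \code{recovery_V} (default -120 mV) with
#'     log-spaced durations 0.1-1000 ms, then a 20 ms probe (P2) at -20 mV.}
#'   \item{\code{slow_repriming}}{as fast repriming but P1 lasts 1000 ms and
#'     the recovery intervals span 0.1-7000 ms.}
#'   \item{\code{slow_onset}}{P1 at -20 mV with log-spaced durations
#'     10-10000 ms, a 30 ms repolarization at -120 mV, then a 20 ms test
#'     pulse (P2) at -20 mV (development of slow inactivation).}
#' }
#' Every sweep starts from the steady state at the holding potential
#' (-120 mV by default).
#'
#' @param name protocol name (see Details).
#' @param sweep_values optional replacement for the swept level/duration grid
#'   (must be finite and strictly monotone).
#' @param holding_V holding potential initializing each sweep (mV).
#' @param recovery_V recovery/repolarization level for the repriming
#'   protocols (mV).
#' @param p1_duration override of the conditioning-pulse duration (ms) for
#'   the repriming protocols.
#' @param per_decade points per decade for log-spaced duration grids.
#' @return an object of class \code{protocol_spec}: list with \code{name},
#'   \code{holding_V}, \code{epochs} (each \code{list(V, dur)}, with
#'   \code{NA} marking the swept quantity), \code{sweep}
#'   (\code{epoch}, \code{var}, \code{values}) and \code{measure} (epoch
#'   indices: \code{test} or \code{p1}/\code{p2}).
#' @export
make_protocol <- function(name = c("activation", "deactivation",
                                   "availability", "fast_repriming",
                                   "slow_repriming", "slow_onset"),
                          sweep_values = NULL, holding_V = -120,
                          recovery_V = -120, p1_duration = NULL,
                          per_decade = 8) {
  name <- match.arg(name)
  sp <- switch(name,
    activation = list(
      epochs = list(list(V = -120, dur = 2), list(V = NA, dur = 14)),
      sweep = list(epoch = 2L, var = "level", values = seq(-90, 60, by = 5)),
      measure = list(test = 2L)),
    deactivation = list(
      epochs = list(list(V = -120, dur = 0.5), list(V = -10, dur = 0.5),
                    list(V = NA, dur = 5)),
      sweep = list(epoch = 3L, var = "level", values = seq(-100, -30, by = 10)),
      measure = list(test = 3L)),
    availability = list(
      epochs = list(list(V = NA, dur = 500), list(V = -10, dur = 20)),
      sweep = list(epoch = 1L, var = "level", values = seq(-120, 0, by = 5)),
      measure = list(test = 2L)),
    fast_repriming = list(
      epochs = list(list(V = -20, dur = if (is.null(p1_duration)) 30 else p1_duration),
                    list(V = recovery_V, dur = NA),
                    list(V = -20, dur = 20)),
      sweep = list(epoch = 2L, var = "duration",
                   values = log_grid(0.1, 1000, per_decade)),
      measure = list(p1 = 1L, p2 = 3L)),
    slow_repriming = list(
      epochs = list(list(V = -20, dur = if (is.null(p1_duration)) 1000 else p1_duration),
                    list(V = recovery_V, dur = NA),
                    list(V = -20, dur = 20)),
      sweep = list(epoch = 2L, var = "duration",
                   values = log_grid(0.1, 7000, per_decade)),
      measure = list(p1 = 1L, p2 = 3L)),
    slow_onset = list(
      epochs = list(list(V = -20, dur = NA), list(V = -120, dur = 30),
                    list(V = -20, dur = 20)),
      sweep = list(epoch = 1L, var = "duration",
                   values = log_grid(10, 10000, per_decade)),
      measure = list(p1 = 1L, p2 = 3L)))
  if (!is.null(sweep_values)) sp$sweep$values <- sweep_values
  v <- sp$sweep$values
  if (any(!is.finite(v)) || length(v) < 2 ||
      !(all(diff(v) > 0) || all(diff(v) < 0)))
    stop("sweep values must be finite and strictly monotone", call. = FALSE)
  if (sp$sweep$var == "duration" && any(v <= 0))
    stop("swept durations must be positive", call. = FALSE)
  for (e in sp$epochs)
    if (!is.na(e$dur) && e$dur <= 0)
      stop("epoch durations must be positive", call. = FALSE)
  structure(c(list(name = name, holding_V = holding_V), sp),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %s: %d epochs, %d sweeps (%s of epoch %d), hold %g mV\n",
              x$name, length(x$epochs), length(x$sweep$values),
              x$sweep$var, x$sweep$epoch, x$holding_V))
  invisible(x)
}

#' Run a voltage-clamp protocol
#'
#' Simulates every sweep of a protocol under ideal voltage clamp (no
#' capacitive or leak component; equivalent to capacitive-current
#' subtraction): the channel is initialized at the steady state of the
#' holding potential, propagated in closed form through each constant-voltage
#' epoch, and the Ohmic current density is recorded at every sample.
#'
#' Long epochs are recorded on an internally coarsened grid (at most
#' \code{max_epoch_samples} points) — propagation is exact, so the sampling
#' density affects only the recorded trace, never the end state.
#'
#' @param channel a \code{nav_channel}.
#' @param protocol a \code{\link{protocol_spec}}.
#' @param dt sampling interval, ms (default 0.025).
#' @param max_epoch_samples cap on recorded samples per epoch.
#' @return an object of class \code{sweep_set}: list with \code{protocol},
#'   \code{channel}, \code{dt} and \code{sweeps}; each sweep holds the swept
#'   \code{value}, sample vectors \code{t} (global time, ms), \code{V} (mV),
#'   \code{I} (mA/cm^2), integer \code{epoch} labels and the \code{states}
#'   matrix.
#' @export
run_protocol <- function(channel, protocol, dt = 0.025,
                         max_epoch_samples = 4000) {
  stopifnot(inherits(channel, "nav_channel"),
            inherits(protocol, "protocol_spec"), dt > 0)
  p0 <- steady_state(channel, protocol$holding_V)
  eig_cache <- new.env(parent = emptyenv())
  get_eig <- function(V) {
    if (!inherits(channel, "markov_channel")) return(NULL)
    key <- format(V, digits = 15)
    if (is.null(eig_cache[[key]]))
      eig_cache[[key]] <- list(value = generator_eigen(build_generator(channel, V)))
    eig_cache[[key]]$value
  }
  sweeps <- lapply(protocol$sweep$values, function(val) {
    state <- p0
    t_off <- 0
    tl <- Vl <- Il <- el <- list()
    sl <- list()
    for (i in seq_along(protocol$epochs)) {
      ep <- protocol$epochs[[i]]
      V <- ep$V; dur <- ep$dur
      if (i == protocol$sweep$epoch) {
        if (protocol$sweep$var == "level") V <- val else dur <- val
      }
      times <- NULL
      if (dur / dt > max_epoch_samples) {
        # keep the first 25 ms at full resolution (peaks live there),
        # coarsen the remainder; propagation itself is exact either way
        head <- seq(0, min(dur, 25), by = dt)
        tail <- seq(0, dur, length.out = max_epoch_samples)
        times <- unique(sort(c(head, tail)))
      }
      tr <- propagate_epoch(channel, state, V, dur, dt, eig = get_eig(V),
                            times = times)
      tl[[i]] <- tr$t + t_off
      Vl[[i]] <- rep(V, length(tr$t))
      Il[[i]] <- channel_current(channel, tr$states, V)
      el[[i]] <- rep(i, length(tr$t))
      sl[[i]] <- tr$states
      state <- tr$end
      t_off <- t_off + dur
    }
    list(value = val, t = unlist(tl), V = unlist(Vl), I = unlist(Il),
         epoch = unlist(el), states = do.call(rbind, sl))
  })
  structure(list(protocol = protocol, channel = channel, dt = dt,
                 sweeps = sweeps),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s protocol, %s channel: %d sweeps, %d samples each (dt %g ms)\n",
              x$protocol$name,
              if (is.null(x$channel$name)) x$channel$family else x$channel$name,
              length(x$sweeps), length(x$sweeps[[1]]$t), x$dt))
  invisible(x)
}

#' Flatten a sweep set to a long-format data frame
#'
#' @param x a \code{sweep_set}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns \code{sweep_id}, \code{sweep_value},
#'   \code{epoch}, \code{t_ms}, \code{V_mV}, \code{I_mA_cm2} and one column
#'   per channel state.
#' @export
as.data.frame.sweep_set <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  do.call(rbind, lapply(seq_along(x$sweeps), function(i) {
    s <- x$sweeps[[i]]
    cbind(data.frame(sweep_id = i, sweep_value = s$value, epoch = s$epoch,
                     t_ms = s$t, V_mV = s$V, I_mA_cm2 = s$I),
          as.data.frame(s$states))
  }))
}

#' Peak current within one epoch of a sweep
#'
#' Returns the extremum of largest absolute value inside the epoch, excluding
#' the first sample after the voltage step (the discontinuity sample).
#'
#' @param sweep one element of \code{sweep_set$sweeps}.
#' @param epoch_index epoch number.
#' @param zero_tol traces whose largest magnitude is below this are flagged
#'   as all-zero and return a (0, 0) peak.
#' @return list with \code{I_peak} (signed, mA/cm^2), \code{t_peak} (ms,
#'   relative to epoch start) and logical \code{flagged}.
#' @export
peak_current <- function(sweep, epoch_index, zero_tol = 1e-12) {
  idx <- which(sweep$epoch == epoch_index)
  if (!length(idx))
    stop("epoch ", epoch_index, " not present in sweep", call. = FALSE)
  t0 <- sweep$t[idx[1]]
  idx <- idx[-1]                      # discontinuity guard
  I <- sweep$I[idx]
  if (!length(I) || max(abs(I)) < zero_tol)
    return(list(I_peak = 0, t_peak = 0, flagged = TRUE))
  j <- which.max(abs(I))
  list(I_peak = I[j], t_peak = sweep$t[idx[j]] - t0, flagged = FALSE)
}

#' Peak currents across all sweeps of a set
#'
#' @param sweep_set a \code{sweep_set}.
#' @param epoch_index epoch in which to measure.
#' @return data.frame with \code{sweep_value}, signed \code{I_peak},
#'   \code{t_peak} and \code{flagged}.
#' @export
sweep_peaks <- function(sweep_set, epoch_index) {
  pk <- lapply(sweep_set$sweeps, peak_current, epoch_index = epoch_index)
  data.frame(
    sweep_value = vapply(sweep_set$sweeps, `[[`, numeric(1), "value"),
    I_peak = vapply(pk, `[[`, numeric(1), "I_peak"),
    t_peak = vapply(pk, `[[`, numeric(1), "t_peak"),
    flagged = vapply(pk, `[[`, logical(1), "flagged"))
}
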