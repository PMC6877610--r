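# model definitions for fit_curve: prediction function, parameter names,
# and a deterministic multi-start grid built from the data
fit_models <- list(
  boltzmann = list(
    pars = c("V12", "k"),
    fn = function(p, x) 1 / (1 + exp((x - p[["V12"]]) / p[["k"]])),
    starts = function(x, y) {
      v0 <- x[which.min(abs(y - 0.5))]
      expand.grid(V12 = unique(c(v0, stats::median(x))),
                  k = c(-20, -8, -3, 3, 8, 20))
    }),
  boltzmann_offset = list(
    pars = c("A", "V12", "k"),
    fn = function(p, x)
      p[["A"]] + (1 - p[["A"]]) / (1 + exp((x - p[["V12"]]) / p[["k"]])),
    starts = function(x, y) {
      v0 <- x[which.min(abs(y - (max(y) + min(y)) / 2))]
      expand.grid(A = c(0, max(0, min(y))), V12 = unique(c(v0, stats::median(x))),
                  k = c(-15, -5, 5, 15))
    }),
  mono_exp = list(
    pars = c("A", "tau"),
    fn = function(p, x) p[["A"]] * exp(-x / p[["tau"]]),
    starts = function(x, y) {
      a0 <- y[which.min(x)]
      expand.grid(A = unique(c(a0, max(y), min(y))), tau = tau_grid(x))
    }),
  hh_m3h = list(
    pars = c("A", "tau_m", "tau_h"),
    fn = function(p, x)
      p[["A"]] * (1 - exp(-x / p[["tau_m"]]))^3 * exp(-x / p[["tau_h"]]),
    starts = function(x, y) {
      pk <- which.max(abs(y))
      a0 <- y[pk] * c(1.5, 3)
      tp <- max(x[pk], min(x[x > 0]))
      expand.grid(A = a0, tau_m = tp * c(0.2, 0.5, 1),
                  tau_h = unique(c(tp * c(2, 6), max(x) / 2)))
    }),
  recovery_single = list(
    pars = c("A1", "tau1"),
    fn = function(p, x) p[["A1"]] * (1 - exp(-x / p[["tau1"]])),
    starts = function(x, y)
      expand.grid(A1 = unique(c(max(y), 1)), tau1 = tau_grid(x))),
  slow_onset_exp = list(
    pars = c("A1", "A2", "tau"),
    fn = function(p, x) p[["A1"]] + p[["A2"]] * exp(-x / p[["tau"]]),
    starts = function(x, y)
      expand.grid(A1 = min(y), A2 = max(y) - min(y), tau = tau_grid(x))),
  recovery_double = list(
    pars = c("A1", "tau1", "A2", "tau2"),
    fn = function(p, x)
      p[["A1"]] * (1 - exp(-x / p[["tau1"]])) +
      p[["A2"]] * (1 - exp(-x / p[["tau2"]])),
    starts = function(x, y) {
      tg <- tau_grid(x)
      g <- expand.grid(f1 = c(0.5, 0.8), tau1 = tg, tau2 = tg)
      g <- g[g$tau1 < g$tau2, ]
      a <- max(y)
      data.frame(A1 = a * g$f1, tau1 = g$tau1, A2 = a * (1 - g$f1),
                 tau2 = g$tau2)
    })
)

# decade-spaced time-constant starts spanning the abscissa range
tau_grid <- function(x) {
  xp <- x[x > 0]
  lo <- max(min(xp), 1e-3)
  hi <- max(xp)
  10^seq(log10(lo), log10(hi), length.out = 6)
}

#' Deterministic nonlinear least-squares curve fit
#'
#' Fits one of the standard electrophysiological fit equations by
#' Levenberg-Marquardt least squares with a deterministic multi-start grid
#' derived from the data (no randomness: identical inputs give identical
#' results). Supported models and their free parameters:
#' \describe{
#'   \item{\code{boltzmann}}{\code{y = 1/(1 + exp((x - V12)/k))} — normalized
#'     conductance-voltage curve (\code{V12}, \code{k}).}
#'   \item{\code{boltzmann_offset}}{\code{y = A + (1 - A)/(1 + exp((x -
#'     V12)/k))} — steady-state availability with non-inactivating fraction
#'     \code{A}.}
#'   \item{\code{mono_exp}}{\code{y = A exp(-x/tau)} — tail-current decay.}
#'   \item{\code{hh_m3h}}{\code{y = A (1 - exp(-x/tau_m))^3 exp(-x/tau_h)} —
#'     activation/decay of one voltage-clamp current trace.}
#'   \item{\code{recovery_single}}{\code{y = A1 (1 - exp(-x/tau1))} —
#'     recovery from fast inactivation (P2/P1 vs interval).}
#'   \item{\code{slow_onset_exp}}{\code{y = A1 + A2 exp(-x/tau)} —
#'     development of slow inactivation (P2/P1 vs P1 duration).}
#'   \item{\code{recovery_double}}{\code{y = A1 (1 - exp(-x/tau1)) +
#'     A2 (1 - exp(-x/tau2))} with \code{tau1 < tau2} by convention —
#'     recovery from slow inactivation.}
#' }
#'
#' @param model model name (see Details).
#' @param x,y numeric vectors of equal length (at least one more point than
#'   free parameters).
#' @param init optional named vector used as an additional start.
#' @return an object of class \code{fit_result}: list with \code{model},
#'   named \code{par}, \code{ssr} (squared-residual norm), logical
#'   \code{converged}, \code{n} and \code{fitted} (function of x).
#'   Non-convergence is reported through the flag, never as an error.
#' @export
fit_curve <- function(model, x, y, init = NULL) {
  def <- fit_models[[match.arg(model, names(fit_models))]]
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < length(def$pars) + 1)
    stop("need at least ", length(def$pars) + 1, " points to fit ", model,
         call. = FALSE)
  starts <- def$starts(x, y)
  if (!is.null(init)) {
    init <- as.data.frame(as.list(init))[def$pars]
    starts <- rbind(starts[, def$pars, drop = FALSE], init)
  }
  resid_fn <- function(p, x, y) {
    p <- stats::setNames(as.numeric(p), def$pars)
    r <- y - def$fn(p, x)
    r[!is.finite(r)] <- 1e6
    r
  }
  lower <- ifelse(grepl("^tau", def$pars), 1e-9, -Inf)
  upper <- ifelse(grepl("^tau", def$pars), 1e9, Inf)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- stats::setNames(as.numeric(starts[i, def$pars]), def$pars)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, x = x, y = y,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid_fn(fit$par, x, y)^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || ssr < best$ssr - 1e-15 ||
        (ssr <= best$ssr && conv && !best$converged))
      best <- list(par = stats::setNames(as.numeric(fit$par), def$pars),
                   ssr = ssr, converged = conv)
  }
  if (is.null(best))
    best <- list(par = stats::setNames(rep(NA_real_, length(def$pars)),
                                       def$pars),
                 ssr = Inf, converged = FALSE)
  if (model == "recovery_double" && !anyNA(best$par) &&
      best$par[["tau1"]] > best$par[["tau2"]])
    best$par <- best$par[c("A2", "tau2", "A1", "tau1")] |>
      stats::setNames(c("A1", "tau1", "A2", "tau2"))
  structure(list(model = model, par = best$par, ssr = best$ssr,
                 converged = best$converged, n = length(x),
                 fitted = function(xx)
                   def$fn(stats::setNames(best$par, def$pars), xx)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: %s; ssr = %.3g, converged = %s (n = %d)\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "),
              x$ssr, x$converged, x$n))
  invisible(x)
}

new_feature_set <- function(protocol, features, tables = list(),
                            fits = list(), flags = character(0)) {
  structure(list(protocol = protocol, features = features, tables = tables,
                 fits = fits, flags = flags), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s\n", x$protocol))
  for (nm in names(x$features))
    cat(sprintf("  %s = %.6g\n", nm, x$features[[nm]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# trace of one epoch with time relative to the epoch start, first sample
# after the voltage step dropped
epoch_trace <- function(sweep, epoch_index) {
  idx <- which(sweep$epoch == epoch_index)
  t0 <- sweep$t[idx[1]]
  idx <- idx[-1]
  list(t = sweep$t[idx] - t0, I = sweep$I[idx])
}

#' Activation features: conductance-voltage Boltzmann and time constants
#'
#' Converts per-sweep peak currents to conductances through the driving
#' force, \code{G = I_peak/(V - E_rev)}, normalizes by the maximal
#' conductance across sweeps, and fits the Boltzmann
#' \code{G/Gmax = 1/(1 + exp((V - V12)/k))} with \code{V12} and \code{k}
#' free. Per-sweep activation/decay time constants are obtained by fitting
#' each test-epoch trace to \code{A (1 - exp(-t/tau_m))^3 exp(-t/tau_h)}.
#'
#' Sweeps whose test level is within 1 mV of the reversal potential are
#' excluded from the conductance conversion (zero driving force); sweeps
#' with peak currents below 5 percent of the maximum are excluded from the
#' time-constant table.
#'
#' @param sweeps an activation \code{sweep_set}.
#' @param E_rev reversal potential (mV); defaults to the channel's.
#' @param fit_tau also fit the per-sweep time constants (default TRUE).
#' @return a \code{feature_set} with features \code{V12}, \code{k}, tables
#'   \code{gv} (V, G, G_norm, used) and \code{tau} (V, tau_m, tau_h).
#' @export
activation_features <- function(sweeps, E_rev = sweeps$channel$E_rev,
                                fit_tau = TRUE) {
  stopifnot(inherits(sweeps, "sweep_set"))
  te <- sweeps$protocol$measure$test
  pk <- sweep_peaks(sweeps, te)
  used <- abs(pk$sweep_value - E_rev) >= 1
  G <- ifelse(used, pk$I_peak / (pk$sweep_value - E_rev), NA_real_)
  gn <- G / max(G, na.rm = TRUE)
  fit <- fit_curve("boltzmann", pk$sweep_value[used], gn[used])
  tab <- data.frame(V = pk$sweep_value, G = G, G_norm = gn, used = used)
  tau <- NULL
  if (fit_tau) {
    keep <- which(used & abs(pk$I_peak) >= 0.05 * max(abs(pk$I_peak)))
    tau <- data.frame(V = pk$sweep_value[keep], tau_m = NA_real_,
                      tau_h = NA_real_)
    for (j in seq_along(keep)) {
      tr <- epoch_trace(sweeps$sweeps[[keep[j]]], te)
      f <- fit_curve("hh_m3h", tr$t, tr$I)
      tau$tau_m[j] <- f$par[["tau_m"]]
      tau$tau_h[j] <- f$par[["tau_h"]]
    }
  }
  new_feature_set("activation",
                  features = list(V12 = fit$par[["V12"]], k = fit$par[["k"]]),
                  tables = c(list(gv = tab), if (!is.null(tau)) list(tau = tau)),
                  fits = list(boltzmann = fit),
                  flags = if (any(!used)) "sweeps at the reversal potential excluded" else character(0))
}

#' Steady-state availability features
#'
#' Normalizes the test-pulse peak currents by their maximum and fits the
#' offset Boltzmann \code{I/Imax = A + (1 - A)/(1 + exp((V - V12)/k))}
#' against the conditioning voltage.
#'
#' @param sweeps an availability \code{sweep_set}.
#' @return a \code{feature_set} with features \code{V12}, \code{k}, \code{A}
#'   and table \code{availability} (V, I_norm). A flat curve (relative span
#'   below 5 percent, i.e. no inactivation) is flagged as degenerate.
#' @export
availability_features <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  pk <- sweep_peaks(sweeps, sweeps$protocol$measure$test)
  y <- abs(pk$I_peak) / max(abs(pk$I_peak))
  tab <- data.frame(V = pk$sweep_value, I_norm = y)
  if (diff(range(y)) < 0.05) {
    return(new_feature_set("availability",
      features = list(V12 = NA_real_, k = NA_real_, A = 1),
      tables = list(availability = tab),
      flags = "degenerate: flat availability curve (no inactivation)"))
  }
  fit <- fit_curve("boltzmann_offset", pk$sweep_value, y)
  new_feature_set("availability",
                  features = list(V12 = fit$par[["V12"]], k = fit$par[["k"]],
                                  A = fit$par[["A"]]),
                  tables = list(availability = tab),
                  fits = list(boltzmann_offset = fit))
}

#' Repriming (recovery from inactivation) features
#'
#' Computes the per-sweep P2/P1 peak-current ratio against the recovery
#' interval and fits the fast protocol to the single exponential
#' \code{A1 (1 - exp(-t/tau1))}, or the slow protocol to the double
#' exponential \code{A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2))}
#' (\code{tau1 < tau2}); fractional recoveries are \code{A1/(A1 + A2)} and
#' \code{A2/(A1 + A2)}.
#'
#' @param sweeps a repriming \code{sweep_set}.
#' @param kind \code{"fast"} or \code{"slow"}.
#' @return a \code{feature_set} with features \code{tau1}, \code{A1} (fast)
#'   plus \code{tau2}, \code{A2}, \code{frac1}, \code{frac2} (slow), and
#'   table \code{recovery} (interval, ratio).
#' @export
repriming_features <- function(sweeps, kind = c("fast", "slow")) {
  kind <- match.arg(kind)
  stopifnot(inherits(sweeps, "sweep_set"))
  m <- sweeps$protocol$measure
  p1 <- sweep_peaks(sweeps, m$p1)
  p2 <- sweep_peaks(sweeps, m$p2)
  ratio <- abs(p2$I_peak) / abs(p1$I_peak)
  x <- p1$sweep_value
  tab <- data.frame(interval = x, ratio = ratio)
  if (kind == "fast") {
    fit <- fit_curve("recovery_single", x, ratio)
    feats <- list(tau1 = fit$par[["tau1"]], A1 = fit$par[["A1"]])
  } else {
    fit <- fit_curve("recovery_double", x, ratio)
    a1 <- fit$par[["A1"]]; a2 <- fit$par[["A2"]]
    feats <- list(tau1 = fit$par[["tau1"]], A1 = a1,
                  tau2 = fit$par[["tau2"]], A2 = a2,
                  frac1 = a1 / (a1 + a2), frac2 = a2 / (a1 + a2))
  }
  new_feature_set(paste0(kind, "_repriming"), features = feats,
                  tables = list(recovery = tab), fits = list(recovery = fit))
}

#' Deactivation (tail-current) features
#'
#' Fits each repolarization-level tail current, starting one sample after
#' the voltage step, to the mono-exponential \code{A exp(-t/tau)}.
#'
#' @param sweeps a deactivation \code{sweep_set}.
#' @return a \code{feature_set} with table \code{tau} (V, tau, A).
#' @export
deactivation_features <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  te <- sweeps$protocol$measure$test
  vals <- vapply(sweeps$sweeps, `[[`, numeric(1), "value")
  tab <- data.frame(V = vals, tau = NA_real_, A = NA_real_)
  fits <- vector("list", length(vals))
  for (i in seq_along(sweeps$sweeps)) {
    tr <- epoch_trace(sweeps$sweeps[[i]], te)
    f <- fit_curve("mono_exp", tr$t, tr$I)
    tab$tau[i] <- f$par[["tau"]]
    tab$A[i] <- f$par[["A"]]
    fits[[i]] <- f
  }
  new_feature_set("deactivation", features = list(), tables = list(tau = tab),
                  fits = fits)
}

#' Development-of-slow-inactivation features
#'
#' Fits the P2/P1 ratio against the conditioning-pulse duration to
#' \code{A1 + A2 exp(-t/tau)}; \code{A1} is the non-slow-inactivating
#' plateau.
#'
#' @param sweeps a slow-onset \code{sweep_set}.
#' @return a \code{feature_set} with features \code{tau} (ms), \code{plateau}
#'   and table \code{onset} (duration, ratio). A flat curve (no slow
#'   inactivation) is flagged as degenerate.
#' @export
slow_onset_features <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  m <- sweeps$protocol$measure
  p1 <- sweep_peaks(sweeps, m$p1)
  p2 <- sweep_peaks(sweeps, m$p2)
  ratio <- abs(p2$I_peak) / abs(p1$I_peak)
  x <- p1$sweep_value
  tab <- data.frame(duration = x, ratio = ratio)
  if (diff(range(ratio)) < 0.02)
    return(new_feature_set("slow_onset",
      features = list(tau = NA_real_, plateau = mean(ratio)),
      tables = list(onset = tab),
      flags = "degenerate: flat onset curve (no slow inactivation)"))
  fit <- fit_curve("slow_onset_exp", x, ratio)
  new_feature_set("slow_onset",
                  features = list(tau = fit$par[["tau"]],
                                  plateau = fit$par[["A1"]]),
                  tables = list(onset = tab), fits = list(onset = fit))
}
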