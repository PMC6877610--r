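#' Voltage-dependent rate law
#'
#' Constructs one voltage-dependent rate-constant function. Five functional
#' forms are supported, covering the classical Hodgkin-Huxley empirical fits
#' and the (double-)sigmoid transition rates of simplified Markov kinetic
#' schemes, plus a constant form for synthetic test schemes.
#'
#' Forms and their parameters (voltages in mV, rates in 1/ms):
#' \describe{
#'   \item{\code{exponential}}{\code{A * exp((V - V12)/k)}; parameters
#'     \code{A}, \code{V12}, \code{k}.}
#'   \item{\code{linoid}}{\code{A * (V - V12) / (1 - exp(-(V - V12)/k))},
#'     the linear-times-exponential form of the classical activation forward
#'     rate, written in the sign convention that is positive and increasing
#'     with the conventional positive \code{k} (the removable singularity at
#'     \code{V == V12} evaluates to \code{A * k}); parameters \code{A}
#'     (1/ms/mV), \code{V12}, \code{k}.}
#'   \item{\code{sigmoid}}{\code{A / (1 + exp((V - V12)/k))}; parameters
#'     \code{A}, \code{V12}, \code{k}.}
#'   \item{\code{double_sigmoid}}{sum of two opposite sigmoid branches,
#'     \code{B_hyp/(1 + exp((V - V_hyp)/k_hyp)) +
#'     B_dep/(1 + exp((V - V_dep)/k_dep))}; by convention \code{k_hyp > 0}
#'     (branch active at hyperpolarized voltages) and \code{k_dep < 0}
#'     (depolarized branch). Either branch may be omitted or given a zero
#'     magnitude.}
#'   \item{\code{offset_sigmoid}}{sigmoid with a non-zero minimum asymptote,
#'     \code{tau_min + tau_max/(1 + exp((V - V12)/k))}; parameters
#'     \code{tau_min}, \code{tau_max}, \code{V12}, \code{k}.}
#'   \item{\code{constant}}{\code{A} independent of voltage.}
#' }
#'
#' @param form one of \code{"exponential"}, \code{"linoid"}, \code{"sigmoid"},
#'   \code{"double_sigmoid"}, \code{"offset_sigmoid"}, \code{"constant"}.
#' @param ... named numeric parameters for the chosen form (see Details).
#' @return an object of class \code{rate_law}.
#' @examples
#' am <- rate_law("linoid", A = 0.1, V12 = -40, k = 10)
#' eval_rate_law(am, c(-40, -20))
#' @export
rate_law <- function(form, ...) {
  form <- match.arg(form, c("exponential", "linoid", "sigmoid",
                            "double_sigmoid", "offset_sigmoid", "constant"))
  params <- list(...)
  if (length(params) == 1L && is.null(names(params)) && is.list(params[[1L]]))
    params <- params[[1L]]
  params <- lapply(params, as.numeric)
  law <- structure(list(form = form, params = params), class = "rate_law")
  validate_rate_law(law)
  law
}

required_rate_params <- list(
  exponential    = c("A", "V12", "k"),
  linoid         = c("A", "V12", "k"),
  sigmoid        = c("A", "V12", "k"),
  double_sigmoid = character(0),   # at least one branch, checked below
  offset_sigmoid = c("tau_min", "tau_max", "V12", "k"),
  constant       = "A"
)

validate_rate_law <- function(law) {
  if (!is.list(law$params) || any(!vapply(law$params, is.finite, logical(1))))
    stop("rate_law parameters must be finite numbers", call. = FALSE)
  p <- law$params
  need <- required_rate_params[[law$form]]
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop(sprintf("rate_law form '%s' is missing parameter(s): %s",
                 law$form, paste(missing, collapse = ", ")), call. = FALSE)
  if (law$form %in% c("exponential", "linoid", "sigmoid", "offset_sigmoid") &&
      p$k == 0)
    stop("rate_law slope parameter k must be non-zero", call. = FALSE)
  if (law$form == "double_sigmoid") {
    has_hyp <- all(c("B_hyp", "V_hyp", "k_hyp") %in% names(p))
    has_dep <- all(c("B_dep", "V_dep", "k_dep") %in% names(p))
    if (!has_hyp && !has_dep)
      stop("double_sigmoid needs at least one complete branch ",
           "(B_hyp/V_hyp/k_hyp or B_dep/V_dep/k_dep)", call. = FALSE)
    if (has_hyp && p$k_hyp == 0) stop("k_hyp must be non-zero", call. = FALSE)
    if (has_dep && p$k_dep == 0) stop("k_dep must be non-zero", call. = FALSE)
  }
  invisible(law)
}

#' @export
print.rate_law <- function(x, ...) {
  cat("<rate_law>", x$form, " ",
      paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a rate law at one or more voltages
#'
#' @param law a \code{\link{rate_law}}.
#' @param V numeric vector of membrane voltages (mV).
#' @return numeric vector of rates (1/ms), same length as \code{V}.
#' @export
eval_rate_law <- function(law, V) {
  stopifnot(inherits(law, "rate_law"), is.numeric(V), all(is.finite(V)))
  p <- law$params
  switch(law$form,
    constant = rep(p$A, length(V)),
    exponential = p$A * exp((V - p$V12) / p$k),
    sigmoid = p$A / (1 + exp((V - p$V12) / p$k)),
    offset_sigmoid = p$tau_min + p$tau_max / (1 + exp((V - p$V12) / p$k)),
    linoid = {
      x <- V - p$V12
      # series expansion x/(1 - exp(-x/k)) = k + x/2 + x^2/(12 k) + O(x^4)
      # near the removable singularity
      near <- abs(x / p$k) < 1e-6
      out <- numeric(length(V))
      out[near] <- p$A * (p$k + x[near] / 2)
      out[!near] <- p$A * x[!near] / (1 - exp(-x[!near] / p$k))
      out
    },
    double_sigmoid = {
      out <- numeric(length(V))
      if (!is.null(p$B_hyp))
        out <- out + p$B_hyp / (1 + exp((V - p$V_hyp) / p$k_hyp))
      if (!is.null(p$B_dep))
        out <- out + p$B_dep / (1 + exp((V - p$V_dep) / p$k_dep))
      out
    })
}

#' Temperature specification and Q10 scaling
#'
#' Kinetic rates are scaled by the temperature coefficient
#' \code{q10_base^((T - T_base)/10)}: every transition rate (and hence every
#' gate rate constant) is multiplied by this factor, so temperature acts as a
#' pure rescaling of time. Steady-state quantities are unaffected.
#'
#' @param T simulation temperature, degrees C.
#' @param T_base reference temperature at which the rate parameters are
#'   stated, degrees C.
#' @param q10_base the Q10 coefficient (default 3).
#' @return an object of class \code{temperature_spec}.
#' @export
temperature_spec <- function(T = 24, T_base = 20, q10_base = 3) {
  stopifnot(is.finite(T), is.finite(T_base), is.finite(q10_base),
            q10_base > 0)
  structure(list(T = T, T_base = T_base, q10_base = q10_base),
            class = "temperature_spec")
}

#' @rdname temperature_spec
#' @param spec a \code{temperature_spec}.
#' @return \code{q10_factor}: the dimensionless multiplicative factor
#'   applied to all rates (always positive).
#' @export
q10_factor <- function(spec) {
  stopifnot(inherits(spec, "temperature_spec"))
  spec$q10_base^((spec$T - spec$T_base) / 10)
}

#' Steady-state value and time constant of a first-order gate
#'
#' For a gating particle with forward rate \code{alpha(V)} and backward rate
#' \code{beta(V)}, the steady state is \code{alpha/(alpha + beta)} (independent
#' of temperature) and the relaxation time constant is
#' \code{1/((alpha + beta) * q10)}.
#'
#' @param alpha,beta \code{\link{rate_law}} objects.
#' @param V voltage (mV), may be a vector.
#' @param q10 temperature factor applied to both rates (default 1).
#' @return list with numeric components \code{x_infty} and \code{tau} (ms).
#' @export
gate_infty_tau <- function(alpha, beta, V, q10 = 1) {
  a <- eval_rate_law(alpha, V)
  b <- eval_rate_law(beta, V)
  s <- a + b
  if (any(s == 0))
    stop("degenerate gate: alpha + beta = 0 at some requested voltage",
         call. = FALSE)
  list(x_infty = a / s, tau = 1 / (s * q10))
}
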