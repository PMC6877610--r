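#' Read / write channel specifications as JSON
#'
#' Channel presets are stored as plain JSON with the schema
#' \code{{"name", "family" ("hh"|"markov"), "gbar", "E_rev",
#' "temperature": {"T", "T_base", "q10_base"}, ...}} where HH channels carry a
#' \code{"gates"} array (\code{name}, \code{exponent}, \code{alpha},
#' \code{beta}) and Markov channels carry \code{"states"}, \code{"open_state"}
#' and a \code{"transitions"} array (\code{from}, \code{to}, \code{rate}).
#' Rate laws are \code{{"form": ..., "params": {...}}} with voltages in mV and
#' rates in 1/ms.
#'
#' @param path file path.
#' @return \code{channel_from_json}: a \code{nav_channel}.
#' @export
channel_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  channel_from_list(x)
}

channel_from_list <- function(x) {
  tp <- x$temperature
  temp <- temperature_spec(T = tp$T, T_base = tp$T_base,
                           q10_base = if (is.null(tp$q10_base)) 3 else tp$q10_base)
  law <- function(l) do.call(rate_law, c(list(form = l$form), l$params))
  if (x$family == "hh") {
    gates <- lapply(x$gates, function(g)
      list(name = g$name, exponent = g$exponent,
           alpha = law(g$alpha), beta = law(g$beta)))
    hh_channel(gates, gbar = x$gbar, E_rev = x$E_rev, temperature = temp,
               name = x$name)
  } else if (x$family == "markov") {
    transitions <- lapply(x$transitions, function(tr)
      list(from = tr$from, to = tr$to, rate = law(tr$rate)))
    markov_channel(states = unlist(x$states), open_state = x$open_state,
                   transitions = transitions, gbar = x$gbar, E_rev = x$E_rev,
                   temperature = temp, name = x$name)
  } else stop("unknown channel family: ", x$family, call. = FALSE)
}

#' @rdname channel_from_json
#' @param channel a \code{nav_channel}.
#' @return \code{channel_to_json}: the path, invisibly.
#' @export
channel_to_json <- function(channel, path) {
  law <- function(l) list(form = l$form, params = l$params)
  x <- list(name = channel$name, family = channel$family,
            gbar = channel$gbar, E_rev = channel$E_rev,
            temperature = unclass(channel$temperature))
  if (channel$family == "hh") {
    x$gates <- lapply(unname(channel$gates), function(g)
      list(name = g$name, exponent = g$exponent,
           alpha = law(g$alpha), beta = law(g$beta)))
  } else {
    x$states <- channel$states
    x$open_state <- channel$open_state
    x$transitions <- lapply(channel$transitions, function(tr)
      list(from = tr$from, to = tr$to, rate = law(tr$rate)))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled channel presets
#'
#' Loads one of the channel parameter sets shipped with the package:
#' \describe{
#'   \item{\code{hh_squid_original}}{the classical squid-axon sodium channel
#'     rate constants rewritten in modern voltage conventions.}
#'   \item{\code{nav15_hh_row_a} ... \code{nav15_hh_row_h}}{the staged manual
#'     tuning sequence of the HH model towards Na_V_1.5 (rows a-f are m^3 h;
#'     rows g and h add the slow-inactivation gate s, m^3 h s).}
#'   \item{\code{nav15_hh_variant_a/b/c}}{the three alternative alpha_h
#'     settings exposing the HH availability-vs-repriming conflict:
#'     variant a is tuned to the recovery from fast inactivation, variant b to
#'     the steady-state availability, variant c is the trade-off (m^3 h
#'     presets).}
#'   \item{\code{nav15_markov}}{the five-state Markov kinetic scheme for
#'     Na_V_1.5 (states C1, C2, O1, I1, I2).}
#' }
#'
#' All presets default to gbar = 0.1 S/cm^2, E_Na = 65 mV and a simulation
#' temperature of 24 C. The Markov rates are referenced to a 20 C base
#' (Q10 = 3); the HH presets are referenced to the classical 6.3 C base,
#' which reproduces the published HH kinetic benchmarks (see the package
#' vignette), and the base is overridable.
#'
#' @param name preset name (see Details).
#' @param T simulation temperature, degrees C (default from the preset file).
#' @param T_base override of the Q10 reference temperature (default from the
#'   preset file).
#' @param gbar,E_rev optional overrides.
#' @return a \code{nav_channel}.
#' @examples
#' ch <- nav_preset("nav15_markov")
#' steady_state(ch, -120)
#' @export
nav_preset <- function(name, T = NULL, T_base = NULL, gbar = NULL,
                       E_rev = NULL) {
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "navkit")
  if (path == "")
    stop("unknown preset '", name, "'; available: ",
         paste(nav_preset_names(), collapse = ", "), call. = FALSE)
  ch <- channel_from_json(path)
  if (!is.null(T) || !is.null(T_base))
    ch <- set_temperature(ch, T = T, T_base = T_base)
  if (!is.null(gbar)) ch$gbar <- gbar
  if (!is.null(E_rev)) ch$E_rev <- E_rev
  ch
}

#' @rdname nav_preset
#' @return \code{nav_preset_names}: character vector of bundled preset names.
#' @export
nav_preset_names <- function() {
  dir <- system.file("extdata", "presets", package = "navkit")
  sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
}
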