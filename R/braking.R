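#' Ship emergency-braking scenario
#'
#' Parameters of the three-stroke emergency stop: the ship travels at its
#' initial speed during the driver's reaction time `t1`, keeps that speed
#' while the engine reverses (until `t2`, measured from the danger signal),
#' then decelerates to rest under reverse thrust and water resistance.
#'
#' @param u Initial ship speed (m/s by default).
#' @param t1 Driver reaction time, s (`0 <= t1 <= t2`).
#' @param t2 Time at the end of engine reversing, s from signal onset.
#' @param m Full-load displacement, kg.
#' @param R Water-flow resistance coefficient, N s/m: the resistive power at
#'   speed `V` is `R V^2`, i.e. the denominator term `R V` of the braking
#'   integrand is in watts, like the reverse propeller power.
#' @param P Maximum reverse propeller power, W.
#' @param speed_units `"m/s"` (default) or `"km/h"`; speeds in km/h are
#'   converted on input.
#'
#' @return An object of class `braking_scenario`.
#' @export
#' @examples
#' braking_scenario(u = 20, t1 = 2, t2 = 30, m = 1e7, R = 1e4, P = 1e6,
#'                  speed_units = "km/h")
braking_scenario <- function(u, t1, t2, m, R, P, speed_units = c("m/s", "km/h")) {
  speed_units <- match.arg(speed_units)
  if (speed_units == "km/h") u <- u / 3.6
  if (!is.numeric(u) || u < 0) abort("`u` must be a speed >= 0.")
  if (t1 < 0) abort("`t1` must be >= 0.")
  if (t2 < t1) abort("`t2` must be >= `t1` (reversing ends after the reaction).")
  if (m <= 0) abort("`m` (displacement) must be positive.")
  if (R < 0) abort("`R` (resistance coefficient) must be >= 0.")
  if (P <= 0) abort("`P` (reverse power) must be positive.")
  structure(list(u = u, t1 = t1, t2 = t2, m = m, R = R, P = P),
            class = "braking_scenario")
}

#' @export
print.braking_scenario <- function(x, ...) {
  cat(sprintf(
    "<braking_scenario> u = %.3g m/s, t1 = %.3g s, t2 = %.3g s, m = %.3g kg, R = %.3g, P = %.3g W\n",
    x$u, x$t1, x$t2, x$m, x$R, x$P
  ))
  invisible(x)
}

#' Reaction stroke
#'
#' Distance travelled at the initial speed during the driver's reaction
#' time: `S1 = u * t1`.
#'
#' @param sc A [braking_scenario()].
#' @return Meters.
#' @export
reaction_stroke <- function(sc) {
  stopifnot(inherits(sc, "braking_scenario"))
  sc$u * sc$t1
}

#' Reversing stroke
#'
#' Distance travelled while the engine reverses, under the simplification
#' that the ship holds its initial speed through the reversing phase:
#' `S2 = u * (t2 - t1)`.
#'
#' @param sc A [braking_scenario()].
#' @return Meters.
#' @export
reversing_stroke <- function(sc) {
  stopifnot(inherits(sc, "braking_scenario"))
  sc$u * (sc$t2 - sc$t1)
}

# g(x) = (x^2/2 - x + log(1+x)) / x^3  =  sum_{j>=0} (-x)^j / (j+3),
# so that s3 = (m u^3 / P) g(R u / P). The series form avoids the
# catastrophic cancellation of the log form when x << 1.
braking_g <- function(x) {
  if (x < 0.5) {
    j <- 0:30
    sum((-x)^j / (j + 3))
  } else {
    (x^2 / 2 - x + log1p(x)) / x^3
  }
}

#' Braking stroke
#'
#' Distance covered while decelerating from `u` to rest under reverse
#' thrust and water resistance:
#' \deqn{S_3 = \int_0^u \frac{m V^2}{R V + P}\, dV.}
#' The closed form is evaluated as \eqn{S_3 = (m u^3 / P)\, g(R u / P)} with
#' \eqn{g(x) = (x^2/2 - x + \ln(1+x))/x^3}, computed by series for small
#' \eqn{x} (including the `R = 0` limit \eqn{m u^3 / 3P}) to avoid
#' cancellation. The quadrature method integrates the same integrand
#' adaptively; the two agree to better than 1e-8 relative error.
#'
#' @param sc A [braking_scenario()].
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @return Meters.
#' @export
#' @examples
#' sc <- braking_scenario(u = 10, t1 = 2, t2 = 30, m = 1e7, R = 1e4, P = 1e6)
#' braking_stroke(sc)
braking_stroke <- function(sc, method = c("closed_form", "quadrature")) {
  stopifnot(inherits(sc, "braking_scenario"))
  method <- match.arg(method)
  if (sc$u == 0) return(0)
  if (method == "closed_form") {
    x <- sc$R * sc$u / sc$P
    sc$m * sc$u^3 / sc$P * braking_g(x)
  } else {
    integrate(function(V) sc$m * V^2 / (sc$R * V + sc$P),
              lower = 0, upper = sc$u,
              rel.tol = 1e-12, abs.tol = 0)$value
  }
}

#' Total safe braking distance
#'
#' Sum of the three strokes, `S = S1 + S2 + S3`: the safe braking distance
#' from the danger signal to the ship's complete halt.
#'
#' @param sc A [braking_scenario()].
#' @param method Passed to [braking_stroke()].
#' @return A one-row tibble with `s1`, `s2`, `s3`, `s_total` (meters);
#'   `s_total` is exactly the component sum.
#' @export
#' @examples
#' total_braking_distance(
#'   braking_scenario(u = 10, t1 = 2, t2 = 30, m = 1e7, R = 1e4, P = 1e6)
#' )
total_braking_distance <- function(sc, method = "closed_form") {
  s1 <- reaction_stroke(sc)
  s2 <- reversing_stroke(sc)
  s3 <- braking_stroke(sc, method)
  tibble::tibble(s1 = s1, s2 = s2, s3 = s3, s_total = s1 + s2 + s3)
}

#' Map a predicted fatigue score to a driver reaction time
#'
#' Linear-with-cap coupling between the predicted FSS-scale fatigue score
#' and the reaction time entering the reaction stroke:
#' `t1 = min(t_base + slope * fss, t_max)`, monotone non-decreasing in
#' `fss`. The defaults (1 s baseline, 0.5 s per fatigue unit, 10 s cap) are
#' a deliberately simple operational assumption; calibration to a given
#' crew or bridge task is the user's responsibility.
#'
#' @param fss Predicted fatigue score, >= 0.
#' @param t_base Reaction time at `fss = 0`, s (> 0).
#' @param slope Added reaction time per fatigue unit, s (>= 0).
#' @param t_max Cap on the reaction time, s (`>= t_base`).
#' @return Reaction time in seconds (vectorized over `fss`).
#' @export
#' @examples
#' fatigue_to_reaction_time(c(0, 2, 4))
fatigue_to_reaction_time <- function(fss, t_base = 1, slope = 0.5,
                                     t_max = 10) {
  if (any(fss < 0)) abort("`fss` must be >= 0.")
  if (t_base <= 0 || slope < 0 || t_max < t_base) {
    abort("Need t_base > 0, slope >= 0, t_max >= t_base.")
  }
  pmin(t_base + slope * fss, t_max)
}

#' Speed-time curve of the simplified braking trajectory
#'
#' Constant speed through the reaction and reversing phases, then the
#' deceleration implied by the braking-stroke integrand,
#' `dV/dt = -(R V + P)/(m V)`, integrated in closed form as
#' `t(V) = t2 + (m/R) (u - V) - (m P / R^2) ln((R u + P)/(R V + P))`
#' (with the `R = 0` limit `t2 + m (u^2 - V^2) / (2 P)`).
#'
#' @param sc A [braking_scenario()].
#' @param n Number of points on the deceleration branch.
#' @return A tibble `time_s`, `speed_ms`, `phase`.
#' @export
speed_time_curve <- function(sc, n = 200) {
  stopifnot(inherits(sc, "braking_scenario"))
  v <- seq(sc$u, 0, length.out = n)
  t_of_v <- if (sc$R > 0) {
    sc$t2 + (sc$m / sc$R) * (sc$u - v) -
      (sc$m * sc$P / sc$R^2) * log((sc$R * sc$u + sc$P) / (sc$R * v + sc$P))
  } else {
    sc$t2 + sc$m * (sc$u^2 - v^2) / (2 * sc$P)
  }
  dplyr::bind_rows(
    tibble::tibble(time_s = c(0, sc$t1), speed_ms = sc$u, phase = "reaction"),
    tibble::tibble(time_s = c(sc$t1, sc$t2), speed_ms = sc$u,
                   phase = "reversing"),
    tibble::tibble(time_s = t_of_v, speed_ms = v, phase = "braking")
  )
}

#' Plot the braking speed-time trajectory
#'
#' @param sc A [braking_scenario()].
#' @param ... Passed to [speed_time_curve()].
#' @return A ggplot object.
#' @export
plot_braking_curve <- function(sc, ...) {
  curve <- speed_time_curve(sc, ...)
  ggplot2::ggplot(curve, ggplot2::aes(.data$time_s, .data$speed_ms,
                                      colour = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time since danger signal (s)", y = "speed (m/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
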