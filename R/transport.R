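#' Kinetic parameters of a single transporter species
#'
#' Bundles the four kinetic constants of a symmetric alternating-access
#' carrier (uniporter): the translocation rate of the loaded carrier, the
#' translocation rate of the empty carrier, the substrate dissociation
#' constant (identical on both membrane faces) and the total amount of
#' transporter. All quantities are in arbitrary model units.
#'
#' @param k2 Loaded-carrier translocation rate (per unit time), `> 0`.
#' @param k4 Empty-carrier translocation rate (per unit time), `> 0`.
#' @param Kd Substrate dissociation constant on either membrane face
#'   (concentration units), `> 0`.
#' @param et Total transporter amount (amount units), `> 0`.
#'
#' @return An object of class `transporter_params`.
#' @examples
#' p <- transporter_params(k2 = 4, k4 = 4, Kd = 10, et = 10)
#' carrier_flux(p, s_out = 30, s_in = 0)
#' @export
transporter_params <- function(k2 = 4, k4 = 4, Kd = 10, et = 10) {
  for (nm in c("k2", "k4", "Kd", "et")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single finite positive number", call. = FALSE)
  }
  structure(list(k2 = k2, k4 = k4, Kd = Kd, et = et),
            class = "transporter_params")
}

#' @export
print.transporter_params <- function(x, ...) {
  cat("Transporter kinetic parameters (symmetric carrier)\n")
  cat(sprintf("  k2 (loaded translocation) = %g\n", x$k2))
  cat(sprintf("  k4 (empty translocation)  = %g\n", x$k4))
  cat(sprintf("  Kd (dissociation const.)  = %g\n", x$Kd))
  cat(sprintf("  et (total transporter)    = %g\n", x$et))
  invisible(x)
}

#' Rapid-equilibrium binding occupancy
#'
#' Fraction of carrier binding sites occupied at substrate concentration `s`
#' under rapid-equilibrium binding with dissociation constant `Kd`:
#' `s / (Kd + s)`.
#'
#' @param s Substrate concentration(s), `>= 0`. Vectorized.
#' @param Kd Dissociation constant, `> 0`.
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @export
occupancy <- function(s, Kd) {
  if (!is.numeric(Kd) || length(Kd) != 1L || !is.finite(Kd) || Kd <= 0)
    stop("'Kd' must be a single positive number", call. = FALSE)
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop("'s' must be finite and nonnegative", call. = FALSE)
  s / (Kd + s)
}

## Derivation of the carrier steady-state flux law.
##
## The alternating-access cycle has four states: outward-facing empty (Co),
## outward-facing loaded (CoS), inward-facing empty (Ci), inward-facing
## loaded (CiS). Binding on each face is taken at rapid equilibrium with the
## same Kd, so the four states collapse to two pools, Eo = Co + CoS facing
## out and Ei = Ci + CiS facing in, with loaded fractions
##   theta_o = s_out/(Kd+s_out),   theta_i = s_in/(Kd+s_in).
## Loaded carriers translocate at rate k2 in both directions and empty
## carriers at rate k4 in both directions (symmetric cycle), so
##   dEo/dt = -[k2 theta_o + k4 (1-theta_o)] Eo
##            +[k2 theta_i + k4 (1-theta_i)] Ei,      Eo + Ei = et.
## At steady state Eo/Ei = [k2 theta_i + k4(1-theta_i)] /
##                         [k2 theta_o + k4(1-theta_o)], and the net import
## rate is the difference of the loaded translocation fluxes,
##   J = k2 (theta_o Eo - theta_i Ei)
##     = et k2 k4 (theta_o - theta_i) /
##       [k2 (theta_o + theta_i) + k4 (2 - theta_o - theta_i)].
## Influx and efflux are coupled through the shared carrier pool: at high
## s_out the empty-carrier return step (k4) limits the cycle, which is what
## makes J(s_in) collapse onto a single curve and the internal set point
## insensitive to the external concentration.

#' Steady-state net import rate of the symmetric carrier
#'
#' Net import rate `J` (positive = import) of a symmetric alternating-access
#' carrier at clamped external and internal substrate concentrations, from
#' the closed-form steady state of the four-state cycle (see source for the
#' derivation):
#' \deqn{J = e_t k_2 k_4 (\theta_o - \theta_i) /
#'       [k_2(\theta_o + \theta_i) + k_4(2 - \theta_o - \theta_i)]}
#' with \eqn{\theta = s/(K_d + s)} the binding occupancy on each face.
#'
#' @param p A [transporter_params()] object.
#' @param s_out,s_in External / internal substrate concentrations, `>= 0`.
#'   Vectorized (recycled against each other).
#' @return Net import rate(s), amount per unit time.
#' @seealso [mm_flux()] for the uncoupled comparator, [carrier_ode_flux()]
#'   for the ODE oracle.
#' @export
carrier_flux <- function(p, s_out, s_in) {
  stopifnot(inherits(p, "transporter_params"))
  to <- occupancy(s_out, p$Kd)
  ti <- occupancy(s_in, p$Kd)
  p$et * p$k2 * p$k4 * (to - ti) /
    (p$k2 * (to + ti) + p$k4 * (2 - to - ti))
}

#' Michaelis-Menten comparator flux
#'
#' Uncoupled saturable influx/efflux comparator sharing the carrier's
#' parameters: `J = et * (k2 * theta_o - k4 * theta_i)`. Influx and efflux
#' saturate independently; there is no shared carrier pool, so above the
#' critical threshold the internal concentration tracks the external one
#' instead of collapsing onto a robust set point.
#'
#' @inheritParams carrier_flux
#' @return Net import rate(s).
#' @export
mm_flux <- function(p, s_out, s_in) {
  stopifnot(inherits(p, "transporter_params"))
  p$et * (p$k2 * occupancy(s_out, p$Kd) - p$k4 * occupancy(s_in, p$Kd))
}

#' ODE oracle for the carrier steady-state flux
#'
#' Integrates the mass-action ODE of the carrier cycle at clamped substrate
#' concentrations until stationarity and reports the net loaded-translocation
#' flux. Under rapid-equilibrium binding the four carrier states reduce to
#' the outward- and inward-facing pools (see the derivation in the source of
#' [carrier_flux()]); the pool ODE is integrated with a stiff-capable
#' solver and serves as an independent dynamical route to the same steady
#' state as the closed form.
#'
#' @inheritParams carrier_flux
#' @param t_end Maximum integration time. The default is long relative to
#'   the slowest relaxation mode of the cycle.
#' @param tol Stationarity criterion: integration is accepted once
#'   `|dEo/dt| < tol * et`.
#' @return Net import rate at steady state (scalar; `s_out`, `s_in` must be
#'   scalars).
#' @export
carrier_ode_flux <- function(p, s_out, s_in, t_end = NULL, tol = 1e-9) {
  stopifnot(inherits(p, "transporter_params"),
            length(s_out) == 1L, length(s_in) == 1L)
  to <- occupancy(s_out, p$Kd)
  ti <- occupancy(s_in, p$Kd)
  ko <- p$k2 * to + p$k4 * (1 - to)   # out -> in total rate
  ki <- p$k2 * ti + p$k4 * (1 - ti)   # in -> out total rate
  if (is.null(t_end)) t_end <- 100 / (ko + ki)
  rhs <- function(t, y, parms) {
    list(-ko * y[[1L]] + ki * (p$et - y[[1L]]))
  }
  sol <- deSolve::ode(y = c(Eo = p$et / 2), times = c(0, t_end), func = rhs,
                      parms = NULL, method = "lsoda",
                      atol = 1e-12 * p$et, rtol = 1e-12)
  Eo <- sol[nrow(sol), "Eo"]
  deriv <- -ko * Eo + ki * (p$et - Eo)
  if (abs(deriv) >= tol * p$et)
    stop("carrier ODE did not reach stationarity within t_end; ",
         "increase 't_end'", call. = FALSE)
  p$k2 * (to * Eo - ti * (p$et - Eo))
}

#' Steady-state carrier microstate occupancies
#'
#' Occupancies of the four carrier states (outward empty, outward loaded,
#' inward empty, inward loaded) at the steady state of the cycle, obtained
#' from the two-pool steady state split by the rapid-equilibrium binding
#' fractions. The four occupancies sum to `et` exactly.
#'
#' @inheritParams carrier_ode_flux
#' @return Named numeric vector `c(Co, CoS, Ci, CiS)`.
#' @export
carrier_microstate <- function(p, s_out, s_in) {
  stopifnot(inherits(p, "transporter_params"),
            length(s_out) == 1L, length(s_in) == 1L)
  to <- occupancy(s_out, p$Kd)
  ti <- occupancy(s_in, p$Kd)
  D <- p$k2 * (to + ti) + p$k4 * (2 - to - ti)
  Eo <- p$et * (p$k2 * ti + p$k4 * (1 - ti)) / D
  Ei <- p$et - Eo
  c(Co = Eo * (1 - to), CoS = Eo * to, Ci = Ei * (1 - ti), CiS = Ei * ti)
}

#' Flux surface over a concentration grid
#'
#' Evaluates a flux law on the Cartesian product of external and internal
#' concentration grids, in long format.
#'
#' @inheritParams carrier_flux
#' @param model `"carrier"` or `"mm"`.
#' @param s_out_grid,s_in_grid Nonnegative concentration grids.
#' @return A `data.frame` with columns `model`, `s_out`, `s_in`, `J`.
#' @export
flux_surface <- function(p, model = c("carrier", "mm"),
                         s_out_grid, s_in_grid) {
  model <- match.arg(model)
  flux <- if (model == "carrier") carrier_flux else mm_flux
  g <- expand.grid(s_in = s_in_grid, s_out = s_out_grid,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(model = model, s_out = g$s_out, s_in = g$s_in,
             J = flux(p, g$s_out, g$s_in))
}
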