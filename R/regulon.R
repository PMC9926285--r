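## Dual-transporter Pho regulon state machine.
##
## Two carrier systems import phosphate: a constitutive low-affinity system
## (large Kd, inactivated post-translationally by Spl2) and a Pho4-induced
## high-affinity system (small Kd, expression level e_H). The internal
## phosphate concentration is a fast variable: transport and metabolite
## relaxation act on seconds-to-minutes while expression and dilution act on
## hours, so s_in is slaved to the instantaneous flux balance
##     a_L * J_L(s_out, s_in) + e_H * J_H(s_out, s_in) = J_demand.
## The nuclear Pho4 level n(s_in) is a smoothed three-level step (0 above
## phi_plateau, n_mid between phi_full and phi_plateau, 1 below phi_full),
## and two promoter classes read n through Hill functions with midpoints
## K_p < n_mid < K_d_prom: plateau promoters respond to intermediate n,
## decoupled promoters only to full nuclear localization.

#' Parameters of the dual-transporter Pho regulon model
#'
#' Assembles kinetics of the low- and high-affinity transporter systems,
#' the consumption demand, expression/dilution rates, the Spl2 inhibition
#' law, the three-level Pho4 nuclear transfer function and the two promoter
#' classes. All quantities are in arbitrary model units with the
#' high-affinity dissociation constant as the concentration scale
#' (`Kd_H = 1`) and the dilution rate as the inverse time scale
#' (`delta = 1`). Defaults reproduce the off / plateau / on program with
#' bistability and hysteresis; see the package vignette for how each value
#' was chosen.
#'
#' @param params_L [transporter_params()] of the constitutive low-affinity
#'   system (`Kd` large).
#' @param params_H [transporter_params()] shape of the high-affinity system
#'   with `et = 1`; the actual transporter amount is the dynamic expression
#'   level `e_H(t)` which multiplies the per-unit flux.
#' @param J_demand Constant phosphate consumption rate (`> 0`).
#' @param alpha_H,alpha_S,alpha_P Maximal synthesis rates of the
#'   high-affinity transporter, Spl2, and the reporters.
#' @param beta_P Basal (Pho4-independent) reporter synthesis rate; the
#'   basal reporter level is `beta_P / delta`.
#' @param delta First-order dilution/degradation rate shared by all
#'   expressed species.
#' @param K_S,m Spl2 inhibition constant and Hill coefficient: the active
#'   fraction of low-affinity transporters is `1 / (1 + (spl2/K_S)^m)`.
#'   `K_S = Inf` disables the inhibition.
#' @param phi_plateau,phi_full Internal-phosphate thresholds for partial and
#'   full Pho4 dephosphorylation (`phi_full < phi_plateau`).
#' @param n_mid Intermediate nuclear Pho4 level in `(0, 1)`.
#' @param n_hill Hill coefficient (`>= 8`) of the two smoothed steps in the
#'   Pho4 transfer function.
#' @param K_p,K_d_prom,h Activation midpoints (`K_p < n_mid < K_d_prom <= 1`)
#'   and Hill coefficient of the plateau-class and decoupled-class promoter
#'   response functions.
#' @return An object of class `regulon_params`.
#' @export
regulon_params <- function(params_L = transporter_params(4, 4, 100, 10),
                           params_H = transporter_params(4, 4, 1, 1),
                           J_demand = 15,
                           alpha_H = 10, alpha_S = 10, alpha_P = 100,
                           beta_P = 1, delta = 1,
                           K_S = 1, m = 2,
                           phi_plateau = 5, phi_full = 0.2,
                           n_mid = 0.4, n_hill = 16,
                           K_p = 0.15, K_d_prom = 0.8, h = 8) {
  stopifnot(inherits(params_L, "transporter_params"),
            inherits(params_H, "transporter_params"),
            params_H$Kd < params_L$Kd,
            J_demand > 0, alpha_H > 0, alpha_S > 0, alpha_P > 0,
            beta_P > 0, delta > 0, K_S > 0, m > 0,
            phi_full > 0, phi_full < phi_plateau,
            n_mid > 0, n_mid < 1, n_hill >= 8,
            K_p > 0, K_p < n_mid, n_mid < K_d_prom, K_d_prom <= 1, h > 0)
  structure(list(params_L = params_L, params_H = params_H,
                 J_demand = J_demand,
                 alpha_H = alpha_H, alpha_S = alpha_S, alpha_P = alpha_P,
                 beta_P = beta_P, delta = delta, K_S = K_S, m = m,
                 phi_plateau = phi_plateau, phi_full = phi_full,
                 n_mid = n_mid, n_hill = n_hill,
                 K_p = K_p, K_d_prom = K_d_prom, h = h),
            class = "regulon_params")
}

#' @export
print.regulon_params <- function(x, ...) {
  cat("Pho regulon model parameters\n")
  cat(sprintf("  low-affinity : k2=%g k4=%g Kd=%g et=%g (Spl2: K_S=%g m=%g)\n",
              x$params_L$k2, x$params_L$k4, x$params_L$Kd, x$params_L$et,
              x$K_S, x$m))
  cat(sprintf("  high-affinity: k2=%g k4=%g Kd=%g, max e_H=%g\n",
              x$params_H$k2, x$params_H$k4, x$params_H$Kd,
              x$alpha_H / x$delta))
  cat(sprintf("  demand J=%g, delta=%g\n", x$J_demand, x$delta))
  cat(sprintf("  Pho4 thresholds: phi_full=%g phi_plateau=%g, n_mid=%g\n",
              x$phi_full, x$phi_plateau, x$n_mid))
  cat(sprintf("  promoters: K_p=%g (plateau) K_d_prom=%g (decoupled) h=%g\n",
              x$K_p, x$K_d_prom, x$h))
  invisible(x)
}

#' Three-level Pho4 nuclear transfer function
#'
#' Maps the internal phosphate concentration to the nuclear Pho4 level: 0
#' when `s_in` is above `phi_plateau` (fully phosphorylated, cytoplasmic),
#' `n_mid` between `phi_full` and `phi_plateau` (partial dephosphorylation,
#' intermediate nuclear level), and 1 below `phi_full` (full
#' dephosphorylation, full nuclear localization). Implemented as the sum of
#' two steep descending Hill steps so the map is continuous:
#' `n = n_mid / (1 + (s/phi_plateau)^n_hill) +
#'  (1 - n_mid) / (1 + (s/phi_full)^n_hill)`.
#'
#' @param s_in Internal phosphate concentration(s), `>= 0`. Vectorized.
#' @param p A [regulon_params()] object.
#' @return Nuclear Pho4 level(s) in `[0, 1]`.
#' @export
pho4_nuclear <- function(s_in, p) {
  stopifnot(inherits(p, "regulon_params"))
  if (any(!is.finite(s_in)) || any(s_in < 0))
    stop("'s_in' must be finite and nonnegative", call. = FALSE)
  p$n_mid / (1 + (s_in / p$phi_plateau)^p$n_hill) +
    (1 - p$n_mid) / (1 + (s_in / p$phi_full)^p$n_hill)
}

## Closed-form quasi-steady internal concentration.
##
## Each carrier's flux is a Moebius (degree 1/1 rational) function of s_in:
## with theta = s/(K+s),
##   J(s) = [a K + (a+b) s] / [c K + (c+d) s],
##   a = E k2 k4 theta_o, b = -E k2 k4,
##   c = k2 theta_o + k4 (2 - theta_o), d = k2 - k4,
## so the two-carrier balance  J_L + J_H = J_demand  clears to a quadratic
## in s_in. Its leading coefficient is strictly negative (both numerator
## slopes are negative and the demand term contributes -J_demand times a
## positive product), so the parabola opens downward; when the constant term
## (total flux at s_in = 0 minus demand, times positive denominators) is
## nonnegative the unique nonnegative root is the larger quadratic root,
## and when it is negative the demand cannot be met and s_in collapses to 0.
.moebius_coef <- function(k2, k4, Kd, E, s_out) {
  to <- s_out / (Kd + s_out)
  a <- E * k2 * k4 * to
  b <- -E * k2 * k4
  cc <- k2 * to + k4 * (2 - to)
  d <- k2 - k4
  list(n0 = a * Kd, n1 = a + b, d0 = cc * Kd, d1 = cc + d)
}

.qss_internal <- function(e_H, a_L, s_out, p, et_L = p$params_L$et) {
  L <- .moebius_coef(p$params_L$k2, p$params_L$k4, p$params_L$Kd,
                     a_L * et_L, s_out)
  H <- .moebius_coef(p$params_H$k2, p$params_H$k4, p$params_H$Kd,
                     e_H * p$params_H$et, s_out)
  Jd <- p$J_demand
  A <- L$n1 * H$d1 + H$n1 * L$d1 - Jd * L$d1 * H$d1
  B <- L$n0 * H$d1 + L$n1 * H$d0 + H$n0 * L$d1 + H$n1 * L$d0 -
    Jd * (L$d0 * H$d1 + L$d1 * H$d0)
  C <- L$n0 * H$d0 + H$n0 * L$d0 - Jd * L$d0 * H$d0
  disc <- pmax(B * B - 4 * A * C, 0)
  q <- -(B + ifelse(B >= 0, 1, -1) * sqrt(disc)) / 2
  r1 <- q / A
  r2 <- ifelse(q != 0, C / q, 0)
  s <- pmax(r1, r2)          # larger root of the downward parabola
  ifelse(C <= 0, 0, pmax(s, 0))
}

#' Quasi-steady internal phosphate of the dual-transporter system
#'
#' Internal concentration at which the combined import of the (partially
#' inhibited) low-affinity system and the expressed high-affinity system
#' exactly balances the consumption demand. Solved in closed form (the
#' two-carrier flux balance reduces to a quadratic in `s_in`; see source).
#' Returns 0 when total import at `s_in = 0` falls short of the demand
#' (starvation collapses to a drained internal pool).
#'
#' @param e_H High-affinity expression level(s), `>= 0`.
#' @param a_L Active fraction(s) of low-affinity transporters in `[0, 1]`.
#' @param s_out External phosphate concentration, `>= 0`.
#' @param p A [regulon_params()] object.
#' @param et_L Total low-affinity transporter amount; defaults to the value
#'   in `p` (vectorized, for cell-to-cell variability).
#' @return Internal concentration(s), `>= 0`.
#' @export
quasi_steady_internal <- function(e_H, a_L, s_out, p,
                                  et_L = p$params_L$et) {
  stopifnot(inherits(p, "regulon_params"))
  if (any(e_H < 0) || any(a_L < 0) || any(a_L > 1) || any(s_out < 0))
    stop("need e_H >= 0, a_L in [0,1], s_out >= 0", call. = FALSE)
  .qss_internal(e_H, a_L, s_out, p, et_L)
}

## promoter response functions
.g_hill <- function(n, K, h) {
  nh <- n^h
  nh / (nh + K^h)
}

.active_fraction <- function(spl2, K_S, m) 1 / (1 + (spl2 / K_S)^m)

## One vectorized Euler step block over n_steps for a population sharing a
## common s_out. 'state' holds numeric vectors e_H, spl2, p_p, p_d (one
## element per cell). Optionally records thinned trajectories and window
## means over the last 'window_steps' steps.
.step_population <- function(state, s_out, p, dt, n_steps, et_L,
                             window_steps = 0L, record_every = 0L) {
  e_H <- state$e_H; spl2 <- state$spl2; p_p <- state$p_p; p_d <- state$p_d
  nc <- length(e_H)
  rec <- NULL
  if (record_every > 0L) {
    idx <- seq(record_every, n_steps, by = record_every)
    rec <- list(step = idx,
                s_in = matrix(NA_real_, length(idx), nc),
                n = matrix(NA_real_, length(idx), nc),
                e_H = matrix(NA_real_, length(idx), nc),
                spl2 = matrix(NA_real_, length(idx), nc),
                a_L = matrix(NA_real_, length(idx), nc),
                p_p = matrix(NA_real_, length(idx), nc),
                p_d = matrix(NA_real_, length(idx), nc))
    ri <- 1L
  }
  if (window_steps > 0L) {
    acc <- list(n = 0, s_in = 0, p_p = 0, p_d = 0, e_H = 0, a_L = 0,
                n_min = Inf, n_max = -Inf,
                p_p_min = Inf, p_p_max = -Inf,
                p_d_min = Inf, p_d_max = -Inf)
  }
  for (k in seq_len(n_steps)) {
    a_L <- .active_fraction(spl2, p$K_S, p$m)
    s_in <- .qss_internal(e_H, a_L, s_out, p, et_L)
    n <- pho4_nuclear(s_in, p)
    g_p <- .g_hill(n, p$K_p, p$h)
    g_d <- .g_hill(n, p$K_d_prom, p$h)
    e_H <- e_H + dt * (p$alpha_H * g_p - p$delta * e_H)
    spl2 <- spl2 + dt * (p$alpha_S * g_p - p$delta * spl2)
    p_p <- p_p + dt * (p$beta_P + p$alpha_P * g_p - p$delta * p_p)
    p_d <- p_d + dt * (p$beta_P + p$alpha_P * g_d - p$delta * p_d)
    if (any(e_H < 0) || any(spl2 < 0) || any(p_p < 0) || any(p_d < 0))
      stop("integration unstable (negative level); use a smaller dt",
           call. = FALSE)
    if (record_every > 0L && k %% record_every == 0L) {
      rec$s_in[ri, ] <- s_in; rec$n[ri, ] <- n
      rec$e_H[ri, ] <- e_H; rec$spl2[ri, ] <- spl2; rec$a_L[ri, ] <- a_L
      rec$p_p[ri, ] <- p_p; rec$p_d[ri, ] <- p_d
      ri <- ri + 1L
    }
    if (window_steps > 0L && k > n_steps - window_steps) {
      acc$n <- acc$n + n; acc$s_in <- acc$s_in + s_in
      acc$p_p <- acc$p_p + p_p; acc$p_d <- acc$p_d + p_d
      acc$e_H <- acc$e_H + e_H; acc$a_L <- acc$a_L + a_L
      acc$n_min <- pmin(acc$n_min, n); acc$n_max <- pmax(acc$n_max, n)
      acc$p_p_min <- pmin(acc$p_p_min, p_p)
      acc$p_p_max <- pmax(acc$p_p_max, p_p)
      acc$p_d_min <- pmin(acc$p_d_min, p_d)
      acc$p_d_max <- pmax(acc$p_d_max, p_d)
    }
  }
  out <- list(state = list(e_H = e_H, spl2 = spl2, p_p = p_p, p_d = p_d),
              rec = rec)
  if (window_steps > 0L) {
    w <- window_steps
    out$window <- list(n = acc$n / w, s_in = acc$s_in / w,
                       p_p = acc$p_p / w, p_d = acc$p_d / w,
                       e_H = acc$e_H / w, a_L = acc$a_L / w,
                       n_range = cbind(acc$n_min, acc$n_max),
                       p_p_range = cbind(acc$p_p_min, acc$p_p_max),
                       p_d_range = cbind(acc$p_d_min, acc$p_d_max))
  }
  out
}

#' Initial expression state of a regulon simulation
#'
#' Convenience presets: `"off"` (no induced expression, reporters at basal
#' level), `"on"` (full expression, both reporters induced) and `"plateau"`
#' (full transporter/Spl2 expression, plateau reporter induced, decoupled
#' reporter basal).
#'
#' @param p A [regulon_params()] object.
#' @param state One of `"off"`, `"on"`, `"plateau"`.
#' @return A list with elements `e_H`, `spl2`, `p_plateau`, `p_decoupled`.
#' @export
regulon_init <- function(p, state = c("off", "on", "plateau")) {
  state <- match.arg(state)
  basal <- p$beta_P / p$delta
  full <- (p$beta_P + p$alpha_P) / p$delta
  switch(state,
    off = list(e_H = 0, spl2 = 0, p_plateau = basal, p_decoupled = basal),
    on = list(e_H = p$alpha_H / p$delta, spl2 = p$alpha_S / p$delta,
              p_plateau = full, p_decoupled = full),
    plateau = list(e_H = p$alpha_H / p$delta, spl2 = p$alpha_S / p$delta,
                   p_plateau = full, p_decoupled = basal))
}

#' Simulate a single-cell Pho regulon trajectory
#'
#' Integrates the expression dynamics of the high-affinity transporter,
#' Spl2 and the two reporter classes with a fixed-step explicit Euler
#' scheme, treating the internal phosphate concentration as an
#' instantaneously equilibrated fast variable
#' ([quasi_steady_internal()]). The external phosphate concentration
#' follows a piecewise-constant schedule.
#'
#' @param p A [regulon_params()] object.
#' @param schedule A `data.frame` with columns `duration` (`> 0`) and
#'   `s_out` (`>= 0`): successive external-phosphate epochs.
#' @param init Initial expression state, as from [regulon_init()].
#' @param dt Integration step; must satisfy `dt <= 0.05 / delta`.
#' @param record_every Record every this many steps (default records every
#'   step).
#' @return A `cell_trajectory` object: a `data.frame` with columns `time`,
#'   `s_out`, `s_in`, `e_H`, `spl2`, `a_L`, `n`, `p_plateau`,
#'   `p_decoupled`, with the model parameters in attribute `params` and the
#'   terminal state label (or `NA` if the tail is not stationary) in
#'   attribute `state`.
#' @examples
#' p <- regulon_params()
#' traj <- simulate_regulon(p, data.frame(duration = 12, s_out = 50))
#' attr(traj, "state")  # "PLATEAU"
#' @export
simulate_regulon <- function(p, schedule, init = regulon_init(p, "off"),
                             dt = 0.01 / p$delta, record_every = 1L) {
  stopifnot(inherits(p, "regulon_params"),
            is.data.frame(schedule),
            all(c("duration", "s_out") %in% names(schedule)),
            all(schedule$duration > 0), all(schedule$s_out >= 0))
  if (dt > 0.05 / p$delta)
    stop("'dt' must be <= 0.05/delta to resolve the expression dynamics",
         call. = FALSE)
  state <- list(e_H = init$e_H, spl2 = init$spl2,
                p_p = init$p_plateau, p_d = init$p_decoupled)
  rows <- list()
  t0 <- 0
  for (i in seq_len(nrow(schedule))) {
    n_steps <- max(1L, round(schedule$duration[i] / dt))
    res <- .step_population(state, schedule$s_out[i], p, dt, n_steps,
                            et_L = p$params_L$et,
                            record_every = record_every)
    state <- res$state
    rec <- res$rec
    rows[[i]] <- data.frame(time = t0 + rec$step * dt,
                            s_out = schedule$s_out[i],
                            s_in = rec$s_in[, 1], e_H = rec$e_H[, 1],
                            spl2 = rec$spl2[, 1], a_L = rec$a_L[, 1],
                            n = rec$n[, 1], p_plateau = rec$p_p[, 1],
                            p_decoupled = rec$p_d[, 1])
    t0 <- t0 + n_steps * dt
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  class(traj) <- c("cell_trajectory", "data.frame")
  attr(traj, "params") <- p
  attr(traj, "state") <- tryCatch(
    classify_state(traj, window = 1 / p$delta),
    error = function(e) NA_character_)
  traj
}

#' @export
print.cell_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Pho regulon cell trajectory: %d timepoints, t in [%g, %g]\n",
              nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  terminal state: %s\n", attr(x, "state")))
  tail_row <- x[nrow(x), ]
  cat(sprintf("  terminal n=%.3f s_in=%.3g e_H=%.3g a_L=%.3f p_plateau=%.3g p_decoupled=%.3g\n",
              tail_row$n, tail_row$s_in, tail_row$e_H, tail_row$a_L,
              tail_row$p_plateau, tail_row$p_decoupled))
  invisible(x)
}

#' @export
plot.cell_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$s_in, type = "l", xlab = "time",
                 ylab = "internal Pi", log = "y", ...)
  graphics::plot(x$time, x$n, type = "l", xlab = "time",
                 ylab = "nuclear Pho4", ylim = c(0, 1), ...)
  graphics::plot(x$time, x$e_H, type = "l", xlab = "time",
                 ylab = "levels", col = "darkred",
                 ylim = range(c(x$e_H, x$spl2)), ...)
  graphics::lines(x$time, x$spl2, col = "steelblue")
  graphics::legend("topleft", c("e_H", "Spl2"), lty = 1, bty = "n",
                   col = c("darkred", "steelblue"))
  graphics::plot(x$time, x$p_plateau, type = "l", xlab = "time",
                 ylab = "reporters", log = "y", col = "darkgreen",
                 ylim = range(c(x$p_plateau, x$p_decoupled)), ...)
  graphics::lines(x$time, x$p_decoupled, col = "purple")
  graphics::legend("topleft", c("plateau", "decoupled"), lty = 1,
                   bty = "n", col = c("darkgreen", "purple"))
  invisible(x)
}

#' Classify the terminal state of a trajectory
#'
#' Labels the terminal state by the time-averaged nuclear Pho4 level and
#' reporter levels over the final `window` of the trajectory: `"OFF"`
#' (`n` near 0, both reporters basal), `"PLATEAU"` (`n` near `n_mid`,
#' plateau reporter induced, decoupled reporter basal) or `"ON"` (`n` near
#' 1, both reporters induced). The tolerance on `n` is `0.1 * n_mid`;
#' a reporter counts as induced above 10 times its basal level. Errors
#' (condition class `phostat_not_converged`) when the tail is not
#' stationary (relative drift above 1%) or the averages fall between the
#' level tolerances.
#'
#' @param traj A `cell_trajectory` from [simulate_regulon()].
#' @param window Averaging window (time units) at the end of the
#'   trajectory; must be shorter than the trajectory.
#' @return One of `"OFF"`, `"PLATEAU"`, `"ON"`.
#' @export
classify_state <- function(traj, window = 1) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 3L)
  p <- attr(traj, "params")
  if (is.null(p)) stop("trajectory has no 'params' attribute", call. = FALSE)
  t_end <- max(traj$time)
  if (window >= t_end - min(traj$time))
    stop("'window' must be shorter than the trajectory", call. = FALSE)
  tail_rows <- traj[traj$time > t_end - window, , drop = FALSE]
  drift <- function(v) {
    m <- mean(abs(v))
    if (m < 1e-12) 0 else (max(v) - min(v)) / m
  }
  if (max(drift(tail_rows$n), drift(tail_rows$p_plateau),
          drift(tail_rows$p_decoupled), drift(tail_rows$e_H)) > 0.01)
    stop(structure(class = c("phostat_not_converged", "error", "condition"),
                   list(message = "trajectory tail is not stationary",
                        call = sys.call())))
  .label_state(mean(tail_rows$n), mean(tail_rows$p_plateau),
               mean(tail_rows$p_decoupled), p)
}

.label_state <- function(n, p_p, p_d, p) {
  tol_n <- 0.1 * p$n_mid
  basal <- p$beta_P / p$delta
  ind_p <- p_p > 10 * basal
  ind_d <- p_d > 10 * basal
  if (n < tol_n && !ind_p && !ind_d) return("OFF")
  if (n > 1 - tol_n && ind_p && ind_d) return("ON")
  if (abs(n - p$n_mid) < tol_n && ind_p && !ind_d) return("PLATEAU")
  stop(structure(class = c("phostat_not_converged", "error", "condition"),
                 list(message = sprintf(
                   "ambiguous terminal state (n=%.3f, p_plateau=%.3g, p_decoupled=%.3g)",
                   n, p_p, p_d), call = sys.call())))
}

## default external-phosphate grid for sweeps; chosen to cover the three
## regimes while staying clear of the narrow transition bands where the
## smoothed Pho4 steps give genuinely intermediate nuclear levels
.default_sweep_grid <- function() c(1, 2, 4, 7, 18, 35, 70, 140, 250, 500, 1000)

#' Hysteretic state sweep over external phosphate
#'
#' Runs the regulon to stationarity at each grid concentration, carrying
#' the terminal expression state forward as the next initial condition
#' (path dependence is the point). `"down_from_rich"` traverses the sorted
#' grid from the highest concentration starting in the off state;
#' `"up_from_starved"` traverses from the lowest starting fully on.
#'
#' @param p A [regulon_params()] object.
#' @param s_out_grid Sorted external concentrations.
#' @param direction `"down_from_rich"` or `"up_from_starved"`.
#' @param duration Time simulated per grid point (`>= 10 / delta`).
#' @param dt Integration step.
#' @return A `regulon_sweep` object: a `data.frame` with columns `s_out`,
#'   `direction`, `label`, `n`, `s_in`, `p_plateau`, `p_decoupled`
#'   (window-averaged terminal values), ordered along the sweep. A
#'   stationary point whose averages fall between the three canonical
#'   programs is labeled `"MIXED"`.
#' @examples
#' p <- regulon_params()
#' sw <- regulon_sweep(p, direction = "down_from_rich")
#' table(sw$label)
#' @export
regulon_sweep <- function(p, s_out_grid = .default_sweep_grid(),
                          direction = c("down_from_rich", "up_from_starved"),
                          duration = 12 / p$delta, dt = 0.01 / p$delta) {
  direction <- match.arg(direction)
  stopifnot(inherits(p, "regulon_params"), !is.unsorted(s_out_grid),
            duration >= 10 / p$delta)
  grid <- if (direction == "down_from_rich") rev(s_out_grid) else s_out_grid
  init <- regulon_init(p, if (direction == "down_from_rich") "off" else "on")
  state <- list(e_H = init$e_H, spl2 = init$spl2,
                p_p = init$p_plateau, p_d = init$p_decoupled)
  n_steps <- max(1L, round(duration / dt))
  w_steps <- max(2L, round((1 / p$delta) / dt))
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    res <- .step_population(state, grid[i], p, dt, n_steps,
                            et_L = p$params_L$et, window_steps = w_steps)
    state <- res$state
    w <- res$window
    .check_window_stationary(w)
    ## a stationary point that sits between the three canonical programs
    ## (possible e.g. without Spl2 inhibition, where the pure negative
    ## feedback admits a continuum of intermediate fixed points) is
    ## reported as MIXED rather than forced into a program
    label <- tryCatch(.label_state(w$n[1], w$p_p[1], w$p_d[1], p),
                      phostat_not_converged = function(e) "MIXED")
    out[[i]] <- data.frame(s_out = grid[i], direction = direction,
                           label = label, n = w$n[1], s_in = w$s_in[1],
                           p_plateau = w$p_p[1], p_decoupled = w$p_d[1])
  }
  sw <- do.call(rbind, out)
  rownames(sw) <- NULL
  class(sw) <- c("regulon_sweep", "data.frame")
  attr(sw, "params") <- p
  sw
}

.check_window_stationary <- function(w, cells = 1L) {
  rel <- function(rng, m) {
    d <- (rng[cells, 2] - rng[cells, 1]) / pmax(abs(m[cells]), 1e-12)
    max(d)
  }
  if (max(rel(w$n_range, w$n), rel(w$p_p_range, w$p_p),
          rel(w$p_d_range, w$p_d)) > 0.01)
    stop(structure(class = c("phostat_not_converged", "error", "condition"),
                   list(message = "sweep point did not reach stationarity",
                        call = sys.call())))
  invisible(TRUE)
}

#' @export
print.regulon_sweep <- function(x, ...) {
  cat(sprintf("Pho regulon state sweep (%s), %d grid points\n",
              x$direction[1], nrow(x)))
  print.data.frame(format(as.data.frame(x), digits = 4), ...)
  invisible(x)
}

#' @export
plot.regulon_sweep <- function(x, ...) {
  cols <- c(OFF = "grey40", PLATEAU = "orange", ON = "firebrick")
  graphics::plot(x$s_out, x$n, log = "x", pch = 19, col = cols[x$label],
                 xlab = "external Pi", ylab = "nuclear Pho4",
                 ylim = c(0, 1), ...)
  graphics::legend("topright", names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}

#' Bistable window of the off and plateau attractors
#'
#' Scans a concentration grid for coexistence of the off and plateau
#' states: at each point the model is run both from the off-like and from
#' the plateau-like initial condition, and the point qualifies when the
#' first run ends `"OFF"` and the second `"PLATEAU"`. The deterministic
#' window may be right-unbounded (commitment); the experimentally finite
#' bistable range emerges only with cell-to-cell transporter variability
#' ([population_sweep()]).
#'
#' @inheritParams regulon_sweep
#' @return A list with `lower` and `upper` (min/max qualifying grid point,
#'   `NA` if none), the qualifying `s_out` values, and `empty`.
#' @export
bistable_window <- function(p, s_out_grid = .default_sweep_grid(),
                            duration = 12 / p$delta, dt = 0.01 / p$delta) {
  stopifnot(inherits(p, "regulon_params"))
  n_steps <- max(1L, round(duration / dt))
  w_steps <- max(2L, round((1 / p$delta) / dt))
  qual <- logical(length(s_out_grid))
  for (i in seq_along(s_out_grid)) {
    lab <- vapply(c("off", "plateau"), function(ini) {
      init <- regulon_init(p, ini)
      res <- .step_population(list(e_H = init$e_H, spl2 = init$spl2,
                                   p_p = init$p_plateau,
                                   p_d = init$p_decoupled),
                              s_out_grid[i], p, dt, n_steps,
                              et_L = p$params_L$et, window_steps = w_steps)
      w <- res$window
      tryCatch(.label_state(w$n[1], w$p_p[1], w$p_d[1], p),
               error = function(e) NA_character_)
    }, character(1))
    qual[i] <- identical(unname(lab), c("OFF", "PLATEAU"))
  }
  pts <- s_out_grid[qual]
  list(lower = if (length(pts)) min(pts) else NA_real_,
       upper = if (length(pts)) max(pts) else NA_real_,
       s_out = pts, empty = length(pts) == 0L)
}

#' Population state fractions with transporter variability
#'
#' Draws a per-cell low-affinity transporter amount from a lognormal
#' distribution with the given coefficient of variation, runs the
#' down-from-rich sweep for every cell (vectorized), and reports the
#' fraction of cells not in the off state at each grid concentration.
#' Cell-to-cell spread in `et_L` turns the deterministic commitment
#' boundary into a mixed region where off and plateau cells coexist, the
#' population-level signature of the bistable range.
#'
#' @inheritParams regulon_sweep
#' @param cv_etL Coefficient of variation of the low-affinity transporter
#'   amount (`>= 0`; `0` gives a deterministic population).
#' @param n_cells Number of cells (`>= 1`).
#' @param seed Integer seed.
#' @param detail If `TRUE`, attach the per-cell window means (`n`, `s_in`,
#'   `p_plateau`, `p_decoupled`, activation flag) for every grid point as
#'   attribute `cells`, along with the drawn `et_L` values.
#' @return A `data.frame` with columns `s_out` and `fraction_activated`
#'   (fraction of cells not OFF), in descending grid order.
#' @export
population_sweep <- function(p, s_out_grid = .default_sweep_grid(),
                             cv_etL = 0.3, n_cells = 200L, seed = 1L,
                             duration = 12 / p$delta, dt = 0.01 / p$delta,
                             detail = FALSE) {
  stopifnot(inherits(p, "regulon_params"), cv_etL >= 0, n_cells >= 1)
  et_L <- if (cv_etL > 0) {
    sdlog <- sqrt(log(1 + cv_etL^2))
    withr::with_seed(seed,
      stats::rlnorm(n_cells, log(p$params_L$et) - sdlog^2 / 2, sdlog))
  } else rep(p$params_L$et, n_cells)
  grid <- rev(sort(s_out_grid))
  init <- regulon_init(p, "off")
  state <- list(e_H = rep(init$e_H, n_cells),
                spl2 = rep(init$spl2, n_cells),
                p_p = rep(init$p_plateau, n_cells),
                p_d = rep(init$p_decoupled, n_cells))
  n_steps <- max(1L, round(duration / dt))
  w_steps <- max(2L, round((1 / p$delta) / dt))
  frac <- numeric(length(grid))
  cells <- if (detail) vector("list", length(grid)) else NULL
  tol_n <- 0.1 * p$n_mid
  basal <- p$beta_P / p$delta
  for (i in seq_along(grid)) {
    res <- .step_population(state, grid[i], p, dt, n_steps, et_L,
                            window_steps = w_steps)
    state <- res$state
    w <- res$window
    off <- w$n < tol_n & w$p_p < 10 * basal & w$p_d < 10 * basal
    frac[i] <- mean(!off)
    if (detail)
      cells[[i]] <- data.frame(s_out = grid[i], cell = seq_len(n_cells),
                               et_L = et_L, n = w$n, s_in = w$s_in,
                               p_plateau = w$p_p, p_decoupled = w$p_d,
                               activated = !off)
  }
  out <- data.frame(s_out = grid, fraction_activated = frac)
  if (detail) attr(out, "cells") <- do.call(rbind, cells)
  out
}
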