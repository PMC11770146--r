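# Frequency-domain solver for the coupled two-coil resonant link, and a
# least-squares calibration of the coupling and receiver loss against a
# measured receiver-voltage curve.

# Two-mesh phasor solve, vectorised over angular frequency.  Primary mesh:
# source amplitude vs behind Rs, transmitter coil (R1, L1).  Secondary mesh:
# receiver coil (R2, L2) in series with the tank capacitance C; the
# electrode/receiver voltage is taken across C.  Mesh equations:
#   (Rs + R1 + jwL1) I1 - jwM I2 = Vs
#  -jwM I1 + (R2 + jwL2 + 1/(jwC)) I2 = 0
two_mesh_response <- function(w, vs, Rs, R1, L1, R2, L2, C, M) {
  z1 <- complex(real = Rs + R1, imaginary = w * L1)
  z2 <- complex(real = R2, imaginary = w * L2 - 1 / (w * C))
  zm <- complex(real = 0, imaginary = w * M)
  det <- z1 * z2 + zm * zm   # z1*z2 - (jwM)(jwM) with the mesh sign convention
  if (any(Mod(det) == 0))
    stop_domain("singular two-mesh system (all impedances zero)")
  i1 <- vs * z2 / det
  i2 <- vs * zm / det
  v_cap <- i2 / complex(imaginary = w * C)
  v_tx <- vs - i1 * Rs
  list(v_tx = v_tx, v_rx = v_cap)
}

#' Receiver-voltage frequency sweep of the inductive link
#'
#' Solves, at each frequency, the coupled two-mesh circuit formed by the
#' driven transmitter coil and the receiver LC tank (receiver coil in series
#' with the total tank capacitance; the electrode voltage is the capacitor
#' voltage), and reports transmitter and receiver peak-to-peak voltages
#' together with the location of the receiver-voltage maximum.  This is the
#' model behind the measured receiver-voltage-versus-frequency curves of a
#' resonant inductive power link: a single peak near
#' \eqn{1/(2\pi\sqrt{L_2 C})} whose height grows with coupling and shrinks
#' with loss.
#'
#' @param tx_coil transmitter [planar_coil()].
#' @param rx_tank receiver [receiver_tank()].
#' @param coupling [coupling_spec()].
#' @param drive [transmitter_drive()] (its `frequency` field is ignored; the
#'   sweep range is given explicitly).
#' @param f_min,f_max sweep range in Hz (0 < f_min < f_max).
#' @param n_points number of frequencies (>= 2), linearly spaced.
#' @return An object of class `dep_sweep`: a list with `frequencies`,
#'   `v_tx_pp`, `v_rx_pp` (all vectors), `resonance_peak` (Hz), and the
#'   circuit description used.
#' @examples
#' tx <- planar_coil(13, 4.6e-6, 2)
#' rx <- receiver_tank(planar_coil(13, 4.6e-6, 2),
#'                     interdigitated_electrodes(10),
#'                     c_added = 450e-12, c_parasitic_override = 35e-12)
#' sw <- sweep_receiver_voltage(tx, rx, coupling_spec(0.1),
#'                              transmitter_drive(20, 3.5e6),
#'                              f_min = 1e6, f_max = 6e6, n_points = 501)
#' sw$resonance_peak  # near 3.4 MHz
#' @export
sweep_receiver_voltage <- function(tx_coil, rx_tank, coupling, drive,
                                   f_min, f_max, n_points = 401) {
  stopifnot(inherits(tx_coil, "planar_coil"),
            inherits(rx_tank, "receiver_tank"),
            inherits(coupling, "coupling_spec"),
            inherits(drive, "transmitter_drive"))
  check_number(f_min, "f_min", min = 0, strict_min = TRUE)
  check_number(f_max, "f_max", min = f_min, strict_min = TRUE)
  check_count(n_points, "n_points", min = 2L)

  freqs <- seq(f_min, f_max, length.out = n_points)
  C <- total_capacitance(rx_tank)
  L1 <- tx_coil$inductance
  L2 <- rx_tank$coil$inductance
  M <- mutual_inductance(L1, L2, coupling$k)
  vs <- drive$v_pp / 2   # phasor amplitude of the source

  resp <- two_mesh_response(2 * pi * freqs, vs, drive$source_resistance,
                            tx_coil$series_resistance, L1,
                            rx_tank$coil$series_resistance, L2, C, M)
  v_tx <- 2 * Mod(resp$v_tx)
  v_rx <- 2 * Mod(resp$v_rx)

  structure(list(frequencies = freqs, v_tx_pp = v_tx, v_rx_pp = v_rx,
                 resonance_peak = freqs[which.max(v_rx)],
                 c_total = C,
                 tx_coil = tx_coil, rx_tank = rx_tank,
                 coupling = coupling, drive = drive),
            class = "dep_sweep")
}

#' @export
print.dep_sweep <- function(x, ...) {
  cat("Inductive-link frequency sweep:",
      si_format(min(x$frequencies), "Hz"), "-",
      si_format(max(x$frequencies), "Hz"),
      "(", length(x$frequencies), "points )\n")
  cat("  C_total =", si_format(x$c_total, "F"),
      " k =", x$coupling$k, "\n")
  cat("  receiver peak:", si_format(max(x$v_rx_pp), "Vpp"), "at",
      si_format(x$resonance_peak, "Hz"), "\n")
  invisible(x)
}

#' @export
plot.dep_sweep <- function(x, ...) {
  graphics::plot(x$frequencies / 1e6, x$v_rx_pp, type = "l", col = "firebrick",
                 xlab = "Frequency (MHz)", ylab = "Voltage (Vpp)",
                 ylim = range(0, x$v_rx_pp, x$v_tx_pp), ...)
  graphics::lines(x$frequencies / 1e6, x$v_tx_pp, col = "steelblue")
  graphics::abline(v = x$resonance_peak / 1e6, lty = 3)
  graphics::legend("topright", c("receiver", "transmitter"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' As-data-frame method for sweeps
#' @param x a `dep_sweep`.
#' @param ... unused.
#' @export
as.data.frame.dep_sweep <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, v_tx_pp = x$v_tx_pp,
             v_rx_pp = x$v_rx_pp)
}

#' Calibrate coupling and receiver loss from a measured sweep
#'
#' The coupling coefficient `k` and the receiver coil resistance of a real
#' device are rarely known; both can be recovered from a measured
#' receiver-voltage curve.  This fits the two-mesh forward model's `k` and
#' receiver series resistance to the `v_rx_pp` curve of `sweep` by bounded
#' Levenberg-Marquardt least squares (all other circuit values are taken from
#' `tx_coil` and `rx_tank`).
#'
#' @param sweep a `dep_sweep` (or a list with `frequencies`, `v_rx_pp` and a
#'   `drive`) holding the measured curve; needs at least 5 points bracketing
#'   an interior peak.
#' @param tx_coil transmitter [planar_coil()].
#' @param rx_tank receiver [receiver_tank()] (its coil resistance is the
#'   fitted quantity; its stored value is ignored).
#' @param drive [transmitter_drive()]; defaults to the one stored in `sweep`.
#' @param start named list of starting values (`k`, `R`); by default both
#'   are estimated from the curve (half-power width for R, peak height for
#'   k), falling back to k = 0.3, R = 5 ohm when the peak is unresolved.
#' @return An object of class `coupling_fit` with elements `k`, `r_rx`,
#'   `residual_norm`, `fitted` and the underlying `nls` fit.  `coef()`
#'   returns `c(k, r_rx)`.
#' @export
fit_coupling_and_loss <- function(sweep, tx_coil, rx_tank, drive = sweep$drive,
                                  start = NULL) {
  stopifnot(inherits(tx_coil, "planar_coil"),
            inherits(rx_tank, "receiver_tank"),
            inherits(drive, "transmitter_drive"))
  freqs <- sweep$frequencies
  v_meas <- sweep$v_rx_pp
  if (length(freqs) < 5L)
    stop_invalid("sweep must contain at least 5 points")
  ipk <- which.max(v_meas)
  if (max(v_meas) <= 0 || ipk == 1L || ipk == length(v_meas))
    stop(structure(class = c("depspin_fit_failure", "error", "condition"),
                   list(message = "no interior receiver-voltage peak to fit",
                        call = sys.call())))

  C <- total_capacitance(rx_tank)
  L1 <- tx_coil$inductance
  L2 <- rx_tank$coil$inductance
  vs <- drive$v_pp / 2

  model_curve <- function(k, R) {
    2 * Mod(two_mesh_response(2 * pi * freqs, vs, drive$source_resistance,
                              tx_coil$series_resistance, L1,
                              R, L2, C, k * sqrt(L1 * L2))$v_rx)
  }

  # The (k, R) landscape of the squared-error surface has local minima for
  # sharply resonant curves, so refinement is started from the best points
  # of a coarse log-spaced grid rather than a single guess.
  starts <- if (!is.null(start)) list(start) else {
    grid <- expand.grid(k = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.6),
                        R = c(0.2, 1, 3, 8, 20, 60))
    lapply(seq_len(nrow(grid)), function(i)
      list(k = grid$k[i], R = grid$R[i]))
  }
  df <- data.frame(v = v_meas)
  best <- NULL
  for (s in starts) {
    fit_try <- tryCatch(
      minpack.lm::nlsLM(v ~ model_curve(k, R), data = df, start = s,
                        lower = c(k = 1e-6, R = 1e-4),
                        upper = c(k = 1, R = 1e4),
                        control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit_try)) next
    rss <- sum(stats::resid(fit_try)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit_try, rss = rss)
  }
  if (is.null(best))
    stop(structure(class = c("depspin_fit_failure", "error", "condition"),
                   list(message = "calibration fit did not converge",
                        call = sys.call())))
  fit <- best$fit
  est <- stats::coef(fit)
  # polish: profile R on a fine log grid at the fitted k and refit from the
  # profile minimum, which escapes shallow local minima in the R direction
  r_grid <- 10^seq(-1, 2.5, length.out = 80)
  sse_r <- vapply(r_grid, function(r)
    sum((model_curve(est[["k"]], r) - v_meas)^2), numeric(1))
  r_best <- r_grid[which.min(sse_r)]
  if (min(sse_r) < best$rss) {
    fit2 <- tryCatch(
      minpack.lm::nlsLM(v ~ model_curve(k, R), data = df,
                        start = list(k = est[["k"]], R = r_best),
                        lower = c(k = 1e-6, R = 1e-4),
                        upper = c(k = 1, R = 1e4),
                        control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit2) && sum(stats::resid(fit2)^2) < best$rss) fit <- fit2
  }
  est <- stats::coef(fit)
  fitted_v <- model_curve(est[["k"]], est[["R"]])
  structure(list(k = unname(est[["k"]]), r_rx = unname(est[["R"]]),
                 residual_norm = sqrt(sum((fitted_v - v_meas)^2)),
                 fitted = fitted_v, fit = fit),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat("Coupled-link calibration fit:\n",
      " k    =", signif(x$k, 6), "\n",
      " R_rx =", si_format(x$r_rx, "ohm"), "\n",
      " residual norm =", signif(x$residual_norm, 4), "Vpp\n")
  invisible(x)
}

#' @export
coef.coupling_fit <- function(object, ...) {
  c(k = object$k, r_rx = object$r_rx)
}
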