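# Overdamped particle transport in the electrode unit cell: DEP force from
# the solved field map, Stokes drag, and the centrifugal body force of the
# spinning disc.  Classifies trap-versus-wash outcomes.

#' Disc spin condition
#'
#' @param rpm disc rotation speed in revolutions per minute (>= 0).
#' @param radial_position distance of the electrode region from the spin axis
#'   in m (> 0; default 25 mm).
#' @param direction +1 if the disc-radial (outward) direction coincides with
#'   the unit cell's +x axis, -1 for the opposite orientation.  Electrode
#'   fingers are assumed perpendicular to the disc radius.
#' @return An object of class `spin_condition` (stores `omega` in rad/s).
#' @export
spin_condition <- function(rpm, radial_position = 25e-3, direction = 1) {
  check_number(rpm, "rpm", min = 0)
  check_number(radial_position, "radial_position", min = 0, strict_min = TRUE)
  stopifnot(direction %in% c(-1, 1))
  structure(list(rpm = rpm, omega = rpm * 2 * pi / 60,
                 radial_position = radial_position, direction = direction),
            class = "spin_condition")
}

#' @export
print.spin_condition <- function(x, ...) {
  cat("Spin:", x$rpm, "RPM at R =", si_format(x$radial_position, "m"),
      "(", si_format(x$omega^2 * x$radial_position, "m/s^2"),
      "centripetal )\n")
  invisible(x)
}

# Buoyant centrifugal body force magnitude (N), signed along +x
centrifugal_force <- function(suspension, spin) {
  r <- suspension$particle$radius
  (4 / 3) * pi * r^3 *
    (suspension$density_particle - suspension$density_medium) *
    spin$omega^2 * spin$radial_position * spin$direction
}

#' Net force on a particle in the unit cell
#'
#' Sum of the DEP force (via [dep_force()] on the interpolated
#' \eqn{\nabla|E|^2}) and the buoyant centrifugal body force
#' \eqn{(4/3)\pi r^3(\rho_p - \rho_m)\,\omega^2 R} directed along the unit
#' cell's lateral (+x) axis.  A neutrally buoyant particle feels no
#' centrifugal term; at zero spin the net force reduces to the DEP force
#' exactly.
#'
#' @param suspension a [suspension()].
#' @param f drive frequency in Hz.
#' @param field a `field_map` from [solve_unit_cell()].
#' @param spin a [spin_condition()].
#' @param position length-2 position (x, y) in m.
#' @return length-2 force vector in N.
#' @export
net_force <- function(suspension, f, field, spin, position) {
  stopifnot(inherits(suspension, "suspension"),
            inherits(field, "field_map"),
            inherits(spin, "spin_condition"))
  fq <- field_at(field, position[1], position[2])
  f_dep <- dep_force(suspension$particle, suspension$medium, f, fq$grad_e_sq)
  f_dep + c(centrifugal_force(suspension, spin), 0)
}

# Return a field map rescaled to a new drive voltage; Laplace linearity makes
# phi ~ V, so e_sq and grad(e_sq) scale as V^2.
rescale_voltage <- function(field, v_pp) {
  check_number(v_pp, "v_pp", min = 0)
  s <- (v_pp / field$geometry$applied_v_pp)^2
  field$e_sq <- field$e_sq * s
  field$ge_x <- field$ge_x * s
  field$ge_y <- field$ge_y * s
  field$geometry$applied_v_pp <- v_pp
  field
}

#' Simulate an overdamped particle trajectory
#'
#' Integrates the inertialess force balance \eqn{v = F / (6\pi\mu r)} (DEP +
#' centrifugal against Stokes drag; Reynolds and Stokes numbers for
#' micrometre beads are far below 1) with adaptive explicit Euler stepping:
#' the step is capped so no single move exceeds half a grid cell, which keeps
#' the integration stable in the steep near-edge field.  The lateral
#' coordinate wraps periodically across the unit cell while the cumulative
#' drift is tracked.
#'
#' Outcomes: `"trapped"` when the windowed mean speed falls below
#' `trap_speed` while the particle sits within `trap_radius` of an electrode
#' edge; `"washed"` when the cumulative lateral drift exceeds
#' `wash_periods` unit-cell periods; `"undecided"` at `t_max`.
#'
#' @param suspension a [suspension()].
#' @param f drive frequency in Hz.
#' @param field a `field_map`; its stored drive voltage is used unless
#'   `v_pp` overrides it (the field is then rescaled by \eqn{V^2}, not
#'   re-solved).
#' @param spin a [spin_condition()].
#' @param start length-2 start position (x, y) in m; default: mid-gap, one
#'   cell above the floor.
#' @param v_pp optional drive voltage override in Vpp.
#' @param dt nominal time step in s.
#' @param t_max simulated time horizon in s.
#' @param trap_speed trap speed threshold in m/s (default 0.1 um/s).
#' @param trap_radius capture radius around an electrode edge in m (default
#'   1.5 grid cells).
#' @param wash_periods cumulative drift (in unit-cell periods) that counts as
#'   washed away.
#' @param record keep every `record`-th step in the output path (thinning).
#' @return An object of class `dep_trajectory`: `times`, `positions` (two
#'   columns, x wrapped), `drift` (unwrapped lateral displacement),
#'   `outcome`, `final_speed`, `t_end`.
#' @export
simulate_trajectory <- function(suspension, f, field, spin,
                                start = NULL, v_pp = NULL,
                                dt = 5e-3, t_max = 120,
                                trap_speed = 1e-7, trap_radius = NULL,
                                wash_periods = 5, record = 10L) {
  stopifnot(inherits(suspension, "suspension"),
            inherits(field, "field_map"),
            inherits(spin, "spin_condition"))
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  check_number(t_max, "t_max", min = 0, strict_min = TRUE)
  if (!is.null(v_pp)) field <- rescale_voltage(field, v_pp)

  geom <- field$geometry
  P <- geom$period
  H <- geom$channel_height
  r <- suspension$particle$radius
  drag <- 6 * pi * suspension$viscosity * r
  y_floor <- min(max(r, field$hy / 2), H / 2)
  h_cell <- min(field$hx, field$hy)
  if (is.null(trap_radius)) trap_radius <- 1.5 * field$hx
  if (is.null(start)) start <- c(geom$electrode_width + geom$gap / 2,
                                 y_floor + field$hy)
  if (start[2] < 0 || start[2] > H) stop_domain("start position outside domain")

  near_edge <- function(x, y) {
    if (length(field$edge_x) == 0) return(FALSE)
    dx <- abs(x - field$edge_x)
    dx <- pmin(dx, P - dx)
    any(sqrt(dx^2 + y^2) <= trap_radius + y_floor)
  }

  pos <- start
  t <- 0
  drift <- 0
  outcome <- "undecided"
  # Trap detection has two routes.  (1) Windowed speed: the time-averaged
  # position over successive windows; a particle settling onto the field
  # maximum has a vanishing mean drift even if the discrete map limit-cycles
  # around the attractor.  (2) Oscillation: near an edge the discrete map can
  # orbit the attractor at finite step speed; a path length far exceeding the
  # net displacement identifies that pinned state independently of the step
  # size (a drifting particle has path ~ net).
  window <- max(0.25, 10 * dt)
  win_t <- 0; win_sum <- c(0, 0); win_w <- 0
  prev_mean <- NULL
  speed_win <- Inf
  conf_count <- 0L; conf_path <- 0; conf_p0 <- pos
  conf_need <- 200L
  n_cap <- 500000L

  times <- numeric(0); xs <- numeric(0); ys <- numeric(0)
  step_i <- 0L
  while (t < t_max && step_i < n_cap) {
    step_i <- step_i + 1L
    if (step_i %% record == 1L || record == 1L) {
      times <- c(times, t); xs <- c(xs, pos[1] %% P); ys <- c(ys, pos[2])
    }
    F <- net_force(suspension, f, field, spin, c(pos[1] %% P, pos[2]))
    v <- F / drag
    sp <- sqrt(sum(v^2))
    dt_eff <- if (sp > 0) min(dt, 0.5 * h_cell / sp) else dt
    step_vec <- v * dt_eff
    if (sqrt(sum(step_vec^2)) > 10 * h_cell) {      # instability guard
      dt_eff <- dt_eff / 2
      step_vec <- v * dt_eff
      if (sqrt(sum(step_vec^2)) > 10 * h_cell)
        stop_domain("integration unstable: step exceeds 10 grid cells")
    }
    new <- pos + step_vec
    new[2] <- min(max(new[2], y_floor), H)
    drift <- drift + (new[1] - pos[1])
    pos <- new
    t <- t + dt_eff

    if (abs(drift) > wash_periods * P) { outcome <- "washed"; break }

    if (near_edge(pos[1] %% P, pos[2])) {
      conf_count <- conf_count + 1L
      conf_path <- conf_path + sqrt(sum(step_vec^2))
      if (conf_count >= conf_need) {
        conf_net <- sqrt(sum((pos - conf_p0)^2))
        if (conf_path > 10 * conf_net && conf_net <= 3 * h_cell &&
            conf_path > 0) {
          speed_win <- conf_net / max(t, dt)
          outcome <- "trapped"; break
        }
        conf_count <- 0L; conf_path <- 0; conf_p0 <- pos
      }
    } else {
      conf_count <- 0L; conf_path <- 0; conf_p0 <- pos
    }

    win_sum <- win_sum + pos * dt_eff; win_w <- win_w + dt_eff
    if (t - win_t >= window) {
      m <- win_sum / win_w
      if (!is.null(prev_mean)) {
        speed_win <- sqrt(sum((m - prev_mean)^2)) / window
        if (speed_win < trap_speed && near_edge(m[1] %% P, m[2])) {
          outcome <- "trapped"; break
        }
      }
      prev_mean <- m
      win_t <- t; win_sum <- c(0, 0); win_w <- 0
    }
  }
  times <- c(times, t); xs <- c(xs, pos[1] %% P); ys <- c(ys, pos[2])

  structure(list(times = times,
                 positions = cbind(x = xs, y = ys),
                 drift = drift, outcome = outcome,
                 final_speed = if (is.finite(speed_win)) speed_win else
                   sqrt(sum((net_force(suspension, f, field, spin,
                                       c(pos[1] %% P, pos[2])) / drag)^2)),
                 t_end = t, start = start,
                 v_pp = field$geometry$applied_v_pp, spin = spin),
            class = "dep_trajectory")
}

#' @export
print.dep_trajectory <- function(x, ...) {
  cat("Particle trajectory:", x$outcome, "after", signif(x$t_end, 4), "s\n")
  cat("  drive", si_format(x$v_pp, "Vpp"), " spin", x$spin$rpm, "RPM\n")
  cat("  lateral drift", si_format(x$drift, "m"),
      " final speed", si_format(x$final_speed, "m/s"), "\n")
  invisible(x)
}

#' @export
plot.dep_trajectory <- function(x, ...) {
  graphics::plot(x$positions[, "x"] * 1e6, x$positions[, "y"] * 1e6,
                 type = "p", pch = 16, cex = 0.4,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::points(x$positions[1, "x"] * 1e6, x$positions[1, "y"] * 1e6,
                   col = "forestgreen", pch = 17)
  n <- nrow(x$positions)
  graphics::points(x$positions[n, "x"] * 1e6, x$positions[n, "y"] * 1e6,
                   col = if (x$outcome == "trapped") "firebrick" else "grey40",
                   pch = 15)
  invisible(x)
}

#' Trap-versus-wash map over start positions
#'
#' Runs [simulate_trajectory()] from a lattice of start positions spanning
#' the unit cell and reports the per-start outcome and the fraction trapped.
#' This is the simulated counterpart of the spin-with-voltage versus
#' spin-without-voltage contrast: with no drive every dense particle washes
#' outward, while a sufficient drive holds particles at the electrode edges.
#'
#' @inheritParams simulate_trajectory
#' @param n_starts number of start positions (>= 4), arranged on a lattice.
#' @return An object of class `trapping_map`: data frame `starts` (x, y,
#'   outcome) and `fraction_trapped`.
#' @export
trapping_map <- function(suspension, f, field, spin, n_starts = 12,
                         v_pp = NULL, ...) {
  n_starts <- check_count(n_starts, "n_starts", min = 4L)
  if (!is.null(v_pp)) field <- rescale_voltage(field, v_pp)
  geom <- field$geometry
  nx_s <- max(2L, as.integer(ceiling(sqrt(n_starts))))
  ny_s <- max(2L, as.integer(ceiling(n_starts / nx_s)))
  xg <- seq(0.05, 0.95, length.out = nx_s) * geom$period
  yg <- seq(0.15, 0.75, length.out = ny_s) * geom$channel_height
  grid <- expand.grid(x = xg, y = yg)[seq_len(min(n_starts, nx_s * ny_s)), ]

  outcomes <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tr <- simulate_trajectory(suspension, f, field, spin,
                              start = c(grid$x[i], grid$y[i]), ...)
    outcomes[i] <- tr$outcome
  }
  structure(list(starts = data.frame(x = grid$x, y = grid$y,
                                     outcome = outcomes),
                 fraction_trapped = mean(outcomes == "trapped"),
                 v_pp = field$geometry$applied_v_pp, spin = spin, f = f),
            class = "trapping_map")
}

#' @export
print.trapping_map <- function(x, ...) {
  cat("Trapping map:", nrow(x$starts), "starts at",
      si_format(x$v_pp, "Vpp"), "/", x$spin$rpm, "RPM\n")
  print(table(x$starts$outcome))
  cat("  fraction trapped:", signif(x$fraction_trapped, 4), "\n")
  invisible(x)
}

#' Minimum holding voltage against the centrifugal wash
#'
#' Bisects the drive voltage for the trapped/washed transition of a reference
#' trajectory (started near an electrode edge).  The field is solved once and
#' rescaled by \eqn{V^2} per bisection step rather than re-solved.  The force
#' balance \eqn{F_{DEP} \propto V^2} against \eqn{F_c \propto \omega^2 R}
#' implies the holding voltage scales as \eqn{\sqrt{\omega^2 R}}.
#'
#' @inheritParams simulate_trajectory
#' @param v_cap largest voltage tried, in Vpp; if even `v_cap` does not trap
#'   (e.g. a negative-DEP particle over edge-maxima geometry), returns `Inf`.
#' @param tol relative bisection tolerance (default 2%).
#' @return smallest trapping voltage in Vpp, or `Inf`.
#' @export
minimum_holding_voltage <- function(suspension, f, field, spin,
                                    start = NULL, v_cap = 200, tol = 0.02,
                                    ...) {
  stopifnot(inherits(field, "field_map"))
  geom <- field$geometry
  if (is.null(start))
    start <- c(geom$electrode_width + 0.15 * geom$gap,
               max(suspension$particle$radius, field$hy / 2) + field$hy)
  trapped_at <- function(v) {
    tr <- simulate_trajectory(suspension, f, field, spin, start = start,
                              v_pp = v, ...)
    tr$outcome == "trapped"
  }
  if (!trapped_at(v_cap)) return(Inf)
  lo <- 0; hi <- v_cap
  while (hi - lo > tol * hi) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (trapped_at(mid)) hi <- mid else lo <- mid
  }
  hi
}
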