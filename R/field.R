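# Finite-difference Laplace solver for one periodic unit cell of the
# interdigitated electrode array.  Supplies |E|^2 and grad|E|^2, the field
# factors of the DEP force.

#' Unit-cell geometry of an interdigitated electrode array
#'
#' One period of the array cross-section: a +V/4 finger, a gap, a -V/4
#' finger, a gap (period `2 * (electrode_width + gap)`), with the sample
#' channel of height `channel_height` above.  The electrode potentials are
#' \eqn{\pm V_{pp}/4} so that the differential peak-to-peak voltage equals
#' `applied_v_pp`.  Copper height is retained for capacitance bookkeeping but
#' the field solve treats the fingers as flat equipotential segments on the
#' channel floor (valid for copper much thinner than the gap).
#'
#' @param electrode_width finger width in m.
#' @param gap inter-finger gap in m.
#' @param channel_height height of the liquid channel above the fingers in m.
#' @param copper_height copper thickness in m.
#' @param applied_v_pp peak-to-peak differential drive voltage in V.
#' @return An object of class `unit_cell_geometry`.
#' @export
unit_cell_geometry <- function(electrode_width = 75e-6, gap = 125e-6,
                               channel_height = 100e-6, copper_height = 35e-6,
                               applied_v_pp = 20) {
  check_number(electrode_width, "electrode_width", min = 0, strict_min = TRUE)
  check_number(gap, "gap", min = 0, strict_min = TRUE)
  check_number(channel_height, "channel_height", min = 0, strict_min = TRUE)
  check_number(copper_height, "copper_height", min = 0, strict_min = TRUE)
  check_number(applied_v_pp, "applied_v_pp", min = 0, strict_min = TRUE)
  structure(list(electrode_width = electrode_width, gap = gap,
                 channel_height = channel_height,
                 copper_height = copper_height,
                 applied_v_pp = applied_v_pp,
                 period = 2 * (electrode_width + gap)),
            class = "unit_cell_geometry")
}

#' @export
print.unit_cell_geometry <- function(x, ...) {
  cat("Electrode unit cell: width", si_format(x$electrode_width, "m"),
      " gap", si_format(x$gap, "m"),
      " period", si_format(x$period, "m"), "\n",
      " channel height", si_format(x$channel_height, "m"),
      " drive", si_format(x$applied_v_pp, "Vpp"), "\n")
  invisible(x)
}

#' Solve the electric field of one electrode unit cell
#'
#' Solves the Laplace equation \eqn{\nabla^2\phi = 0} on the 2D cross-section
#' of one unit cell by the 5-point finite-difference stencil with a direct
#' sparse factorisation: Dirichlet electrodes at \eqn{\pm V_{pp}/4} on the
#' floor, insulating (Neumann) gaps and top wall, periodic lateral
#' boundaries.  The field is obtained by central differences, then
#' \eqn{|E|^2} and its gradient by further central differences.  The medium
#' is treated as homogeneous: a uniform permittivity scales the energy but
#' not the shape of the Laplace solution.
#'
#' The discrete solution obeys the maximum principle (potential extrema on
#' the electrodes) and concentrates \eqn{|E|^2} at the finger edges, which is
#' the mechanism that collects positive-DEP particles there.  Note the field
#' at an electrode edge is singular (\eqn{|E| \sim r^{-1/2}} at the mixed
#' boundary corner), so nodal values adjacent to edges grow under grid
#' refinement; interior values converge.
#'
#' @param geom a [unit_cell_geometry()].
#' @param resolution number of nodes per period in x (>= 32).
#' @param layout `"interdigitated"` for the two-finger unit cell, or
#'   `"parallel_plate"` for the degenerate validation case (full-width
#'   electrode at \eqn{+V_{pp}/4} on the floor, grounded top plate), whose
#'   interior field is the uniform analytic \eqn{V/g}.
#' @param swap_polarity logical; exchange the two fingers' polarities
#'   (\eqn{\phi \to -\phi}; `e_sq` is unchanged).
#' @param residual_tol maximum admissible relative residual of the linear
#'   solve.
#' @return An object of class `field_map`: node coordinates `x` (length nx,
#'   periodic, excludes the duplicate at the period) and `y` (length ny),
#'   matrices `phi`, `e_sq`, `ge_x`, `ge_y` (nx by ny), grid spacings, the
#'   electrode edge x-positions `edge_x`, and the geometry.
#' @export
solve_unit_cell <- function(geom, resolution = 128,
                            layout = c("interdigitated", "parallel_plate"),
                            swap_polarity = FALSE, residual_tol = 1e-8) {
  stopifnot(inherits(geom, "unit_cell_geometry"))
  layout <- match.arg(layout)
  resolution <- check_count(resolution, "resolution", min = 32L)

  P <- geom$period
  H <- geom$channel_height
  nx <- resolution
  hx <- P / nx
  ny <- max(8L, as.integer(round(H / hx)) + 1L)
  hy <- H / (ny - 1)
  x <- (seq_len(nx) - 1L) * hx
  y <- (seq_len(ny) - 1L) * hy
  v0 <- geom$applied_v_pp / 4 * (if (swap_polarity) -1 else 1)
  w <- geom$electrode_width
  g <- geom$gap

  # Dirichlet mask and values on the full grid
  dir_val <- matrix(NA_real_, nx, ny)
  if (layout == "parallel_plate") {
    dir_val[, 1] <- v0
    dir_val[, ny] <- 0
  } else {
    on_a <- x <= w + 1e-9 * P                     # finger at +V/4: [0, w]
    on_b <- x >= (w + g) - 1e-9 * P & x <= (2 * w + g) + 1e-9 * P
    dir_val[on_a, 1] <- v0
    dir_val[on_b, 1] <- -v0
  }
  is_dir <- !is.na(dir_val)

  idx <- matrix(0L, nx, ny)                        # unknown numbering
  idx[!is_dir] <- seq_len(sum(!is_dir))
  n_unk <- sum(!is_dir)
  if (n_unk == 0L) stop_domain("no unknown nodes: grid fully constrained")

  ax2 <- 1 / hx^2; ay2 <- 1 / hy^2
  ii <- jj <- integer(0); vv <- numeric(0)
  rhs <- numeric(n_unk)
  # build COO triplets column-wise; vectorised over the grid
  trip_i <- vector("list", ny); trip_j <- vector("list", ny)
  trip_v <- vector("list", ny)
  for (j in seq_len(ny)) {
    unk <- which(!is_dir[, j])
    if (length(unk) == 0L) next
    rows <- idx[unk, j]
    ti <- tj <- integer(0); tv <- numeric(0)
    add <- function(nb_i, nb_j, coef) {
      # neighbour contribution: unknown -> matrix entry, Dirichlet -> RHS
      nb_dir <- is_dir[cbind(nb_i, nb_j)]
      if (any(!nb_dir)) {
        ti <<- c(ti, rows[!nb_dir])
        tj <<- c(tj, idx[cbind(nb_i[!nb_dir], nb_j[!nb_dir])])
        tv <<- c(tv, rep(coef, sum(!nb_dir)))
      }
      if (any(nb_dir))
        rhs[rows[nb_dir]] <<- rhs[rows[nb_dir]] -
          coef * dir_val[cbind(nb_i[nb_dir], nb_j[nb_dir])]
    }
    east <- unk %% nx + 1L
    west <- (unk - 2L) %% nx + 1L
    add(east, rep(j, length(unk)), ax2)
    add(west, rep(j, length(unk)), ax2)
    diag_c <- rep(-2 * ax2, length(unk))
    if (j == 1L) {                 # insulating floor (gap nodes): ghost mirror
      add(unk, rep(2L, length(unk)), 2 * ay2)
      diag_c <- diag_c - 2 * ay2
    } else if (j == ny) {          # insulating top wall
      add(unk, rep(ny - 1L, length(unk)), 2 * ay2)
      diag_c <- diag_c - 2 * ay2
    } else {
      add(unk, rep(j - 1L, length(unk)), ay2)
      add(unk, rep(j + 1L, length(unk)), ay2)
      diag_c <- diag_c - 2 * ay2
    }
    ti <- c(ti, rows); tj <- c(tj, rows); tv <- c(tv, diag_c)
    trip_i[[j]] <- ti; trip_j[[j]] <- tj; trip_v[[j]] <- tv
  }
  ii <- unlist(trip_i); jj <- unlist(trip_j); vv <- unlist(trip_v)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n_unk, n_unk))
  sol <- as.numeric(Matrix::solve(A, rhs))

  res <- as.numeric(A %*% sol - rhs)
  rel_res <- sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)
  if (!is.finite(rel_res) || rel_res > residual_tol)
    stop_domain("field solve did not reach the residual tolerance: ",
                "relative residual ", format(rel_res))

  phi <- dir_val
  phi[!is_dir] <- sol

  # E = -grad(phi): periodic central differences in x, one-sided at walls
  roll <- function(m, s) m[(seq_len(nx) - 1L + s) %% nx + 1L, , drop = FALSE]
  ex <- -(roll(phi, 1L) - roll(phi, -1L)) / (2 * hx)
  ey <- matrix(0, nx, ny)
  ey[, 2:(ny - 1)] <- -(phi[, 3:ny] - phi[, 1:(ny - 2)]) / (2 * hy)
  ey[, 1] <- -(phi[, 2] - phi[, 1]) / hy
  ey[, ny] <- -(phi[, ny] - phi[, ny - 1]) / hy
  e_sq <- ex^2 + ey^2

  ge_x <- (roll(e_sq, 1L) - roll(e_sq, -1L)) / (2 * hx)
  ge_y <- matrix(0, nx, ny)
  ge_y[, 2:(ny - 1)] <- (e_sq[, 3:ny] - e_sq[, 1:(ny - 2)]) / (2 * hy)
  ge_y[, 1] <- (e_sq[, 2] - e_sq[, 1]) / hy
  ge_y[, ny] <- (e_sq[, ny] - e_sq[, ny - 1]) / hy

  edge_x <- if (layout == "parallel_plate") numeric(0) else
    c(0, w, w + g, 2 * w + g, P)

  structure(list(x = x, y = y, hx = hx, hy = hy,
                 phi = phi, e_sq = e_sq, ge_x = ge_x, ge_y = ge_y,
                 edge_x = edge_x, layout = layout, geometry = geom,
                 residual = rel_res),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("Field map (", x$layout, "): ", length(x$x), " x ", length(x$y),
      " nodes, spacing ", si_format(x$hx, "m"), "\n", sep = "")
  cat("  max |E| =", si_format(sqrt(max(x$e_sq)), "V/m"),
      " residual =", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.field_map <- function(x, ...) {
  graphics::image(x$x * 1e6, x$y * 1e6, log10(pmax(x$e_sq, max(x$e_sq) * 1e-8)),
                  xlab = "x (um)", ylab = "y (um)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  if (length(x$edge_x))
    graphics::abline(v = x$edge_x * 1e6, col = "white", lty = 3)
  invisible(x)
}

#' As-data-frame export of a field map
#'
#' Long-format table with one row per node: `x_m`, `y_m`, `phi_v`, `e_sq`,
#' `ge_x`, `ge_y`.
#' @param x a `field_map`.
#' @param ... unused.
#' @export
as.data.frame.field_map <- function(x, ...) {
  nx <- length(x$x); ny <- length(x$y)
  data.frame(x_m = rep(x$x, ny), y_m = rep(x$y, each = nx),
             phi_v = as.vector(x$phi), e_sq = as.vector(x$e_sq),
             ge_x = as.vector(x$ge_x), ge_y = as.vector(x$ge_y))
}

#' Interpolate field quantities at a point
#'
#' Bilinear interpolation of \eqn{|E|^2} and \eqn{\nabla|E|^2} at an
#' arbitrary point of the solved domain; exact at grid nodes.  `x` wraps
#' periodically across the unit cell; `y` must lie inside `[0, H]`.
#'
#' @param map a `field_map` from [solve_unit_cell()].
#' @param x,y query point coordinates in m.
#' @return list with `e_sq` (scalar) and `grad_e_sq` (length-2 vector).
#' @export
field_at <- function(map, x, y) {
  stopifnot(inherits(map, "field_map"))
  P <- map$geometry$period
  H <- map$geometry$channel_height
  if (!is.finite(x) || !is.finite(y) || y < -1e-12 || y > H + 1e-12)
    stop_domain("query point outside the solved domain (y in [0, ",
                format(H), "])")
  y <- min(max(y, 0), H)
  x <- x %% P
  nx <- length(map$x); ny <- length(map$y)
  fx <- x / map$hx
  i0 <- floor(fx); tx <- fx - i0
  if (tx > 1 - 1e-9) { i0 <- i0 + 1; tx <- 0 }    # snap to the nearest node
  if (tx < 1e-9) tx <- 0
  i0 <- as.integer(i0) %% nx; i1 <- (i0 + 1L) %% nx
  fy <- y / map$hy
  j0 <- floor(fy); ty <- fy - j0
  if (ty > 1 - 1e-9) { j0 <- j0 + 1; ty <- 0 }
  if (ty < 1e-9) ty <- 0
  if (j0 > ny - 2L) { j0 <- ny - 2L; ty <- 1 }    # top wall node
  j0 <- max(as.integer(j0), 0L); j1 <- j0 + 1L

  blend <- function(m) {
    (1 - tx) * (1 - ty) * m[i0 + 1L, j0 + 1L] +
      tx * (1 - ty) * m[i1 + 1L, j0 + 1L] +
      (1 - tx) * ty * m[i0 + 1L, j1 + 1L] +
      tx * ty * m[i1 + 1L, j1 + 1L]
  }
  list(e_sq = blend(map$e_sq),
       grad_e_sq = c(blend(map$ge_x), blend(map$ge_y)))
}
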