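# 2D convection-diffusion-reaction companion model: thrombin loading into,
# and elution from, a porous fibrin zone in a rectangular flow channel.
#
# Discretization: cell-centred finite volumes on a uniform grid (x downstream
# from the inlet, y up from the bottom wall); velocities on faces (staggered/
# MAC layout). Steady Stokes-Brinkman flow is solved once by a direct sparse
# solve; transport uses backward-Euler steps with upwind advection and
# harmonic-mean central diffusion, operator-split with an implicit per-cell
# solve of the stiff two-site binding kinetics.

#' Flow-channel geometry with an embedded clot zone
#'
#' @param length,height Channel dimensions (um).
#' @param clot_length,clot_height Clot (porous fibrin zone) dimensions (um).
#' @param clot_x0 Distance of the clot's leading edge from the inlet (um).
#' @param nx,ny Number of grid cells in x and y. Grids whose spacings divide
#'   the clot edges exactly are recommended so refinement studies compare
#'   identical clot masks; a message is emitted if the clot is resolved by
#'   fewer than 10 vertical cells.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(length = 1000, height = 60,
                             clot_length = 250, clot_height = 15,
                             clot_x0 = 150, nx = 40, ny = 40) {
  if (clot_x0 <= 0 || clot_x0 + clot_length >= length || clot_height >= height)
    stop("channel_geometry: clot zone must lie strictly inside the channel",
         call. = FALSE)
  dx <- length / nx; dy <- height / ny
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  clot_cols <- which(xc > clot_x0 & xc < clot_x0 + clot_length)
  clot_rows <- which(yc < clot_height)
  if (length(clot_rows) < 10)
    message(sprintf("channel_geometry: clot resolved by %d vertical cells",
                    length(clot_rows)))
  g <- list(length = length, height = height,
            clot_length = clot_length, clot_height = clot_height,
            clot_x0 = clot_x0, nx = nx, ny = ny, dx = dx, dy = dy,
            xc = xc, yc = yc, clot_cols = clot_cols, clot_rows = clot_rows)
  g$clot_mask <- matrix(FALSE, nx, ny)
  g$clot_mask[clot_cols, clot_rows] <- TRUE
  class(g) <- "channel_geometry"
  g
}

#' Transport and material parameters for the channel model
#'
#' @param D_free Thrombin diffusivity in free solution (um^2/s); default 60
#'   (Stokes-Einstein scale for a ~36 kDa protein).
#' @param D_clot Effective diffusivity inside the fibrin zone (um^2/s);
#'   default 15 (porosity/tortuosity factor 0.25 on `D_free`).
#' @param permeability Clot Darcy permeability (um^2).
#' @param porosity Clot porosity (used for documentation/derived quantities).
#' @param shear_rate Clean-channel wall shear rate at the inlet (s^-1).
#' @param sites Thrombin-fibrin binding site table
#'   (see [default_parameters()]).
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D_free = 60, D_clot = 15, permeability = 1e-3,
                             porosity = 0.5, shear_rate = 200,
                             sites = default_parameters()$sites) {
  if (D_free <= 0 || D_clot <= 0)
    stop("transport_params: diffusivities must be positive", call. = FALSE)
  if (shear_rate <= 0)
    stop("transport_params: shear_rate must be positive", call. = FALSE)
  if (permeability <= 0)
    stop("transport_params: permeability must be positive", call. = FALSE)
  structure(list(D_free = D_free, D_clot = D_clot,
                 permeability = permeability, porosity = porosity,
                 shear_rate = shear_rate, sites = sites),
            class = "transport_params")
}

#' Steady Stokes-Brinkman velocity field
#'
#' Solves creeping incompressible flow on the staggered grid: Stokes flow in
#' the open channel and Brinkman drag (viscosity over permeability) inside
#' the clot zone. The inlet carries the fully developed parabolic profile
#' scaled to the requested clean-channel wall shear rate; walls are no-slip;
#' the outlet is an open boundary at zero reference pressure.
#'
#' @param geom A [channel_geometry()].
#' @param tp A [transport_params()].
#' @return List of class `pde_velocity` with face velocities `u`
#'   (`(nx+1) x ny`) and `v` (`nx x (ny+1)`) in um/s, cell pressures `p`,
#'   and `div_max`, the largest cellwise divergence relative to the inlet
#'   shear rate.
#' @export
solve_velocity <- function(geom, tp) {
  nx <- geom$nx; ny <- geom$ny; dx <- geom$dx; dy <- geom$dy
  H <- geom$height
  mu <- 1
  invK <- matrix(0, nx, ny)
  invK[geom$clot_mask] <- 1 / tp$permeability
  Nu <- (nx + 1) * ny; Nv <- nx * (ny + 1); Np <- nx * ny
  iu <- function(i, j) (j - 1) * (nx + 1) + i + 1          # i in 0..nx
  iv <- function(i, j) Nu + j * nx + i                      # j in 0..ny
  ip <- function(i, j) Nu + Nv + (j - 1) * nx + i
  N <- Nu + Nv + Np
  nmax <- 12L * N
  II <- integer(nmax); JJ <- integer(nmax); XX <- numeric(nmax)
  B <- numeric(N)
  kk <- 0L
  add <- function(r, c, x) {
    kk <<- kk + 1L; II[kk] <<- r; JJ[kk] <<- c; XX[kk] <<- x
  }
  u_in <- tp$shear_rate * geom$yc * (1 - geom$yc / H)

  # -- u faces ---------------------------------------------------------
  for (j in seq_len(ny)) {
    r <- iu(0, j); add(r, r, 1); B[r] <- u_in[j]            # inlet Dirichlet
    for (i in seq_len(nx)) {
      r <- iu(i, j)
      ikl <- invK[i, j]
      ikr <- if (i < nx) invK[min(i + 1, nx), j] else invK[nx, j]
      diag_coef <- -2 * mu / dx^2 - 2 * mu / dy^2 - mu * (ikl + ikr) / 2
      add(r, iu(i - 1, j), mu / dx^2)
      if (i < nx) add(r, iu(i + 1, j), mu / dx^2)
      else diag_coef <- diag_coef + mu / dx^2               # du/dx = 0 ghost
      if (j > 1) add(r, iu(i, j - 1), mu / dy^2)
      else diag_coef <- diag_coef - mu / dy^2               # no-slip ghost
      if (j < ny) add(r, iu(i, j + 1), mu / dy^2)
      else diag_coef <- diag_coef - mu / dy^2
      add(r, r, diag_coef)
      add(r, ip(i, j), 1 / dx)                              # +p_i/dx
      if (i < nx) add(r, ip(i + 1, j), -1 / dx)             # outlet ghost p=0
    }
  }
  # -- v faces ---------------------------------------------------------
  for (i in seq_len(nx)) {
    r <- iv(i, 0); add(r, r, 1)                             # walls: v = 0
    r <- iv(i, ny); add(r, r, 1)
  }
  for (j in seq_len(ny - 1)) for (i in seq_len(nx)) {
    r <- iv(i, j)
    diag_coef <- -2 * mu / dx^2 - 2 * mu / dy^2 -
      mu * (invK[i, j] + invK[i, j + 1]) / 2
    if (i > 1) add(r, iv(i - 1, j), mu / dx^2)
    else diag_coef <- diag_coef - mu / dx^2                 # inlet: v = 0 ghost
    if (i < nx) add(r, iv(i + 1, j), mu / dx^2)
    else diag_coef <- diag_coef + mu / dx^2                 # outlet: dv/dx = 0
    add(r, iv(i, j - 1), mu / dy^2)
    add(r, iv(i, j + 1), mu / dy^2)
    add(r, r, diag_coef)
    add(r, ip(i, j), 1 / dy)
    add(r, ip(i, j + 1), -1 / dy)
  }
  # -- continuity ------------------------------------------------------
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    r <- ip(i, j)
    add(r, iu(i, j), 1 / dx); add(r, iu(i - 1, j), -1 / dx)
    add(r, iv(i, j), 1 / dy); add(r, iv(i, j - 1), -1 / dy)
  }
  A <- Matrix::sparseMatrix(i = II[seq_len(kk)], j = JJ[seq_len(kk)],
                            x = XX[seq_len(kk)], dims = c(N, N))
  sol <- tryCatch(as.numeric(Matrix::solve(A, B)),
                  error = function(e)
                    stop(sprintf("solve_velocity: sparse solve failed (%s)",
                                 conditionMessage(e)), call. = FALSE))
  u <- matrix(sol[seq_len(Nu)], nx + 1, ny)                 # rows i = 0..nx
  v <- matrix(sol[Nu + seq_len(Nv)], nx, ny + 1)            # cols j = 0..ny
  p <- matrix(sol[Nu + Nv + seq_len(Np)], nx, ny)
  div <- (u[-1, , drop = FALSE] - u[-(nx + 1), , drop = FALSE]) / dx +
    (v[, -1, drop = FALSE] - v[, -(ny + 1), drop = FALSE]) / dy
  structure(list(u = u, v = v, p = p,
                 div_max = max(abs(div)) / tp$shear_rate),
            class = "pde_velocity")
}

# Sparse transport operator L such that dc/dt = L c + sources, for upwind
# advection plus harmonic-mean central diffusion. `closed = TRUE` drops all
# boundary exchange (sealed box; used by conservation audits). Face layout:
# u[i+1, j] is the face between cells (i, j) and (i+1, j) (u[1, ] inlet,
# u[nx+1, ] outlet); v[i, j+1] is the face between (i, j) and (i, j+1)
# (v[, 1] bottom wall, v[, ny+1] top wall).
transport_operator <- function(geom, tp, vel, closed = FALSE) {
  nx <- geom$nx; ny <- geom$ny; dx <- geom$dx; dy <- geom$dy
  Dcell <- matrix(tp$D_free, nx, ny)
  Dcell[geom$clot_mask] <- tp$D_clot
  id <- function(i, j) (j - 1) * nx + i
  u <- vel$u; v <- vel$v
  if (closed) { u[] <- 0; v[] <- 0 }
  hmean <- function(a, b) 2 * a * b / (a + b)
  nmax <- 14L * nx * ny
  II <- integer(nmax); JJ <- integer(nmax); XX <- numeric(nmax)
  k <- 0L
  add <- function(r, c, x) {
    k <<- k + 1L; II[k] <<- r; JJ[k] <<- c; XX[k] <<- x
  }
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    r <- id(i, j)
    # east face
    uf <- u[i + 1, j]
    if (i < nx) {
      Df <- hmean(Dcell[i, j], Dcell[i + 1, j])
      add(r, r, -Df / dx^2); add(r, id(i + 1, j), Df / dx^2)
      if (uf >= 0) add(r, r, -uf / dx) else add(r, id(i + 1, j), -uf / dx)
    } else if (!closed && uf >= 0) {
      add(r, r, -uf / dx)              # advective outflow; no outlet diffusion
    }
    # west face
    uf <- u[i, j]
    if (i > 1) {
      Df <- hmean(Dcell[i - 1, j], Dcell[i, j])
      add(r, r, -Df / dx^2); add(r, id(i - 1, j), Df / dx^2)
      if (uf >= 0) add(r, id(i - 1, j), uf / dx) else add(r, r, uf / dx)
    } else if (!closed && uf < 0) {
      add(r, r, uf / dx)               # backflow out through the inlet
    }                                  # inflow carries c = 0
    # north face (wall at j = ny: v = 0, zero-flux)
    if (j < ny) {
      vf <- v[i, j + 1]
      Df <- hmean(Dcell[i, j], Dcell[i, j + 1])
      add(r, r, -Df / dy^2); add(r, id(i, j + 1), Df / dy^2)
      if (vf >= 0) add(r, r, -vf / dy) else add(r, id(i, j + 1), -vf / dy)
    }
    # south face (wall at j = 1: v = 0, zero-flux; influx enters as a source)
    if (j > 1) {
      vf <- v[i, j]
      Df <- hmean(Dcell[i, j - 1], Dcell[i, j])
      add(r, r, -Df / dy^2); add(r, id(i, j - 1), Df / dy^2)
      if (vf >= 0) add(r, id(i, j - 1), vf / dy) else add(r, r, vf / dy)
    }
  }
  Matrix::sparseMatrix(i = II[seq_len(k)], j = JJ[seq_len(k)],
                       x = XX[seq_len(k)], dims = c(nx * ny, nx * ny))
}

# Implicit (backward-Euler) update of the two-site binding kinetics in every
# clot cell, conserving local total thrombin exactly. Given end-of-step free
# concentration c, the bound pools follow in closed form from their own
# backward-Euler updates; the scalar conservation equation per cell is solved
# by a vectorized, bracketed Newton iteration (the residual is monotone).
binding_step <- function(c, es, gs, theta_E, theta_G, sites, dt) {
  kfE <- sites$kf[sites$name == "E"];     krE <- sites$kr[sites$name == "E"]
  kfG <- sites$kf[sites$name == "gamma"]; krG <- sites$kr[sites$name == "gamma"]
  M <- c + es + gs
  esf <- function(cc) (es + dt * kfE * cc * theta_E) / (1 + dt * (kfE * cc + krE))
  gsf <- function(cc) (gs + dt * kfG * cc * theta_G) / (1 + dt * (kfG * cc + krG))
  x <- pmin(pmax(c, 0), M)
  for (iter in 1:60) {
    esx <- esf(x); gsx <- gsf(x)
    f <- x + esx + gsx - M
    desx <- dt * kfE * (theta_E * (1 + dt * krE) - es) /
      (1 + dt * (kfE * x + krE))^2
    dgsx <- dt * kfG * (theta_G * (1 + dt * krG) - gs) /
      (1 + dt * (kfG * x + krG))^2
    step <- f / (1 + desx + dgsx)
    x <- pmin(pmax(x - step, 0), M)
    if (max(abs(f)) < 1e-13 * max(max(M), 1)) break
  }
  es_new <- esf(x); gs_new <- gsf(x)
  list(c = M - es_new - gs_new, es = es_new, gs = gs_new)
}

as_time_fun <- function(x, what) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(function(t) rep(x, length(t)))
  if (is.data.frame(x) && ncol(x) >= 2)
    return(stats::approxfun(x[[1]], x[[2]], rule = 2))
  stop(sprintf("%s must be a function, a constant, or a (time, value) frame",
               what), call. = FALSE)
}

new_pde_field <- function(geom, tp, vel, c, es, gs, time, fibrin,
                          budget = c(influx = 0, efflux = 0)) {
  structure(list(geom = geom, tp = tp, vel = vel, c = c, es = es, gs = gs,
                 time = time, fibrin = fibrin, budget = budget),
            class = "pde_field")
}

#' @export
print.pde_field <- function(x, ...) {
  cl <- x$geom$clot_mask
  cat(sprintf(
    "pde_field at t = %g s (%d x %d cells): clot-avg free %.4g uM, total %.4g uM\n",
    x$time, x$geom$nx, x$geom$ny, mean(x$c[cl]),
    mean(x$c[cl] + x$es[cl] + x$gs[cl])))
  invisible(x)
}

field_stored <- function(f) sum(f$c + f$es + f$gs) * f$geom$dx * f$geom$dy

clot_averages <- function(f) {
  cl <- f$geom$clot_mask
  c(free = mean(f$c[cl]), bound_E = mean(f$es[cl]),
    bound_gamma = mean(f$gs[cl]),
    total = mean(f$c[cl] + f$es[cl] + f$gs[cl]))
}

# Core time-stepping loop shared by loading and elution. J_fun gives the
# bottom-boundary thrombin flux (uM*um/s) applied along the clot footprint;
# fibrin_fun the uniform clot fibrin concentration (uM).
pde_advance <- function(field, J_fun, fibrin_fun, t_end, dt,
                        record_every = 10L, closed = FALSE) {
  geom <- field$geom; tp <- field$tp
  nx <- geom$nx; ny <- geom$ny; dx <- geom$dx; dy <- geom$dy
  L <- transport_operator(geom, tp, field$vel, closed = closed)
  Np <- nx * ny
  A <- Matrix::Diagonal(Np) - dt * L
  LU <- Matrix::lu(A)
  # outlet advective efflux row-sums, evaluated on end-of-step fields so the
  # discrete budget closes exactly with the implicit update
  u_out <- field$vel$u[nx + 1, ]
  if (closed) u_out <- rep(0, ny)
  out_idx <- (seq_len(ny) - 1L) * nx + nx
  u_in <- field$vel$u[1, ]
  in_idx <- (seq_len(ny) - 1L) * nx + 1L
  cvec <- as.numeric(field$c); es <- field$es; gs <- field$gs
  cl_cols <- geom$clot_cols; cl_mask <- geom$clot_mask
  spm <- field$tp$sites$sites_per_monomer
  nE <- spm[field$tp$sites$name == "E"]
  nG <- spm[field$tp$sites$name == "gamma"]
  nsteps <- max(1L, ceiling((t_end - field$time) / dt))
  times <- field$time + dt * seq_len(nsteps)
  rec_i <- unique(c(seq(0L, nsteps, by = record_every), nsteps))
  series <- matrix(NA_real_, length(rec_i), 8,
                   dimnames = list(NULL, c("time", "free", "bound_E",
                                           "bound_gamma", "total", "influx",
                                           "efflux", "stored")))
  influx <- field$budget[["influx"]]; efflux <- field$budget[["efflux"]]
  rec_row <- 1L
  record <- function(tnow) {
    f <- list(c = matrix(cvec, nx, ny), es = es, gs = gs, geom = geom)
    cl <- cl_mask
    series[rec_row, ] <<- c(tnow, mean(f$c[cl]), mean(es[cl]), mean(gs[cl]),
                            mean(f$c[cl] + es[cl] + gs[cl]), influx, efflux,
                            sum(f$c + es + gs) * dx * dy)
    rec_row <<- rec_row + 1L
  }
  record(field$time)
  src <- numeric(Np)
  bottom_idx <- cl_cols                      # (j = 1) row-major ids = i
  for (n in seq_len(nsteps)) {
    tnow <- times[n]
    # transport (backward Euler): (I - dt L) c_new = c_old + dt * src
    Jn <- J_fun(tnow)
    src[] <- 0
    src[bottom_idx] <- Jn / dy
    cvec <- as.numeric(Matrix::solve(LU, cvec + dt * src))
    influx <- influx + Jn * dx * length(bottom_idx) * dt  # uM*um^2 per um width
    efflux <- efflux + dt * sum(pmax(u_out, 0) * cvec[out_idx] * dy) +
      dt * sum(pmax(-u_in, 0) * cvec[in_idx] * dy)
    # binding (implicit, clot cells only)
    fib <- fibrin_fun(tnow)
    cmat <- matrix(cvec, nx, ny)
    idx <- which(cl_mask)
    bs <- binding_step(cmat[idx], es[idx], gs[idx],
                       theta_E = nE * fib, theta_G = nG * fib,
                       sites = tp$sites, dt = dt)
    cmat[idx] <- bs$c; es[idx] <- bs$es; gs[idx] <- bs$gs
    cvec <- as.numeric(cmat)
    if (n %in% rec_i) record(tnow)
  }
  field$c <- matrix(cvec, nx, ny); field$es <- es; field$gs <- gs
  field$time <- times[nsteps]
  field$fibrin <- fibrin_fun(field$time)
  field$budget <- c(influx = influx, efflux = efflux)
  list(field = field, series = as.data.frame(series))
}

#' Thrombin loading of the clot zone
#'
#' Integrates the transport equations (advection-diffusion of free thrombin
#' coupled to per-cell two-site binding kinetics, sites only inside the clot
#' zone) with a thrombin flux applied along the clot's bottom boundary and a
#' time-varying uniform fibrin concentration in the clot.
#'
#' @param geom A [channel_geometry()].
#' @param tp A [transport_params()].
#' @param J Bottom-wall thrombin flux (uM*um/s): a function of time, a
#'   constant, or a `(time, value)` data.frame.
#' @param fibrin Clot fibrin concentration (uM): same accepted forms.
#' @param t_end Loading duration (s).
#' @param dt Backward-Euler step (s).
#' @param vel Optional precomputed [solve_velocity()] result.
#' @param record_every Record clot averages every this many steps.
#' @param closed Seal the domain (zero velocity, no boundary exchange);
#'   used for conservation audits.
#' @return An object of class `pde_history`: list with the final `field`
#'   (class `pde_field`), a `series` data.frame of clot-averaged free/bound/
#'   total thrombin (uM) and the running budget (influx/efflux/stored,
#'   uM*um^2 per um of channel width).
#' @export
run_loading <- function(geom, tp, J, fibrin, t_end = 800, dt = 0.1,
                        vel = NULL, record_every = 10L, closed = FALSE) {
  if (t_end <= 0 || dt <= 0)
    stop("run_loading: t_end and dt must be positive", call. = FALSE)
  if (is.null(vel)) vel <- solve_velocity(geom, tp)
  J_fun <- as_time_fun(J, "J")
  fibrin_fun <- as_time_fun(fibrin, "fibrin")
  z <- matrix(0, geom$nx, geom$ny)
  field <- new_pde_field(geom, tp, vel, z, z, z, time = 0,
                         fibrin = fibrin_fun(0))
  out <- pde_advance(field, J_fun, fibrin_fun, t_end, dt,
                     record_every = record_every, closed = closed)
  structure(list(field = out$field, series = out$series),
            class = "pde_history")
}

#' Elution of thrombin from a loaded clot
#'
#' Continues a transport simulation with the bottom-wall flux set to zero and
#' fibrin frozen at its current value, following the clot-averaged total
#' thrombin and reporting its apparent half-life (via [elution_halflife()]).
#'
#' @param state A `pde_field` (e.g. `run_loading(...)$field`) or a
#'   `pde_history` whose final field is used.
#' @param t_end Absolute end time of the elution phase (s).
#' @param dt Backward-Euler step (s); elution dynamics are slow, so a larger
#'   step than during loading is appropriate.
#' @param record_every Record clot averages every this many steps.
#' @return A `pde_history` with an additional `halflife` element: the time
#'   (s, measured from the start of elution) at which clot-averaged total
#'   thrombin halves, or `NA` if not reached in the window.
#' @export
run_elution <- function(state, t_end, dt = 0.5, record_every = 10L) {
  field <- if (inherits(state, "pde_history")) state$field else state
  stopifnot(inherits(field, "pde_field"))
  if (t_end <= field$time)
    stop("run_elution: t_end must exceed the state's current time", call. = FALSE)
  out <- pde_advance(field, J_fun = function(t) 0,
                     fibrin_fun = function(t) field$fibrin,
                     t_end = t_end, dt = dt, record_every = record_every)
  hl <- elution_halflife(out$series$time - out$series$time[1],
                         out$series$total)
  structure(list(field = out$field, series = out$series, halflife = hl),
            class = "pde_history")
}

#' @export
print.pde_history <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("pde_history: %d records, t in [%g, %g] s\n",
              n, x$series$time[1], x$series$time[n]))
  cat(sprintf("  clot-avg total thrombin: %.4g uM; budget closure %.3g%%\n",
              x$series$total[n], 100 * budget_closure(x)))
  if (!is.null(x$halflife))
    cat(sprintf("  apparent elution half-life: %s s\n",
                format(unclass(x$halflife))))
  invisible(x)
}

#' Clot-averaged concentration series
#'
#' Volume-weighted means of free, E-bound, gamma'-bound and total thrombin
#' over the clot zone, with the running mass budget.
#'
#' @param history A `pde_history`.
#' @return data.frame with columns `time`, `free`, `bound_E`, `bound_gamma`,
#'   `total` (uM), `influx`, `efflux`, `stored` (uM*um^2 per um width).
#' @export
spatial_averages <- function(history) {
  stopifnot(inherits(history, "pde_history"))
  history$series
}

#' Relative mass-budget closure error
#'
#' `(stored - influx + efflux) / max(influx, stored)` at the final record;
#' zero for a perfectly conservative run.
#'
#' @param history A `pde_history`.
#' @return Signed relative closure error.
#' @export
budget_closure <- function(history) {
  s <- history$series[nrow(history$series), ]
  denom <- max(s$influx, s$stored, .Machine$double.eps)
  (s$stored - (s$influx - s$efflux)) / denom
}

#' Build an equilibrated pre-loaded clot state
#'
#' Constructs a `pde_field` whose clot zone carries a uniform total thrombin
#' concentration partitioned between free and the two bound pools at binding
#' equilibrium (via [equilibrium_free_fraction()]), with zero thrombin
#' elsewhere. Useful as a controlled initial condition for elution studies.
#'
#' @param geom A [channel_geometry()].
#' @param tp A [transport_params()].
#' @param fibrin Clot fibrin concentration (uM).
#' @param total Total thrombin in the clot (uM).
#' @param vel Optional precomputed velocity field.
#' @return A `pde_field` at time 0 with budget influx preset to the stored
#'   amount (so budgets in a following [run_elution()] close).
#' @export
equilibrate_clot_state <- function(geom, tp, fibrin, total, vel = NULL) {
  if (is.null(vel)) vel <- solve_velocity(geom, tp)
  s <- tp$sites
  ff <- equilibrium_free_fraction(total, fibrin, s)
  cfree <- ff * total
  thE <- s$sites_per_monomer[s$name == "E"] * fibrin
  thG <- s$sites_per_monomer[s$name == "gamma"] * fibrin
  esb <- thE * cfree / (s$Kd[s$name == "E"] + cfree)
  gsb <- thG * cfree / (s$Kd[s$name == "gamma"] + cfree)
  z <- matrix(0, geom$nx, geom$ny)
  cm <- z; em <- z; gm <- z
  cm[geom$clot_mask] <- cfree; em[geom$clot_mask] <- esb
  gm[geom$clot_mask] <- gsb
  f <- new_pde_field(geom, tp, vel, cm, em, gm, time = 0, fibrin = fibrin)
  f$budget <- c(influx = field_stored(f), efflux = 0)
  f
}
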