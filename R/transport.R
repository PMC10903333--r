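#' Simulate osmotic cell volume trajectories
#'
#' Integrates the two-parameter membrane transport model with a regulatory
#' leak for one or many cells simultaneously. Per cell the normalized state is
#' water `w`, non-permeating content `n` and permeating solute `s` (all 1 or 0
#' at the isosmotic baseline), with
#' \deqn{M_i = M_0 (n + s) / w}
#' \deqn{dw/dt = k_w (M_i - M_e - S_e) / M_0}
#' \deqn{ds/dt = k_s (S_e - M_0 s / w) / M_0}
#' \deqn{dn/dt = -k_{rvd} (v - 1)^+ + k_{rvi} (1 - v)^+, \quad n \ge 0}
#' \deqn{v = b + (1 - b) w}
#' where `M_e(t)`, `S_e(t)` are the local extracellular non-permeating and
#' permeating osmolalities. With `k_s = k_r = 0` the equilibrium obeys the
#' Boyle-van't Hoff relation `v = b + (1 - b) M_0 / M_e`; a permeating-solute
#' step produces the classic shrink-swell excursion; the regulatory leak
#' returns the volume toward 1: osmolyte loss while swollen (RVD, rate
#' `k_r`) and gain while shrunken (RVI, rate `k_rvi`, typically slower).
#'
#' Integration is classical fixed-step RK4, vectorized across cells. Forcings
#' may be scalars, functions of time returning one value per cell, or matrices
#' sampled at `forcing_times` (linearly interpolated, as produced by
#' [field_at_points()]).
#'
#' @param params a [transport_params()]
#' @param Me,Se extracellular osmolality forcings (mOsm/kg): scalar, function
#'   of `t`, or matrix `(length(forcing_times), n_cells)`
#' @param M0 baseline osmolality (mOsm/kg)
#' @param times output times (s), non-negative, increasing
#' @param forcing_times sample times of matrix forcings
#' @param dt integration step (s)
#' @param n_cells number of cells when forcings are scalar/function
#' @param pre_equilibrated if `TRUE`, start with intracellular permeating
#'   solute equilibrated to `Se(0)`; otherwise `s(0) = 0`
#' @return object of class `volume_trajectories`: list with `times` and
#'   matrices `v, w, n, s` of dim `(length(times), n_cells)`
#' @export
simulate_cell_volume <- function(params, Me, Se = 0, M0 = 300, times,
                                 forcing_times = NULL, dt = 0.5,
                                 n_cells = NULL, pre_equilibrated = FALSE) {
  stopifnot(inherits(params, "transport_params"))
  if (any(diff(times) <= 0)) stopf("output times must be strictly increasing")

  as_forcing <- function(f) {
    if (is.function(f)) return(f)
    if (is.matrix(f)) {
      if (is.null(forcing_times) || length(forcing_times) != nrow(f))
        stopf("matrix forcings need forcing_times matching their row count")
      ft <- forcing_times
      return(function(t) {
        if (t <= ft[1]) return(f[1, ])
        if (t >= ft[length(ft)]) return(f[length(ft), ])
        i <- findInterval(t, ft)
        a <- (t - ft[i]) / (ft[i + 1] - ft[i])
        (1 - a) * f[i, ] + a * f[i + 1, ]
      })
    }
    function(t) f
  }
  Mef <- as_forcing(Me)
  Sef <- as_forcing(Se)
  nc <- n_cells %||% (if (is.matrix(Me)) ncol(Me) else if (is.matrix(Se)) ncol(Se) else 1L)

  w <- rep(1, nc)
  n <- rep(1, nc)
  s <- if (pre_equilibrated) rep_len(Sef(times[1]) / M0, nc) else rep(0, nc)
  b <- params$b

  deriv <- function(t, w, n, s) {
    Mi <- M0 * (n + s) / w
    me <- Mef(t); se <- Sef(t)
    v <- b + (1 - b) * w
    kr_eff <- ifelse(v > 1, params$k_r, params$k_rvi %||% params$k_r)
    list(dw = params$k_w * (Mi - me - se) / M0,
         ds = params$k_s * (se - M0 * s / w) / M0,
         dn = -kr_eff * (v - 1))
  }

  nt <- length(times)
  V <- W <- N <- S <- matrix(NA_real_, nt, nc)
  snap <- function(k) {
    W[k, ] <<- w; N[k, ] <<- n; S[k, ] <<- s
    V[k, ] <<- b + (1 - b) * w
  }
  tcur <- times[1]
  snap(1L)
  for (k in seq_len(nt - 1L)) {
    tend <- times[k + 1L]
    nstep <- max(1L, ceiling((tend - tcur) / dt))
    h <- (tend - tcur) / nstep
    for (ss in seq_len(nstep)) {
      k1 <- deriv(tcur, w, n, s)
      k2 <- deriv(tcur + h / 2, w + h / 2 * k1$dw, n + h / 2 * k1$dn, s + h / 2 * k1$ds)
      k3 <- deriv(tcur + h / 2, w + h / 2 * k2$dw, n + h / 2 * k2$dn, s + h / 2 * k2$ds)
      k4 <- deriv(tcur + h, w + h * k3$dw, n + h * k3$dn, s + h * k3$ds)
      w <- w + h / 6 * (k1$dw + 2 * k2$dw + 2 * k3$dw + k4$dw)
      n <- pmax(0, n + h / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn))
      s <- s + h / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
      tcur <- tcur + h
      if (any(w <= 0))
        stopf("water volume became non-positive during integration; reduce the step size dt (= %g s)", dt)
    }
    tcur <- tend
    snap(k + 1L)
  }
  structure(list(times = times, v = V, w = W, n = N, s = S, params = params, M0 = M0),
            class = "volume_trajectories")
}

#' Boyle-van't Hoff equilibrium volume
#'
#' Closed-form equilibrium normalized volume for a non-permeating osmolality
#' `Me` without solute transport or regulation.
#'
#' @param Me external non-permeating osmolality (mOsm/kg)
#' @param M0 baseline osmolality (mOsm/kg)
#' @param b osmotically inactive fraction
#' @return normalized equilibrium volume `b + (1 - b) * M0 / Me`
#' @export
boyle_vant_hoff <- function(Me, M0 = 300, b = 0.3) b + (1 - b) * M0 / Me
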