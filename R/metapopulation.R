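#' Species parameters of the patch-occupancy model
#'
#' The model tracks the probability that each reach is occupied. An
#' occupied reach goes locally extinct at rate `E_i = e / l_i^omega`
#' (longer reaches are safer), and an empty reach `i` is colonized at rate
#' `C_i(p) = c l_i^gamma sum_j l_j^epsilon exp(-d_ij / D) cdir_ij p_j`:
#' colonizers are produced in proportion to source length to the power
#' `epsilon`, discounted exponentially with swim distance relative to the
#' mean dispersal distance `D`, and thinned by the directed cumulative
#' barrier passability.
#'
#' Long-term outcomes (persistence vs extinction, the steady state) depend
#' only on the ratio `c / e`; the defaults fix `c / e = 10` with `e = 1`.
#' With all barriers fully passable and `omega = epsilon = 1`, `gamma = 0`
#' the model reduces to the classic incidence-function metapopulation model
#' for terrestrial landscapes.
#'
#' @param c colonization strength (per unit time), > 0.
#' @param e extinction parameter (per unit time), > 0.
#' @param omega length-extinction exponent in `[0, 1]`.
#' @param gamma length-attractiveness exponent, >= 0; 0 makes colonization
#'   independent of recipient length.
#' @param epsilon length-productivity exponent, >= 0.
#' @param D mean dispersal distance (same units as reach lengths).
#' @return A `species_params` list.
#' @export
species_params <- function(c = 10, e = 1, omega = 1, gamma = 0, epsilon = 1,
                           D = 1) {
  if (!is.numeric(c) || c <= 0 || !is.numeric(e) || e <= 0 ||
      !is.numeric(D) || D <= 0) {
    stop("c, e and D must be positive", call. = FALSE)
  }
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]", call. = FALSE)
  if (gamma < 0 || epsilon < 0) {
    stop("gamma and epsilon must be nonnegative", call. = FALSE)
  }
  structure(list(c = c, e = e, omega = omega, gamma = gamma,
                 epsilon = epsilon, D = D),
            class = "species_params")
}

#' Per-reach extinction rates
#'
#' `E_i = e / l_i^omega`: local extinction slows down with reach length
#' (more habitat, larger local population). `omega = 0` removes the length
#' dependence.
#'
#' @param net a `river_network`.
#' @param params a [species_params()].
#' @return positive vector of length `n_reaches`.
#' @export
extinction_rates <- function(net, params) {
  validate_river_network(net)
  params$e / net$length^params$omega
}

#' Colonization-gain matrix
#'
#' `B[i, j] = c l_i^gamma l_j^epsilon exp(-d_ij / D) cdir_ij` for `i != j`
#' and 0 on the diagonal, so that the colonization rate of reach `i` is
#' `C_i(p) = sum_j B[i, j] p_j`. `B` collects everything the linearized
#' model needs about geometry, habitat and barriers.
#'
#' @param net a `river_network`.
#' @param params a [species_params()].
#' @param conn optional precomputed [river_connectivity()] for `net`.
#' @return nonnegative `N x N` matrix with zero diagonal.
#' @export
colonization_matrix <- function(net, params, conn = river_connectivity(net)) {
  n <- net$n_reaches
  if (!identical(dim(conn$c_dir), c(n, n))) {
    stop("connectivity result does not match the network size", call. = FALSE)
  }
  l <- net$length
  B <- params$c * outer(l^params$gamma, l^params$epsilon) *
    exp(-conn$d / params$D) * conn$c_dir
  diag(B) <- 0
  B
}

#' Linearize the model at the extinction state
#'
#' At the all-empty state the model linearizes to `dp/dt = J p` with
#' `J = B - diag(E)`. `J` is a Metzler matrix (nonnegative off-diagonal)
#' and irreducible on a connected tree with positive passabilities, so its
#' dominant eigenvalue is real and simple with positive left and right
#' eigenvectors.
#'
#' @param net a `river_network`.
#' @param params a [species_params()].
#' @param conn optional precomputed [river_connectivity()].
#' @return An object of class `metapop_linearization`: list with `B`, `E`,
#'   `J`, `lambda` (metapopulation growth rate), `R` (basic reproduction
#'   number), and `v` (reproductive values, the positive left eigenvector
#'   of `lambda` normalized to unit sum of squares).
#' @export
linearize_metapop <- function(net, params, conn = river_connectivity(net)) {
  B <- colonization_matrix(net, params, conn)
  E <- extinction_rates(net, params)
  J <- B - diag(E, nrow = net$n_reaches)
  lambda <- dominant_eigenvalue(J)
  v <- perron_left_vector(J, lambda)
  R <- next_generation_radius(B, E)
  structure(list(B = B, E = E, J = J, lambda = lambda, R = R, v = v),
            class = "metapop_linearization")
}

#' Metapopulation growth rate
#'
#' Dominant eigenvalue of the Jacobian at extinction: the exponential rate
#' of change of the number of occupied reaches at low occupancy. The
#' metapopulation persists iff `lambda > 0`.
#'
#' @inheritParams linearize_metapop
#' @return scalar `lambda`.
#' @export
growth_rate <- function(net, params, conn = river_connectivity(net)) {
  linearize_metapop(net, params, conn)$lambda
}

#' Basic reproduction number
#'
#' Expected number of reaches that a single occupied reach colonizes in an
#' otherwise empty network: the spectral radius of the next-generation
#' matrix `K[i, j] = B[i, j] / E[j]` (colonization pressure times the mean
#' occupied lifetime `1 / E_j` of the source). Persistence iff `R > 1`,
#' consistently with `lambda > 0`.
#'
#' @inheritParams linearize_metapop
#' @return scalar `R >= 0`.
#' @export
reproduction_number <- function(net, params, conn = river_connectivity(net)) {
  linearize_metapop(net, params, conn)$R
}

#' Reach reproductive values
#'
#' Left eigenvector of the dominant eigenvalue of the Jacobian at
#' extinction, normalized to `sum(v^2) = 1`: the contribution of each
#' reach to growth in patch occupancy at low density.
#'
#' @inheritParams linearize_metapop
#' @return positive vector of length `n_reaches`.
#' @export
reproductive_values <- function(net, params, conn = river_connectivity(net)) {
  linearize_metapop(net, params, conn)$v
}

dominant_eigenvalue <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  lam <- ev[which.max(Re(ev))]
  if (abs(Im(lam)) > 1e-8 * max(1, abs(Re(lam)))) {
    stop("dominant eigenvalue is not real; the network may be degenerate",
         call. = FALSE)
  }
  Re(lam)
}

perron_left_vector <- function(J, lambda) {
  n <- nrow(J)
  if (n == 1L) return(1)
  es <- eigen(t(J))
  k <- which.min(abs(es$values - lambda))
  v <- Re(es$vectors[, k])
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)                 # Perron direction: clip numeric dust
  v / sqrt(sum(v^2))
}

next_generation_radius <- function(B, E) {
  K <- sweep(B, 2L, E, "/")
  max(Mod(eigen(K, only.values = TRUE)$values))
}

#' Steady-state occupancy probabilities
#'
#' When the extinction state is unstable (`lambda > 0`) the model has a
#' unique positive equilibrium `p*` solving
#' `p_i = C_i(p) / (C_i(p) + E_i)`. It is found by monotone fixed-point
#' iteration starting from full occupancy (the iteration decreases
#' monotonically from `p = 1`), polished by a Newton step on the residual
#' `C_i(p)(1 - p_i) - E_i p_i` near the solution; the Newton polish keeps
#' convergence fast near the persistence threshold, where plain iteration
#' slows down. When `lambda <= 0` the zero vector is returned.
#'
#' @param net a `river_network`.
#' @param params a [species_params()].
#' @param conn optional precomputed [river_connectivity()].
#' @param tol max-norm residual tolerance.
#' @param max_iter iteration budget before giving up.
#' @return vector `p*` in `[0, 1)^N`.
#' @export
steady_state <- function(net, params, conn = river_connectivity(net),
                         tol = 1e-12, max_iter = 10000L) {
  lin <- linearize_metapop(net, params, conn)
  steady_state_from_linearization(lin, tol = tol, max_iter = max_iter)
}

steady_state_from_linearization <- function(lin, tol = 1e-12,
                                            max_iter = 10000L) {
  B <- lin$B; E <- lin$E; n <- base::length(E)
  if (lin$lambda <= 0) return(numeric(n))
  p <- rep(1, n)
  for (it in seq_len(max_iter)) {
    C <- as.numeric(B %*% p)
    p_new <- C / (C + E)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < 1e-10) break
  }
  # Newton polish on F(p) = C(p)(1 - p) - E p
  for (it in seq_len(50L)) {
    C <- as.numeric(B %*% p)
    Fp <- C * (1 - p) - E * p
    if (max(abs(Fp)) < tol) break
    Jac <- (1 - p) * B - diag(C + E, nrow = n)
    step <- tryCatch(solve(Jac, Fp), error = function(e) NULL)
    if (is.null(step)) break
    p_try <- p - step
    if (any(!is.finite(p_try)) || any(p_try < 0) || any(p_try >= 1)) break
    p <- p_try
  }
  C <- as.numeric(B %*% p)
  resid <- max(abs(C * (1 - p) - E * p))
  if (resid > 1e-8) {
    stop("steady-state solver did not converge (residual ",
         format(resid), ")", call. = FALSE)
  }
  p
}

#' Integrate the occupancy dynamics
#'
#' Numerically integrates `dp_i/dt = C_i(p)(1 - p_i) - E_i p_i` with a
#' classical fixed-step fourth-order Runge-Kutta scheme (the system is
#' small, smooth and non-stiff at these scales; the step is chosen from the
#' fastest per-reach rate). Used to validate the analytic steady state
#' against the long-time behaviour of the dynamics.
#'
#' @param net a `river_network`.
#' @param params a [species_params()].
#' @param p0 initial occupancy probabilities in `[0, 1]^N`.
#' @param t_end end time of integration.
#' @param n_save number of saved time points (including `t = 0`).
#' @param conn optional precomputed [river_connectivity()].
#' @return list with `time` (vector) and `p` (matrix, rows = saved times),
#'   all occupancies clamped to `[0, 1]`.
#' @export
integrate_occupancy <- function(net, params, p0, t_end, n_save = 101L,
                                conn = river_connectivity(net)) {
  lin <- linearize_metapop(net, params, conn)
  n <- base::length(lin$E)
  if (base::length(p0) != n || any(p0 < 0) || any(p0 > 1)) {
    stop("p0 must lie in [0, 1]^N", call. = FALSE)
  }
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  B <- lin$B; E <- lin$E
  rate_scale <- max(rowSums(B) + E)
  dt <- min(0.25 / rate_scale, t_end / 100)
  n_steps <- ceiling(t_end / dt)
  dt <- t_end / n_steps
  deriv <- function(p) {
    C <- as.numeric(B %*% p)
    C * (1 - p) - E * p
  }
  save_at <- unique(round(seq(0, n_steps, length.out = n_save)))
  out <- matrix(NA_real_, base::length(save_at), n)
  times <- save_at * dt
  p <- as.numeric(p0)
  si <- 1L
  if (save_at[1L] == 0L) { out[1L, ] <- p; si <- 2L }
  for (step in seq_len(n_steps)) {
    k1 <- deriv(p)
    k2 <- deriv(p + dt / 2 * k1)
    k3 <- deriv(p + dt / 2 * k2)
    k4 <- deriv(p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p <- pmin(pmax(p, 0), 1)
    if (si <= base::length(save_at) && step == save_at[si]) {
      out[si, ] <- p
      si <- si + 1L
    }
  }
  list(time = times, p = out)
}

#' Relative persistence metrics against the barrier-free baseline
#'
#' The DCI is a relative index (100 = no barriers), so the metapopulation
#' metrics are likewise expressed relative to the same network with every
#' barrier fully passable (identical topology and lengths, all
#' passabilities 1):
#' * `G_s = exp(lambda - lambda_0)` — relative annualized growth;
#' * `R_s = R / R_0` — relative basic reproduction number;
#' * `P_s = pbar / pbar_0` — relative mean steady-state occupancy;
#' * `O_s(i) = p_i* / p_i0*` — relative reach occupancy;
#' * `V_s(i) = v_i / v_i0` — relative reach reproductive value.
#'
#' `G_s`, `R_s` and `V_s` are low-density (density-independent) metrics;
#' `P_s` and `O_s` are steady-state (density-dependent) metrics. The
#' occupancy ratios are `NA` when the focal or baseline metapopulation does
#' not persist.
#'
#' @param net a `river_network` (the focal, barrier-carrying network).
#' @param params a [species_params()].
#' @param conn optional precomputed [river_connectivity()] of `net`.
#' @return An object of class `metric_bundle`: list with scalars `G_s`,
#'   `R_s`, `P_s`, vectors `O_s`, `V_s`, and the underlying `lambda`,
#'   `lambda_0`, `R`, `R_0`, `p_bar`, `p_bar_0`, `p_star`, `p_star_0`,
#'   `v`, `v_0`.
#' @export
relative_metrics <- function(net, params, conn = river_connectivity(net)) {
  validate_river_network(net)
  baseline <- river_network(length = net$length, parent = net$parent,
                            alpha_up = rep(1, net$n_reaches),
                            alpha_down = rep(1, net$n_reaches))
  lin <- linearize_metapop(net, params, conn)
  lin0 <- linearize_metapop(baseline, params)
  p <- steady_state_from_linearization(lin)
  p0 <- steady_state_from_linearization(lin0)
  persists <- lin$lambda > 0
  persists0 <- lin0$lambda > 0
  p_bar <- if (persists) mean(p) else 0
  p_bar0 <- if (persists0) mean(p0) else 0
  P_s <- if (persists0) p_bar / p_bar0 else NA_real_
  O_s <- if (persists0) p / p0 else rep(NA_real_, net$n_reaches)
  structure(list(
    G_s = exp(lin$lambda - lin0$lambda),
    R_s = if (lin0$R > 0) lin$R / lin0$R else NA_real_,
    P_s = P_s, O_s = O_s, V_s = lin$v / lin0$v,
    lambda = lin$lambda, lambda_0 = lin0$lambda,
    R = lin$R, R_0 = lin0$R,
    p_bar = p_bar, p_bar_0 = p_bar0,
    p_star = p, p_star_0 = p0, v = lin$v, v_0 = lin0$v),
    class = "metric_bundle")
}
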