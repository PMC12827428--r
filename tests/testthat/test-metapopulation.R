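# symmetric two-patch fixture: unit lengths, one barrier, closed forms
# available for every quantity
two_patch <- function(alpha = 0.5, c = 10, e = 1, D = 2) {
  net <- river_network(c(1, 1), c(NA, 1), c(NA, alpha), c(NA, alpha))
  list(net = net, params = species_params(c = c, e = e, D = D))
}

test_that("extinction rates decrease with length as e / l^omega", {
  net <- river_network(c(1, 0.5, 2), c(NA, 1, 2))
  expect_equal(extinction_rates(net, species_params(e = 1, omega = 1)),
               c(1, 2, 0.5))
  # omega = 0: length-independent; l = 1: E = e for any omega
  expect_equal(extinction_rates(net, species_params(e = 3, omega = 0)),
               rep(3, 3))
  expect_equal(extinction_rates(net, species_params(e = 5, omega = 0.7))[1], 5)
})

test_that("colonization matrix evaluates the gain formula entry by entry", {
  tp <- two_patch(alpha = 0.5)
  B <- colonization_matrix(tp$net, tp$params)
  # c * l^eps * exp(-d / D) * cdir = 10 * exp(-1/2) * 0.5
  expect_equal(B[1, 2], 10 * exp(-0.5) * 0.5, tolerance = 1e-12)
  expect_equal(diag(B), c(0, 0))

  # full formula on a random asymmetric network, independent hand build
  set.seed(31)
  net <- random_network(6, symmetric = FALSE)
  pr <- species_params(c = 4, e = 2, omega = 0.8, gamma = 0.3,
                       epsilon = 1.2, D = 1.3)
  B <- colonization_matrix(net, pr)
  for (i in 1:6) for (j in setdiff(1:6, i)) {
    expect_equal(B[i, j],
                 4 * net$length[i]^0.3 * net$length[j]^1.2 *
                   exp(-oracle_d(net, i, j) / 1.3) * oracle_cdir(net, j, i),
                 tolerance = 1e-12)
  }
})

test_that("linearization matches 1-patch and symmetric 2-patch closed forms", {
  # single reach: no colonization, lambda = -E, R = 0, v = 1
  one <- river_network(0.8, NA)
  pr <- species_params(e = 2, omega = 1)
  lin <- linearize_metapop(one, pr)
  expect_equal(lin$lambda, -2 / 0.8, tolerance = 1e-8)
  expect_equal(lin$R, 0)
  expect_equal(lin$v, 1)
  expect_equal(steady_state(one, pr), 0)

  # symmetric two-patch: lambda = b - E, R = sqrt(B12 B21 / (E1 E2)),
  # p* = 1 - 1/b, v = (1, 1) / sqrt(2)
  tp <- two_patch(alpha = 0.5)
  lin <- linearize_metapop(tp$net, tp$params)
  b <- 10 * exp(-0.5) * 0.5
  expect_equal(lin$lambda, b - 1, tolerance = 1e-8)
  expect_equal(lin$R, sqrt(b * b), tolerance = 1e-8)
  expect_equal(lin$v, rep(1 / sqrt(2), 2), tolerance = 1e-8)
  expect_equal(steady_state(tp$net, tp$params), rep(1 - 1 / b, 2),
               tolerance = 1e-8)

  # jointly scaling (c, e) by k scales lambda by k
  k <- 3.7
  lin_k <- linearize_metapop(tp$net,
                             species_params(c = 10 * k, e = k, D = 2))
  expect_equal(lin_k$lambda, k * lin$lambda, tolerance = 1e-8)
  expect_equal(lin_k$R, lin$R, tolerance = 1e-10)  # R depends on c/e only
})

test_that("the Jacobian is Metzler with a real dominant eigenvalue and positive Perron vectors", {
  set.seed(47)
  for (rep in 1:20) {
    net <- random_network(sample(3:20, 1), symmetric = FALSE)
    pr <- species_params(D = dispersal_distance(net, "global"))
    lin <- linearize_metapop(net, pr)
    expect_true(all(lin$B >= 0))
    expect_true(all(diag(lin$B) == 0))
    offdiag <- lin$J - diag(diag(lin$J))
    expect_true(all(offdiag >= 0))
    expect_true(is.numeric(lin$lambda) && is.finite(lin$lambda))
    expect_true(all(lin$v > 0))
    expect_equal(sum(lin$v^2), 1, tolerance = 1e-10)
    # left eigenvector residual: v J = lambda v
    expect_lt(max(abs(lin$v %*% lin$J - lin$lambda * lin$v)), 1e-10)
  }
})

test_that("growth rate and reproduction number agree on the persistence threshold", {
  set.seed(53)
  for (rep in 1:200) {
    net <- random_network(sample(3:15, 1), symmetric = FALSE)
    # span both regimes by varying colonization strength
    pr <- species_params(c = 10^runif(1, -2, 2),
                         D = dispersal_distance(net,
                                                sample(c("global", "local"), 1)))
    lin <- linearize_metapop(net, pr)
    if (abs(lin$R - 1) < 1e-8) next  # numerically on the threshold itself
    expect_identical(lin$lambda > 0, lin$R > 1,
                     label = sprintf("lambda = %g, R = %g", lin$lambda, lin$R))
  }
})

test_that("the steady state solves the equilibrium equation exactly", {
  set.seed(59)
  for (rep in 1:20) {
    net <- random_network(sample(3:25, 1), symmetric = FALSE)
    pr <- species_params(D = dispersal_distance(net, "global"))
    lin <- linearize_metapop(net, pr)
    p <- steady_state(net, pr)
    if (lin$lambda <= 0) {
      expect_equal(p, numeric(net$n_reaches))
    } else {
      expect_true(all(p > 0 & p < 1))
      C <- as.numeric(lin$B %*% p)
      expect_lt(max(abs(C * (1 - p) - lin$E * p)), 1e-10)
    }
  }
})

test_that("the occupancy dynamics stay in [0,1] and approach the steady state", {
  set.seed(61)
  # extinction state is invariant
  tp <- two_patch()
  sol <- integrate_occupancy(tp$net, tp$params, p0 = c(0, 0), t_end = 5)
  expect_true(all(sol$p == 0))

  # subcritical: any initial state decays toward extinction
  weak <- two_patch(alpha = 0.5, c = 0.5)
  expect_lt(growth_rate(weak$net, weak$params), 0)
  sol <- integrate_occupancy(weak$net, weak$params, p0 = c(0.9, 0.9),
                             t_end = 60)
  expect_lt(max(sol$p[nrow(sol$p), ]), 1e-6)

  # supercritical: trajectories converge to the analytic equilibrium
  for (rep in 1:5) {
    net <- random_network(sample(3:10, 1), symmetric = FALSE)
    pr <- species_params(D = dispersal_distance(net, "global"))
    if (growth_rate(net, pr) < 0.3) next  # keep the transient short
    p_star <- steady_state(net, pr)
    sol <- integrate_occupancy(net, pr, p0 = rep(0.5, net$n_reaches),
                               t_end = 80)
    expect_lt(max(abs(sol$p[nrow(sol$p), ] - p_star)), 1e-6)
    expect_true(all(sol$p >= 0 & sol$p <= 1))
  }
})

test_that("relative metrics are 1 on a barrier-free network and follow closed forms", {
  skel <- build_topology("binary", 7)
  free <- river_network(runif(7, 0.5, 1), skel$parent)
  m <- relative_metrics(free, species_params(D = total_length(free)))
  expect_equal(m$G_s, 1, tolerance = 1e-10)
  expect_equal(m$R_s, 1, tolerance = 1e-10)
  expect_equal(m$P_s, 1, tolerance = 1e-8)
  expect_equal(m$O_s, rep(1, 7), tolerance = 1e-8)
  expect_equal(m$V_s, rep(1, 7), tolerance = 1e-8)

  # symmetric two-patch with alpha = 0.5: R scales as the single directed
  # passability, so R_s = alpha
  tp <- two_patch(alpha = 0.5, D = 2)
  m <- relative_metrics(tp$net, tp$params)
  expect_equal(m$R_s, 0.5, tolerance = 1e-10)
})

test_that("metric ranks are invariant to joint rescaling of c and e", {
  set.seed(67)
  cfg <- scenario_config("binary", "symmetric", "global",
                         n_reaches = 7, n_replicates = 15, seed = 4)
  nets <- generate_networks(cfg)
  metrics <- function(k) {
    vapply(nets, function(net) {
      pr <- species_params(c = 10 * k, e = k,
                           D = dispersal_distance(net, "global"))
      m <- relative_metrics(net, pr)
      c(G = m$G_s, R = m$R_s, P = m$P_s)
    }, numeric(3))
  }
  m1 <- metrics(1); m3 <- metrics(3)
  # R_s and P_s depend only on c/e; G_s is raised to the power k, which
  # preserves ranks
  expect_equal(m1["R", ], m3["R", ], tolerance = 1e-8)
  expect_equal(m1["P", ], m3["P", ], tolerance = 1e-6)
  expect_equal(m3["G", ], m1["G", ]^3, tolerance = 1e-6)
  for (row in rownames(m1)) {
    expect_identical(rank(m1[row, ]), rank(m3[row, ]))
  }
})
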