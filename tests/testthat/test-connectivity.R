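test_that("tree_path follows the unique path through the common confluence", {
  net <- fig1_network()
  p <- tree_path(net, 4, 5)
  expect_equal(p$n_barriers, 2L)
  expect_equal(p$steps$barrier, c(4L, 5L))
  expect_equal(p$steps$direction, c("downstream", "upstream"))

  p <- tree_path(net, 4, 1)
  expect_equal(p$steps$barrier, c(4L, 2L))
  expect_equal(p$steps$direction, c("downstream", "downstream"))

  p <- tree_path(net, 3, 3)
  expect_equal(p$n_barriers, 0L)

  # reversing endpoints reverses step order and flips every direction
  fwd <- tree_path(net, 4, 7)
  rev_ <- tree_path(net, 7, 4)
  expect_equal(rev_$steps$barrier, rev(fwd$steps$barrier))
  expect_equal(rev_$steps$direction,
               rev(ifelse(fwd$steps$direction == "upstream",
                          "downstream", "upstream")))
  expect_error(tree_path(net, 1, 9), "unknown reach")
})

test_that("cumulative passabilities multiply along the path", {
  net <- fig1_network()
  expect_equal(cumulative_passability(net, 3, 3), 1)  # empty product
  two <- river_network(c(1, 1), c(NA, 1), c(NA, 0.5), c(NA, 0.8))
  expect_equal(cumulative_passability(two, 1, 2), 0.4)
  # two barriers at (0.5, 0.5) each: (0.25)^2
  expect_equal(cumulative_passability(net, 4, 5), 0.0625)
})

test_that("directed passability respects travel direction and composes to c_ij", {
  asym <- river_network(c(1, 1), c(NA, 1), c(NA, 0.25), c(NA, 1))
  expect_equal(directed_cumulative_passability(asym, 1, 2), 0.25)  # upstream
  expect_equal(directed_cumulative_passability(asym, 2, 1), 1)     # downstream

  set.seed(11)
  for (rep in 1:20) {
    net <- random_network(sample(3:12, 1), symmetric = FALSE)
    conn <- river_connectivity(net)
    # c_dir[i, j] * c_dir[j, i] = c[i, j]: each barrier contributes both
    # alpha_u and alpha_d across the two directions
    expect_equal(conn$c_dir * t(conn$c_dir), conn$c, tolerance = 1e-12)
    expect_true(all(abs(conn$c - t(conn$c)) < 1e-14))
    expect_equal(diag(conn$c), rep(1, net$n_reaches))
  }

  # symmetric barriers: directed product is the square root of c
  sym <- fig1_network(alpha_up = c(NA, runif(6, .2, .9)))
  conn <- river_connectivity(sym)
  expect_equal(conn$c_dir^2, conn$c, tolerance = 1e-12)
})

test_that("swim distance uses the midpoint convention", {
  net <- fig1_network()
  expect_equal(swim_distance(net, 2, 2), 0)
  expect_equal(swim_distance(net, 1, 2), 1)      # adjacent unit reaches
  expect_equal(swim_distance(net, 4, 5), 2)      # through the full parent
  mixed <- river_network(c(2, 0.5, 1), c(NA, 1, 2))
  expect_equal(swim_distance(mixed, 1, 3), 2)    # 1 + 0.5 + 0.5
})

test_that("pairwise matrices match exhaustive path enumeration (N <= 6)", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    net <- random_network(n, symmetric = FALSE)
    conn <- river_connectivity(net)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      expect_equal(conn$c[i, j], oracle_c(net, i, j), tolerance = 1e-12)
      expect_equal(conn$c_dir[i, j], oracle_cdir(net, j, i),
                   tolerance = 1e-12)
      expect_equal(conn$d[i, j], oracle_d(net, i, j), tolerance = 1e-12)
      expect_equal(swim_distance(net, i, j), oracle_d(net, i, j),
                   tolerance = 1e-12)
      expect_equal(cumulative_passability(net, i, j), oracle_c(net, i, j),
                   tolerance = 1e-12)
      expect_equal(directed_cumulative_passability(net, j, i),
                   oracle_cdir(net, j, i), tolerance = 1e-12)
    }
  }
})

test_that("DCIp matches hand-evaluated cases and is 100 without barriers", {
  # barrier-free networks score exactly 100 whatever the lengths/topology
  set.seed(5)
  for (shape in c("linear", "binary")) {
    skel <- build_topology(shape, 9)
    net <- river_network(runif(9, 0.5, 1), skel$parent)
    expect_equal(dci_p(net), 100, tolerance = 1e-12)
  }
  expect_equal(dci_p(river_network(2.3, NA)), 100)

  # two equal reaches, product 0.25: (1 + 0.25 + 0.25 + 1) / 4 * 100
  two <- river_network(c(1, 1), c(NA, 1), c(NA, 0.5), c(NA, 0.5))
  expect_equal(dci_p(two), 62.5)
  expect_equal(dci_s(two), c(62.5, 62.5))
  expect_equal(dci_s(two, 1), 62.5)
  expect_error(dci_s(two, 5), "unknown reach")
})

test_that("DCIp is the length-weighted average of DCIs", {
  set.seed(77)
  for (rep in 1:50) {
    net <- random_network(sample(3:50, 1), symmetric = FALSE)
    v <- dci_s(net)
    expect_equal(sum(v * net$length) / total_length(net), dci_p(net),
                 tolerance = 1e-10)
  }
})

test_that("both indices increase when any single passability increases", {
  set.seed(19)
  for (rep in 1:10) {
    net <- random_network(sample(4:10, 1), symmetric = FALSE)
    base_p <- dci_p(net)
    base_s <- dci_s(net)
    k <- sample(2:net$n_reaches, 1)
    up <- net
    up$alpha_up[k] <- min(1, up$alpha_up[k] * 1.2)
    expect_gt(dci_p(up), base_p)
    expect_true(all(dci_s(up) >= base_s - 1e-14))
  }
})

test_that("paired symmetric/asymmetric networks share all undirected quantities", {
  skel <- build_topology("binary", 10)
  row <- lhs_matrix(1, 19, seed = 8)[1, ]
  sym <- assign_attributes(skel, "symmetric", row)
  asym <- assign_attributes(skel, "asymmetric", row)
  cs <- river_connectivity(sym); ca <- river_connectivity(asym)
  expect_equal(cs$c, ca$c, tolerance = 1e-12)
  expect_equal(cs$dci_p, ca$dci_p, tolerance = 1e-12)
  expect_equal(cs$dci_s, ca$dci_s, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cs$c_dir, ca$c_dir)))  # dynamics differ
})
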