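# The worked two-flux example has closed-form means, deviation matrix and
# feasibility geometry; it anchors the exactness tests.  Random instances
# cross-check the matrix identities against direct variance computations.

test_that("mean rows are probability-weighted scenario averages", {
  ex <- toy_example()
  expect_equal(mean_row(ex$p, ex$S_hat), c(1, -1), tolerance = 1e-15)
  expect_equal(mean_row(1, matrix(c(2, 3), 1)), c(2, 3))
  set.seed(9)
  for (rep in 1:20) {
    q <- sample(2:6, 1); n <- sample(2:5, 1)
    p <- stats::runif(q); p <- p / sum(p)
    S_hat <- matrix(stats::rnorm(q * n), q, n)
    brute <- colSums(p * S_hat)
    expect_equal(mean_row(p, S_hat), brute, tolerance = 1e-12)
  }
  expect_error(mean_row(c(0.5, 0.5), matrix(1, 3, 2)), "shape error")
})

test_that("the worked example's deviation matrix is reproduced entrywise", {
  ex <- toy_example()
  R <- deviation_matrix(ex$p, ex$S_hat, ex$delta)
  want <- matrix(c(-0.15, -0.30,
                   0, 0,
                   0.15, 0.30), nrow = 3, byrow = TRUE)
  expect_equal(R, want, tolerance = 1e-12)
  # identical scenario rows carry no deviation
  expect_equal(deviation_matrix(c(0.3, 0.7), matrix(1, 2, 3), 3),
               matrix(0, 2, 3), tolerance = 1e-15)
})

test_that("||R v|| equals delta times the scenario standard deviation", {
  set.seed(10)
  for (rep in 1:100) {
    q <- sample(2:6, 1); n <- sample(2:5, 1)
    p <- stats::runif(q); p <- p / sum(p)
    S_hat <- matrix(stats::rnorm(q * n), q, n)
    v <- stats::rnorm(n)
    delta <- stats::runif(1, 0.5, 4)
    R <- deviation_matrix(p, S_hat, delta)
    vals <- as.numeric(S_hat %*% v)
    mu <- sum(p * vals)
    sigma <- sqrt(sum(p * (vals - mu)^2))
    expect_equal(sqrt(sum(as.numeric(R %*% v)^2)), delta * sigma,
                 tolerance = 1e-10)
  }
})

test_that("the growth-column norm collapses the cone to a scalar coefficient", {
  expect_equal(growth_norm_coefficient(c(0.3, 0.7), c(2, 2), 3), 0)
  # worked-example growth column: 3 * sqrt(1/4 * 0.01 + 0 + 1/4 * 0.01)
  r <- growth_norm_coefficient(c(1/4, 1/2, 1/4), c(0.9, 1, 1.1), 3)
  expect_equal(round(r, 4), 0.2121)
  expect_equal(r, 3 * sqrt(0.005), tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:20) {
    q <- sample(2:5, 1); n <- sample(2:4, 1)
    p <- stats::runif(q); p <- p / sum(p)
    base <- stats::rnorm(n)
    s <- stats::rnorm(q, base[n], 0.2)
    S_hat <- matrix(rep(base, each = q), q, n)
    S_hat[, n] <- s
    v <- stats::rnorm(n); v[n] <- stats::runif(1, 0.5, 2)
    R <- deviation_matrix(p, S_hat, 3)
    expect_equal(growth_norm_coefficient(p, s, 3),
                 sqrt(sum(as.numeric(R %*% v)^2)) / abs(v[n]),
                 tolerance = 1e-9)
  }
})

test_that("uncertainty-set members never violate the audited bound", {
  pr <- toy_ramp_problem()
  st <- solve_ramp(pr)
  expect_identical(st$status, "optimal")
  v <- as.numeric(st$v)
  expect_true(is_feasible(audit_feasibility(v, pr, tolerance = 1e-7)))
  ex <- toy_example()
  R <- deviation_matrix(ex$p, ex$S_hat, ex$delta)
  set.seed(13)
  for (rep in 1:200) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2)) * stats::runif(1)^0.5
    row <- sample_uncertainty_constraint(ex$p, ex$S_hat, ex$delta, u)
    expect_lte(sum(row * v), ex$M + 1e-9)
  }
  # u aligned with R v attains the norm exactly
  Rv <- as.numeric(R %*% v)
  u_star <- Rv / sqrt(sum(Rv^2))
  row <- sample_uncertainty_constraint(ex$p, ex$S_hat, ex$delta, u_star)
  expect_equal(sum(row * v),
               sum(mean_row(ex$p, ex$S_hat) * v) + sqrt(sum(Rv^2)),
               tolerance = 1e-10)
  expect_equal(sample_uncertainty_constraint(ex$p, ex$S_hat, ex$delta,
                                             c(0, 0, 0)),
               mean_row(ex$p, ex$S_hat))
  expect_error(sample_uncertainty_constraint(ex$p, ex$S_hat, ex$delta,
                                             c(1, 1, 1)), "parameter error")
})

test_that("the worked example separates the robust and steady-state regions", {
  pr <- toy_ramp_problem()       # M = 0.2
  aud <- audit_feasibility(c(0.75, 0.75), pr)
  expect_false(is_feasible(aud))
  # |S v| = 0: steady-state feasible, yet deviation exceeds M
  expect_equal(aud$mu[1], 0, tolerance = 1e-12)
  expect_equal(aud$deviation[1], sqrt(2) * 0.45 * 0.75, tolerance = 1e-10)
  expect_equal(round(aud$deviation[1], 4), 0.4773)
  expect_true(is_feasible(audit_feasibility(c(0, 0), pr)))
  # and conversely a point off steady state that the robust region accepts
  v_off <- c(0.1, 0)             # S v = 0.1 != 0, within M and deviation
  expect_true(is_feasible(audit_feasibility(v_off, pr)))
})

test_that("the linear assembly rejects structures it cannot linearize", {
  ex_net <- chain_network()
  sc <- build_model3(ex_net, 0.1)
  neg <- ex_net; neg$lower[neg$growth_index] <- -5
  expect_error(assemble_linear_ramp(neg, sc, 0), "nonnegative growth")
  # general two-column scenario rows only fit the cone path
  pr <- toy_ramp_problem()
  expect_error(assemble_linear_ramp(pr$network, pr$scenarios, 0.2),
               "unsupported structure")
})

test_that("zero scenario spread with M = 0 recovers the steady-state optimum", {
  for (s in 1:5) {
    rn <- random_network(8, 14, seed = s)
    fba <- solve_fba(rn)
    sc0 <- build_model3(rn, 0)
    lin <- solve_ramp(assemble_linear_ramp(rn, sc0, 0))
    expect_equal(lin$objective, fba$objective, tolerance = 1e-8)
  }
})

test_that("the linear and cone paths agree on growth-column uncertainty", {
  for (s in c(1, 3)) {
    rn <- random_network(6, 10, seed = s)
    sc <- build_model3(rn, 0.2)
    fit <- fit_M(rn, sc)
    lin <- solve_ramp(assemble_linear_ramp(rn, sc, fit$M))
    soc <- solve_ramp(assemble_socp_ramp(rn, sc, fit$M))
    expect_equal(lin$objective, soc$objective, tolerance = 1e-6)
  }
  net <- chain_network()
  sc <- build_model3(net, 0.2)
  fit <- fit_M(net, sc)
  lin <- solve_ramp(assemble_linear_ramp(net, sc, fit$M))
  soc <- solve_ramp(assemble_socp_ramp(net, sc, fit$M))
  expect_equal(lin$objective, soc$objective, tolerance = 1e-6)
})

test_that("growth is non-decreasing in each deviation bound", {
  rn <- random_network(6, 10, seed = 2)
  sc <- build_model3(rn, 0.2)
  fit <- fit_M(rn, sc)
  base <- solve_ramp(assemble_linear_ramp(rn, sc, fit$M))$objective
  for (i in seq_along(fit$M)) {
    M2 <- fit$M
    M2[i] <- M2[i] + 0.5
    grew <- solve_ramp(assemble_linear_ramp(rn, sc, M2))$objective
    expect_gte(grew, base - 1e-8)
  }
  # huge M: constraints vacuous, bounds-only optimum
  rlx <- solve_ramp(assemble_linear_ramp(rn, sc, 1e5))
  bounds_only <- rampflux:::lp_solve(
    replace(numeric(ncol(rn$S)), rn$growth_index, 1),
    matrix(0, 1, ncol(rn$S)), "<=", 1e9, rn$lower, rn$upper)
  expect_equal(rlx$objective, bounds_only$objective, tolerance = 1e-8)
})

test_that("L1-minimal deviation bounds restore the steady-state growth rate", {
  for (s in 1:6) {
    rn <- random_network(8, 14, seed = s)
    gamma <- solve_fba(rn)$objective
    sc <- build_model3(rn, 0.2)
    fit <- fit_M(rn, sc)
    expect_identical(fit$status, "optimal")
    expect_true(all(fit$M >= 0))
    st <- solve_ramp(assemble_linear_ramp(rn, sc, fit$M))
    expect_equal(st$objective, gamma, tolerance = 1e-6)
  }
  # zero spread: FBA already attains gamma*, so M = 0
  rn <- random_network(8, 14, seed = 1)
  fit0 <- fit_M(rn, build_model3(rn, 0))
  expect_equal(max(fit0$M), 0, tolerance = 1e-8)
  # unattainable target growth
  gamma <- solve_fba(rn)$objective
  bad <- fit_M(rn, build_model3(rn, 0.1), gamma_star = gamma * 1.01)
  expect_identical(bad$status, "infeasible")
})

test_that("solver outputs always audit as feasible", {
  for (s in 1:4) {
    rn <- random_network(8, 14, seed = s)
    sc <- build_model3(rn, 0.15)
    fit <- fit_M(rn, sc)
    pr <- assemble_linear_ramp(rn, sc, fit$M)
    st <- solve_ramp(pr)
    expect_identical(st$status, "optimal")
    expect_true(is_feasible(audit_feasibility(as.numeric(st$v), pr,
                                              tolerance = 1e-6)))
  }
})

test_that("scenario possibility requires identical scenario values", {
  ex <- toy_example()
  pr <- toy_ramp_problem()
  # the worked example's scenarios at v = (1, 1): values (-0.3, 0, 0.3)
  res <- biologically_possible(pr$scenarios, c(1, 1))
  expect_false(res$possible[1])
  # constructed so every scenario row gives the same value
  net <- chain_network()
  sc0 <- build_model3(net, 0)        # zero spread: identical by construction
  res0 <- biologically_possible(sc0, c(1, 1, 1, 1))
  expect_true(all(res0$possible))
  # scenarios scaled along a direction orthogonal to variation
  S_hat <- matrix(c(1, 1, 2, 0, 1.5, 0.5), 3, 2, byrow = TRUE)
  net2 <- metabolic_network(matrix(c(1.5, 0.5), 1,
                                   dimnames = list("m", c("a", "b"))),
                            lower = c(-10, -10), upper = c(10, 10),
                            growth_id = 1)
  sc2 <- rampflux:::new_scenario_set(
    c(1/3, 1/3, 1/3), matrix(S_hat[, 1], 1), delta = 3, base_column = 1,
    network = net2, scenario_rows = list(S_hat))
  # v = (1, 1): scenario values (2, 2, 2) -> possible with alpha 2
  res2 <- biologically_possible(sc2, c(1, 1))
  expect_true(res2$possible[1])
  expect_equal(res2$alpha[1], 2, tolerance = 1e-12)
})

test_that("shrinking scenario spread drives the robust optimum to the steady-state one", {
  # small version of the limiting property; the full sweep runs in the
  # acceptance suite
  for (s in 1:3) {
    rn <- random_network(8, 14, seed = s)
    gamma <- solve_fba(rn)$objective
    gaps <- vapply(c(0, 3, 6), function(k) {
      sc <- build_model3(rn, 0.2 * 10^-k)
      fit <- fit_M(rn, sc)
      abs(solve_ramp(assemble_linear_ramp(rn, sc, fit$M))$objective - gamma)
    }, numeric(1))
    expect_lt(gaps[3], 1e-6)
  }
})
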