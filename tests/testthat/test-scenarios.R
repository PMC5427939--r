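# Reference values for the digit-level scenario rule come from the
# reference two-row scenario table (growth coefficients 53.95 and -0.000223).

growth_net <- function(coefs) {
  # minimal network whose biomass column carries the given coefficients
  m <- length(coefs)
  mets <- names(coefs)
  S <- cbind(diag(m), coefs)
  dimnames(S) <- list(mets, c(paste0("EX_", mets), "GROWTH"))
  metabolic_network(S, lower = rep(0, m + 1), upper = rep(1000, m + 1),
                    growth_id = m + 1)
}

test_that("the digit step of a printed coefficient is one past its last decimal", {
  expect_equal(infer_digit_step("53.95"), 1e-3)
  expect_equal(infer_digit_step("-0.000223"), 1e-7)
  expect_equal(infer_digit_step("2"), 0.1)
  expect_error(infer_digit_step("abc"), "cannot parse")
})

test_that("digit-level scenarios reproduce the reference scenario table rows", {
  net <- growth_net(c(adp = 53.95, ohph2 = -0.000223))
  sc <- build_model1(net, coefficient_texts = c(adp = "53.95",
                                                ohph2 = "-0.000223"))
  expect_equal(sc$q, 5L)
  expect_equal(sc$delta, 3)
  expect_equal(sc$probabilities, c(0.0351, 0.2389, 0.4520, 0.2389, 0.0351))
  expect_equal(sum(sc$probabilities), 1, tolerance = 1e-15)
  expect_equal(as.numeric(sc$growth_scenarios["adp", ]),
               c(53.948, 53.949, 53.95, 53.951, 53.952), tolerance = 1e-12)
  expect_equal(as.numeric(sc$growth_scenarios["ohph2", ]),
               c(-0.0002232, -0.0002231, -0.000223, -0.0002229, -0.0002228),
               tolerance = 1e-12)
})

test_that("scaled digit-level scenarios multiply the step by rho", {
  net <- growth_net(c(adp = 53.95))
  sc2 <- build_model2(net, coefficient_texts = c(adp = "53.95"), rho = 2)
  expect_equal(range(sc2$growth_scenarios["adp", ]), c(53.946, 53.954),
               tolerance = 1e-12)
  sc1a <- build_model2(net, coefficient_texts = c(adp = "53.95"), rho = 1)
  sc1b <- build_model1(net, coefficient_texts = c(adp = "53.95"))
  expect_equal(sc1a$growth_scenarios, sc1b$growth_scenarios)
  expect_error(build_model2(net, rho = 10), "parameter error")
  expect_error(build_model2(net, rho = 0), "parameter error")
})

test_that("digit-level scaling preserves coefficient signs up to rho = 9", {
  net <- growth_net(c(adp = 53.95, ohph2 = -0.000223))
  texts <- c(adp = "53.95", ohph2 = "-0.000223")
  for (rho in c(2, 5, 9)) {
    sc <- build_model2(net, coefficient_texts = texts, rho = rho)
    base_sign <- sign(growth_coefficients(net))
    expect_true(all(sign(sc$growth_scenarios) ==
                      matrix(base_sign, nrow = 2, ncol = 5)))
  }
})

test_that("proportional scenarios scale the coefficient itself", {
  net <- growth_net(c(x = -1))
  sc <- build_model3(net, sigma = 0.2)
  # the scenario set {c(1 - sigma), ..., c(1 + sigma)} for c = -1
  expect_equal(sort(as.numeric(sc$growth_scenarios["x", ])),
               c(-1.2, -1.1, -1.0, -0.9, -0.8), tolerance = 1e-12)
  sc0 <- build_model3(net, sigma = 0)
  expect_true(all(sc0$growth_scenarios == -1))
  expect_equal(unname(scenario_spread(sc0)["x"]), 0)
})

test_that("percentile-varied scenarios map tail mass to the normal quantile", {
  net <- growth_net(c(x = 1))
  expect_equal(build_model4(net, 0.0027)$delta, 3, tolerance = 5e-4)
  expect_equal(build_model4(net, 0.3173)$delta, 1, tolerance = 5e-4)
  d <- vapply(c(0.01, 0.1, 0.5, 0.9), function(e2)
    build_model4(net, e2)$delta, numeric(1))
  expect_true(all(diff(d) < 0))            # larger tail mass, smaller delta
  expect_error(build_model4(net, 0), "parameter error")
  expect_error(build_model4(net, 1), "parameter error")
})

test_that("single-coefficient scenarios perturb only the target row", {
  net <- growth_net(c(x = 1, y = 2))
  sc <- build_single_coefficient(net, "x", sigma = 0.1)
  expect_equal(as.numeric(sc$growth_scenarios["x", ]),
               c(0.9, 0.95, 1, 1.05, 1.1), tolerance = 1e-12)
  spread <- scenario_spread(sc)
  expect_gt(spread[["x"]], 0)
  expect_equal(unname(spread[setdiff(names(spread), "x")]),
               rep(0, length(spread) - 1))
  sc0 <- build_single_coefficient(net, "x", sigma = 0)
  expect_true(all(scenario_spread(sc0) == 0))
  expect_error(build_single_coefficient(net, "absent", 0.1), "lookup error")
})

test_that("every scenario family is mean-preserving and monotone in the scenario index", {
  set.seed(5)
  for (s in 1:4) {
    rn <- random_network(8, 14, seed = s)
    base <- growth_coefficients(rn)
    builders <- list(
      build_model1(rn),
      build_model2(rn, rho = 3),
      build_model3(rn, sigma = 0.25),
      build_model4(rn, epsilon2 = 0.1),
      build_single_coefficient(
        rn, names(base)[which(base != 0)[1]], sigma = 0.3))
    for (sc in builders) {
      mu <- as.numeric(sc$growth_scenarios %*% sc$probabilities)
      expect_equal(mu, unname(base), tolerance = 1e-9)
      mono <- apply(sc$growth_scenarios, 1, function(r)
        all(diff(r) >= -1e-12) || all(diff(r) <= 1e-12))
      expect_true(all(mono))
    }
  }
})

test_that("recomputed probabilities are the literal normal band masses", {
  p <- ramp_probabilities(recompute = TRUE)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[1], pnorm(-1.5), tolerance = 1e-12)
  expect_equal(p[3], 2 * pnorm(0.5) - 1, tolerance = 1e-12)
})
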