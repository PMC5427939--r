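toy_json <- function(path) {
  doc <- list(
    metabolites = list(list(id = "A"), list(id = "B")),
    reactions = list(
      list(id = "EX_A", metabolites = list(A = 1),
           lower_bound = 0, upper_bound = 10, gene_reaction_rule = ""),
      list(id = "R1", metabolites = list(A = -1, B = 1),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "g1"),
      list(id = "GROWTH", metabolites = list(B = -1),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "", objective_coefficient = 1)),
    genes = list(list(id = "g1")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

test_that("COBRA-style JSON models load, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  net <- read_metabolic_model(toy_json(f))
  expect_s3_class(net, "metabolic_network")
  expect_identical(dim(net$S), c(2L, 3L))
  expect_identical(net$reaction_ids[net$growth_index], "GROWTH")

  f2 <- withr::local_tempfile(fileext = ".json")
  write_cobra_json(net, f2)
  net2 <- read_metabolic_model(f2)
  expect_true(all(net$S == net2$S))
  expect_equal(net$lower, net2$lower)
  expect_equal(net$upper, net2$upper)
  expect_identical(net$gpr, net2$gpr)
})

test_that("invalid models are rejected with informative errors", {
  expect_error(metabolic_network(matrix(c(1, -1), 1), lower = c(2, 0),
                                 upper = c(1, 0), growth_id = 1),
               "lower bound exceeds upper")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', f)
  expect_error(read_metabolic_model(f), "lacks")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f2)
  expect_error(read_metabolic_model(f2), "parse failure")
})

test_that("SBML level 3 + fbc models load with bounds, GPRs and objective", {
  net <- read_metabolic_model(system.file("extdata", "toy_chain.xml",
                                          package = "rampflux"))
  expect_identical(net$metabolite_ids, c("A", "B", "BIOMASS"))
  expect_identical(net$reaction_ids[net$growth_index], "GROWTH")
  expect_equal(net$upper[1], 10)          # uptake bound via parameter ref
  expect_equal(as.numeric(net$S["B", "GROWTH"]), -0.73)
  expect_true(evaluate_gpr(net$gpr[2], "g1"))    # g1 or g2
  expect_false(evaluate_gpr(net$gpr[2], c("g1", "g2")))
  expect_equal(solve_fba(net)$objective, 10 / 0.73, tolerance = 1e-9)
})

test_that("GPR evaluation follows boolean semantics", {
  expect_true(evaluate_gpr("(g1 and g2) or g3", "g1"))
  expect_false(evaluate_gpr("(g1 and g2) or g3", c("g1", "g3")))
  expect_true(evaluate_gpr("", c("g1")))        # empty rule: always on
  expect_error(evaluate_gpr("g1 and (g2", character(0)), "malformed")
  expect_error(evaluate_gpr("g1 and or g2", character(0)), "malformed")
})

test_that("GPR evaluation agrees with R's own boolean evaluator on random rules", {
  set.seed(7)
  genes <- paste0("g", 1:6)
  for (rep in 1:40) {
    rule <- random_gpr_rule(genes)
    for (k in 0:3) {
      knocked <- sample(genes, k)
      expect_identical(evaluate_gpr(rule, knocked),
                       gpr_eval_via_r(rule, knocked, genes),
                       info = paste(rule, "| knocked:",
                                    paste(knocked, collapse = ",")))
    }
  }
})

test_that("knockouts zero reaction bounds and are idempotent and monotone", {
  net <- chain_network()
  expect_identical(apply_knockout(net, character(0)), net)
  expect_error(apply_knockout(net, "nope"), "unknown gene")

  ko <- apply_knockout(net, "g1")
  expect_equal(ko$lower[2], 0)
  expect_equal(ko$upper[2], 0)
  expect_equal(solve_fba(ko)$objective, 0, tolerance = 1e-9)
  expect_identical(apply_knockout(ko, "g1"), ko)   # idempotent

  # monotone: growing the knockout set never raises the optimum
  set.seed(11)
  for (s in 1:5) {
    rn <- random_network(8, 14, seed = s)
    genes <- sample(rn$gene_ids)
    vals <- vapply(seq_along(genes), function(k)
      solve_fba(apply_knockout(rn, genes[seq_len(k)]))$objective, numeric(1))
    expect_true(all(diff(vals) <= 1e-8))
  }
})

test_that("knockout of a gene absent from every rule leaves the network unchanged", {
  net <- metabolic_network(matrix(c(1, -1, 0, 0, 1, -1), 2, 3,
                                  dimnames = list(c("A", "B"),
                                                  c("EX", "R1", "GROWTH"))),
                           lower = rep(0, 3), upper = c(10, 1000, 1000),
                           growth_id = 3, gpr = c("", "g1", ""),
                           gene_ids = c("g1", "g_spare"))
  expect_identical(apply_knockout(net, "g_spare"), net)
})

test_that("FBA solves the steady-state LP", {
  net <- chain_network()
  sol <- solve_fba(net)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)    # chain closed form
  expect_lt(max(abs(as.numeric(net$S %*% sol$v))), 1e-6)

  # all bounds zero: only the zero flux remains
  z <- net; z$lower[] <- 0; z$upper[] <- 0
  expect_equal(solve_fba(z)$objective, 0, tolerance = 1e-12)
})

test_that("FBA matches an independent vertex-enumeration solve", {
  net <- chain_network()
  obj <- numeric(4); obj[net$growth_index] <- 1
  want <- lp_vertex_oracle(obj, as.matrix(net$S), rep("==", 3), rep(0, 3),
                           net$lower, net$upper)
  expect_equal(solve_fba(net)$objective, want$objective, tolerance = 1e-8)
})

test_that("steady state holds at optimum across random fixtures", {
  for (s in 1:6) {
    rn <- random_network(8, 14, seed = s)
    sol <- solve_fba(rn)
    expect_identical(sol$status, "optimal")
    expect_lt(max(abs(as.numeric(rn$S %*% sol$v))), 1e-6)
  }
})

test_that("growth environments apply to exchange reactions by name", {
  net <- chain_network()
  # tighten uptake of the carbon source to 4 via the medium interface
  med <- apply_medium(net, uptake = c(A = 4))
  expect_equal(solve_fba(med)$objective, 4, tolerance = 1e-9)
})
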