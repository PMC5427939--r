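# Built-in example systems: the fully worked two-flux illustration, small
# hand-constructed networks with known optima, and a seeded random-network
# generator so every part of the package is testable without downloads.

#' The two-flux worked example
#'
#' A single uncertain stoichiometric row `s1 v1 + s2 v2 = 0` with average
#' values (1, -1), bounds `[-1, 1]^2`, three scenarios
#' `(0.9, -1.2), (1, -1), (1.1, -0.8)` with probabilities (1/4, 1/2, 1/4),
#' `delta = 3`, and `M = 0.2`.  Its deviation matrix, mean row, and
#' feasibility geometry are known in closed form, which makes it the
#' package's primary exactness fixture.
#'
#' @return A list with `p`, `S_hat`, `delta`, `M`, `base_row`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' ex <- toy_example()
#' mean_row(ex$p, ex$S_hat)                 # (1, -1)
#' deviation_matrix(ex$p, ex$S_hat, ex$delta)
toy_example <- function() {
  list(p = c(1/4, 1/2, 1/4),
       S_hat = matrix(c(0.9, -1.2,
                        1.0, -1.0,
                        1.1, -0.8), nrow = 3, byrow = TRUE),
       delta = 3, M = 0.2,
       base_row = c(1, -1),
       lower = c(-1, -1), upper = c(1, 1))
}

#' Assembled robust problem for the worked example
#'
#' Wraps [toy_example()] into a one-metabolite, two-reaction network with
#' general (two-column) scenario rows, assembled on the cone path, with the
#' first flux as the objective.
#'
#' @param M Deviation bound (default 0.2 as in the worked example).
#' @return A `ramp_problem` of cone form.
#' @export
toy_ramp_problem <- function(M = 0.2) {
  ex <- toy_example()
  net <- metabolic_network(S = matrix(ex$base_row, nrow = 1,
                                      dimnames = list("met1", c("v1", "v2"))),
                           lower = ex$lower, upper = ex$upper,
                           growth_id = "v1")
  sc <- new_scenario_set(ex$p,
                         growth_scenarios = matrix(ex$S_hat[, 1], nrow = 1),
                         delta = ex$delta, base_column = 1, network = net,
                         scenario_rows = list(ex$S_hat))
  assemble_socp_ramp(net, sc, M = M)
}

#' Linear chain network
#'
#' Uptake (capacity 10) -> A -> B -> biomass, with a gene-gated interior
#' step.  The FBA optimum equals the uptake capacity in closed form.
#'
#' @param uptake Uptake capacity (default 10 mmol/gDW/h).
#' @return A `metabolic_network` with growth reaction `GROWTH`.
#' @export
chain_network <- function(uptake = 10) {
  mets <- c("A", "B", "BIOMASS")
  rxns <- c("EX_glc", "T1", "GROWTH", "EX_biomass")
  S <- matrix(0, 3, 4, dimnames = list(mets, rxns))
  S["A", "EX_glc"] <- 1
  S["A", "T1"] <- -1; S["B", "T1"] <- 1
  S["B", "GROWTH"] <- -1; S["BIOMASS", "GROWTH"] <- 1
  S["BIOMASS", "EX_biomass"] <- -1
  metabolic_network(S, lower = c(0, 0, 0, 0),
                    upper = c(uptake, 1000, 1000, 1000),
                    growth_id = "GROWTH",
                    gpr = c("", "g1", "", ""), gene_ids = "g1")
}

#' Two-branch network with a knockout of intermediate severity
#'
#' Two parallel routes feed the biomass precursor: an unconstrained branch
#' gated by gene `gA` and a capacity-limited branch gated by `gB`.  With
#' branch capacity below half the uptake, knocking out `gA` cuts growth to
#' just under 50% of wild type, so the essentiality call of `gA` flips at a
#' closed-form uncertainty level — the transition probed by
#' [max_sigma_search()].
#'
#' @param branch_capacity Capacity of the `gB` branch (default 4.5).
#' @param uptake Uptake capacity (default 10).
#' @return A `metabolic_network`.
#' @export
parallel_path_network <- function(branch_capacity = 4.5, uptake = 10) {
  mets <- c("A", "B", "BIOMASS")
  rxns <- c("EX_glc", "P1", "P2", "GROWTH", "EX_biomass")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "EX_glc"] <- 1
  S["A", "P1"] <- -1; S["B", "P1"] <- 1
  S["A", "P2"] <- -1; S["B", "P2"] <- 1
  S["B", "GROWTH"] <- -1; S["BIOMASS", "GROWTH"] <- 1
  S["BIOMASS", "EX_biomass"] <- -1
  metabolic_network(S, lower = rep(0, 5),
                    upper = c(uptake, 1000, branch_capacity, 1000, 1000),
                    growth_id = "GROWTH",
                    gpr = c("", "gA", "gB", "", ""),
                    gene_ids = c("gA", "gB"))
}

#' Chain network with a freely exchangeable biomass component
#'
#' Extends [parallel_path_network()] with a mineral-like biomass component
#' `W` that is freely available in the environment and imported at no
#' energetic or metabolic burden.  Varying its biomass coefficient leaves
#' the rest of the flux pattern unchanged, so the robust and deterministic
#' essential-gene sets agree at any uncertainty level — the unbounded case
#' of the sigma search.
#'
#' @inheritParams parallel_path_network
#' @param w_coefficient Biomass coefficient of the free component
#'   (default -0.05).
#' @return A `metabolic_network`.
#' @export
free_uptake_network <- function(branch_capacity = 4.5, uptake = 10,
                                w_coefficient = -0.05) {
  mets <- c("A", "B", "W", "BIOMASS")
  rxns <- c("EX_glc", "P1", "P2", "EX_W", "GROWTH", "EX_biomass")
  S <- matrix(0, 4, 6, dimnames = list(mets, rxns))
  S["A", "EX_glc"] <- 1
  S["A", "P1"] <- -1; S["B", "P1"] <- 1
  S["A", "P2"] <- -1; S["B", "P2"] <- 1
  S["W", "EX_W"] <- -1
  S["B", "GROWTH"] <- -1; S["W", "GROWTH"] <- w_coefficient
  S["BIOMASS", "GROWTH"] <- 1
  S["BIOMASS", "EX_biomass"] <- -1
  metabolic_network(S, lower = c(0, 0, 0, -1000, 0, 0),
                    upper = c(uptake, 1000, branch_capacity, 1000, 1000, 1000),
                    growth_id = "GROWTH",
                    gpr = c("", "gA", "gB", "", "", ""),
                    gene_ids = c("gA", "gB"))
}

#' Seeded random metabolic network
#'
#' Deterministic per seed.  A backbone chain routes a capacity-10 uptake
#' through intermediates into a biomass reaction with non-integer
#' coefficients (1-6 decimal places, mimicking empirically determined
#' growth equations), guaranteeing a positive FBA optimum by construction.
#' Around the backbone: random integer-stoichiometry side reactions, some
#' reversible, a fixed-flux two-cycle (an ATP-maintenance-like implied
#' equality), and random GPR rules over a small gene set.
#'
#' @param n_metabolites,n_reactions Network size (small; at most 50 x 100).
#' @param seed Integer seed.
#' @param n_genes Size of the gene pool (default 6).
#' @return A `metabolic_network`.
#' @export
random_network <- function(n_metabolites = 8, n_reactions = 14, seed = 1,
                           n_genes = 6) {
  if (n_metabolites > 50 || n_reactions > 100)
    stop("random_network is meant for small fixtures (<= 50 x 100)")
  if (n_metabolites < 2 || n_reactions < n_metabolites + 1)
    stop("need at least 2 metabolites and n_metabolites + 1 reactions")
  for (attempt in 1:10) {
    net <- build_random_network(n_metabolites, n_reactions,
                                seed + (attempt - 1L) * 1000003L, n_genes)
    sol <- solve_fba(net)
    if (sol$status == "optimal" && sol$objective > 1e-6) return(net)
  }
  stop("failed to construct a feasible random network after 10 attempts")
}

build_random_network <- function(n_metabolites, n_reactions, seed, n_genes) {
  set.seed(seed)
  k <- n_metabolites - 1L  # backbone intermediates; last metabolite is biomass
  mets <- c(paste0("M", seq_len(k)), "BIOMASS")
  genes <- paste0("g", seq_len(n_genes))

  n_core <- k + 2L  # uptake + (k-1) chain steps + growth + biomass drain
  n_side <- n_reactions - n_core
  rxns <- c("EX_up", if (k > 1L) paste0("C", seq_len(k - 1L)),
            "GROWTH", "EX_biomass",
            if (n_side > 0) paste0("S", seq_len(n_side)))
  S <- matrix(0, n_metabolites, length(rxns), dimnames = list(mets, rxns))
  lower <- rep(0, length(rxns)); upper <- rep(1000, length(rxns))
  gpr <- rep("", length(rxns))

  S["M1", "EX_up"] <- 1; upper[1] <- 10
  random_rule <- function() {
    g <- sample(genes, 3)
    switch(sample(4, 1),
           g[1],
           paste(g[1], "and", g[2]),
           paste0("(", g[1], " and ", g[2], ") or ", g[3]),
           paste(g[1], "or", g[2]))
  }
  for (j in seq_len(k - 1L)) {
    id <- paste0("C", j)
    S[paste0("M", j), id] <- -1
    S[paste0("M", j + 1L), id] <- 1
    gpr[match(id, rxns)] <- random_rule()
    if (stats::runif(1) < 0.25) lower[match(id, rxns)] <- -1000
  }
  # biomass: drain the chain terminus plus a random subset of intermediates,
  # with decimal coefficients of 1..6 places
  dec_coef <- function(lo, hi) {
    d <- sample(1:6, 1)
    x <- 0
    while (x == 0) x <- round(stats::runif(1, lo, hi), d)
    x
  }
  S[paste0("M", k), "GROWTH"] <- -dec_coef(0.2, 2)
  extra <- if (k > 2) sample(seq_len(k - 1L), min(2, k - 2L)) else integer(0)
  for (i in extra) S[paste0("M", i), "GROWTH"] <- -dec_coef(0.001, 0.3)
  S["BIOMASS", "GROWTH"] <- 1
  S["BIOMASS", "EX_biomass"] <- -1

  if (n_side >= 2) {
    # fixed-flux two-cycle between two intermediates (maintenance-like)
    ij <- sample(seq_len(k), 2)
    a <- paste0("M", ij[1]); b <- paste0("M", ij[2])
    S[a, "S1"] <- -1; S[b, "S1"] <- 1
    S[b, "S2"] <- -1; S[a, "S2"] <- 1
    j1 <- match("S1", rxns)
    lower[j1] <- 1; upper[j1] <- 1
    for (j in seq(3, length.out = max(0, n_side - 2L))) {
      id <- paste0("S", j)
      ij <- sample(seq_len(k), 2)
      # never mass-creating: at least as much consumed as produced, and
      # only balanced (1:1) side reactions may run in reverse
      a <- sample(1:2, 1)
      S[paste0("M", ij[1]), id] <- -a
      S[paste0("M", ij[2]), id] <- 1
      jj <- match(id, rxns)
      if (a == 1 && stats::runif(1) < 0.4) lower[jj] <- -1000
      if (stats::runif(1) < 0.5) gpr[jj] <- random_rule()
    }
  } else if (n_side == 1) {
    ij <- sample(seq_len(k), 2)
    S[paste0("M", ij[1]), "S1"] <- -1
    S[paste0("M", ij[2]), "S1"] <- 1
  }

  metabolic_network(S, lower, upper, growth_id = "GROWTH", gpr = gpr,
                    gene_ids = genes)
}

#' Random essentiality labels with a known error rate
#'
#' Runs the deterministic FBA knockout screen to obtain ground truth, then
#' flips each label independently with probability `flip_rate`, so scored
#' confusion matrices have known expected cell counts.
#'
#' @param net A `metabolic_network`.
#' @param seed Integer seed for the flips.
#' @param flip_rate Per-gene flip probability in 0..1.
#' @param threshold Essentiality threshold for the truth screen.
#' @return A tibble with `gene_id` and `essential` (0/1).
#' @export
random_essentiality_labels <- function(net, seed = 1, flip_rate = 0,
                                       threshold = 0.5) {
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must lie in 0..1")
  screen <- screen_knockouts(net, method = "fba", threshold = threshold)
  truth <- screen$results$essential
  set.seed(seed)
  flip <- stats::runif(length(truth)) < flip_rate
  tibble::tibble(gene_id = screen$results$gene,
                 essential = as.integer(xor(truth, flip)))
}
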