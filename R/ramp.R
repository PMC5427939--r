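# Assembly and solution of the robust counterpart to FBA: scenario means,
# deviation matrices, the second-order-cone constraint system, its exact
# linearization when uncertainty is confined to the growth column, L1-minimal
# calibration of the steady-state deviation bounds M, feasibility audits, and
# the identical-components test for biologically possible scenarios.

#' Probability-weighted mean of scenario rows
#'
#' @param p Probability vector (length q).
#' @param S_hat q x n matrix whose k-th row is the k-th scenario of a
#'   stoichiometric row.
#' @return The length-n mean row `p' S_hat`.
#' @export
mean_row <- function(p, S_hat) {
  S_hat <- as.matrix(S_hat)
  if (length(p) != nrow(S_hat)) stop("shape error: length(p) != nrow(S_hat)")
  as.numeric(crossprod(p, S_hat))
}

#' Deviation matrix of a scenario family
#'
#' `R = delta * sqrt(P) (I - e p') S_hat`, so that `||R v||` equals `delta`
#' times the probability-weighted standard deviation of the scenario values
#' `S_k v`.
#'
#' @inheritParams mean_row
#' @param delta Standard-normal percentile scaling the standard deviation.
#' @return The q x n deviation matrix.
#' @export
#' @examples
#' ex <- toy_example()
#' deviation_matrix(ex$p, ex$S_hat, ex$delta)
deviation_matrix <- function(p, S_hat, delta) {
  S_hat <- as.matrix(S_hat)
  q <- nrow(S_hat)
  if (length(p) != q) stop("shape error: length(p) != nrow(S_hat)")
  if (delta <= 0) stop("delta must be positive")
  centered <- S_hat - tcrossprod(rep(1, q), mean_row(p, S_hat))
  delta * sqrt(p) * centered
}

#' Growth-column norm coefficient of a single-uncertain-column row
#'
#' When only the growth column of a row is uncertain, the cone norm
#' collapses to a scalar multiple of the growth flux:
#' `||R v|| = ||delta sqrt(P) (I - e p') s|| * v_Growth`, where `s` holds the
#' q scenario values of the growth coefficient.  This scalar is what the
#' linearized constraints use.
#'
#' @inheritParams deviation_matrix
#' @param s Length-q vector of growth-coefficient scenario values.
#' @return The nonnegative scalar norm coefficient.
#' @export
growth_norm_coefficient <- function(p, s, delta) {
  mu <- sum(p * s)
  delta * sqrt(sum(p * (s - mu)^2))
}

#' One member of the uncertainty set of a robust row
#'
#' Robust feasibility is equivalent to satisfying `S_i v <= M_i` for every
#' row in the set `{p' S_hat + u' R : ||u|| <= 1}`; this returns the member
#' selected by `u`.
#'
#' @inheritParams deviation_matrix
#' @param u Length-q direction with `||u|| <= 1`.
#' @return A length-n stoichiometric row.
#' @export
sample_uncertainty_constraint <- function(p, S_hat, delta, u) {
  if (sqrt(sum(u^2)) > 1 + 1e-12)
    stop("parameter error: ||u|| must be at most 1")
  R <- deviation_matrix(p, S_hat, delta)
  mean_row(p, S_hat) + as.numeric(crossprod(u, R))
}

# Reconstruct the q x n scenario row matrix for metabolite i: the base row
# with the growth coefficient replaced by its scenario values.
scenario_row_matrix <- function(scenarios, i) {
  if (!is.null(scenarios$scenario_rows)) return(scenarios$scenario_rows[[i]])
  base <- as.numeric(scenarios$base_S[i, ])
  rows <- matrix(rep(base, each = scenarios$q), nrow = scenarios$q)
  rows[, scenarios$base_column] <- scenarios$growth_scenarios[i, ]
  rows
}

ramp_mean_matrix <- function(scenarios) {
  m <- length(scenarios$metabolite_ids)
  if (!is.null(scenarios$scenario_rows)) {
    t(vapply(seq_len(m), function(i)
      mean_row(scenarios$probabilities, scenario_row_matrix(scenarios, i)),
      numeric(ncol(scenarios$base_S))))
  } else {
    Sbar <- as.matrix(scenarios$base_S)
    Sbar[, scenarios$base_column] <-
      as.numeric(scenarios$growth_scenarios %*% scenarios$probabilities)
    Sbar
  }
}

new_ramp_problem <- function(net, scenarios, M, form,
                             growth_norm = NULL, R_list = NULL) {
  m <- nrow(net$S)
  M <- rep_len(as.numeric(M), m)
  if (any(M < -1e-12)) stop("M must be nonnegative")
  M[M < 0] <- 0
  structure(
    list(network = net, scenarios = scenarios,
         mean_rows = ramp_mean_matrix(scenarios),
         growth_norm = growth_norm, R = R_list, M = M, form = form),
    class = "ramp_problem")
}

#' @export
print.ramp_problem <- function(x, ...) {
  cat("<ramp_problem> form: ", x$form, ", ", nrow(x$mean_rows),
      " robust rows, sum(M) = ", format(sum(x$M), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Assemble the linearized robust problem
#'
#' When scenario uncertainty is confined to the growth column and the growth
#' flux is nonnegative, each cone constraint collapses exactly to the linear
#' pair `p' S_hat v -/+ r_i v_Growth >= -M_i / <= M_i` with `r_i` the
#' growth-column norm coefficient.  This is the default computational path;
#' it solves with an ordinary simplex and is stable at scale.
#'
#' @param net A `metabolic_network`.
#' @param scenarios A `scenario_set` with growth-column uncertainty only.
#' @param M Nonnegative deviation bounds (scalar or length-m).
#' @return A `ramp_problem` of linear form.
#' @export
assemble_linear_ramp <- function(net, scenarios, M) {
  if (!is.null(scenarios$scenario_rows))
    stop("unsupported structure: scenarios vary outside the growth column; ",
         "use assemble_socp_ramp()")
  if (net$lower[net$growth_index] < 0)
    stop("the linearized path requires a nonnegative growth flux ",
         "(L_Growth >= 0); use assemble_socp_ramp()")
  p <- scenarios$probabilities
  r <- vapply(seq_len(nrow(net$S)), function(i)
    growth_norm_coefficient(p, scenarios$growth_scenarios[i, ],
                            scenarios$delta), numeric(1))
  new_ramp_problem(net, scenarios, M, form = "linear", growth_norm = r)
}

#' Assemble the cone-form robust problem
#'
#' The full second-order-cone system
#' `||R_i v|| - M_i <= p' S_hat_i v <= M_i - ||R_i v||`, `L <= v <= U`.
#' Solved by outer approximation over the uncertainty set; intended for
#' small instances, worked examples, and as a cross-check of the linearized
#' path.
#'
#' @inheritParams assemble_linear_ramp
#' @return A `ramp_problem` of cone form.
#' @export
assemble_socp_ramp <- function(net, scenarios, M) {
  p <- scenarios$probabilities
  R_list <- lapply(seq_len(nrow(net$S)), function(i)
    deviation_matrix(p, scenario_row_matrix(scenarios, i), scenarios$delta))
  new_ramp_problem(net, scenarios, M, form = "socp", R_list = R_list)
}

linear_ramp_constraints <- function(problem) {
  A_mean <- problem$mean_rows
  m <- nrow(A_mean); n <- ncol(A_mean)
  g <- problem$network$growth_index
  A_lo <- A_mean; A_lo[, g] <- A_lo[, g] - problem$growth_norm
  A_up <- A_mean; A_up[, g] <- A_up[, g] + problem$growth_norm
  list(A = rbind(A_lo, A_up),
       dir = c(rep(">=", m), rep("<=", m)),
       rhs = c(-problem$M, problem$M))
}

solve_ramp_linear <- function(problem, objective = NULL, maximize = TRUE) {
  net <- problem$network
  n <- ncol(net$S)
  if (is.null(objective)) {
    objective <- numeric(n); objective[net$growth_index] <- 1
  }
  cons <- linear_ramp_constraints(problem)
  lp_solve(objective, cons$A, cons$dir, cons$rhs, net$lower, net$upper,
           maximize = maximize)
}

# Outer approximation of the cone system: start from the relaxed interval
# constraints -M <= mean v <= M, then repeatedly cut with the most violated
# member of each row's uncertainty set (u aligned with R v / ||R v||) until
# the incumbent satisfies every cone constraint.
solve_ramp_socp <- function(problem, objective = NULL, maximize = TRUE,
                            tol = 1e-9, max_iter = 500) {
  net <- problem$network
  n <- ncol(net$S); m <- nrow(problem$mean_rows)
  if (is.null(objective)) {
    objective <- numeric(n); objective[net$growth_index] <- 1
  }
  A <- rbind(problem$mean_rows, -problem$mean_rows)
  rhs <- c(problem$M, problem$M)
  for (iter in seq_len(max_iter)) {
    res <- lp_solve(objective, A, rep("<=", nrow(A)), rhs,
                    net$lower, net$upper, maximize = maximize)
    if (res$status != "optimal") return(res)
    v <- res$x
    violated <- FALSE
    for (i in seq_len(m)) {
      Rv <- as.numeric(problem$R[[i]] %*% v)
      dev <- sqrt(sum(Rv^2))
      if (dev <= tol) next
      u <- Rv / dev
      cut <- as.numeric(crossprod(u, problem$R[[i]]))
      mu <- sum(problem$mean_rows[i, ] * v)
      if (mu + dev > problem$M[i] + tol) {
        A <- rbind(A, problem$mean_rows[i, ] + cut)
        rhs <- c(rhs, problem$M[i])
        violated <- TRUE
      }
      if (-mu + dev > problem$M[i] + tol) {
        A <- rbind(A, -problem$mean_rows[i, ] + cut)
        rhs <- c(rhs, problem$M[i])
        violated <- TRUE
      }
    }
    if (!violated) return(res)
  }
  list(status = "numeric_failure", x = rep(NA_real_, n), objective = NA_real_)
}

#' Solve an assembled robust problem
#'
#' Maximizes the growth flux over the robust constraint system.  The linear
#' form solves one LP; the cone form runs the outer-approximation loop.
#'
#' @param problem A `ramp_problem`.
#' @return A [flux_state].
#' @export
#' @examples
#' net <- chain_network()
#' sc <- build_model3(net, sigma = 0.2)
#' M <- fit_M(net, sc)
#' solve_ramp(assemble_linear_ramp(net, sc, M$M))
solve_ramp <- function(problem) {
  res <- if (problem$form == "linear") solve_ramp_linear(problem)
         else solve_ramp_socp(problem)
  flux_state(stats::setNames(res$x, problem$network$reaction_ids),
             res$objective, res$status)
}

#' Calibrate the deviation bounds M by L1 minimization
#'
#' Solves `min ||M||_1` subject to the robust constraints, `v_Growth >=
#' gamma_star`, the flux bounds, and `M >= 0`, jointly in `(v, M)`.  Setting
#' M to this optimum tightens the robust constraints as far as possible
#' while holding the growth rate at the FBA target.
#'
#' @param net A `metabolic_network`.
#' @param scenarios A `scenario_set` (growth-column uncertainty).
#' @param gamma_star Target growth rate; defaults to the FBA optimum of
#'   `net`.
#' @param m_cap Upper bound placed on each M_i inside the LP; by default
#'   scaled to comfortably exceed any attainable deviation at the given
#'   scenario spread and flux bounds.
#' @return An object of class `m_fit`: list with `M` (named vector), `v`
#'   (the certifying flux vector), `gamma_star` and `status`
#'   (`"infeasible"` when the target growth is unattainable).
#' @export
fit_M <- function(net, scenarios, gamma_star = NULL, m_cap = NULL) {
  fba <- solve_fba(net)
  if (fba$status != "optimal")
    stop("screen error: FBA on the supplied network is ", fba$status)
  if (is.null(gamma_star)) {
    gamma_star <- fba$objective
  } else if (gamma_star > fba$objective * (1 + 1e-9) + 1e-12) {
    # precondition: the target must be attainable on the mean system;
    # larger targets could only be bought with spurious steady-state slack
    return(structure(list(M = stats::setNames(rep(NA_real_, nrow(net$S)),
                                              net$metabolite_ids),
                          v = stats::setNames(rep(NA_real_, ncol(net$S)),
                                              net$reaction_ids),
                          gamma_star = gamma_star, status = "infeasible"),
                     class = "m_fit"))
  }
  problem <- assemble_linear_ramp(net, scenarios, M = 0)
  if (is.null(m_cap)) {
    vmax <- max(abs(c(net$lower, net$upper)), 1)
    m_cap <- max(1e6, 100 * max(problem$growth_norm) * vmax)
  }
  cons <- linear_ramp_constraints(problem)
  m <- nrow(net$S); n <- ncol(net$S)
  # variables (v, M); robust rows move M to the constraint matrix
  A_v <- cons$A
  A_M <- rbind(diag(m), -diag(m))  # lower rows get +M_i, upper rows -M_i
  A <- cbind(A_v, A_M)
  dir <- rep(">=", 2 * m)          # lower: >= 0 ; upper rewritten as >= form
  A[cons$dir == "<=", ] <- -A[cons$dir == "<=", ]
  rhs <- rep(0, 2 * m)
  grow <- c(numeric(n), numeric(m)); grow[net$growth_index] <- 1
  A <- rbind(A, grow); dir <- c(dir, ">="); rhs <- c(rhs, gamma_star)
  obj <- c(numeric(n), rep(1, m))
  res <- lp_solve(obj, A, dir, rhs,
                  lower = c(net$lower, rep(0, m)),
                  upper = c(net$upper, rep(m_cap, m)),
                  maximize = FALSE)
  v <- res$x[seq_len(n)]
  M <- res$x[n + seq_len(m)]
  if (res$status == "optimal") {
    # Recompute M from the certifying flux vector: the minimal bound for v
    # is |mean_i v| + r_i v_Growth exactly, which removes LP-level rounding
    # in M.  The binding rows have dual prices on the order of 1/r_i, so
    # that rounding would otherwise be amplified into the growth rate.
    mu <- as.numeric(problem$mean_rows %*% v)
    M_needed <- abs(mu) + problem$growth_norm * v[net$growth_index]
    M <- pmin(M_needed * (1 + 1e-12), m_cap)
  }
  structure(list(M = stats::setNames(M, net$metabolite_ids),
                 v = stats::setNames(v, net$reaction_ids),
                 gamma_star = gamma_star, status = res$status),
            class = "m_fit")
}

#' @export
print.m_fit <- function(x, ...) {
  cat("<m_fit> status: ", x$status, sep = "")
  if (identical(x$status, "optimal"))
    cat(", ||M||_1 = ", format(sum(x$M), digits = 6),
        ", gamma* = ", format(x$gamma_star, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy the fitted deviation bounds
#'
#' @param x An `m_fit`.
#' @param ... Unused.
#' @return A tibble with `metabolite` and `M`.
#' @export
tidy.m_fit <- function(x, ...) {
  tibble::tibble(metabolite = names(x$M), M = as.numeric(x$M))
}

row_deviation <- function(problem, v) {
  if (problem$form == "linear") {
    g <- problem$network$growth_index
    problem$growth_norm * abs(v[g])
  } else {
    vapply(problem$R, function(R) sqrt(sum(as.numeric(R %*% v)^2)), numeric(1))
  }
}

#' Audit a flux vector against the robust constraints
#'
#' For each metabolite row, reports the mean value `mu = p' S_hat v`, the
#' deviation `||R v||`, and the two slacks of
#' `||R v|| - M <= mu <= M - ||R v||`; the vector is feasible when every
#' slack is above `-tolerance` and the flux bounds hold.
#'
#' @param v Flux vector (length n).
#' @param problem A `ramp_problem`.
#' @param tolerance Absolute slack tolerance (default 1e-9).
#' @return A `constraint_audit`: tibble with per-row columns `metabolite`,
#'   `mu`, `deviation`, `lower_slack`, `upper_slack`, `feasible`, and an
#'   overall `feasible` attribute (also via [is_feasible()]).
#' @export
audit_feasibility <- function(v, problem, tolerance = 1e-9) {
  v <- as.numeric(v)
  if (length(v) != ncol(problem$mean_rows))
    stop("flux vector length does not match the problem")
  mu <- as.numeric(problem$mean_rows %*% v)
  dev <- row_deviation(problem, v)
  lower_slack <- mu - (dev - problem$M)
  upper_slack <- (problem$M - dev) - mu
  rows_ok <- lower_slack >= -tolerance & upper_slack >= -tolerance
  net <- problem$network
  bounds_ok <- all(v >= net$lower - tolerance) && all(v <= net$upper + tolerance)
  out <- tibble::tibble(metabolite = problem$scenarios$metabolite_ids,
                        mu = mu, deviation = dev,
                        lower_slack = lower_slack, upper_slack = upper_slack,
                        feasible = rows_ok)
  attr(out, "feasible") <- all(rows_ok) && bounds_ok
  attr(out, "bounds_ok") <- bounds_ok
  class(out) <- c("constraint_audit", class(out))
  out
}

#' Overall verdict of a constraint audit
#'
#' @param audit A `constraint_audit` from [audit_feasibility()].
#' @return Logical scalar.
#' @export
is_feasible <- function(audit) isTRUE(attr(audit, "feasible"))

#' Test whether scenarios are biologically possible for a flux state
#'
#' A scenario family is biologically possible for an optimal flux vector
#' `v_hat` exactly when, row by row, all q scenario values `S_ik v_hat`
#' (restricted to the nonzero fluxes) coincide — i.e. `S'_i v' = alpha_i e`.
#' Rows whose scenario values differ admit no probability assignment that
#' keeps `v_hat` optimal as the chance constraints tighten.  The common
#' value `alpha_i` is reported; rows with `alpha_i` near zero are flagged
#' rather than rejected, since steady-state feasibility of the mean system
#' itself forces `alpha_i = 0`.
#'
#' @param scenarios A `scenario_set`.
#' @param v_hat Candidate flux vector.
#' @param tolerance Equality tolerance on the scenario values (default 1e-8).
#' @return A tibble with `metabolite`, `possible`, `alpha`,
#'   `alpha_near_zero`.
#' @export
biologically_possible <- function(scenarios, v_hat, tolerance = 1e-8) {
  v_hat <- as.numeric(v_hat)
  nz <- which(abs(v_hat) > 0)
  m <- length(scenarios$metabolite_ids)
  vals <- vapply(seq_len(m), function(i) {
    rows <- scenario_row_matrix(scenarios, i)
    as.numeric(rows[, nz, drop = FALSE] %*% v_hat[nz])
  }, numeric(scenarios$q))
  vals <- matrix(vals, nrow = scenarios$q)
  spread <- apply(vals, 2, function(x) max(x) - min(x))
  alpha <- colMeans(vals)
  tibble::tibble(metabolite = scenarios$metabolite_ids,
                 possible = spread <= tolerance,
                 alpha = alpha,
                 alpha_near_zero = abs(alpha) <= tolerance)
}
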