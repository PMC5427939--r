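# Independent brute-force oracles used to cross-check the package's
# optimization layer.  These deliberately share no code with the
# implementation: the LP oracle enumerates basic vertices, the QP oracle
# enumerates active sets of the KKT system.

# Maximize c'x s.t. A x (dir) rhs, lower <= x <= upper by enumerating all
# vertices (intersections of n constraint hyperplanes).  Exponential: only
# for tiny instances.
lp_vertex_oracle <- function(objective, A, dir, rhs, lower, upper,
                             maximize = TRUE, tol = 1e-8) {
  n <- length(objective)
  A_all <- rbind(as.matrix(A), diag(n), diag(n))
  rhs_all <- c(rhs, lower, upper)
  dir_all <- c(dir, rep(">=", n), rep("<=", n))
  m <- nrow(A_all)
  feasible <- function(x) {
    lhs <- as.numeric(A_all %*% x)
    all(ifelse(dir_all == "<=", lhs <= rhs_all + tol,
               ifelse(dir_all == ">=", lhs >= rhs_all - tol,
                      abs(lhs - rhs_all) <= tol)))
  }
  best <- NULL; best_val <- if (maximize) -Inf else Inf
  for (rows in utils::combn(m, n, simplify = FALSE)) {
    B <- A_all[rows, , drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    x <- tryCatch(solve(B, rhs_all[rows]), error = function(e) NULL)
    if (is.null(x) || !feasible(x)) next
    val <- sum(objective * x)
    if ((maximize && val > best_val) || (!maximize && val < best_val)) {
      best_val <- val; best <- x
    }
  }
  list(x = best, objective = best_val,
       status = if (is.null(best)) "infeasible" else "optimal")
}

# Minimize 0.5 x'D x - d'x s.t. A_eq x = b_eq, A_in x >= b_in by
# enumerating active subsets of the inequalities and solving each KKT
# system.  Exponential: tiny instances only.
qp_kkt_oracle <- function(D, d, A_eq = NULL, b_eq = NULL,
                          A_in = NULL, b_in = NULL, tol = 1e-8) {
  n <- length(d)
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  if (is.null(A_in)) { A_in <- matrix(0, 0, n); b_in <- numeric(0) }
  m_in <- nrow(A_in)
  best <- NULL; best_val <- Inf
  for (k in 0:m_in) for (act in utils::combn(m_in, k, simplify = FALSE)) {
    Aa <- rbind(A_eq, A_in[act, , drop = FALSE])
    ba <- c(b_eq, b_in[act])
    # stationarity: D x - d - Aa' mu = 0 with mu >= 0 on active inequalities
    K <- rbind(cbind(D, -t(Aa)),
               cbind(Aa, matrix(0, nrow(Aa), nrow(Aa))))
    sol <- tryCatch(solve(K, c(d, ba)), error = function(e) NULL)
    if (is.null(sol)) next
    x <- sol[seq_len(n)]
    mult <- sol[-seq_len(n)]
    mu <- if (nrow(A_eq) < length(mult))
      mult[(nrow(A_eq) + 1):length(mult)] else numeric(0)
    if (length(mu) && any(mu < -tol)) next
    if (m_in > length(act)) {
      inact <- setdiff(seq_len(m_in), act)
      if (any(as.numeric(A_in[inact, , drop = FALSE] %*% x) <
              b_in[inact] - tol)) next
    }
    val <- 0.5 * sum(x * (D %*% x)) - sum(d * x)
    if (val < best_val - 1e-12) { best_val <- val; best <- x }
  }
  list(x = best, objective = best_val,
       status = if (is.null(best)) "infeasible" else "optimal")
}

# Evaluate a GPR rule string through R's own parser as an independent
# boolean oracle: genes become logical variables.
gpr_eval_via_r <- function(rule, knocked_out, genes) {
  txt <- gsub("\\band\\b", "&", rule, ignore.case = TRUE)
  txt <- gsub("\\bor\\b", "|", txt, ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% knocked_out), envir = env)
  eval(parse(text = txt), envir = env)
}

# Random GPR rule tree over the given genes, rendered as a string.
random_gpr_rule <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  left <- random_gpr_rule(genes, depth - 1)
  right <- random_gpr_rule(genes, depth - 1)
  paste0("(", left, " ", op, " ", right, ")")
}
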