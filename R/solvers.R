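# Thin LP / QP layer used by every optimization in the package.
#
# LPs are solved by a dense two-phase simplex written here: the robust
# constraint systems are heavily degenerate (paired rows, implied
# equalities), which calls for explicit pivot tolerances and an
# anti-cycling fallback.  General box-constrained problems are shifted onto
# standard form (x >= 0, nonnegative right-hand sides) first.  QPs go
# through quadprog::solve.QP().  Both wrappers report a status instead of
# raising on infeasibility, so callers can propagate solver outcomes.

# Two-phase tableau simplex for min c'x s.t. A x (dir) b, x >= 0, b >= 0.
# Dantzig pricing with a switch to Bland's rule after `bland_after`
# iterations guarantees termination on degenerate problems.  The tableau is
# periodically refactorized from the original columns (and always before an
# optimality claim is accepted), which stops the error accumulated across
# rank-one updates from corrupting the pricing step.
simplex_core <- function(cc, A, dir, b, max_iter = 10000L,
                         pivtol = 1e-9, bland_after = 500L,
                         refac_every = 40L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(b >= 0))
  n_slack <- sum(dir != "==")
  art_rows <- which(dir != "<=")
  n_art <- length(art_rows)
  ncol_T <- n + n_slack + n_art
  Tb <- matrix(0, m, ncol_T)
  Tb[, seq_len(n)] <- A
  basis <- integer(m)
  sj <- n
  for (i in seq_len(m)) {
    if (dir[i] == "<=") { sj <- sj + 1L; Tb[i, sj] <- 1; basis[i] <- sj }
    else if (dir[i] == ">=") { sj <- sj + 1L; Tb[i, sj] <- -1 }
  }
  aj <- n + n_slack
  for (i in art_rows) { aj <- aj + 1L; Tb[i, aj] <- 1; basis[i] <- aj }
  rhs <- b
  orig <- Tb  # unpivoted columns, used for refactorization

  # recompute (Tb, rhs) = B^{-1} (orig, b) for the current basis
  refactor <- function(Tb, rhs, basis) {
    B <- orig[, basis, drop = FALSE]
    out <- tryCatch(solve(B, cbind(orig, b)), error = function(e) NULL)
    if (is.null(out) || anyNA(out) || any(!is.finite(out)))
      return(list(Tb = Tb, rhs = rhs, fresh = FALSE))
    new_rhs <- out[, ncol_T + 1L]
    if (any(new_rhs < -1e-7)) return(list(Tb = Tb, rhs = rhs, fresh = FALSE))
    list(Tb = out[, seq_len(ncol_T), drop = FALSE],
         rhs = pmax(new_rhs, 0), fresh = TRUE)
  }

  run_phase <- function(costs, Tb, rhs, basis, allowed) {
    it <- 0L
    fresh <- TRUE  # tableau exact for the current basis?
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(ok = FALSE, Tb = Tb, rhs = rhs, basis = basis))
      if (!fresh && it %% refac_every == 0L) {
        rf <- refactor(Tb, rhs, basis)
        Tb <- rf$Tb; rhs <- rf$rhs; fresh <- rf$fresh
      }
      cb <- costs[basis]
      # reduced costs: c_j - cb' Tb[, j]
      red <- costs - as.numeric(crossprod(cb, Tb))
      red[basis] <- 0
      cand <- which(red < -pivtol & allowed)
      if (!length(cand)) {
        if (!fresh) {  # re-verify the optimality claim on an exact tableau
          rf <- refactor(Tb, rhs, basis)
          Tb <- rf$Tb; rhs <- rf$rhs
          if (rf$fresh) { fresh <- TRUE; next }
        }
        return(list(ok = TRUE, Tb = Tb, rhs = rhs, basis = basis))
      }
      q <- if (it > bland_after) cand[1] else cand[which.min(red[cand])]
      col <- Tb[, q]
      pos <- which(col > pivtol)
      if (!length(pos)) return(list(ok = NA, Tb = Tb, rhs = rhs, basis = basis))
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + 1e-12]
      p <- ties[which.min(basis[ties])]  # Bland tie-break on leaving index
      piv <- Tb[p, q]
      Tb[p, ] <- Tb[p, ] / piv
      rhs[p] <- rhs[p] / piv
      other <- setdiff(seq_len(nrow(Tb)), p)
      f <- Tb[other, q]
      Tb[other, ] <- Tb[other, ] - tcrossprod(f, Tb[p, ])
      rhs[other] <- rhs[other] - f * rhs[p]
      rhs[rhs < 0 & rhs > -1e-11] <- 0
      basis[p] <- q
      fresh <- FALSE
    }
  }

  if (n_art > 0) {
    costs1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- run_phase(costs1, Tb, rhs, basis, allowed = rep(TRUE, ncol_T))
    if (!isTRUE(ph1$ok)) return(list(status = "numeric_failure"))
    Tb <- ph1$Tb; rhs <- ph1$rhs; basis <- ph1$basis
    obj1 <- sum(rhs[basis > n + n_slack])
    if (obj1 > 1e-7) return(list(status = "infeasible"))
    # pivot remaining artificials out of the basis where possible
    for (i in which(basis > n + n_slack)) {
      row <- Tb[i, seq_len(n + n_slack)]
      j <- which(abs(row) > pivtol)[1]
      if (!is.na(j)) {
        piv <- Tb[i, j]
        Tb[i, ] <- Tb[i, ] / piv; rhs[i] <- rhs[i] / piv
        other <- setdiff(seq_len(m), i)
        f <- Tb[other, j]
        Tb[other, ] <- Tb[other, ] - tcrossprod(f, Tb[i, ])
        rhs[other] <- rhs[other] - f * rhs[i]
        basis[i] <- j
      }
    }
  }
  allowed <- c(rep(TRUE, n + n_slack), rep(FALSE, n_art))
  costs2 <- c(cc, rep(0, n_slack + n_art))
  ph2 <- run_phase(costs2, Tb, rhs, basis, allowed)
  if (is.na(ph2$ok)) return(list(status = "unbounded"))
  if (!isTRUE(ph2$ok)) return(list(status = "numeric_failure"))
  x <- numeric(ncol_T)
  x[ph2$basis] <- ph2$rhs
  list(status = "optimal", x = x[seq_len(n)],
       objective = sum(cc * x[seq_len(n)]))
}

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) `objective %*% x` subject to linear constraints
#' `A x (dir) rhs` and finite box bounds `lower <= x <= upper`.
#'
#' @param objective Numeric objective vector (length n).
#' @param A Constraint matrix (rows are constraints; may be a sparse
#'   [Matrix::Matrix]).
#' @param dir Character vector of constraint directions, one of `"<="`,
#'   `">="`, `"=="` per row.
#' @param rhs Numeric right-hand sides.
#' @param lower,upper Finite variable bounds.
#' @param maximize Maximize (`TRUE`, default) or minimize.
#' @param n_iter Simplex iteration cap.
#'
#' @return A list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"numeric_failure"`), `x` (primal solution, `NA` unless optimal) and
#'   `objective` (attained value).
#' @keywords internal
lp_solve <- function(objective, A, dir, rhs, lower, upper,
                     maximize = TRUE, n_iter = NULL) {
  A <- as.matrix(A)
  n <- length(objective)
  stopifnot(ncol(A) == n, nrow(A) == length(rhs), length(dir) == length(rhs),
            length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("lp_solve requires finite variable bounds")
  if (any(lower > upper + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # shift to y = x - lower >= 0
  rhs_s <- rhs - as.numeric(A %*% lower)
  ub <- upper - lower
  A_all <- rbind(A, diag(n))
  dir_all <- c(dir, rep("<=", n))
  rhs_all <- c(rhs_s, ub)

  # the standard-form core needs nonnegative right-hand sides: flip rows
  neg <- rhs_all < 0
  A_all[neg, ] <- -A_all[neg, , drop = FALSE]
  rhs_all[neg] <- -rhs_all[neg]
  dir_all[neg] <- ifelse(dir_all[neg] == "<=", ">=",
                         ifelse(dir_all[neg] == ">=", "<=", "=="))

  if (is.null(n_iter)) n_iter <- 200L * (n + nrow(A_all) + 20L)
  cc <- if (maximize) -objective else objective
  res <- simplex_core(cc, A_all, dir_all, rhs_all, max_iter = n_iter)
  if (res$status != "optimal")
    return(list(status = res$status, x = rep(NA_real_, n), objective = NA_real_))
  x <- res$x + lower
  list(status = "optimal", x = x, objective = sum(objective * x))
}

#' Solve a convex quadratic program
#'
#' Minimizes `0.5 x' D x - d' x` subject to `A_eq x = b_eq` and
#' `A_in x >= b_in` via [quadprog::solve.QP()].  `D` must be positive
#' definite; callers with semidefinite objectives add a documented ridge.
#'
#' @param D Positive-definite quadratic coefficient matrix.
#' @param d Linear coefficient vector.
#' @param A_eq,b_eq Equality constraints (may have zero rows).
#' @param A_in,b_in Inequality constraints `A_in x >= b_in`.
#'
#' @return A list with `status`, `x` and `objective`
#'   (the attained `0.5 x'Dx - d'x`).
#' @keywords internal
qp_solve <- function(D, d, A_eq = NULL, b_eq = NULL, A_in = NULL, b_in = NULL) {
  n <- length(d)
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  if (is.null(A_in)) { A_in <- matrix(0, 0, n); b_in <- numeric(0) }
  A_eq <- as.matrix(A_eq); A_in <- as.matrix(A_in)
  Amat <- t(rbind(A_eq, A_in))
  bvec <- c(b_eq, b_in)
  res <- tryCatch(
    quadprog::solve.QP(Dmat = D, dvec = d, Amat = Amat, bvec = bvec,
                       meq = nrow(A_eq)),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    status <- if (grepl("inconsistent|no solution", conditionMessage(res)))
      "infeasible" else "numeric_failure"
    return(list(status = status, x = rep(NA_real_, n), objective = NA_real_))
  }
  list(status = "optimal", x = res$solution, objective = res$value)
}
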