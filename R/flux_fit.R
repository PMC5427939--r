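# Quadratic fitting of model fluxes to experimentally measured fluxes,
# under either the robust constraint system or strict steady state, plus
# mean-square-error scoring.

check_measurements <- function(net, measurements) {
  if (!all(c("reaction_id", "flux") %in% names(measurements)))
    stop("measurements need columns 'reaction_id' and 'flux'")
  idx <- match(as.character(measurements$reaction_id), net$reaction_ids)
  if (anyNA(idx))
    stop("measurement reaction(s) not in the network: ",
         paste(measurements$reaction_id[is.na(idx)], collapse = ", "))
  list(idx = idx, target = as.numeric(measurements$flux))
}

# Shared QP: min sum over measured coordinates of (v_j - target_j)^2,
# subject to the supplied linear system, a growth floor, and bounds.
# Unmeasured coordinates carry a 1e-10 ridge so the quadratic form is
# positive definite (quadprog requirement); among degenerate optima this
# acts as a minimal-norm tie-break and perturbs the objective by < 1e-7
# at the bound magnitudes used here.
flux_fit_qp <- function(net, A_eq, b_eq, A_in, b_in, idx, target, theta,
                        gamma_star) {
  n <- ncol(net$S)
  w <- rep(1e-10, n); w[idx] <- 1
  tvec <- numeric(n); tvec[idx] <- target
  D <- diag(2 * w)
  d <- 2 * w * tvec
  grow <- numeric(n); grow[net$growth_index] <- 1
  A_in_all <- rbind(A_in, grow, diag(n), -diag(n))
  b_in_all <- c(b_in, theta * gamma_star, net$lower, -net$upper)
  res <- qp_solve(D, d, A_eq, b_eq, A_in_all, b_in_all)
  if (res$status != "optimal")
    return(flux_state(stats::setNames(rep(NA_real_, n), net$reaction_ids),
                      NA_real_, res$status))
  v <- stats::setNames(res$x, net$reaction_ids)
  flux_state(v, sum((v[idx] - target)^2), "optimal")
}

#' Fit fluxes to measurements under the robust constraints
#'
#' Minimizes the squared distance between the model fluxes and the measured
#' fluxes (summed over the measured reactions only) subject to the
#' linearized robust constraint system, a growth floor `v_Growth >= theta *
#' gamma_star`, and the flux bounds.  M defaults to the L1-minimal
#' calibration at the FBA optimum; scenarios default to the proportional
#' model with `sigma = 0.2`.
#'
#' @param net A `metabolic_network`.
#' @param measurements Data frame with columns `reaction_id`, `flux`, and
#'   optionally `sd` (accepted, unused in the default unweighted objective).
#' @param scenarios A `scenario_set`; default `build_model3(net, 0.2)`.
#' @param M Deviation bounds; `NULL` fits them at the FBA optimum.
#' @param theta Growth floor as a fraction of the FBA optimum (default
#'   0.9, reflecting that measured cultures need not be fully optimized).
#' @return A [flux_state] whose `objective` is the attained squared
#'   distance over measured coordinates.
#' @export
fit_fluxes_ramp <- function(net, measurements, scenarios = NULL, M = NULL,
                            theta = 0.9) {
  meas <- check_measurements(net, measurements)
  if (is.null(scenarios)) scenarios <- build_model3(net, sigma = 0.2)
  fba <- solve_fba(net)
  if (fba$status != "optimal") stop("FBA on the network is ", fba$status)
  gamma_star <- fba$objective
  if (is.null(M)) {
    fit <- fit_M(net, scenarios, gamma_star = gamma_star)
    if (fit$status != "optimal") stop("M calibration is ", fit$status)
    M <- fit$M
  }
  problem <- assemble_linear_ramp(net, scenarios, M)
  cons <- linear_ramp_constraints(problem)
  A_in <- cons$A
  A_in[cons$dir == "<=", ] <- -A_in[cons$dir == "<=", ]
  b_in <- ifelse(cons$dir == "<=", -cons$rhs, cons$rhs)
  flux_fit_qp(net, A_eq = NULL, b_eq = NULL, A_in = A_in, b_in = b_in,
              idx = meas$idx, target = meas$target, theta = theta,
              gamma_star = gamma_star)
}

#' Fit fluxes to measurements under strict steady state
#'
#' As [fit_fluxes_ramp()] but with the deterministic constraint `S v = 0`.
#'
#' @inheritParams fit_fluxes_ramp
#' @return A [flux_state].
#' @export
fit_fluxes_fba <- function(net, measurements, theta = 0.9) {
  meas <- check_measurements(net, measurements)
  fba <- solve_fba(net)
  if (fba$status != "optimal") stop("FBA on the network is ", fba$status)
  flux_fit_qp(net, A_eq = as.matrix(net$S), b_eq = rep(0, nrow(net$S)),
              A_in = NULL, b_in = NULL,
              idx = meas$idx, target = meas$target, theta = theta,
              gamma_star = fba$objective)
}

#' Mean square error of a fitted flux state
#'
#' `MSE = ||v_predicted - v_measured||^2 / N` over the N measured
#' reactions.
#'
#' @param fitted A [flux_state] with named fluxes.
#' @param measurements Data frame with `reaction_id` and `flux`.
#' @return The scalar MSE.
#' @export
mse <- function(fitted, measurements) {
  ids <- as.character(measurements$reaction_id)
  common <- ids %in% names(fitted$v)
  if (!any(common)) stop("scoring error: no overlapping reactions")
  resid <- fitted$v[ids[common]] - as.numeric(measurements$flux)[common]
  sum(resid^2) / sum(common)
}

#' Side-by-side fit of measurements under both constraint systems
#'
#' Convenience wrapper running [fit_fluxes_fba()] and [fit_fluxes_ramp()]
#' and reporting both MSEs and their ratio (robust MSE / FBA MSE).
#'
#' @inheritParams fit_fluxes_ramp
#' @return A list with `ramp`, `fba` (flux states), `comparison` (tibble of
#'   measured vs fitted fluxes), `mse_ramp`, `mse_fba`, `relative_mse`.
#' @export
compare_flux_fits <- function(net, measurements, scenarios = NULL, M = NULL,
                              theta = 0.9) {
  fr <- fit_fluxes_ramp(net, measurements, scenarios = scenarios, M = M,
                        theta = theta)
  ff <- fit_fluxes_fba(net, measurements, theta = theta)
  ids <- as.character(measurements$reaction_id)
  comparison <- tibble::tibble(
    reaction_id = ids,
    measured = as.numeric(measurements$flux),
    fba_fit = as.numeric(ff$v[ids]),
    ramp_fit = as.numeric(fr$v[ids]))
  mse_ramp <- mse(fr, measurements)
  mse_fba <- mse(ff, measurements)
  list(ramp = fr, fba = ff, comparison = comparison,
       mse_ramp = mse_ramp, mse_fba = mse_fba,
       relative_mse = mse_ramp / mse_fba)
}
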