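#' Flux state constructor
#'
#' @param v Named flux vector.
#' @param objective Attained objective value.
#' @param status One of `"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"numeric_failure"`.
#' @return An object of class `flux_state`.
#' @keywords internal
flux_state <- function(v, objective, status) {
  structure(list(v = v, objective = objective, status = status),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status: ", x$status, sep = "")
  if (identical(x$status, "optimal"))
    cat(", objective: ", format(x$objective, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux state into a tibble of fluxes
#'
#' @param x A `flux_state`.
#' @param ... Unused.
#' @return A tibble with columns `reaction_id` and `flux`.
#' @export
tidy.flux_state <- function(x, ...) {
  tibble::tibble(reaction_id = names(x$v), flux = as.numeric(x$v))
}

#' One-row summary of a flux state
#'
#' @param x A `flux_state`.
#' @param ... Unused.
#' @return A one-row tibble with `objective` and `status`.
#' @export
glance.flux_state <- function(x, ...) {
  tibble::tibble(objective = x$objective, status = x$status)
}

#' Solve the flux balance analysis linear program
#'
#' Maximizes the growth flux subject to steady state (`S v = 0`) and the flux
#' bounds: `max { v_Growth : S v = 0, L <= v <= U }`.
#'
#' @param net A `metabolic_network`.
#' @return A [flux_state]; infeasibility is reported in `status`, never
#'   raised.
#' @export
#' @examples
#' solve_fba(chain_network())$objective  # 10, the uptake limit
solve_fba <- function(net) {
  n <- ncol(net$S)
  obj <- numeric(n); obj[net$growth_index] <- 1
  res <- lp_solve(obj, net$S, rep("==", nrow(net$S)), rep(0, nrow(net$S)),
                  net$lower, net$upper, maximize = TRUE)
  v <- stats::setNames(res$x, net$reaction_ids)
  flux_state(v, res$objective, res$status)
}
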