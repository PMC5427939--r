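# Scenario sets: discrete probabilistic models of the uncertain biomass
# (growth) coefficients.  Four builders cover the standard probabilistic
# models (digit-level, digit-level scaled, proportional, percentile-varied)
# plus the single-coefficient multiplier experiment.

#' Scenario probabilities for the five-scenario models
#'
#' The five scenarios correspond to standard-normal bands around the mean
#' (no perturbation; half-step; full step).  The default probabilities are
#' the reference constants (0.0351, 0.2389, 0.4520, 0.2389, 0.0351), which
#' sum to exactly 1.  `recompute = TRUE` instead returns the literal band
#' masses for cut points at 1/2 and 3/2 standard deviations.
#'
#' @param recompute Use literal normal band masses instead of the reference
#'   constants.
#' @return Length-5 probability vector.
#' @export
ramp_probabilities <- function(recompute = FALSE) {
  if (!recompute) return(c(0.0351, 0.2389, 0.4520, 0.2389, 0.0351))
  outer_p <- stats::pnorm(-1.5)
  mid_p <- stats::pnorm(1.5) - stats::pnorm(0.5)
  ctr_p <- 2 * stats::pnorm(0.5) - 1
  c(outer_p, mid_p, ctr_p, mid_p, outer_p)
}

#' Infer the digit-level perturbation step of a printed coefficient
#'
#' The first unspecified significant digit of a decimal text with `d` digits
#' after the decimal point is at position `d + 1`, so the step is
#' `10^-(d+1)`; integers step by `10^-1`.
#'
#' @param coefficient_text Decimal text, e.g. `"53.95"` or `"-0.000223"`.
#' @return The step size `10^-(d+1)`.
#' @export
#' @examples
#' infer_digit_step("53.95")      # 0.001
#' infer_digit_step("-0.000223")  # 1e-7
infer_digit_step <- function(coefficient_text) {
  txt <- trimws(as.character(coefficient_text))
  txt <- gsub("−", "-", txt)  # tolerate a typographic minus
  if (grepl("[eE]", txt)) txt <- decimal_text(as.numeric(txt))
  if (!grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", txt))
    stop("cannot parse coefficient text '", coefficient_text, "' as a decimal")
  d <- if (grepl("\\.", txt)) nchar(sub("^[^.]*\\.", "", txt)) else 0L
  10^(-(d + 1L))
}

# Shortest round-tripping plain-decimal representation of a double.
decimal_text <- function(x) {
  for (d in 1:17) {
    s <- format(x, digits = d, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == x) return(s)
  }
  format(x, digits = 17, scientific = FALSE, trim = TRUE)
}

new_scenario_set <- function(probabilities, growth_scenarios, delta,
                             base_column, network, scenario_rows = NULL) {
  q <- length(probabilities)
  if (q < 1) stop("need at least one scenario")
  if (any(probabilities <= 0)) stop("scenario probabilities must be positive")
  if (abs(sum(probabilities) - 1) > 1e-9)
    stop("scenario probabilities must sum to 1 (got ", sum(probabilities), ")")
  if (delta <= 0) stop("delta must be positive")
  growth_scenarios <- as.matrix(growth_scenarios)
  if (ncol(growth_scenarios) != q)
    stop("growth_scenarios must have q columns")
  structure(
    list(q = q, probabilities = probabilities,
         growth_scenarios = growth_scenarios, delta = delta,
         base_column = base_column,
         metabolite_ids = network$metabolite_ids,
         base_S = network$S, scenario_rows = scenario_rows),
    class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  spread <- scenario_spread(x)
  cat("<scenario_set> q = ", x$q, ", delta = ", format(x$delta, digits = 6),
      ", ", sum(spread > 0), "/", length(spread),
      " uncertain metabolite rows\n", sep = "")
  invisible(x)
}

#' Per-row scenario standard deviation of the growth coefficient
#'
#' @param scenarios A `scenario_set`.
#' @return Named numeric vector of probability-weighted standard deviations.
#' @export
scenario_spread <- function(scenarios) {
  p <- scenarios$probabilities
  mu <- as.numeric(scenarios$growth_scenarios %*% p)
  dev <- sqrt(colSums(p * (t(scenarios$growth_scenarios) - rep(mu, each = scenarios$q))^2))
  stats::setNames(dev, scenarios$metabolite_ids)
}

#' Scenario table in the standard audit layout
#'
#' @param scenarios A `scenario_set`.
#' @param nonzero_only Keep only rows with scenario spread (default `TRUE`).
#' @return A tibble: metabolite, base coefficient, one column per scenario.
#' @export
scenario_table <- function(scenarios, nonzero_only = TRUE) {
  base <- as.numeric(scenarios$growth_scenarios %*% scenarios$probabilities)
  tb <- tibble::tibble(metabolite = scenarios$metabolite_ids, base = base)
  for (k in seq_len(scenarios$q))
    tb[[paste0("scenario", k)]] <- scenarios$growth_scenarios[, k]
  if (nonzero_only) tb <- tb[scenario_spread(scenarios) > 0, ]
  tb
}

growth_texts <- function(net, coefficient_texts) {
  coef <- growth_coefficients(net)
  nz <- names(coef)[coef != 0]
  if (is.null(coefficient_texts)) {
    coefficient_texts <- vapply(coef[nz], decimal_text, character(1))
    names(coefficient_texts) <- nz
  } else {
    missing <- setdiff(nz, names(coefficient_texts))
    if (length(missing))
      stop("coverage error: no coefficient text for growth metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  coefficient_texts
}

digit_scenarios <- function(net, coefficient_texts, rho) {
  coef <- growth_coefficients(net)
  texts <- growth_texts(net, coefficient_texts)
  gs <- matrix(rep(coef, 5), ncol = 5,
               dimnames = list(names(coef), NULL))
  for (met in names(texts)) {
    step <- rho * infer_digit_step(texts[[met]])
    gs[met, ] <- coef[[met]] + step * c(-2, -1, 0, 1, 2)
  }
  gs
}

#' Digit-level scenario model (default model)
#'
#' The mean of each growth coefficient is its stated model value; variation
#' is restricted to the first unspecified significant digit.  Each nonzero
#' coefficient gets five scenarios perturbed by `eta * 10^-d` with
#' `eta = -2, -1, 0, 1, 2`; `delta = 3`.
#'
#' @param net A `metabolic_network`.
#' @param coefficient_texts Optional named character vector giving the
#'   printed decimal text per growth metabolite (defaults to the shortest
#'   round-trip decimal of the stored value).
#' @param recompute_probabilities See [ramp_probabilities()].
#' @return A `scenario_set`.
#' @export
build_model1 <- function(net, coefficient_texts = NULL,
                         recompute_probabilities = FALSE) {
  new_scenario_set(ramp_probabilities(recompute_probabilities),
                   digit_scenarios(net, coefficient_texts, rho = 1),
                   delta = 3, base_column = net$growth_index, network = net)
}

#' Scaled digit-level scenario model
#'
#' Multiplies the digit-level perturbations of the default model by the
#' integer scalar `rho`.  Integers beyond 9 flip coefficient signs and are
#' rejected.
#'
#' @inheritParams build_model1
#' @param rho Integer scale in 1..9 (1 reproduces the default model).
#' @return A `scenario_set`.
#' @export
build_model2 <- function(net, coefficient_texts = NULL, rho,
                         recompute_probabilities = FALSE) {
  if (length(rho) != 1 || rho != round(rho) || rho < 1 || rho > 9)
    stop("parameter error: rho must be an integer in 1..9")
  new_scenario_set(ramp_probabilities(recompute_probabilities),
                   digit_scenarios(net, coefficient_texts, rho = rho),
                   delta = 3, base_column = net$growth_index, network = net)
}

#' Proportional scenario model
#'
#' Scenarios are percentages of the growth coefficient itself:
#' `(1 + eta * sigma) * c` with `eta = -1, -1/2, 0, 1/2, 1`; `delta = 3`.
#'
#' @inheritParams build_model1
#' @param sigma Proportional half-width (>= 0; 0 gives zero spread).
#' @return A `scenario_set`.
#' @export
build_model3 <- function(net, sigma, recompute_probabilities = FALSE) {
  if (sigma < 0) stop("parameter error: sigma must be nonnegative")
  coef <- growth_coefficients(net)
  gs <- outer(coef, 1 + sigma * c(-1, -1/2, 0, 1/2, 1))
  new_scenario_set(ramp_probabilities(recompute_probabilities), gs,
                   delta = 3, base_column = net$growth_index, network = net)
}

#' Percentile-varied scenario model
#'
#' Keeps the digit-level scenarios of the default model but changes the
#' probabilistic guarantee: `delta` becomes the standard-normal
#' `1 - epsilon2/2` quantile, where `epsilon2 = 2 * epsilon` is the total
#' tail mass allowed outside the steady-state band.
#'
#' @inheritParams build_model1
#' @param epsilon2 Total tail mass `2 * epsilon`, in (0, 1).
#' @return A `scenario_set`.
#' @export
build_model4 <- function(net, epsilon2, coefficient_texts = NULL,
                         recompute_probabilities = FALSE) {
  if (epsilon2 <= 0 || epsilon2 >= 1)
    stop("parameter error: epsilon2 must lie in (0, 1)")
  new_scenario_set(ramp_probabilities(recompute_probabilities),
                   digit_scenarios(net, coefficient_texts, rho = 1),
                   delta = stats::qnorm(1 - epsilon2 / 2),
                   base_column = net$growth_index, network = net)
}

#' Single-coefficient multiplier scenarios
#'
#' Only the target metabolite's growth coefficient is uncertain; its five
#' scenarios are `c * (1 + eta * sigma)` with `eta = -1, -1/2, 0, 1/2, 1`;
#' all other rows have zero spread; `delta = 3`.
#'
#' @inheritParams build_model1
#' @param target Metabolite id with a nonzero growth coefficient.
#' @param sigma Multiplier half-width (>= 0).
#' @return A `scenario_set`.
#' @export
build_single_coefficient <- function(net, target, sigma,
                                     recompute_probabilities = FALSE) {
  if (sigma < 0) stop("parameter error: sigma must be nonnegative")
  coef <- growth_coefficients(net)
  if (!target %in% names(coef) || coef[[target]] == 0)
    stop("lookup error: '", target,
         "' has no nonzero coefficient in the biomass equation")
  gs <- matrix(rep(coef, 5), ncol = 5, dimnames = list(names(coef), NULL))
  gs[target, ] <- coef[[target]] * (1 + sigma * c(-1, -1/2, 0, 1/2, 1))
  new_scenario_set(ramp_probabilities(recompute_probabilities), gs,
                   delta = 3, base_column = net$growth_index, network = net)
}
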