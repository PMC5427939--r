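# Gene-essentiality screening: in-silico single-gene knockouts under FBA or
# the robust model, confusion-matrix scoring against experimental labels,
# and the maximal-uncertainty (sigma) search for single biomass coefficients.

#' Knockout screen over all genes of a network
#'
#' For each gene: apply the knockout, re-solve (FBA, or the robust model
#' with the supplied scenarios), and record the growth ratio against wild
#' type.  A gene is called essential when its knockout growth falls strictly
#' below `threshold` times the wild-type growth (default 50% reduction).
#' Infeasible or numerically failed knockout solves are scored as zero
#' growth.  For the robust method the deviation bounds M are fitted once on
#' the wild-type network and held fixed across knockouts, unless `M` is
#' given explicitly or `refit_m = TRUE`.
#'
#' @param net A `metabolic_network`.
#' @param method `"fba"` or `"ramp"`.
#' @param scenarios A `scenario_set` (required for `method = "ramp"`).
#' @param M Explicit deviation bounds; `NULL` fits them at the wild-type
#'   FBA growth rate.
#' @param threshold Essentiality threshold on the growth ratio (default
#'   0.5; strict inequality).
#' @param refit_m Refit M on every knockout network (default `FALSE`).
#' @param genes Genes to screen (default: all `gene_ids`).
#' @return A `knockout_screen`: list with `results` (tibble: gene,
#'   wt_growth, ko_growth, ratio, essential, status), `method`,
#'   `threshold`, `wild_type` growth.
#' @export
#' @examples
#' screen_knockouts(chain_network(), method = "fba")
screen_knockouts <- function(net, method = c("fba", "ramp"), scenarios = NULL,
                             M = NULL, threshold = 0.5, refit_m = FALSE,
                             genes = NULL) {
  method <- match.arg(method)
  if (method == "ramp" && is.null(scenarios))
    stop("screen error: method 'ramp' requires a scenario_set")
  if (is.null(genes)) genes <- net$gene_ids

  solve_net <- function(network, m_vec) {
    if (method == "fba") return(solve_fba(network))
    solve_ramp(assemble_linear_ramp(network, scenarios, m_vec))
  }

  if (method == "ramp" && is.null(M)) {
    fit <- fit_M(net, scenarios)
    if (fit$status != "optimal")
      stop("screen error: M calibration on the wild type is ", fit$status)
    M <- fit$M
  }
  wt <- solve_net(net, M)
  if (wt$status != "optimal")
    stop("screen error: wild-type solve is ", wt$status)
  wt_growth <- wt$objective

  rows <- lapply(genes, function(g) {
    ko <- apply_knockout(net, g)
    st <- if (method == "ramp" && refit_m) {
      refit <- fit_M(ko, scenarios, gamma_star = NULL)
      if (refit$status == "optimal") solve_net(ko, refit$M)
      else flux_state(NULL, NA_real_, refit$status)
    } else solve_net(ko, M)
    growth <- if (st$status == "optimal") max(st$objective, 0) else 0
    tibble::tibble(gene = g, ko_growth = growth, status = st$status)
  })
  results <- dplyr::bind_rows(rows)
  results$wt_growth <- wt_growth
  results$ratio <- if (wt_growth > 0) results$ko_growth / wt_growth else
    as.numeric(results$ko_growth == 0)
  results$essential <- results$ratio < threshold
  results <- results[, c("gene", "wt_growth", "ko_growth", "ratio",
                         "essential", "status")]
  structure(list(results = results, method = method, threshold = threshold,
                 wild_type = wt_growth),
            class = "knockout_screen")
}

#' @export
print.knockout_screen <- function(x, ...) {
  cat("<knockout_screen> method: ", x$method, ", ",
      nrow(x$results), " genes, ", sum(x$results$essential),
      " essential (ratio < ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' @rdname screen_knockouts
#' @param x A `knockout_screen`.
#' @param ... Unused.
#' @export
tidy.knockout_screen <- function(x, ...) x$results

#' Essential-gene set of a screen
#'
#' @param screen A `knockout_screen`.
#' @return Sorted character vector of essential gene ids.
#' @export
essential_genes <- function(screen) {
  sort(screen$results$gene[screen$results$essential])
}

#' Compare a knockout screen with experimental essentiality labels
#'
#' True positive: predicted essential and labeled essential; true negative:
#' predicted nonessential and labeled nonessential; false positive /
#' negative accordingly.  Genes without a label are excluded and counted.
#'
#' @param screen A `knockout_screen`.
#' @param labels A data frame with columns `gene_id` and `essential`
#'   (logical or 0/1), or a named logical vector.
#' @return A `confusion_matrix`: list with `TP`, `FP`, `FN`, `TN`,
#'   `n_unlabeled`.
#' @export
compare_to_experiment <- function(screen, labels) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.logical(labels$essential),
                           as.character(labels$gene_id))
  } else lab <- as.logical(labels) |> stats::setNames(names(labels))
  res <- screen$results
  known <- res$gene %in% names(lab)
  if (!any(known))
    stop("scoring error: no screened gene carries an experimental label")
  pred <- res$essential[known]
  truth <- unname(lab[res$gene[known]])
  confusion_matrix(TP = sum(pred & truth), FP = sum(pred & !truth),
                   FN = sum(!pred & truth), TN = sum(!pred & !truth),
                   n_unlabeled = sum(!known))
}

#' Confusion matrix of essentiality calls
#'
#' @param TP,FP,FN,TN Nonnegative counts.
#' @param n_unlabeled Screened genes without an experimental label.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(TP, FP, FN, TN, n_unlabeled = 0) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  structure(as.list(c(counts, n_unlabeled = n_unlabeled)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP ", x$TP, " | FP ", x$FP, " | FN ", x$FN,
      " | TN ", x$TN, "  (predictive power ",
      sprintf("%.2f%%", 100 * predictive_power(x)), ")\n", sep = "")
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(cell = c("TP", "FP", "FN", "TN"),
                 count = c(x$TP, x$FP, x$FN, x$TN))
}

#' Predictive power of a confusion matrix
#'
#' The fraction of correctly classified genes:
#' `(TP + TN) / (TP + FP + FN + TN)`.
#'
#' @param cm A `confusion_matrix` (or list with those fields).
#' @return Fraction in 0..1.
#' @export
#' @examples
#' predictive_power(confusion_matrix(171, 44, 77, 1074))  # 0.9114...
predictive_power <- function(cm) {
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  if (total <= 0) stop("division error: no scored genes")
  (cm$TP + cm$TN) / total
}

#' Maximal tolerated uncertainty of a single biomass coefficient
#'
#' Finds the largest multiplier `sigma` at which the robust knockout screen
#' (single-coefficient scenarios on `metabolite`, M recalibrated at the
#' wild-type FBA growth rate) returns exactly the FBA essential-gene set.
#' Protocol: starting from `sigma0`, double sigma until the essential sets
#' first disagree, then binary-search the transition to within `accuracy`.
#' If doubling reaches `cap` without a mismatch only a lower bound is known
#' and `bounded` is `FALSE`.
#'
#' @param net A `metabolic_network`.
#' @param metabolite Target metabolite id (nonzero biomass coefficient).
#' @param accuracy Absolute accuracy of the returned sigma (default 1e-4).
#' @param cap Upper search limit (default 1e26).
#' @param sigma0 Initial sigma (default 1e-4).
#' @param threshold Essentiality threshold passed to the screens.
#' @return A `sigma_search` object: list with `metabolite`, `sigma_max`,
#'   `bounded`, `iterations`, `reference_essential` (the FBA set).
#' @export
max_sigma_search <- function(net, metabolite, accuracy = 1e-4, cap = 1e26,
                             sigma0 = 1e-4, threshold = 0.5) {
  fba_screen <- screen_knockouts(net, method = "fba", threshold = threshold)
  reference <- essential_genes(fba_screen)
  iterations <- 0L

  matches <- function(sigma) {
    iterations <<- iterations + 1L
    sc <- build_single_coefficient(net, metabolite, sigma)
    scr <- screen_knockouts(net, method = "ramp", scenarios = sc,
                            threshold = threshold)
    identical(essential_genes(scr), reference)
  }

  if (!matches(sigma0)) {
    return(structure(list(metabolite = metabolite, sigma_max = 0,
                          bounded = TRUE, iterations = iterations,
                          mismatch_at_start = TRUE,
                          reference_essential = reference),
                     class = "sigma_search"))
  }
  lo <- sigma0
  hi <- sigma0
  repeat {
    hi <- 2 * hi
    if (hi > cap) {
      return(structure(list(metabolite = metabolite, sigma_max = lo,
                            bounded = FALSE, iterations = iterations,
                            mismatch_at_start = FALSE,
                            reference_essential = reference),
                       class = "sigma_search"))
    }
    if (!matches(hi)) break
    lo <- hi
  }
  while (hi - lo > accuracy) {
    mid <- (lo + hi) / 2
    if (matches(mid)) lo <- mid else hi <- mid
  }
  structure(list(metabolite = metabolite, sigma_max = lo, bounded = TRUE,
                 iterations = iterations, mismatch_at_start = FALSE,
                 reference_essential = reference),
            class = "sigma_search")
}

#' @export
print.sigma_search <- function(x, ...) {
  cat("<sigma_search> ", x$metabolite, ": ", sep = "")
  if (x$bounded)
    cat("sigma_max = ", format(x$sigma_max, digits = 6), sep = "")
  else
    cat("unbounded (lower bound ", format(x$sigma_max, digits = 3),
        ", cap reached)", sep = "")
  cat(" after ", x$iterations, " screens\n", sep = "")
  invisible(x)
}
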