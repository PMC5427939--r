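# Dump/load of an assembled (linearized) robust problem as JSON: mean rows
# as sparse triplets, the growth-norm coefficients, M, bounds, and ids.

#' Write an assembled robust problem as JSON
#'
#' Only the linear form is serialized (the cone form is a small-instance
#' tool and can be reassembled from its scenario set).
#'
#' @param problem A `ramp_problem` of linear form.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ramp_problem <- function(problem, path) {
  if (problem$form != "linear")
    stop("only linear-form problems are serialized")
  mr <- problem$mean_rows
  nz <- which(mr != 0, arr.ind = TRUE)
  doc <- list(
    form = "linear",
    metabolite_ids = problem$scenarios$metabolite_ids,
    reaction_ids = problem$network$reaction_ids,
    growth_index = problem$network$growth_index,
    mean_triplets = list(i = nz[, 1], j = nz[, 2], x = mr[nz]),
    growth_norm = problem$growth_norm,
    M = unname(problem$M),
    lower = problem$network$lower,
    upper = problem$network$upper)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized robust problem
#'
#' Returns the constraint system in the same shape [solve_ramp()] consumes;
#' scenario provenance is not retained, only the assembled rows.
#'
#' @param path JSON file written by [write_ramp_problem()].
#' @return A `ramp_problem` of linear form.
#' @export
read_ramp_problem <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$form, "linear")) stop("unsupported problem form")
  m <- length(doc$metabolite_ids); n <- length(doc$reaction_ids)
  mr <- matrix(0, m, n, dimnames = list(doc$metabolite_ids, doc$reaction_ids))
  mr[cbind(doc$mean_triplets$i, doc$mean_triplets$j)] <- doc$mean_triplets$x
  net <- metabolic_network(mr, doc$lower, doc$upper,
                           metabolite_ids = doc$metabolite_ids,
                           reaction_ids = doc$reaction_ids,
                           growth_id = doc$growth_index)
  structure(
    list(network = net,
         scenarios = list(metabolite_ids = doc$metabolite_ids),
         mean_rows = mr, growth_norm = doc$growth_norm, R = NULL,
         M = stats::setNames(doc$M, doc$metabolite_ids), form = "linear"),
    class = "ramp_problem")
}
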