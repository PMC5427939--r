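#' Construct a metabolic network
#'
#' The central container of the package: a stoichiometric system with flux
#' bounds, a designated growth (biomass) reaction, and optional boolean
#' gene-protein-reaction (GPR) rules.  Columns of `S` are reactions, rows are
#' metabolites; entries are negative for consumed and positive for produced
#' metabolites.  Bounds are in mmol/gDW/h by the usual COBRA convention.
#'
#' @param S Stoichiometric matrix (m x n); coerced to a sparse
#'   [Matrix::sparseMatrix].
#' @param lower,upper Length-n flux bounds; infinite entries are replaced by
#'   `+/- big_bound`.
#' @param metabolite_ids,reaction_ids Row / column identifiers.
#' @param growth_id Reaction id (or index) of the biomass reaction.
#' @param gpr Character vector of per-reaction boolean gene rules (`""` for
#'   none), e.g. `"(g1 and g2) or g3"`.
#' @param gene_ids Gene identifiers; defaults to the genes referenced by
#'   `gpr`.
#' @param big_bound Replacement magnitude for infinite bounds (default 1000).
#'
#' @return An object of class `metabolic_network` with fields `S`, `lower`,
#'   `upper`, `metabolite_ids`, `reaction_ids`, `growth_index`, `gpr`,
#'   `gene_ids`.
#' @export
#' @examples
#' net <- chain_network()
#' net
metabolic_network <- function(S, lower, upper, metabolite_ids = NULL,
                              reaction_ids = NULL, growth_id,
                              gpr = NULL, gene_ids = NULL,
                              big_bound = 1000) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  m <- nrow(S); n <- ncol(S)
  if (is.null(metabolite_ids)) metabolite_ids <- rownames(S)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("met", seq_len(m))
  if (is.null(reaction_ids)) reaction_ids <- colnames(S)
  if (is.null(reaction_ids)) reaction_ids <- paste0("rxn", seq_len(n))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  if (is.null(gpr)) gpr <- rep("", n)
  gpr[is.na(gpr)] <- ""
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  lower[lower == -Inf] <- -big_bound
  upper[upper == Inf] <- big_bound
  if (is.character(growth_id)) {
    growth_index <- match(growth_id, reaction_ids)
    if (is.na(growth_index))
      stop("growth reaction '", growth_id, "' not found among reaction ids")
  } else {
    growth_index <- as.integer(growth_id)
  }
  referenced <- unique(unlist(lapply(gpr[nzchar(gpr)],
                                     function(r) gpr_genes(parse_gpr(r)))))
  if (is.null(gene_ids)) gene_ids <- referenced
  net <- structure(
    list(S = S, lower = lower, upper = upper,
         metabolite_ids = metabolite_ids, reaction_ids = reaction_ids,
         growth_index = growth_index, gpr = gpr,
         gene_ids = as.character(gene_ids)),
    class = "metabolic_network")
  validate_network(net)
}

#' Validate a metabolic network
#'
#' Checks mutual dimension consistency, `lower <= upper` componentwise, a
#' valid growth index, and that every gene referenced by a GPR is listed in
#' `gene_ids`.
#'
#' @param net A `metabolic_network`.
#' @return The network, invisibly unchanged, or an error.
#' @export
validate_network <- function(net) {
  m <- nrow(net$S); n <- ncol(net$S)
  if (length(net$lower) != n || length(net$upper) != n)
    stop("bound vectors must have one entry per reaction")
  if (length(net$metabolite_ids) != m || length(net$reaction_ids) != n)
    stop("identifier vectors inconsistent with S")
  bad <- which(net$lower > net$upper)
  if (length(bad))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(net$reaction_ids[bad], collapse = ", "))
  if (is.na(net$growth_index) || net$growth_index < 1 || net$growth_index > n)
    stop("growth_index out of range")
  if (length(net$gpr) != n) stop("gpr must have one rule per reaction")
  referenced <- unique(unlist(lapply(net$gpr[nzchar(net$gpr)],
                                     function(r) gpr_genes(parse_gpr(r)))))
  missing <- setdiff(referenced, net$gene_ids)
  if (length(missing))
    stop("genes referenced by GPR rules but absent from gene_ids: ",
         paste(missing, collapse = ", "))
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$S), " metabolites x ", ncol(x$S),
      " reactions, ", length(x$gene_ids), " genes\n", sep = "")
  cat("  growth reaction: ", x$reaction_ids[x$growth_index], "\n", sep = "")
  rev <- sum(x$lower < 0 & x$upper > 0)
  fix <- sum(x$lower == x$upper)
  cat("  ", rev, " reversible, ", fix, " fixed-flux reactions\n", sep = "")
  invisible(x)
}

#' Growth-column coefficients of a network
#'
#' @param net A `metabolic_network`.
#' @return Named numeric vector (one entry per metabolite) of the biomass
#'   column of `S`.
#' @export
growth_coefficients <- function(net) {
  stats::setNames(as.numeric(net$S[, net$growth_index]), net$metabolite_ids)
}

#' Apply a gene knockout to a network
#'
#' Every reaction whose GPR rule evaluates false once the given genes are
#' removed gets its bounds fixed to zero.  Columns are kept (never deleted)
#' so indexing stays comparable across knockouts.
#'
#' @param net A `metabolic_network`.
#' @param genes Character vector of gene ids to knock out (may be empty).
#' @return A modified copy of the network.
#' @export
#' @examples
#' net <- chain_network()
#' ko <- apply_knockout(net, "g1")
#' solve_fba(ko)$objective
apply_knockout <- function(net, genes) {
  genes <- as.character(genes)
  unknown <- setdiff(genes, net$gene_ids)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  if (!length(genes)) return(net)
  for (j in seq_along(net$gpr)) {
    rule <- net$gpr[j]
    if (!nzchar(rule)) next
    if (!evaluate_gpr(rule, genes)) {
      net$lower[j] <- 0
      net$upper[j] <- 0
    }
  }
  net
}

#' Set the growth environment of a network
#'
#' Applies a named uptake profile to exchange reactions (reactions with a
#' single nonzero stoichiometric entry).  All exchange uptake is first closed
#' (lower bound 0), then each named metabolite's exchange lower bound is set
#' to `-rate`; secretion bounds are untouched.  This is how a minimal medium
#' (e.g. limited glucose, unlimited oxygen) is expressed without hard-coding.
#'
#' @param net A `metabolic_network`.
#' @param uptake Named numeric vector: maximal uptake rate (mmol/gDW/h) per
#'   exchanged metabolite id; use `Inf` for unlimited (capped at the
#'   network's big bound, 1000 by default).
#' @return The modified network.
#' @export
apply_medium <- function(net, uptake) {
  exch <- which(Matrix::colSums(net$S != 0) == 1)
  for (j in exch) if (net$lower[j] < 0) net$lower[j] <- 0
  for (met in names(uptake)) {
    i <- match(met, net$metabolite_ids)
    if (is.na(i)) stop("metabolite '", met, "' not in network")
    j <- exch[which(net$S[i, exch] != 0)]
    if (!length(j)) stop("no exchange reaction found for '", met, "'")
    rate <- uptake[[met]]
    if (!is.finite(rate)) rate <- 1000
    # exchange written as export (met coefficient -1): uptake = negative flux
    net$lower[j] <- if (net$S[i, j[1]] < 0) -rate else net$lower[j]
    if (net$S[i, j[1]] > 0) net$upper[j] <- rate
  }
  validate_network(net)
}
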