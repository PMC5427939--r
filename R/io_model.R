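# Model readers: COBRA-style JSON and SBML level 3 with the fbc extension.

#' Read a genome-scale metabolic model
#'
#' Supports the COBRA-style JSON dialect (fields `metabolites`, `reactions`
#' with `id`, `metabolites`, `lower_bound`, `upper_bound`,
#' `gene_reaction_rule`, and `genes`) and SBML level 3 with the fbc
#' extension.  Infinite or absent bounds are replaced by `+/- big_bound`.
#'
#' @param path Path to the model file.
#' @param format `"auto"` (by extension), `"json"`, or `"sbml"`.
#' @param big_bound Replacement for infinite bounds (default 1000).
#' @return A validated [metabolic_network].
#' @export
read_metabolic_model <- function(path, format = c("auto", "json", "sbml"),
                                 big_bound = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format,
         json = read_cobra_json(path, big_bound),
         sbml = read_sbml_fbc(path, big_bound))
}

read_cobra_json <- function(path, big_bound = 1000) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("model error: JSON model lacks 'metabolites' or 'reactions'")
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  m <- length(met_ids); n <- length(rxn_ids)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lower <- numeric(n); upper <- numeric(n); gpr <- character(n)
  obj_coef <- numeric(n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    mets <- r$metabolites
    if (length(mets)) {
      idx <- match(names(mets), met_ids)
      if (anyNA(idx))
        stop("format error: reaction '", r$id, "' references unknown ",
             "metabolite '", names(mets)[which(is.na(idx))[1]], "'")
      ii <- c(ii, idx); jj <- c(jj, rep(j, length(idx)))
      xx <- c(xx, as.numeric(unlist(mets)))
    }
    lower[j] <- if (is.null(r$lower_bound)) -big_bound else as.numeric(r$lower_bound)
    upper[j] <- if (is.null(r$upper_bound)) big_bound else as.numeric(r$upper_bound)
    gpr[j] <- if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule
    obj_coef[j] <- if (is.null(r$objective_coefficient)) 0
                   else as.numeric(r$objective_coefficient)
  }
  growth <- which(obj_coef != 0)
  if (length(growth) != 1)
    stop("model error: expected exactly one reaction with a nonzero ",
         "objective_coefficient, found ", length(growth))
  gene_ids <- if (is.null(doc$genes)) NULL
              else vapply(doc$genes, function(g) g$id, character(1))
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n))
  metabolic_network(S, lower, upper, metabolite_ids = met_ids,
                    reaction_ids = rxn_ids, growth_id = growth,
                    gpr = gpr, gene_ids = gene_ids, big_bound = big_bound)
}

#' Write a network in the COBRA-style JSON dialect
#'
#' Round-trips through [read_metabolic_model()].
#'
#' @param net A `metabolic_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(net, path) {
  rxns <- lapply(seq_along(net$reaction_ids), function(j) {
    col <- net$S[, j]
    nz <- which(col != 0)
    list(id = net$reaction_ids[j],
         metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                               net$metabolite_ids[nz])),
         lower_bound = net$lower[j],
         upper_bound = net$upper[j],
         gene_reaction_rule = net$gpr[j],
         objective_coefficient = as.numeric(j == net$growth_index))
  })
  doc <- list(
    metabolites = lapply(net$metabolite_ids, function(id) list(id = id)),
    reactions = rxns,
    genes = lapply(net$gene_ids, function(id) list(id = id))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- SBML level 3 + fbc ----------------------------------------------------

xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

# namespace-agnostic XPath helpers (fbc elements keep their prefix even
# after xml_ns_strip, so match on local-name)
xp <- function(...) paste0(vapply(c(...), function(nm)
  paste0("*[local-name()='", nm, "']"), character(1)), collapse = "/")
xfind_all <- function(node, ...) xml2::xml_find_all(node, paste0("./", xp(...)))
xfind_first <- function(node, ...) xml2::xml_find_first(node, paste0(".//", xp(...)))

sbml_gpr_string <- function(node) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") return(xattr(node, "geneProduct"))
  parts <- vapply(kids, sbml_gpr_string, character(1))
  parts <- parts[!is.na(parts)]
  if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  if (length(parts) == 1) return(parts)
  NA_character_
}

read_sbml_fbc <- function(path, big_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  model <- xfind_first(doc, "model")
  if (inherits(model, "xml_missing")) stop("format error: no <model> element")

  params <- xfind_all(model, "listOfParameters", "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  species <- xfind_all(model, "listOfSpecies", "species")
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition")
  met_ids <- sp_id[is.na(sp_boundary) | sp_boundary != "true"]
  if (!length(met_ids)) stop("format error: SBML model has no species")

  genes <- xfind_all(model, "listOfGeneProducts", "geneProduct")
  gene_ids <- vapply(genes, function(g) {
    lab <- xattr(g, "label"); id <- xattr(g, "id")
    if (!is.na(lab)) lab else id
  }, character(1))
  gene_by_id <- stats::setNames(gene_ids, xml2::xml_attr(genes, "id"))

  rxns <- xfind_all(model, "listOfReactions", "reaction")
  if (!length(rxns)) stop("format error: SBML model has no reactions")
  n <- length(rxns); m <- length(met_ids)
  rxn_ids <- xml2::xml_attr(rxns, "id")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lower <- rep(-big_bound, n); upper <- rep(big_bound, n)
  gpr <- character(n)
  for (j in seq_len(n)) {
    r <- rxns[[j]]
    for (sr in xfind_all(r, "listOfReactants", "speciesReference")) {
      i <- match(xml2::xml_attr(sr, "species"), met_ids)
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (!is.na(i)) { ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, -st) }
    }
    for (sr in xfind_all(r, "listOfProducts", "speciesReference")) {
      i <- match(xml2::xml_attr(sr, "species"), met_ids)
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (!is.na(i)) { ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, st) }
    }
    lb_ref <- xattr(r, "lowerFluxBound"); ub_ref <- xattr(r, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(pvals)) lower[j] <- pvals[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(pvals)) upper[j] <- pvals[[ub_ref]]
    gpa <- xml2::xml_find_first(r, paste0("./", xp("geneProductAssociation")))
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) {
        rule <- sbml_gpr_string(kids[[1]])
        if (!is.na(rule)) {
          # SBML refers to geneProduct ids; translate to labels where known
          for (gid in names(gene_by_id))
            rule <- gsub(paste0("\\b", gid, "\\b"), gene_by_id[[gid]], rule)
          gpr[j] <- rule
        }
      }
    }
  }

  obj <- xfind_first(model, "listOfObjectives", "objective",
                     "listOfFluxObjectives", "fluxObjective")
  if (inherits(obj, "xml_missing"))
    stop("model error: SBML model declares no active flux objective")
  growth <- match(xattr(obj, "reaction"), rxn_ids)
  if (is.na(growth))
    stop("model error: objective reaction not found among reactions")

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n))
  metabolic_network(S, lower, upper, metabolite_ids = met_ids,
                    reaction_ids = rxn_ids, growth_id = growth, gpr = gpr,
                    gene_ids = unique(gene_ids), big_bound = big_bound)
}
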