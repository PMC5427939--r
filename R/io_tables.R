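# Tabular inputs and outputs: essentiality labels, flux measurements, and
# the TSV reports written by the command-line interface.  Numbers in
# written reports are formatted at 6 significant digits so identical runs
# give byte-identical files.

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt6(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read experimental essentiality labels
#'
#' @param path TSV with columns `gene_id` and `essential` (0/1).
#' @return A tibble with `gene_id` (character) and `essential` (integer).
#' @export
read_essentiality_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "essential") %in% names(df)))
    stop("labels file needs columns 'gene_id' and 'essential'")
  tibble::tibble(gene_id = as.character(df$gene_id),
                 essential = as.integer(df$essential))
}

#' Write essentiality labels
#'
#' @param labels Tibble with `gene_id` and `essential`.
#' @param path Output path.
#' @export
write_essentiality_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read experimental flux measurements
#'
#' @param path TSV with columns `reaction_id`, `flux`, optionally `sd`.
#' @return A tibble.
#' @export
read_flux_measurements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "flux") %in% names(df)))
    stop("measurements file needs columns 'reaction_id' and 'flux'")
  tibble::as_tibble(df)
}

#' Write a flux state as TSV
#'
#' @param state A [flux_state].
#' @param path Output path.
#' @export
write_flux_tsv <- function(state, path) {
  write_tsv_stable(tidy(state), path)
}

#' Write a constraint audit as TSV
#'
#' @param audit A `constraint_audit` from [audit_feasibility()].
#' @param path Output path.
#' @export
write_audit_tsv <- function(audit, path) {
  write_tsv_stable(as.data.frame(audit), path)
}

#' Write the scenario audit table as TSV
#'
#' @param scenarios A `scenario_set`.
#' @param path Output path.
#' @param nonzero_only Keep only uncertain rows.
#' @export
write_scenario_tsv <- function(scenarios, path, nonzero_only = TRUE) {
  tb <- scenario_table(scenarios, nonzero_only = nonzero_only)
  # scenario values are reported verbatim, not rounded: the digit-level
  # models live in the trailing decimals
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
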