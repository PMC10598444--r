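#' Audit a directory of Boolean network rule files
#'
#' Computes, for every rule file in a directory, the summary statistics used
#' when surveying repositories of published gene-regulatory Boolean models:
#' network size (number of variables), average connectivity (mean number of
#' essential regulators per rule), the number of strongly connected
#' components of the wiring diagram, the number of *non-trivial* SCCs
#' (more than one node — a self-loop on a singleton does not count), and the
#' size of the largest SCC. Non-essential regulators are removed before any
#' statistic is computed.
#'
#' @param dir Directory containing rule files.
#' @param pattern Filename pattern (default `\\.bnet$|\\.txt$`).
#' @return A tibble with one row per model: `model`, `n_variables`,
#'   `mean_connectivity`, `n_scc`, `n_nontrivial_scc`, `largest_scc`.
#' @export
audit_models <- function(dir, pattern = "\\.bnet$|\\.txt$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no rule files found in ", dir)
  rows <- lapply(files, function(f) {
    net <- read_rules(f)
    audit_network(net, model = sub("\\.[^.]*$", "", basename(f)))
  })
  dplyr::bind_rows(rows)
}

#' @rdname audit_models
#' @param net A [boolean_network()].
#' @param model Label used in the output row.
#' @export
audit_network <- function(net, model = "network") {
  red <- reduce_to_essential_regulators(net)
  k <- vapply(red$rules, function(r) length(r$regulators), integer(1))
  dag <- strongly_connected_components(wiring_diagram(red))
  tibble::tibble(
    model = model,
    n_variables = length(red$variables),
    n_edges = sum(k),
    mean_connectivity = mean(k),
    n_scc = length(dag$module_vars),
    n_nontrivial_scc = sum(dag$non_trivial),
    largest_scc = max(lengths(dag$module_vars))
  )
}
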