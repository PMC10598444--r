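#' Wiring diagram of a Boolean network
#'
#' The wiring diagram (dependency graph) has one node per variable and a
#' directed edge `u -> v` whenever the rule of `v` depends *essentially* on
#' `u` (non-essential regulators are removed first). External parameters
#' appear as source-only nodes, flagged in the node table.
#'
#' @param net A [boolean_network()].
#' @return An object of class `bn_wiring`: a list with `nodes` (tibble:
#'   `name`, `external`) and `edges` (tibble: `from`, `to`), plus the
#'   underlying `igraph` graph in `$graph`.
#' @examples
#' net <- parse_rules(c("x1, x2 & !x3", "x2, x3", "x3, !x1 & x2"))
#' wiring_diagram(net)$edges
#' @export
wiring_diagram <- function(net) {
  red <- reduce_to_essential_regulators(net)
  from <- unlist(lapply(red$variables, function(v)
    red$rules[[v]]$regulators), use.names = FALSE)
  to <- rep(red$variables, vapply(red$rules, function(r)
    length(r$regulators), integer(1)))
  nodes <- tibble::tibble(
    name = c(red$variables, red$external),
    external = c(rep(FALSE, length(red$variables)),
                 rep(TRUE, length(red$external)))
  )
  edges <- tibble::tibble(from = from, to = to)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "bn_wiring")
}

#' @export
print.bn_wiring <- function(x, ...) {
  cat("Wiring diagram: ", sum(!x$nodes$external), " variables, ",
      nrow(x$edges), " edges", sep = "")
  if (any(x$nodes$external)) {
    cat(", ", sum(x$nodes$external), " external parameters", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Condense a wiring diagram into its module DAG
#'
#' The strongly connected components (SCCs) of the wiring diagram, restricted
#' to the network's own variables, are the structural modules. Connections
#' between two SCCs can only point in one direction, so contracting each SCC
#' to a node yields a directed acyclic graph Q with an edge `(i, j)` whenever
#' some wiring edge runs from module i to module j. A module is *non-trivial*
#' when it contains more than one node; a self-loop on a singleton does not
#' make it non-trivial.
#'
#' @param wd A `bn_wiring` from [wiring_diagram()], or a [boolean_network()]
#'   (converted internally).
#' @return An object of class `bn_module_dag`: list with `module_vars`
#'   (list of character vectors, in topological order), `edges` (tibble
#'   `from`/`to` of module indices), `non_trivial` (logical per module).
#'   Topological ties are broken by the smallest contained variable index, so
#'   module indices are stable across runs.
#' @export
strongly_connected_components <- function(wd) {
  if (inherits(wd, "boolean_network")) wd <- wiring_diagram(wd)
  vars <- wd$nodes$name[!wd$nodes$external]
  g <- igraph::induced_subgraph(wd$graph, vars)
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership[vars]
  groups <- split(vars, member)
  m <- length(groups)
  ## module-level edges from cross-SCC wiring edges (among variables)
  e <- wd$edges[wd$edges$from %in% vars, , drop = FALSE]
  mf <- member[e$from]
  mt <- member[e$to]
  cross <- unique(data.frame(from = mf, to = mt)[mf != mt, , drop = FALSE])
  ## deterministic topological order, ties by smallest variable index
  var_rank <- stats::setNames(seq_along(vars), vars)
  min_rank <- vapply(groups, function(g2) min(var_rank[g2]), numeric(1))
  order_ids <- topo_order(m, cross, min_rank)
  groups <- groups[order_ids]
  relabel <- match(seq_len(m), order_ids)
  edges <- tibble::tibble(from = relabel[cross$from], to = relabel[cross$to])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  ## order variables within each module by declaration order
  groups <- lapply(groups, function(g2) vars[sort(var_rank[g2])])
  structure(
    list(module_vars = unname(groups), edges = edges,
         non_trivial = lengths(groups) > 1L),
    class = "bn_module_dag"
  )
}

## Kahn topological sort over modules 1..m with edges (from,to); among ready
## nodes pick the one with smallest `priority`
topo_order <- function(m, edges, priority) {
  indeg <- tabulate(edges$to, nbins = m)
  out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    nxt <- ready[which.min(priority[ready])]
    out <- c(out, nxt)
    ready <- setdiff(ready, nxt)
    for (j in edges$to[edges$from == nxt]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) ready <- c(ready, j)
    }
  }
  if (length(out) != m) stop("module graph is not acyclic")
  out
}

#' @export
print.bn_module_dag <- function(x, ...) {
  m <- length(x$module_vars)
  cat("Module DAG: ", m, " module", if (m != 1) "s",
      " (", sum(x$non_trivial), " non-trivial), ",
      nrow(x$edges), " edge", if (nrow(x$edges) != 1) "s", "\n", sep = "")
  for (i in seq_len(m)) {
    cat(sprintf("  [%d] {%s}\n", i, paste(x$module_vars[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Export a wiring diagram, module DAG or state space to DOT
#'
#' @param x A `bn_wiring`, `bn_module_dag`, or (for `export_state_space_dot`)
#'   a [boolean_network()] with at most `guard` variables.
#' @param name Graph name in the DOT output.
#' @return A character scalar of DOT source.
#' @export
export_dot <- function(x, name = "G") {
  if (inherits(x, "bn_wiring")) {
    nodes <- vapply(seq_len(nrow(x$nodes)), function(i) {
      sprintf("  \"%s\"%s;", x$nodes$name[i],
              if (x$nodes$external[i]) " [shape=box, style=dashed]" else "")
    }, character(1))
    edges <- sprintf("  \"%s\" -> \"%s\";", x$edges$from, x$edges$to)
  } else if (inherits(x, "bn_module_dag")) {
    nodes <- vapply(seq_along(x$module_vars), function(i) {
      sprintf("  m%d [label=\"%d\", shape=%s];", i,
              length(x$module_vars[[i]]),
              if (x$non_trivial[i]) "doublecircle" else "circle")
    }, character(1))
    edges <- sprintf("  m%d -> m%d;", x$edges$from, x$edges$to)
  } else {
    stop("export_dot() expects a wiring diagram or module DAG")
  }
  paste(c(sprintf("digraph %s {", name), nodes, edges, "}"), collapse = "\n")
}

#' @rdname export_dot
#' @param net A [boolean_network()].
#' @param guard Maximum number of variables for a full state-space export.
#' @export
export_state_space_dot <- function(net, name = "S", guard = 10L) {
  n <- n_vars(net)
  if (n > guard) stop("state space export limited to ", guard, " variables")
  nxt <- transition_table(net, guard = guard)
  codes <- 0:(2^n - 1)
  edges <- sprintf("  \"%s\" -> \"%s\";",
                   code_to_string(codes, n), code_to_string(nxt, n))
  paste(c(sprintf("digraph %s {", name), edges, "}"), collapse = "\n")
}
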