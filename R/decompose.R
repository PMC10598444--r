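#' Restrict a Boolean network to a subset of its variables
#'
#' The restriction `F|_S` keeps the rules of the variables in `S` untouched;
#' regulators outside `S` are kept but become declared external parameters,
#' named after the variable they came from. When `S` is the variable set of
#' one strongly connected component of the wiring diagram, the restriction is
#' a *module* of the network.
#'
#' @param net A [boolean_network()].
#' @param S Non-empty character vector of variable names (subset of
#'   `net$variables`); the restriction keeps their declaration order.
#' @return A [boolean_network()], possibly with external parameters.
#' @examples
#' net <- parse_rules(c("x1, x2 & !x3", "x2, x3", "x3, !x1 & x2"))
#' restriction(net, c("x2", "x3"))  # external parameter x1
#' @export
restriction <- function(net, S) {
  if (!length(S) || !all(S %in% net$variables)) {
    stop("`S` must be a non-empty subset of the network's variables")
  }
  S <- net$variables[net$variables %in% S]   # keep declaration order
  rules <- net$rules[S]
  used <- unique(unlist(lapply(rules, `[[`, "regulators"), use.names = FALSE))
  ext_vars <- net$variables[net$variables %in% setdiff(used, S)]
  ext_old <- net$external[net$external %in% used]
  boolean_network(S, rules, c(ext_vars, ext_old))
}

#' Modules of a Boolean network
#'
#' The modules are the restrictions of the network to the variable sets of
#' the strongly connected components of its wiring diagram, returned in the
#' deterministic topological order of the module DAG.
#'
#' @param net A [boolean_network()].
#' @return A list of [boolean_network()]s (with external parameters where a
#'   module is regulated from upstream).
#' @export
modules <- function(net) {
  dag <- strongly_connected_components(wiring_diagram(net))
  lapply(dag$module_vars, function(S) restriction(net, S))
}

#' Semi-direct product of two Boolean networks
#'
#' Combines an upstream network `F` with a downstream network `G` (which has
#' external parameters) into one network `F |x_P G`: the variables are those
#' of `F` followed by those of `G`, the rules of `F` are unchanged, and each
#' external parameter of `G` that the coupling scheme `P` maps is replaced by
#' its assigned `F` variable. Unmapped parameters remain external. With an
#' empty `P` this is the cross product and the wiring diagram is the disjoint
#' union.
#'
#' @param F_up Upstream [boolean_network()].
#' @param G_down Downstream [boolean_network()] (its external parameters are
#'   the coupling surface).
#' @param P Coupling scheme: named character vector mapping external
#'   parameter names of `G_down` to variable names of `F_up`
#'   (`c(u1 = "x1", u2 = "x2")`). One upstream variable may feed several
#'   parameters. May be empty.
#' @return A [boolean_network()] on the combined variables.
#' @examples
#' F1 <- parse_rules(c("x1, x2", "x2, x1"))
#' G  <- parse_rules(c("# inputs: u1 u2",
#'                     "y1, u1 | (u2 & y2)",
#'                     "y2, !u2 & y1"))
#' semidirect_product(F1, G, c(u1 = "x1", u2 = "x2"))
#' @export
semidirect_product <- function(F_up, G_down, P = character()) {
  P <- as_coupling(P)
  if (length(P)) {
    if (!all(names(P) %in% G_down$external)) {
      stop("coupling scheme keys must be external parameters of the ",
           "downstream network")
    }
    if (!all(P %in% F_up$variables)) {
      stop("coupling scheme values must be variables of the upstream network")
    }
  }
  clash <- intersect(F_up$variables, G_down$variables)
  if (length(clash)) {
    stop("variable name collision: ", paste(clash, collapse = ", "))
  }
  g_rules <- lapply(G_down$rules, rename_regulators, map = P)
  ext <- unique(c(F_up$external, setdiff(G_down$external, names(P))))
  ext <- setdiff(ext, c(F_up$variables, G_down$variables))
  boolean_network(c(F_up$variables, G_down$variables),
                  c(F_up$rules, g_rules), ext)
}

as_coupling <- function(P) {
  if (!length(P)) return(stats::setNames(character(0), character(0)))
  P <- unlist(P)
  if (is.null(names(P)) || any(names(P) == "")) {
    stop("a coupling scheme must be a named vector: parameter -> variable")
  }
  P
}

#' Structural decomposition into modules
#'
#' Decomposes a Boolean network into the unique ordered series of modules
#' `F = F1 |x_P1 (F2 |x_P2 ( ... |x_P(m-1) Fm))`, where each `Fi` is the
#' restriction to one strongly connected component of the wiring diagram and
#' the order is the deterministic topological order of the module DAG. Each
#' coupling scheme is the identity on names: external parameters manufactured
#' by restriction are named after the upstream variable they came from, which
#' makes recomposition trivially auditable.
#'
#' @param net A [boolean_network()] without external parameters.
#' @return An object of class `bn_decomposition`: list with `modules` (list
#'   of networks, topological order), `schemes` (list of m-1 named coupling
#'   vectors), `dag` (the [strongly_connected_components()] result) and
#'   `variable_order` (the original declaration order, used by
#'   [recompose()]).
#' @export
structural_decompose <- function(net) {
  if (length(net$external)) {
    stop("decomposition expects an autonomous network (no external ",
         "parameters)")
  }
  red <- reduce_to_essential_regulators(net)
  dag <- strongly_connected_components(wiring_diagram(red))
  m <- length(dag$module_vars)
  mods <- lapply(dag$module_vars, function(S) restriction(red, S))
  schemes <- vector("list", max(m - 1L, 0L))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      down_ext <- unique(unlist(lapply(mods[(i + 1L):m], `[[`, "external"),
                                use.names = FALSE))
      src <- intersect(mods[[i]]$variables, down_ext)
      schemes[[i]] <- stats::setNames(src, src)
    }
  }
  structure(
    list(modules = mods, schemes = schemes, dag = dag,
         variable_order = net$variables),
    class = "bn_decomposition"
  )
}

#' @export
print.bn_decomposition <- function(x, ...) {
  m <- length(x$modules)
  cat("Structural decomposition into ", m, " module", if (m != 1) "s",
      "\n", sep = "")
  for (i in seq_len(m)) {
    cat(sprintf("  F%d: {%s}\n", i,
                paste(x$modules[[i]]$variables, collapse = ", ")))
  }
  invisible(x)
}

#' Recompose a structural decomposition
#'
#' Folds the modules back together through semi-direct products,
#' `F1 |x_P1 (F2 |x_P2 (...))`, and restores the original variable order, so
#' `recompose(structural_decompose(net))` reproduces `net` (reduced to
#' essential regulators) bit-exactly.
#'
#' @param decomp A `bn_decomposition`.
#' @param reorder Restore the original variable declaration order (default
#'   `TRUE`); with `FALSE` the variables appear module by module.
#' @return A [boolean_network()].
#' @export
recompose <- function(decomp, reorder = TRUE) {
  mods <- decomp$modules
  m <- length(mods)
  G <- mods[[m]]
  if (m > 1L) {
    for (i in (m - 1L):1L) {
      G <- semidirect_product(mods[[i]], G, decomp$schemes[[i]])
    }
  }
  if (reorder && !is.null(decomp$variable_order)) {
    G <- reorder_variables(G, decomp$variable_order)
  }
  G
}

reorder_variables <- function(net, order) {
  stopifnot(setequal(order, net$variables))
  boolean_network(order, net$rules[order], net$external)
}
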