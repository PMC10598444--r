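## Node and edge controls, stabilization, and modular control composition.
##
## A control action models an experimental intervention: pinning a node to a
## constant expression level (node-constant), knocking a node out
## (node-deletion, pinned to 0 and substituted out of every rule), fixing
## the influence a source node exerts on one target rule (edge-constant), or
## severing that influence (edge-deletion, the source read as constant 0 in
## the target rule). A control set stabilizes a network at an attractor C
## when the controlled network has C as its only attractor.

#' Build a control action
#'
#' @param kind One of `"node-constant"`, `"node-deletion"`,
#'   `"edge-constant"`, `"edge-deletion"`.
#' @param target Target variable (the regulated node, for edge kinds).
#' @param value Pinned bit for the constant kinds (deletions use 0).
#' @param source Source variable, for edge kinds only.
#' @return An object of class `bn_control`.
#' @export
control_action <- function(kind = c("node-constant", "node-deletion",
                                    "edge-constant", "edge-deletion"),
                           target, value = NULL, source = NULL) {
  kind <- match.arg(kind)
  edge <- kind %in% c("edge-constant", "edge-deletion")
  if (edge && is.null(source)) stop("edge controls need a `source`")
  if (kind %in% c("node-deletion", "edge-deletion")) value <- 0L
  if (is.null(value)) stop(kind, " needs a `value`")
  structure(list(kind = kind, target = target,
                 source = if (edge) source, value = as.integer(value)),
            class = "bn_control")
}

#' @export
print.bn_control <- function(x, ...) {
  cat(switch(x$kind,
    "node-constant" = sprintf("pin %s := %d", x$target, x$value),
    "node-deletion" = sprintf("delete node %s", x$target),
    "edge-constant" = sprintf("fix edge %s -> %s at %d", x$source, x$target,
                              x$value),
    "edge-deletion" = sprintf("delete edge %s -> %s", x$source, x$target)),
    "\n")
  invisible(x)
}

validate_controls <- function(net, controls) {
  controls <- if (inherits(controls, "bn_control")) list(controls)
              else as.list(controls)
  pins <- list()
  for (a in controls) {
    stopifnot(inherits(a, "bn_control"))
    if (!a$target %in% net$variables) {
      stop("control targets unknown variable '", a$target, "'")
    }
    if (!is.null(a$source)) {
      if (!a$source %in% c(net$variables, net$external)) {
        stop("edge control has unknown source '", a$source, "'")
      }
      if (!a$source %in% net$rules[[a$target]]$regulators) {
        stop("edge control on non-existent edge ", a$source, " -> ",
             a$target)
      }
    }
    if (a$kind %in% c("node-constant", "node-deletion")) {
      prev <- pins[[a$target]]
      if (!is.null(prev) && prev != a$value) {
        stop("conflicting controls pin '", a$target, "' to both 0 and 1")
      }
      pins[[a$target]] <- a$value
    }
  }
  controls
}

#' Apply a set of control actions to a network
#'
#' Node-constant controls replace the target's rule by the constant;
#' node-deletions pin the node to 0 and substitute 0 for it in every other
#' rule; edge controls substitute the given constant for the source inside
#' the target's rule only. The result is reduced to essential regulators.
#' Controlled variables remain in the network (with constant rules), so
#' states of the controlled network are comparable with states of the
#' original.
#'
#' @param net A [boolean_network()].
#' @param controls A list of [control_action()]s (or a single one).
#' @return A [boolean_network()] on the same variables.
#' @export
apply_controls <- function(net, controls) {
  controls <- validate_controls(net, controls)
  rules <- net$rules
  for (a in controls) {
    if (a$kind %in% c("node-constant", "node-deletion")) {
      rules[[a$target]] <- list(regulators = character(0),
                                tt = a$value)
      if (a$kind == "node-deletion") {
        for (v in net$variables) {
          if (v != a$target) {
            rules[[v]] <- substitute_constant(rules[[v]], a$target, 0L)
          }
        }
      }
    } else {
      rules[[a$target]] <- substitute_constant(rules[[a$target]],
                                               a$source, a$value)
    }
  }
  reduce_to_essential_regulators(
    boolean_network(net$variables, rules, net$external))
}

#' Does a control set stabilize a network at a given attractor?
#'
#' Applies the controls and checks that the controlled network's attractor
#' set is exactly `{C}`. A pinned coordinate inconsistent with `C` simply
#' makes the check fail.
#'
#' @param net A [boolean_network()] without external parameters.
#' @param controls List of [control_action()]s (possibly empty).
#' @param C Target `bn_attractor` over `net`'s variables, or a state string
#'   for a steady-state target.
#' @param method `"decompose"` (default) uses [dynamic_decompose()];
#'   `"exhaustive"` sweeps the full state space.
#' @param guard Sweep guard.
#' @return `TRUE` or `FALSE`.
#' @export
verify_stabilization <- function(net, controls, C,
                                 method = c("decompose", "exhaustive"),
                                 guard = 24L) {
  method <- match.arg(method)
  if (is.character(C)) C <- new_attractor(C)
  ctl <- apply_controls(net, controls)
  aset <- if (method == "decompose") dynamic_decompose(ctl, guard = guard)
          else enumerate_attractors(ctl, guard = guard)
  length(aset$attractors) == 1L &&
    identical(aset$attractors[[1L]]$states, C$states)
}

#' Compose module-level controls into a whole-network control set
#'
#' For a decomposable network `F = F1 |x_P F2`, a control set stabilizing
#' `F1` at `C1` and one stabilizing the driven network `F2^C1` at `C2`
#' together stabilize `F` at `C1 (+) C2`, provided `C1` or `C2` is a steady
#' state. This function walks the modules of a decomposition in topological
#' order, checks each module control against the already-stabilized upstream
#' trajectory, enforces the steady-state hypothesis at every pairwise
#' composition, and returns the union of the controls with the composed
#' attractor. The composed pair is finally re-verified on the full network.
#'
#' @param decomp A `bn_decomposition` of the full network.
#' @param module_controls List (one element per module) of lists of
#'   [control_action()]s; actions are expressed on the module's own
#'   variables. May be empty lists for modules needing no control.
#' @param module_targets List (one per module) of target `bn_attractor`s (or
#'   state strings) on the module's variables.
#' @param guard Sweep guard.
#' @return A list with `controls` (the union), `attractor` (the composed
#'   `bn_attractor` on the full network) and `verified` (`TRUE`; failure to
#'   stabilize or an unmet hypothesis raises an error instead).
#' @export
compose_module_controls <- function(decomp, module_controls, module_targets,
                                    guard = 24L) {
  m <- length(decomp$modules)
  stopifnot(length(module_controls) == m, length(module_targets) == m)
  full <- recompose(decomp)
  acc_attr <- NULL                 # composed attractor over acc_vars
  acc_vars <- character(0)
  all_controls <- list()
  for (i in seq_len(m)) {
    Fi <- decomp$modules[[i]]
    Ci <- module_targets[[i]]
    if (is.character(Ci)) Ci <- new_attractor(Ci)
    ctl_i <- validate_controls(Fi, module_controls[[i]])
    Fi_ctl <- apply_controls(Fi, ctl_i)
    if (length(Fi_ctl$external)) {
      ## driven module: stabilize under the upstream trajectory
      if (is.null(acc_attr)) stop("module ", i, " has unresolved inputs")
      P <- stats::setNames(Fi_ctl$external, Fi_ctl$external)
      g <- input_trajectory(acc_attr, P, acc_vars)
      pas <- nonautonomous_attractors(Fi_ctl, g, guard = guard)
      ok <- length(pas) == 1L &&
        identical(pas[[1L]]$attractor$states, Ci$states)
      if (!ok) {
        stop("controls for module ", i,
             " do not stabilize it at the requested attractor under the ",
             "stabilized upstream trajectory")
      }
      pa <- pas[[1L]]
    } else {
      aset <- enumerate_attractors(Fi_ctl, guard = guard)
      ok <- length(aset$attractors) == 1L &&
        identical(aset$attractors[[1L]]$states, Ci$states)
      if (!ok) {
        stop("controls for module ", i,
             " do not stabilize it at the requested attractor")
      }
      pa <- structure(
        list(ys = Ci$states, period = length(Ci$states),
             input_period = max(1L, length(acc_attr$states)),
             phase = 0L, variables = Fi$variables, attractor = Ci),
        class = "bn_phased_attractor")
    }
    if (is.null(acc_attr)) {
      acc_attr <- Ci
      acc_vars <- Fi$variables
    } else {
      if (length(acc_attr$states) > 1L && pa$period > 1L) {
        stop("composition hypothesis unmet: neither the upstream composed ",
             "attractor nor the module target is a steady state")
      }
      ## align a free-running steady/cyclic pair on the combined period
      l <- lcm2(length(acc_attr$states), pa$period)
      if (length(pa$ys) != l) {
        pa$ys <- pa$ys[((seq_len(l) - 1L) %% pa$period) + 1L]
      }
      acc_attr <- compose_attractor(acc_attr, pa, acc_vars, Fi$variables)
      acc_vars <- c(acc_vars, Fi$variables)
    }
    all_controls <- c(all_controls, ctl_i)
  }
  ## express the composed attractor in the full network's variable order
  perm <- match(full$variables, acc_vars)
  states <- vapply(acc_attr$states, function(s)
    paste(string_to_bits(s)[perm], collapse = ""), character(1))
  C_full <- new_attractor(states)
  if (!verify_stabilization(full, all_controls, C_full, guard = guard)) {
    stop("composed controls failed verification on the full network")
  }
  list(controls = all_controls, attractor = C_full, verified = TRUE)
}

lcm2 <- function(a, b) a * b %/% gcd2(a, b)
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Exhaustive search for minimal stabilizing control sets
#'
#' Enumerates candidate node-constant (and optionally edge) control sets by
#' increasing size and returns all sets of the smallest size that stabilize
#' the network at the target attractor. Intended for small networks; the
#' modular strategy in [compose_module_controls()] scales further.
#'
#' @param net A [boolean_network()] without external parameters.
#' @param C Target `bn_attractor` or state string.
#' @param max_size Largest control-set size to try.
#' @param kinds Control kinds to enumerate (default node-constant).
#' @param guard Sweep guard.
#' @return A list of control sets (possibly empty if `max_size` is
#'   exhausted); each element is a list of [control_action()]s.
#' @export
search_minimal_controls <- function(net, C, max_size = 3L,
                                    kinds = "node-constant", guard = 24L) {
  if (is.character(C)) C <- new_attractor(C)
  candidates <- list()
  if ("node-constant" %in% kinds) {
    for (v in net$variables) for (b in c(0L, 1L)) {
      candidates[[length(candidates) + 1L]] <-
        control_action("node-constant", v, b)
    }
  }
  if ("edge-constant" %in% kinds || "edge-deletion" %in% kinds) {
    wd <- wiring_diagram(net)
    for (e in seq_len(nrow(wd$edges))) {
      if ("edge-deletion" %in% kinds) {
        candidates[[length(candidates) + 1L]] <-
          control_action("edge-deletion", wd$edges$to[e],
                         source = wd$edges$from[e])
      }
      if ("edge-constant" %in% kinds) {
        for (b in c(0L, 1L)) {
          candidates[[length(candidates) + 1L]] <-
            control_action("edge-constant", wd$edges$to[e], b,
                           source = wd$edges$from[e])
        }
      }
    }
  }
  for (size in 0:max_size) {
    hits <- list()
    for (idx in combn_list(length(candidates), size)) {
      set <- candidates[idx]
      ok <- tryCatch(
        verify_stabilization(net, set, C, method = "exhaustive",
                             guard = guard),
        error = function(e) FALSE)   # conflicting pins etc.
      if (ok) hits[[length(hits) + 1L]] <- set
    }
    if (length(hits)) return(hits)
  }
  list()
}

combn_list <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  if (k > n) return(list())
  asplit(utils::combn(n, k), 2L)
}
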