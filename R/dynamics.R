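## Dynamics of coupled networks: periodic input trajectories, attractors of
## non-autonomously driven networks, attractor composition, and the dynamic
## decomposition theorem (module attractors compose to exactly the attractors
## of the whole network).

#' Input trajectory induced by an upstream attractor
#'
#' An upstream network sitting on an attractor `C1 = (a_1, ..., a_r)` drives
#' its downstream neighbours through the coupling scheme: at time `t` the
#' downstream network reads the projection of `a_{t mod r}` onto the coupled
#' upstream variables. The resulting periodic sequence `g(t)` has period
#' `r = |C1|` and is anchored at the canonical rotation of `C1` (its
#' lexicographically smallest state at `t = 0`).
#'
#' @param C1 A `bn_attractor` of the upstream network.
#' @param P Coupling scheme: named character vector, downstream parameter ->
#'   upstream variable.
#' @param upstream The upstream [boolean_network()] or its character vector
#'   of variable names (to locate the projected coordinates).
#' @return An object of class `bn_input_trajectory`: list with `values`
#'   (r x |P| 0/1 matrix, columns named by the downstream parameters) and
#'   `period` (r).
#' @export
input_trajectory <- function(C1, P, upstream) {
  P <- as_coupling(P)
  vars <- if (inherits(upstream, "boolean_network")) upstream$variables
          else as.character(upstream)
  if (!all(P %in% vars)) {
    stop("every coupling value must be an upstream variable")
  }
  pos <- match(P, vars)
  vals <- t(vapply(C1$states, function(s) string_to_bits(s)[pos],
                   integer(length(P))))
  if (length(P) == 1L) vals <- matrix(vals, ncol = 1L)
  colnames(vals) <- names(P)
  rownames(vals) <- NULL
  structure(list(values = vals, period = length(C1$states)),
            class = "bn_input_trajectory")
}

#' @export
print.bn_input_trajectory <- function(x, ...) {
  cat("Periodic input trajectory, period ", x$period, ", parameters: ",
      paste(colnames(x$values), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Attractors of a periodically driven Boolean network
#'
#' A network `G` with external parameters driven by a periodic input
#' trajectory `g(t)` of period `r` is a non-autonomous Boolean network
#' `y(t+1) = G(g(t), y(t))`. Its attractors are computed as the cycles of
#' the finite deterministic *product automaton* on pairs
#' `(t mod r, y) -> ((t+1) mod r, G(g(t), y))`: every cycle of this automaton
#' is one attractor of the driven system, reported with its phase anchoring.
#'
#' @param G A [boolean_network()] with external parameters.
#' @param g A `bn_input_trajectory` covering (a subset of) `G`'s parameters.
#' @param constants Named 0/1 vector pinning any parameter not covered by
#'   `g`; every parameter must be covered one way or the other.
#' @param guard Maximum number of variables of `G` for the sweep.
#' @return A list of `bn_phased_attractor` objects, each with elements
#'   `ys` (the driven state sequence over one full combined period
#'   `l = lcm(r, s)`, anchored at phase 0 and the smallest phase-0 state),
#'   `period` (`s`, the minimal period of the driven sequence — the length of
#'   the attractor of the non-autonomous network), `input_period` (`r`) and
#'   `attractor` (the canonical `bn_attractor` on the driven variables).
#' @examples
#' F1 <- parse_rules(c("x1, x2", "x2, x1"))
#' G  <- parse_rules(c("# inputs: u", "x3, u & x4", "x4, x3"))
#' C1 <- enumerate_attractors(F1)$attractors[[2]]  # the 2-cycle (01, 10)
#' g  <- input_trajectory(C1, c(u = "x2"), F1)
#' nonautonomous_attractors(G, g)
#' @export
nonautonomous_attractors <- function(G, g, constants = NULL, guard = 24L) {
  stopifnot(inherits(g, "bn_input_trajectory"))
  pars <- colnames(g$values)
  if (!all(pars %in% G$external)) {
    stop("trajectory drives parameter(s) the network does not declare")
  }
  rest <- setdiff(G$external, pars)
  if (length(rest)) {
    if (is.null(constants) || !all(rest %in% names(constants))) {
      stop("unmapped parameter(s) need constants: ",
           paste(rest, collapse = ", "))
    }
    G <- pin_external(G, constants[rest])
  }
  n <- n_vars(G)
  if (n > guard) stop("driven sweep refused for n = ", n, " > guard")
  r <- g$period
  ## one transition table per phase
  tabs <- lapply(seq_len(r), function(t)
    transition_table(G, fixed = g$values[t, , drop = TRUE], guard = guard))
  size <- 2^n
  nxt1 <- integer(r * size)
  for (t in seq_len(r)) {
    block <- (t - 1L) * size + seq_len(size)
    nxt1[block] <- (t %% r) * size + tabs[[t]] + 1L
  }
  fg <- functional_graph_cycles(nxt1)
  lapply(fg$cycles, function(cyc) {
    code <- cyc - 1L
    phase <- code %/% size
    y <- code %% size
    ## anchor at phase 0, smallest y among phase-0 states
    zero <- which(phase == 0L)
    a <- zero[which.min(y[zero])]
    if (a > 1L) code <- c(code[a:length(code)], code[seq_len(a - 1L)])
    ys <- code_to_string(code %% size, n)
    s <- minimal_period(ys)
    structure(
      list(ys = ys, period = s, input_period = r, phase = 0L,
           variables = G$variables,
           attractor = new_attractor(ys[seq_len(s)])),
      class = "bn_phased_attractor"
    )
  })
}

minimal_period <- function(x) {
  L <- length(x)
  for (s in seq_len(L)) {
    if (L %% s == 0L && all(x == x[((seq_len(L) - 1L) %% s) + 1L])) return(s)
  }
  L
}

#' @export
print.bn_phased_attractor <- function(x, ...) {
  cat("Driven attractor of length ", x$period, " (input period ",
      x$input_period, ", combined length ", length(x$ys), ")\n", sep = "")
  print(x$attractor)
  invisible(x)
}

#' Compose an upstream attractor with a driven attractor
#'
#' Builds the attractor `C1 (+) C2` of the combined network from an upstream
#' attractor `C1` and a phased attractor of the driven downstream network:
#' the `t`-th combined state pairs the upstream state `a_{t mod r}` with the
#' driven state at matching phase, giving a cycle of length
#' `l = lcm(|C1|, |C2|)`.
#'
#' @param C1 Upstream `bn_attractor` (canonical rotation anchors phase 0).
#' @param pa A `bn_phased_attractor` produced from `C1`'s input trajectory.
#' @param upstream_vars,downstream_vars Variable names of the two parts.
#' @param order Variable order of the combined network (default upstream
#'   then downstream).
#' @return A canonical `bn_attractor` on `order`.
#' @export
compose_attractor <- function(C1, pa, upstream_vars, downstream_vars,
                              order = c(upstream_vars, downstream_vars)) {
  r <- length(C1$states)
  if (!identical(pa$input_period, r)) {
    stop("phase mismatch: driven attractor was computed for input period ",
         pa$input_period, ", upstream attractor has length ", r)
  }
  L <- length(pa$ys)
  stopifnot(L %% r == 0L, setequal(order, c(upstream_vars, downstream_vars)))
  up_pos <- match(upstream_vars, order)
  down_pos <- match(downstream_vars, order)
  states <- vapply(seq_len(L), function(t) {
    bits <- integer(length(order))
    bits[up_pos] <- string_to_bits(C1$states[((t - 1L) %% r) + 1L])
    bits[down_pos] <- string_to_bits(pa$ys[t])
    paste(bits, collapse = "")
  }, character(1))
  new_attractor(states)
}

#' All attractors via dynamic decomposition
#'
#' Computes the attractor set of a Boolean network from the attractors of
#' its modules instead of a sweep of the full state space: the network is
#' decomposed structurally, the upstream-most module is enumerated directly,
#' and for each of its attractors the remaining (downstream) part is treated
#' as a non-autonomous network driven by that attractor's trajectory; the
#' resulting driven attractors are composed with the upstream attractor and
#' the procedure recurses. For a decomposable network this yields exactly
#' the same attractor set as [enumerate_attractors()], while never iterating
#' a subsystem larger than the downstream remainder. When the upstream
#' attractor is a steady state the downstream remainder becomes autonomous
#' (parameters pinned to constants) and the decomposition recurses fully.
#'
#' @param net A [boolean_network()] without external parameters.
#' @param guard Sweep guard passed down to the per-part enumerations.
#' @return A `bn_attractor_set` over `net`'s variables (no basin map).
#' @export
dynamic_decompose <- function(net, guard = 24L) {
  red <- reduce_to_essential_regulators(net)
  atts <- dynamic_decompose_impl(red, guard)
  new_attractor_set(atts, net$variables)
}

dynamic_decompose_impl <- function(net, guard) {
  decomp <- structural_decompose(net)
  m <- length(decomp$modules)
  if (m == 1L) {
    return(enumerate_attractors(net, guard = guard)$attractors)
  }
  F1 <- decomp$modules[[1L]]
  down_vars <- setdiff(net$variables, F1$variables)
  G <- restriction(net, down_vars)
  P <- stats::setNames(G$external, G$external)   # identity coupling by name
  A1 <- enumerate_attractors(F1, guard = guard)$attractors
  out <- list()
  for (C1 in A1) {
    if (length(C1$states) == 1L) {
      ## steady upstream drive: pin and recurse on the autonomous remainder
      bits <- string_to_bits(C1$states)
      consts <- stats::setNames(bits[match(P, F1$variables)], names(P))
      G0 <- pin_external(G, consts[G$external])
      for (C2 in dynamic_decompose_impl(G0, guard)) {
        pa <- structure(
          list(ys = C2$states, period = length(C2$states),
               input_period = 1L, phase = 0L, variables = G$variables,
               attractor = C2),
          class = "bn_phased_attractor")
        out[[length(out) + 1L]] <- compose_attractor(
          C1, pa, F1$variables, G$variables, order = net$variables)
      }
    } else {
      g <- input_trajectory(C1, P, F1)
      for (pa in nonautonomous_attractors(G, g, guard = guard)) {
        out[[length(out) + 1L]] <- compose_attractor(
          C1, pa, F1$variables, G$variables, order = net$variables)
      }
    }
  }
  out
}
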