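## Attractors and attractor sets.
##
## An attractor is a minimal state set C with F(C) = C: a steady state
## (length 1) or a limit cycle. Attractors are stored in canonical form as a
## cyclic sequence of bit strings rotated so that the lexicographically
## smallest state comes first, which gives stable set semantics.

new_attractor <- function(states) {
  states <- as.character(states)
  k <- which.min(states)  # lexicographic == numeric order on fixed-width bits
  if (k > 1L) states <- c(states[k:length(states)], states[seq_len(k - 1L)])
  structure(list(states = states), class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  if (length(x$states) == 1L) {
    cat("Steady state ", x$states, "\n", sep = "")
  } else {
    cat("Limit cycle of length ", length(x$states), ": (",
        paste(x$states, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
length.bn_attractor <- function(x) length(x$states)

attractor_key <- function(a) paste(a$states, collapse = ",")

new_attractor_set <- function(attractors, variables,
                              basin_map = NULL, basin_sizes = NULL) {
  keys <- vapply(attractors, attractor_key, character(1))
  ord <- order(keys)
  attractors <- attractors[ord]
  if (!is.null(basin_sizes)) basin_sizes <- basin_sizes[ord]
  if (!is.null(basin_map)) basin_map <- match(basin_map, ord)
  structure(
    list(attractors = attractors, variables = variables,
         basin_map = basin_map, basin_sizes = basin_sizes),
    class = "bn_attractor_set"
  )
}

#' @export
print.bn_attractor_set <- function(x, ...) {
  ns <- sum(lengths(lapply(x$attractors, `[[`, "states")) == 1L)
  cat("Attractor set: ", length(x$attractors), " attractor",
      if (length(x$attractors) != 1) "s",
      " (", ns, " steady state", if (ns != 1) "s", ")\n", sep = "")
  for (i in seq_along(x$attractors)) {
    cat(sprintf("  [%d] ", i))
    print(x$attractors[[i]])
  }
  invisible(x)
}

#' @export
length.bn_attractor_set <- function(x) length(x$attractors)

#' Tabulate an attractor set
#'
#' @param x A `bn_attractor_set` as returned by [enumerate_attractors()] or
#'   [sample_attractors()].
#' @param ... Unused.
#' @return A tibble with one row per attractor: `attractor` (id), `type`,
#'   `period`, `states` (states joined by `"->"`), and `basin_size` when a
#'   full basin map is available.
#' @exportS3Method tibble::as_tibble
as_tibble.bn_attractor_set <- function(x, ...) {
  out <- tibble::tibble(
    attractor = seq_along(x$attractors),
    type = vapply(x$attractors, function(a)
      if (length(a$states) == 1L) "steady state" else "limit cycle",
      character(1)),
    period = lengths(lapply(x$attractors, `[[`, "states")),
    states = vapply(x$attractors, function(a)
      paste(a$states, collapse = "->"), character(1))
  )
  if (!is.null(x$basin_sizes)) out$basin_size <- x$basin_sizes
  out
}

attractor_set_keys <- function(aset) {
  sort(vapply(aset$attractors, attractor_key, character(1)))
}

## cycles of a functional graph given by 1-based successor vector nxt1;
## returns list(cycle_id = per-node id or NA, cycles = list of integer
## vectors (1-based nodes, rotated to smallest), landing = for every node the
## node reached after >= length(nxt1) steps, guaranteed on a cycle)
functional_graph_cycles <- function(nxt1) {
  n_states <- length(nxt1)
  t <- nxt1
  steps <- 1
  while (steps < n_states) {   # pointer doubling: t = f^(2^d)
    t <- t[t]
    steps <- steps * 2
  }
  on_cycle <- unique(t)
  cyc_id <- rep(NA_integer_, n_states)
  cycles <- list()
  for (s in on_cycle) {
    if (!is.na(cyc_id[s])) next
    cur <- s
    cyc <- integer(0)
    repeat {
      cyc <- c(cyc, cur)
      cur <- nxt1[cur]
      if (cur == s) break
    }
    k <- which.min(cyc)
    if (k > 1L) cyc <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
    cycles[[length(cycles) + 1L]] <- cyc
    cyc_id[cyc] <- length(cycles)
  }
  list(cycles = cycles, cycle_id = cyc_id, landing = t)
}

#' Enumerate all attractors of a Boolean network
#'
#' Performs an exhaustive sweep of the full state space: the synchronous map
#' is evaluated for all \eqn{2^n} states, the cycles of the resulting
#' functional graph are the attractors, and every state is assigned to the
#' basin of the attractor its forward orbit reaches.
#'
#' @param net A [boolean_network()] without external parameters (restrict or
#'   couple first, or use [nonautonomous_attractors()]).
#' @param guard Refuse the sweep for more than this many variables (memory
#'   grows as \eqn{2^n}); default 24.
#' @return A `bn_attractor_set` with a total basin map (`basin_map[s + 1]` is
#'   the attractor index of state code `s`) and `basin_sizes` summing to
#'   \eqn{2^n}.
#' @examples
#' net <- parse_rules(c("x1, x2 & !x3", "x2, x3", "x3, !x1 & x2"))
#' enumerate_attractors(net)  # 000, 011 and the 2-cycle (010, 101)
#' @export
enumerate_attractors <- function(net, guard = 24L) {
  if (length(net$external)) {
    stop("network has external parameters; use nonautonomous_attractors()")
  }
  n <- n_vars(net)
  nxt1 <- transition_table(net, guard = guard) + 1L
  fg <- functional_graph_cycles(nxt1)
  atts <- lapply(fg$cycles, function(cyc) new_attractor(code_to_string(cyc - 1L, n)))
  basin_map <- fg$cycle_id[fg$landing]
  basin_sizes <- tabulate(basin_map, nbins = length(atts))
  new_attractor_set(atts, net$variables,
                    basin_map = basin_map, basin_sizes = basin_sizes)
}

#' Follow one trajectory to its attractor
#'
#' Synchronously updates from a start state until a previously visited state
#' recurs, which marks arrival at an attractor.
#'
#' @param net A [boolean_network()] without external parameters.
#' @param start Start state (bit string, 0/1 vector, or integer code).
#' @return A list with `attractor` (canonical `bn_attractor`) and
#'   `transient` (number of steps taken before the first attractor state).
#' @export
iterate_to_attractor <- function(net, start) {
  if (length(net$external)) {
    stop("network has external parameters; pin or couple them first")
  }
  n <- n_vars(net)
  bits <- as_state_bits(start, n)
  cur <- paste(bits, collapse = "")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- character(0)
  repeat {
    if (!is.null(seen[[cur]])) {
      first <- seen[[cur]]
      cyc <- path[first:length(path)]
      return(list(attractor = new_attractor(cyc), transient = first - 1L))
    }
    path <- c(path, cur)
    seen[[cur]] <- length(path)
    cur <- synchronous_step(net, cur)
  }
}

## vectorised trajectory landing for sampled codes when a transition table is
## affordable; returns cycle structure shared with enumerate
sample_landing_small <- function(net, codes, guard) {
  nxt1 <- transition_table(net, guard = guard) + 1L
  fg <- functional_graph_cycles(nxt1)
  fg$cycle_id[fg$landing[codes + 1L]]
}

#' Estimate the attractor repertoire by sampling initial states
#'
#' Draws `n_samples` initial states uniformly at random (with replacement)
#' and follows each to its attractor. The set of distinct attractors found is
#' a lower bound on the true attractor repertoire; an attractor whose basin
#' occupies a fraction `p` of state space is missed with probability
#' \eqn{(1 - p)^{n_{samples}}} (see [attractor_detection_probability()]).
#'
#' @param net A [boolean_network()] without external parameters.
#' @param n_samples Number of random initial states (>= 1).
#' @param seed Integer seed; results are reproducible given `(seed, net)`.
#' @param guard Networks with at most `guard` variables use a precomputed
#'   transition table internally; larger networks follow each trajectory
#'   individually (any number of variables).
#' @return A `bn_attractor_set` (no basin map); the attribute
#'   `"sample_attractor"` holds, per sampled state, the index of the
#'   attractor it reached, and `"sample_codes"`/`"sample_states"` record the
#'   draws so that robustness estimation can reuse them.
#' @export
sample_attractors <- function(net, n_samples, seed = NULL, guard = 24L) {
  stopifnot(n_samples >= 1)
  if (length(net$external)) {
    stop("network has external parameters; pin or couple them first")
  }
  n <- n_vars(net)
  if (!is.null(seed)) set.seed(seed)
  if (n <= guard) {
    codes <- floor(stats::runif(n_samples) * 2^n)
    nxt1 <- transition_table(net, guard = guard) + 1L
    fg <- functional_graph_cycles(nxt1)
    hit <- fg$cycle_id[fg$landing[codes + 1L]]
    found <- sort(unique(hit))
    atts <- lapply(fg$cycles[found],
                   function(cyc) new_attractor(code_to_string(cyc - 1L, n)))
    aset <- new_attractor_set(atts, net$variables)
    ## map per-sample hits onto the canonical (sorted) attractor order
    keys_all <- vapply(fg$cycles[found], function(cyc)
      attractor_key(new_attractor(code_to_string(cyc - 1L, n))), character(1))
    keys_set <- vapply(aset$attractors, attractor_key, character(1))
    attr(aset, "sample_attractor") <- match(keys_all, keys_set)[match(hit, found)]
    attr(aset, "sample_codes") <- codes
    return(aset)
  }
  states <- matrix(stats::rbinom(n_samples * n, 1L, 0.5),
                   nrow = n_samples, ncol = n)
  keys <- character(0)
  atts <- list()
  hit <- integer(n_samples)
  for (i in seq_len(n_samples)) {
    res <- iterate_to_attractor(net, states[i, ])
    key <- attractor_key(res$attractor)
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      atts[[length(atts) + 1L]] <- res$attractor
      j <- length(atts)
    }
    hit[i] <- j
  }
  aset <- new_attractor_set(atts, net$variables)
  keys_set <- vapply(aset$attractors, attractor_key, character(1))
  attr(aset, "sample_attractor") <- match(keys, keys_set)[hit]
  attr(aset, "sample_states") <- states
  aset
}

#' Probability of detecting an attractor by random restarts
#'
#' Closed-form coverage of the sampling strategy: an attractor whose basin
#' attracts a fraction `p` of the state space is found from at least one of
#' `n_samples` independent uniform initial states with probability
#' \eqn{1 - (1 - p)^{n_{samples}}}.
#'
#' @param p Basin fraction(s) in \[0, 1\].
#' @param n_samples Number of random initial states.
#' @return Detection probability (vectorised over `p`).
#' @examples
#' attractor_detection_probability(0.006, 500)  # about 0.95
#' @export
attractor_detection_probability <- function(p, n_samples) {
  stopifnot(all(p >= 0), all(p <= 1), n_samples >= 1)
  1 - (1 - p)^n_samples
}
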