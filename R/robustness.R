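## Phenotypical robustness, Derrida value, dynamical complexity.
##
## Phenotypical robustness r(F) labels every vertex of the Boolean hypercube
## by the attractor its forward orbit reaches and reports the fraction of
## hypercube edges whose two endpoints carry the same label. The ordered and
## unordered formulations agree because the comparison is symmetric; the
## implementation uses unordered edges (normalizer n * 2^(n-1), half the
## work).

new_robustness_report <- function(r, method, n_samples = NA_integer_,
                                  n_attractors = NA_integer_, seed = NULL) {
  structure(
    list(r_estimate = r, method = method, n_samples = n_samples,
         n_attractors_found = n_attractors, seed = seed),
    class = "bn_robustness"
  )
}

#' @export
print.bn_robustness <- function(x, ...) {
  cat("Phenotypical robustness: r = ", format(x$r_estimate),
      " (", x$method, sep = "")
  if (!is.na(x$n_samples)) cat(", ", x$n_samples, " samples", sep = "")
  cat(")\n")
  if (!is.na(x$n_attractors_found)) {
    cat("Attractors found: ", x$n_attractors_found, "\n", sep = "")
  }
  invisible(x)
}

#' Exact phenotypical robustness
#'
#' Computes the full basin map over all \eqn{2^n} states and counts the
#' hypercube edges (pairs of states differing in exactly one bit) whose
#' endpoints flow to the same attractor. The result is
#' `same_edges / (n * 2^(n-1))` and equals 1 exactly when the network has a
#' single attractor.
#'
#' @param net A [boolean_network()] without external parameters.
#' @param guard Sweep guard (default 24 variables).
#' @return A `bn_robustness` report with `method = "exact"`.
#' @export
exact_robustness <- function(net, guard = 24L) {
  n <- n_vars(net)
  aset <- enumerate_attractors(net, guard = guard)
  lab <- aset$basin_map
  codes <- 0:(2^n - 1)
  same <- 0
  for (j in 0:(n - 1L)) {
    nb <- bitwXor(codes, bitwShiftL(1L, j))
    upper <- nb > codes                      # each edge once
    same <- same + sum(lab[codes[upper] + 1L] == lab[nb[upper] + 1L])
  }
  new_robustness_report(same / (n * 2^(n - 1)), "exact",
                        n_attractors = length(aset$attractors))
}

#' Sampled phenotypical robustness
#'
#' Monte-Carlo estimate for networks too large for a full sweep: for each of
#' `n_samples` uniform random states `x0` a single uniformly chosen bit is
#' flipped to give `y0`, both are followed to their attractors, and the
#' estimate is the fraction of pairs reaching the same attractor. Estimates
#' are therefore multiples of `1 / n_samples`. When `aset` (the result of
#' [sample_attractors()] on the same network) is supplied, the same sampled
#' initial states are reused for `x0`, so robustness and dynamical
#' complexity come from one set of draws.
#'
#' @param net A [boolean_network()] without external parameters.
#' @param n_samples Number of perturbation pairs.
#' @param seed Integer seed.
#' @param aset Optional `bn_attractor_set` from [sample_attractors()] whose
#'   recorded draws are reused.
#' @param guard Networks up to this size use a precomputed transition table.
#' @return A `bn_robustness` report with `method = "sampled"`.
#' @export
sampled_robustness <- function(net, n_samples, seed = NULL, aset = NULL,
                               guard = 24L) {
  stopifnot(n_samples >= 1)
  n <- n_vars(net)
  if (length(net$external)) stop("pin or couple external parameters first")
  if (!is.null(seed)) set.seed(seed)
  if (n <= guard) {
    if (!is.null(aset) && !is.null(attr(aset, "sample_codes"))) {
      codes <- attr(aset, "sample_codes")
      n_samples <- length(codes)
    } else {
      codes <- floor(stats::runif(n_samples) * 2^n)
    }
    flip <- floor(stats::runif(n_samples) * n)      # bit position 0..n-1
    pert <- bitwXor(as.integer(codes), bitwShiftL(1L, as.integer(flip)))
    nxt1 <- transition_table(net, guard = guard) + 1L
    fg <- functional_graph_cycles(nxt1)
    lab <- fg$cycle_id[fg$landing]
    score <- lab[codes + 1L] == lab[pert + 1L]
    n_att <- length(unique(lab[codes + 1L]))
    return(new_robustness_report(mean(score), "sampled", n_samples,
                                 n_attractors = n_att, seed = seed))
  }
  if (!is.null(aset) && !is.null(attr(aset, "sample_states"))) {
    states <- attr(aset, "sample_states")
    n_samples <- nrow(states)
  } else {
    states <- matrix(stats::rbinom(n_samples * n, 1L, 0.5), nrow = n_samples)
  }
  flip <- sample.int(n, n_samples, replace = TRUE)
  score <- logical(n_samples)
  keys <- character(n_samples)
  for (i in seq_len(n_samples)) {
    x0 <- states[i, ]
    y0 <- x0
    y0[flip[i]] <- 1L - y0[flip[i]]
    ax <- iterate_to_attractor(net, x0)$attractor
    ay <- iterate_to_attractor(net, y0)$attractor
    keys[i] <- attractor_key(ax)
    score[i] <- identical(ax$states, ay$states)
  }
  new_robustness_report(mean(score), "sampled", n_samples,
                        n_attractors = length(unique(keys)), seed = seed)
}

#' Derrida value of a Boolean network
#'
#' Average Hamming distance between the images of two states that differ in
#' a single bit, after one synchronous update. The exact method averages
#' over all `n * 2^(n-1)` unordered single-flip pairs; the sampled method
#' draws random pairs.
#'
#' @param net A [boolean_network()] without external parameters.
#' @param method `"exact"` (full sweep) or `"sampled"`.
#' @param n_samples,seed Sampling controls for `method = "sampled"`.
#' @param guard Sweep guard.
#' @return The mean Hamming distance (a single number in `[0, n]`).
#' @export
derrida_value <- function(net, method = c("exact", "sampled"),
                          n_samples = 1000L, seed = NULL, guard = 24L) {
  method <- match.arg(method)
  n <- n_vars(net)
  if (method == "exact") {
    nxt <- transition_table(net, guard = guard)
    codes <- 0:(2^n - 1)
    total <- 0
    count <- 0
    for (j in 0:(n - 1L)) {
      nb <- bitwXor(codes, bitwShiftL(1L, j))
      upper <- nb > codes
      total <- total + sum(popcount(bitwXor(nxt[codes[upper] + 1L],
                                            nxt[nb[upper] + 1L]), n))
      count <- count + sum(upper)
    }
    return(total / count)
  }
  if (!is.null(seed)) set.seed(seed)
  states <- matrix(stats::rbinom(n_samples * n, 1L, 0.5), nrow = n_samples)
  flip <- sample.int(n, n_samples, replace = TRUE)
  d <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    x0 <- states[i, ]
    y0 <- x0
    y0[flip[i]] <- 1L - y0[flip[i]]
    fx <- string_to_bits(synchronous_step(net, x0))
    fy <- string_to_bits(synchronous_step(net, y0))
    d[i] <- sum(fx != fy)
  }
  mean(d)
}

## number of set bits for each value (codes < 2^n)
popcount <- function(x, n) {
  out <- integer(length(x))
  for (j in 0:(n - 1L)) out <- out + bitwAnd(bitwShiftR(x, j), 1L)
  out
}

#' Dynamical complexity (sampled lower bound on the number of attractors)
#'
#' The number of attractors of a Boolean network measures its dynamical
#' complexity — the size of its phenotype repertoire. For networks beyond
#' exhaustive reach this is estimated as the number of distinct attractors
#' found from random initial states, a lower bound that is non-decreasing in
#' the number of samples.
#'
#' @inheritParams sample_attractors
#' @return Integer count of distinct attractors found.
#' @export
dynamical_complexity <- function(net, n_samples, seed = NULL, guard = 24L) {
  length(sample_attractors(net, n_samples, seed = seed, guard = guard))
}
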