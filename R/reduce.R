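#' Remove non-essential regulators from every update rule
#'
#' A regulator is *essential* for a rule if toggling it changes the rule's
#' output in at least one context of the remaining regulators. Published
#' models sometimes list regulators that never affect the output; these are
#' dropped here and the truth tables shrunk accordingly. The returned network
#' has state-by-state identical dynamics.
#'
#' @param net A [boolean_network()].
#' @return A [boolean_network()] whose rules depend essentially on every
#'   listed regulator. Idempotent.
#' @export
reduce_to_essential_regulators <- function(net) {
  rules <- lapply(net$rules, reduce_rule)
  boolean_network(net$variables, rules, net$external)
}

reduce_rule <- function(r) {
  regs <- r$regulators
  tt <- r$tt
  repeat {
    k <- length(regs)
    if (k == 0L) break
    dropped <- FALSE
    for (j in seq_len(k)) {
      m <- 0:(2^k - 1)
      bit_j <- bitwAnd(bitwShiftR(m, k - j), 1L)
      lo <- tt[m[bit_j == 0L] + 1L]
      hi <- tt[m[bit_j == 1L] + 1L]
      if (identical(lo, hi)) {      # regulator j never matters
        regs <- regs[-j]
        tt <- lo
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  list(regulators = regs, tt = tt)
}

## fix one regulator of a rule to a constant value, dropping it from the
## regulator list (used by restriction-with-pinning and edge controls)
substitute_constant <- function(r, reg, value) {
  j <- match(reg, r$regulators)
  if (is.na(j)) return(r)
  k <- length(r$regulators)
  m <- 0:(2^k - 1)
  bit_j <- bitwAnd(bitwShiftR(m, k - j), 1L)
  keep <- m[bit_j == as.integer(value)] + 1L
  list(regulators = r$regulators[-j], tt = r$tt[keep])
}

## rename regulators of a rule (truth table untouched; order preserved)
rename_regulators <- function(r, map) {
  hit <- r$regulators %in% names(map)
  r$regulators[hit] <- unname(map[r$regulators[hit]])
  r
}

#' Pin external parameters of a network to constants
#'
#' Substitutes constant values for (a subset of) the external parameters,
#' yielding a network whose remaining external parameters are those not
#' pinned. With all parameters pinned the result is autonomous and can be
#' handed to [enumerate_attractors()].
#'
#' @param net A [boolean_network()] with external parameters.
#' @param values Named 0/1 vector, names a subset of `net$external`.
#' @return A [boolean_network()].
#' @export
pin_external <- function(net, values) {
  stopifnot(all(names(values) %in% net$external))
  rules <- lapply(net$rules, function(r) {
    for (p in intersect(names(values), r$regulators)) {
      r <- substitute_constant(r, p, values[[p]])
    }
    r
  })
  boolean_network(net$variables, rules,
                  setdiff(net$external, names(values)))
}
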