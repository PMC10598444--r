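#' Construct a synchronous Boolean network
#'
#' A Boolean network is a finite dynamical system on binary state vectors
#' \eqn{x = (x_1, \dots, x_n)}, updated coordinate-wise and synchronously by
#' logic rules \eqn{f_i}. Each rule is stored as a truth table over its
#' regulators, so evaluation is a single table lookup. A network may declare
#' *external parameters*: input symbols that appear as regulators but are not
#' themselves updated. A network with external parameters arises naturally as
#' the restriction of a larger network to a subset of its variables (see
#' [restriction()]) and is the building block of semi-direct products.
#'
#' @param variables Character vector of unique variable names. Their order is
#'   fixed and defines the coordinate order of states: the canonical textual
#'   form of a state is the concatenated bit string, first variable leftmost,
#'   so `"010"` means `x1 = 0, x2 = 1, x3 = 0`.
#' @param rules List of rules, one per variable, each a list with elements
#'   `regulators` (character vector of variable or external-parameter names,
#'   possibly empty for a constant rule) and `tt` (integer vector of 0/1 of
#'   length `2^length(regulators)`). Truth tables are indexed by the regulator
#'   values read as a binary number with the *first* regulator as the most
#'   significant bit: entry `1` is the output for all regulators 0, entry
#'   `2^k` the output for all regulators 1.
#' @param external Character vector of external parameter names, disjoint
#'   from `variables`. Defaults to none.
#'
#' @return An object of class `boolean_network`: a list with elements
#'   `variables`, `rules` (named after the variables) and `external`.
#' @examples
#' # The toy network F = (x2 & !x3, x3, !x1 & x2)
#' net <- parse_rules(c("x1, x2 & !x3", "x2, x3", "x3, !x1 & x2"))
#' synchronous_step(net, "010")
#' @export
boolean_network <- function(variables, rules, external = character()) {
  stopifnot(is.character(variables), length(variables) >= 1L)
  if (anyDuplicated(variables)) {
    stop("duplicate variable names: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "))
  }
  if (length(rules) != length(variables)) {
    stop("need exactly one rule per variable")
  }
  if (anyDuplicated(external) || any(external %in% variables)) {
    stop("external parameters must be unique and disjoint from variables")
  }
  names(rules) <- variables
  known <- c(variables, external)
  rules <- lapply(variables, function(v) {
    r <- rules[[v]]
    regs <- as.character(r$regulators %||% character())
    tt <- as.integer(r$tt)
    unknown <- setdiff(regs, known)
    if (length(unknown)) {
      stop("rule for '", v, "' uses unknown name(s): ",
           paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(regs)) stop("rule for '", v, "' lists a regulator twice")
    if (length(tt) != 2^length(regs) || !all(tt %in% c(0L, 1L))) {
      stop("rule for '", v, "' has a malformed truth table")
    }
    list(regulators = regs, tt = tt)
  })
  names(rules) <- variables
  structure(
    list(variables = variables, rules = rules,
         external = as.character(external)),
    class = "boolean_network"
  )
}

#' @export
print.boolean_network <- function(x, ...) {
  n <- length(x$variables)
  cat("Synchronous Boolean network with ", n, " variable",
      if (n != 1) "s", sep = "")
  if (length(x$external)) {
    cat(" and ", length(x$external), " external parameter",
        if (length(x$external) != 1) "s",
        " (", paste(x$external, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  txt <- serialize_rules(x, header = FALSE)
  cat(paste0("  ", txt), sep = "\n")
  invisible(x)
}

n_vars <- function(net) length(net$variables)

#' Number of variables and external parameters of a network
#'
#' @param net A [boolean_network()].
#' @return `bn_size()` returns a named integer vector with the number of
#'   `variables` and `external` parameters.
#' @export
bn_size <- function(net) {
  c(variables = length(net$variables), external = length(net$external))
}

## --- states -----------------------------------------------------------------
## A state is an integer code in 0 .. 2^n - 1 with variable 1 as the most
## significant bit, so numeric order on codes equals lexicographic order on
## the printed bit strings. Codes require n <= 30; trajectory-level functions
## additionally accept raw 0/1 vectors of any length.

state_to_code <- function(bits) {
  sum(as.integer(bits) * 2^((length(bits) - 1):0))
}

code_to_bits <- function(code, n) {
  bitwAnd(bitwShiftR(as.integer(code), (n - 1):0), 1L)
}

code_to_string <- function(code, n) {
  vapply(code, function(s) paste(code_to_bits(s, n), collapse = ""),
         character(1))
}

string_to_bits <- function(s) {
  bits <- as.integer(strsplit(s, "")[[1]])
  if (any(is.na(bits)) || !all(bits %in% c(0L, 1L))) {
    stop("state string must consist of 0s and 1s: '", s, "'")
  }
  bits
}

## Accept a state given as bit string, 0/1 vector, or integer code; return
## the 0/1 vector of length n.
as_state_bits <- function(state, n) {
  if (is.character(state)) {
    bits <- string_to_bits(state)
  } else if (length(state) == 1L && n > 1L) {
    stopifnot(state >= 0, state < 2^n)
    bits <- code_to_bits(state, n)
  } else {
    bits <- as.integer(state)
    stopifnot(all(bits %in% c(0L, 1L)))
  }
  if (length(bits) != n) {
    stop("state has length ", length(bits), " but the network has ", n,
         " variables")
  }
  bits
}

## index into a rule's truth table (1-based) for given regulator values
tt_index <- function(vals) {
  if (!length(vals)) return(1L)
  sum(as.integer(vals) * 2^((length(vals) - 1):0)) + 1L
}

#' Advance a Boolean network by one synchronous step
#'
#' Applies every update rule to the current state simultaneously:
#' \eqn{F(x) = (f_1(x), \dots, f_n(x))}.
#'
#' @param net A [boolean_network()].
#' @param state A state: a bit string such as `"010"`, a 0/1 vector in
#'   variable order, or (for networks with at most 30 variables) an integer
#'   state code.
#' @param inputs Values for the external parameters, required if and only if
#'   the network has any: a named 0/1 vector (names matching
#'   `net$external`), or an unnamed 0/1 vector in `net$external` order.
#' @return The successor state as a bit string.
#' @examples
#' net <- parse_rules(c("x1, x2 & !x3", "x2, x3", "x3, !x1 & x2"))
#' synchronous_step(net, "010")  # "101"
#' @export
synchronous_step <- function(net, state, inputs = NULL) {
  n <- n_vars(net)
  bits <- as_state_bits(state, n)
  env <- stats::setNames(as.list(bits), net$variables)
  if (length(net$external)) {
    if (is.null(inputs)) {
      stop("network has external parameters (",
           paste(net$external, collapse = ", "),
           "); supply `inputs`, or couple/pin them first")
    }
    if (is.null(names(inputs))) {
      stopifnot(length(inputs) == length(net$external))
      inputs <- stats::setNames(as.integer(inputs), net$external)
    }
    if (!all(net$external %in% names(inputs))) {
      stop("`inputs` must cover every external parameter")
    }
    env[net$external] <- as.integer(inputs[net$external])
  } else if (!is.null(inputs)) {
    stop("`inputs` supplied but the network has no external parameters")
  }
  out <- vapply(net$rules, function(r) {
    vals <- unlist(env[r$regulators], use.names = FALSE)
    r$tt[tt_index(vals)]
  }, integer(1))
  paste(out, collapse = "")
}

## --- vectorised transition table -------------------------------------------
## Successor code for every state 0 .. 2^n - 1 at once (0-based codes).
## `fixed` optionally pins external parameters to constants.
transition_table <- function(net, fixed = NULL, guard = 24L) {
  n <- n_vars(net)
  if (length(net$external)) {
    if (is.null(fixed) || !all(net$external %in% names(fixed))) {
      stop("external parameters must be pinned to constants for a full sweep")
    }
  }
  if (n > guard) {
    stop("full 2^n sweep refused for n = ", n, " > guard = ", guard,
         "; raise `guard` explicitly or use sampling/decomposition")
  }
  codes <- 0:(2^n - 1)
  pos <- stats::setNames(seq_len(n), net$variables)
  nxt <- numeric(length(codes))
  for (i in seq_len(n)) {
    r <- net$rules[[i]]
    idx <- rep.int(0L, length(codes))
    for (reg in r$regulators) {
      if (!is.na(pos[reg])) {
        bit <- bitwAnd(bitwShiftR(codes, n - pos[[reg]]), 1L)
      } else {
        bit <- rep.int(as.integer(fixed[[reg]]), length(codes))
      }
      idx <- idx * 2L + bit
    }
    nxt <- nxt + r$tt[idx + 1L] * 2^(n - i)
  }
  as.integer(nxt)
}

## Compare two networks; when `match_order` the variables must agree as an
## ordered sequence, otherwise as a set. Truth tables are compared after
## reduction to essential regulators with regulators sorted, so logically
## identical rules written differently count as equal.
bn_equal <- function(a, b, match_order = TRUE) {
  if (match_order) {
    if (!identical(a$variables, b$variables)) return(FALSE)
  } else {
    if (!setequal(a$variables, b$variables)) return(FALSE)
  }
  if (!setequal(a$external, b$external)) return(FALSE)
  ra <- reduce_to_essential_regulators(a)
  rb <- reduce_to_essential_regulators(b)
  for (v in ra$variables) {
    x <- sort_rule(ra$rules[[v]])
    y <- sort_rule(rb$rules[[v]])
    if (!identical(x$regulators, y$regulators) ||
        !identical(x$tt, y$tt)) return(FALSE)
  }
  TRUE
}

## reorder a rule's regulators alphabetically, permuting the truth table
sort_rule <- function(r) {
  k <- length(r$regulators)
  if (k <= 1L) return(r)
  ord <- order(r$regulators)
  if (identical(ord, seq_len(k))) return(r)
  m <- 0:(2^k - 1)
  bits <- vapply(seq_len(k),
                 function(j) bitwAnd(bitwShiftR(m, k - j), 1L),
                 integer(2^k))                      # col j = value of reg j
  idx_new <- as.integer(bits[, ord, drop = FALSE] %*% 2^((k - 1):0)) + 1L
  tt_new <- integer(2^k)
  tt_new[idx_new] <- r$tt
  list(regulators = r$regulators[ord], tt = tt_new)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
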