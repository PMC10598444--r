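## Shared fixtures: the worked toy networks used across the test files, and
## a tiny independent simulator that evaluates rule expressions directly
## (no truth tables), used as an oracle against the package's machinery.

toy3 <- function() {
  ## F = (x2 & !x3, x3, !x1 & x2)
  parse_rules(c("x1, x2 & !x3", "x2, x3", "x3, !x1 & x2"))
}

two_module_coupled <- function() {
  ## F = (x2, x1, x1 | (x2 & y2), !x2 & y1): upstream 2-cycle module feeding
  ## a 2-node downstream module
  parse_rules(c("x1, x2", "x2, x1",
                "y1, x1 | (x2 & y2)", "y2, !x2 & y1"))
}

cross4 <- function() {
  ## cross product of two independent 2-node swap modules
  parse_rules(c("x1, x2", "x2, x1", "x3, x4", "x4, x3"))
}

coupled4 <- function() {
  ## same but with x2 gating the downstream module
  parse_rules(c("x1, x2", "x2, x1", "x3, x2 & x4", "x4, x3"))
}

## Independent oracle: step a named 0/1 state under string rules by direct
## expression evaluation. `rules` is a named character vector var -> expr.
oracle_step <- function(rules, state_bits, extra = NULL) {
  env <- as.list(c(state_bits, extra))
  vapply(names(rules), function(v) {
    val <- eval(str2lang(rules[[v]]), envir = env)
    as.integer(as.logical(val))
  }, integer(1))
}

## Iterate the oracle from a state until a cycle is found; returns the
## canonical cycle as sorted state strings
oracle_attractor <- function(rules, state_bits) {
  seen <- character(0)
  cur <- state_bits
  repeat {
    key <- paste(cur, collapse = "")
    idx <- match(key, seen)
    if (!is.na(idx)) {
      return(sort(seen[idx:length(seen)]))
    }
    seen <- c(seen, key)
    cur <- oracle_step(rules, setNames(cur, names(rules)))
  }
}

## All attractors of string rules by exhaustive oracle iteration; returns a
## sorted character vector of canonical keys (states of each cycle, sorted
## and joined by ",")
oracle_attractor_keys <- function(rules) {
  n <- length(rules)
  keys <- character(0)
  for (code in 0:(2^n - 1)) {
    bits <- setNames(as.integer(intToBits(code))[n:1], names(rules))
    cyc <- oracle_attractor(rules, bits)
    keys <- c(keys, paste(cyc, collapse = ","))
  }
  sort(unique(keys))
}

## canonical keys of a bn_attractor_set, sorted-state form comparable with
## oracle_attractor_keys
set_keys_sorted <- function(aset) {
  sort(vapply(aset$attractors,
              function(a) paste(sort(a$states), collapse = ","),
              character(1)))
}

## canonical rotation keys (order-preserving within the cycle)
set_keys <- function(aset) {
  sort(vapply(aset$attractors,
              function(a) paste(a$states, collapse = ","),
              character(1)))
}

## a random unstructured Boolean network (arbitrary truth tables), for
## invariant tests
random_plain_network <- function(n, k = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- paste0("v", seq_len(n))
  rules <- lapply(seq_len(n), function(i) {
    regs <- sample(vars, k)
    list(regulators = regs, tt = sample(c(0L, 1L), 2^k, replace = TRUE))
  })
  boolean_network(vars, rules)
}
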