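## Random generation of modular nested-canalizing networks with fixed
## in-degree: random NCF truth tables, rejection-sampled strongly connected
## wiring diagrams, random weakly connected module DAGs, and their assembly.

#' Draw a random nested canalizing truth table
#'
#' A nested canalizing function (NCF) has a hierarchy of canalizing inputs:
#' reading the inputs in some order, the first input found at its canalizing
#' value forces the corresponding canalized output; if no input is at its
#' canalizing value the output is the complement of the last canalized value,
#' which makes the function depend essentially on all `k` inputs. The sampler
#' draws the input order, the canalizing input values and the canalized
#' output values uniformly at random.
#'
#' @param k Number of inputs (>= 1).
#' @param seed Optional integer seed.
#' @return Integer truth table of length `2^k` (indexing as in
#'   [boolean_network()]: first input is the most significant bit).
#' @export
random_nested_canalizing_rule <- function(k, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(k)                       # canalizing hierarchy
  a <- sample(c(0L, 1L), k, replace = TRUE)  # canalizing input values
  b <- sample(c(0L, 1L), k, replace = TRUE)  # canalized output values
  ncf_truth_table(ord, a, b)
}

ncf_truth_table <- function(ord, a, b) {
  k <- length(ord)
  m <- 0:(2^k - 1)
  out <- rep.int(1L - b[k], 2^k)             # default: no input canalizing
  open <- rep.int(TRUE, 2^k)
  for (layer in seq_len(k)) {
    j <- ord[layer]
    bit_j <- bitwAnd(bitwShiftR(m, k - j), 1L)
    hit <- open & (bit_j == a[layer])
    out[hit] <- b[layer]
    open <- open & !hit
  }
  out
}

#' Test whether a truth table is nested canalizing
#'
#' Recursive definition used as an independent check on generated rules: a
#' one-input function is nested canalizing iff it is non-constant; a
#' `k`-input function is nested canalizing iff some input has a value that
#' forces a constant output and the restriction to the other value of that
#' input is nested canalizing in the remaining inputs. Exhaustive over input
#' orders, intended for small `k`.
#'
#' @param tt Integer truth table of length `2^k`.
#' @return `TRUE` or `FALSE`.
#' @export
is_nested_canalizing <- function(tt) {
  k <- as.integer(log2(length(tt)))
  stopifnot(length(tt) == 2^k, k >= 1)
  if (length(unique(tt)) == 1L) return(FALSE)
  if (k == 1L) return(TRUE)
  m <- 0:(2^k - 1)
  for (j in seq_len(k)) {
    bit_j <- bitwAnd(bitwShiftR(m, k - j), 1L)
    for (aval in c(0L, 1L)) {
      side <- tt[m[bit_j == aval] + 1L]
      other <- tt[m[bit_j != aval] + 1L]
      if (length(unique(side)) == 1L && is_nested_canalizing(other)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rejection-sample a strongly connected wiring diagram with fixed in-degree
#'
#' Each of `size` nodes is assigned `in_degree` distinct regulators drawn
#' uniformly at random from the *other* nodes (no self-loops); the draw is
#' repeated until the resulting directed graph is strongly connected. The
#' number of iterations consumed is returned alongside the wiring (for
#' 60 nodes and in-degree 3 this averages roughly 22 draws).
#'
#' @param size Number of nodes (> `in_degree`).
#' @param in_degree Regulators per node (>= 1).
#' @param seed Optional integer seed.
#' @param max_rejections Give up (with an error) after this many draws.
#' @return A list with `regulators` (list of integer vectors, regulators of
#'   each node) and `iterations` (number of draws used).
#' @export
random_strongly_connected_wiring <- function(size, in_degree, seed = NULL,
                                             max_rejections = 10000L) {
  stopifnot(size > in_degree, in_degree >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (it in seq_len(max_rejections)) {
    regs <- lapply(seq_len(size), function(i) {
      pool <- (seq_len(size))[-i]
      pool[sample.int(length(pool), in_degree)]   # safe for length-1 pools
    })
    if (is_strongly_connected_regs(regs, size)) {
      return(list(regulators = regs, iterations = it))
    }
  }
  stop("no strongly connected wiring found in ", max_rejections, " draws")
}

is_strongly_connected_regs <- function(regs, size) {
  from <- unlist(regs, use.names = FALSE)
  to <- rep(seq_len(size), lengths(regs))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  igraph::vcount(g) == size && igraph::is_connected(g, mode = "strong")
}

#' Draw a random weakly connected lower-triangular module matrix
#'
#' Samples uniformly at random among binary lower-triangular `m x m`
#' matrices with all diagonal entries 1 whose off-diagonal 1-entries form a
#' weakly connected (undirected) graph on the `m` modules, by rejection from
#' unbiased off-diagonal coin flips. Entry `D[i, j] = 1` (for `i > j`) means
#' that module `i` regulates module `j`.
#'
#' @param m Number of modules (>= 1).
#' @param seed Optional integer seed.
#' @param max_rejections Rejection budget.
#' @return An `m x m` binary matrix.
#' @export
random_module_dag <- function(m, seed = NULL, max_rejections = 100000L) {
  stopifnot(m >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (m == 1L) return(matrix(1L, 1L, 1L))
  lower <- which(lower.tri(matrix(0L, m, m)))
  for (it in seq_len(max_rejections)) {
    D <- diag(1L, m)
    D[lower] <- sample(c(0L, 1L), length(lower), replace = TRUE)
    pairs <- which(lower.tri(D) & D == 1L, arr.ind = TRUE)
    if (nrow(pairs) >= m - 1L) {
      g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
      if (igraph::is_connected(g, mode = "weak")) return(D)
    }
  }
  stop("no weakly connected module matrix found in ", max_rejections,
       " draws")
}

#' Generate a random modular nested-canalizing Boolean network
#'
#' Builds a network of `N` variables split into `m` modules of equal size,
#' each module a strongly connected wiring diagram with fixed in-degree, the
#' modules connected according to a random weakly connected lower-triangular
#' matrix `D` ([random_module_dag()]). For every off-diagonal `D[i, j] = 1`
#' exactly one cross-module edge is added: a uniformly chosen node of module
#' `i` replaces one uniformly chosen intra-module regulator of a uniformly
#' chosen node of module `j` (re-drawn if the replacement would break the
#' donor module's internal strong connectivity), so every in-degree stays
#' exactly `in_degree`. All rules are random nested canalizing functions on
#' their final regulator sets, which keeps every listed regulator essential
#' and therefore guarantees that the network decomposes into exactly `m`
#' modules.
#'
#' @param N Total number of variables (`m` must divide `N`).
#' @param m Number of modules.
#' @param in_degree Regulators per node (`N/m` must exceed it).
#' @param seed Optional integer seed; the full construction is reproducible
#'   from `(N, m, in_degree, seed)`.
#' @param max_rejections Rejection budget shared by the connectivity loops.
#' @return A [boolean_network()] with attribute `"modules"` (list of
#'   variable-name vectors per module), `"D"` (the module matrix) and
#'   `"iterations"` (wiring draws used per module).
#' @export
generate_modular_network <- function(N, m, in_degree, seed = NULL,
                                     max_rejections = 10000L) {
  stopifnot(m >= 1, N %% m == 0)
  size <- N %/% m
  if (size <= in_degree) {
    stop("module size N/m = ", size, " must exceed the in-degree")
  }
  if (!is.null(seed)) set.seed(seed)
  vars <- paste0("x", seq_len(N))
  block <- function(i) ((i - 1L) * size + 1L):(i * size)
  wirings <- vector("list", m)
  iters <- integer(m)
  for (i in seq_len(m)) {
    w <- random_strongly_connected_wiring(size, in_degree,
                                          max_rejections = max_rejections)
    wirings[[i]] <- w$regulators           # local indices within module i
    iters[i] <- w$iterations
  }
  ## global regulator lists; intra-module regulators as global indices
  regs <- vector("list", N)
  intra <- vector("list", N)               # which of regs are intra-module
  for (i in seq_len(m)) {
    b <- block(i)
    for (v in seq_len(size)) {
      regs[[b[v]]] <- b[wirings[[i]][[v]]]
      intra[[b[v]]] <- rep(TRUE, in_degree)
    }
  }
  D <- random_module_dag(m, max_rejections = max_rejections)
  if (m > 1L) {
    pairs <- which(lower.tri(D) & D == 1L, arr.ind = TRUE)
    for (p in seq_len(nrow(pairs))) {
      src_mod <- pairs[p, "row"]           # module i regulates module j
      dst_mod <- pairs[p, "col"]
      placed <- FALSE
      for (it in seq_len(max_rejections)) {
        src <- sample(block(src_mod), 1L)
        dst <- sample(block(dst_mod), 1L)
        cand <- which(intra[[dst]])
        if (!length(cand) || src %in% regs[[dst]]) next
        slot <- if (length(cand) == 1L) cand else sample(cand, 1L)
        ## would removing this intra-module edge break the donor module?
        local_regs <- lapply(block(dst_mod), function(v) {
          r <- regs[[v]][intra[[v]]]
          if (v == dst) r <- setdiff(r, regs[[dst]][slot])
          match(r, block(dst_mod))
        })
        if (is_strongly_connected_regs(local_regs, size)) {
          regs[[dst]][slot] <- src
          intra[[dst]][slot] <- FALSE
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place cross-module edge within the rejection budget")
      }
    }
  }
  rules <- lapply(seq_len(N), function(v) {
    r <- sort(regs[[v]])
    list(regulators = vars[r],
         tt = random_nested_canalizing_rule(length(r)))
  })
  net <- boolean_network(vars, rules)
  attr(net, "modules") <- lapply(seq_len(m), function(i) vars[block(i)])
  attr(net, "D") <- D
  attr(net, "iterations") <- iters
  net
}
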