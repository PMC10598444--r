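#' Parse Boolean update rules
#'
#' Reads the plain-text rule dialect used throughout the package: one line
#' per variable of the form `name, expression`, where the expression uses
#' the operators `&` (AND), `|` (OR), `!` (NOT), `+` (XOR, for linear rules
#' over GF(2)), parentheses and the constants `0`/`1`. External parameters
#' are declared on a header line `# inputs: u1 u2`; any other name appearing
#' in an expression must be a declared variable or input. A leading
#' `targets, factors` header (BoolNet convention) and blank or `#` comment
#' lines are ignored.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines.
#' @return A [boolean_network()] with truth tables compiled from the
#'   expressions, variables in declaration order.
#' @examples
#' parse_rules(c("x1, x2 & !x3", "x2, x3", "x3, !x1 & x2"))
#' parse_rules(c("# inputs: u1 u2",
#'               "y1, u1 | (u2 & y2)",
#'               "y2, !u2 & y1"))
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  external <- character(0)
  entries <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (line == "") next
    if (grepl("^#", line)) {
      m <- regmatches(line, regexec("^#\\s*inputs\\s*:\\s*(.*)$", line,
                                    ignore.case = TRUE))[[1]]
      if (length(m) == 2L) {
        external <- c(external, strsplit(trimws(m[2]), "[,[:space:]]+")[[1]])
      }
      next
    }
    if (grepl("^targets\\s*,\\s*factors$", line, ignore.case = TRUE)) next
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0) {
      stop("line ", ln, ": expected 'name, expression', got: ", line)
    }
    name <- trimws(substr(line, 1L, comma - 1L))
    expr <- trimws(substr(line, comma + 1L, nchar(line)))
    if (!grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", name)) {
      stop("line ", ln, ": invalid variable name '", name, "'")
    }
    if (expr == "") stop("line ", ln, ": empty expression for '", name, "'")
    entries[[length(entries) + 1L]] <- list(name = name, expr = expr, ln = ln)
  }
  if (!length(entries)) stop("no update rules found")
  variables <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(variables)) {
    stop("duplicate variable: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "))
  }
  external <- setdiff(unique(external), variables)
  known <- c(variables, external)
  rules <- lapply(entries, function(e) {
    compile_expression(e$expr, known, line = e$ln)
  })
  boolean_network(variables, rules, external)
}

#' @rdname parse_rules
#' @param path Path to a rule file.
#' @export
read_rules <- function(path) parse_rules(readLines(path, warn = FALSE))

## compile a logic expression into (regulators, truth table); regulator
## order is first-appearance order in the expression
compile_expression <- function(expr, known, line = NA) {
  where <- if (is.na(line)) "" else paste0("line ", line, ": ")
  ex <- tryCatch(str2lang(expr),
                 error = function(e) stop(where, "syntax error in '", expr, "'",
                                          call. = FALSE))
  check_ops(ex, where)
  regs <- intersect(all.vars(ex), known)  # all.vars: first-appearance order
  unknown <- setdiff(all.vars(ex), known)
  if (length(unknown)) {
    stop(where, "unknown name(s): ", paste(unknown, collapse = ", "),
         " (declare inputs with '# inputs: ...')", call. = FALSE)
  }
  k <- length(regs)
  m <- 0:(2^k - 1)
  env <- new.env(parent = baseenv())
  ## 0/1 integer algebra: `+` is addition over GF(2) (XOR)
  assign("&", function(a, b) as.integer(as.logical(a) & as.logical(b)), envir = env)
  assign("|", function(a, b) as.integer(as.logical(a) | as.logical(b)), envir = env)
  assign("!", function(a) as.integer(!as.logical(a)), envir = env)
  assign("+", function(a, b) as.integer(a + b) %% 2L, envir = env)
  for (j in seq_len(k)) {
    assign(regs[j], bitwAnd(bitwShiftR(m, k - j), 1L), envir = env)
  }
  tt <- as.integer(eval(ex, env))
  if (length(tt) == 1L) tt <- rep.int(tt, 2^k)
  list(regulators = regs, tt = tt)
}

## only logic operators are allowed in rule expressions
check_ops <- function(ex, where) {
  if (is.call(ex)) {
    op <- as.character(ex[[1]])
    if (!op %in% c("&", "|", "!", "(", "+")) {
      stop(where, "operator '", op, "' not allowed in rule expressions",
           call. = FALSE)
    }
    for (i in seq_along(ex)[-1]) check_ops(ex[[i]], where)
  } else if (!(is.name(ex) || (is.numeric(ex) && ex %in% c(0, 1)))) {
    stop(where, "only variable names and the constants 0/1 are allowed",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a Boolean network to the rule dialect
#'
#' Writes one `name, expression` line per variable; rules are emitted in
#' disjunctive normal form over their regulators, so `parse -> serialize ->
#' parse` is the identity on the reduced network (identical truth tables).
#'
#' @param net A [boolean_network()].
#' @param header Emit the `# inputs:` header when the network has external
#'   parameters (default `TRUE`).
#' @return Character vector of lines.
#' @export
serialize_rules <- function(net, header = TRUE) {
  out <- character(0)
  if (header && length(net$external)) {
    out <- paste("# inputs:", paste(net$external, collapse = " "))
  }
  c(out, vapply(net$variables, function(v) {
    r <- net$rules[[v]]
    paste0(v, ", ", rule_to_expression(r))
  }, character(1)))
}

#' @rdname serialize_rules
#' @param path File to write.
#' @export
write_rules <- function(net, path) {
  writeLines(serialize_rules(net), path)
  invisible(path)
}

rule_to_expression <- function(r) {
  k <- length(r$regulators)
  if (all(r$tt == 0L)) return("0")
  if (all(r$tt == 1L)) return("1")
  m <- which(r$tt == 1L) - 1L
  terms <- vapply(m, function(idx) {
    lits <- vapply(seq_len(k), function(j) {
      if (bitwAnd(bitwShiftR(idx, k - j), 1L) == 1L) r$regulators[j]
      else paste0("!", r$regulators[j])
    }, character(1))
    if (k == 1L) lits else paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}
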