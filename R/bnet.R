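# BoolNet-style `.bnet` model files: optional "targets, factors" header,
# one "name, expression" line per node, `#` comments, Boolean expressions
# over node names with ! (NOT), & (AND), | (OR), parentheses and the
# constants 0/1.  NOT binds tighter than AND, which binds tighter than OR.

bnet_tokenize <- function(expr, line_no) {
    pat <- "\\s*([A-Za-z_][A-Za-z0-9_.]*|[01]|[!&|()])"
    toks <- character(0)
    pos <- 1L
    s <- expr
    while (pos <= nchar(s)) {
        m <- regexpr(pat, substr(s, pos, nchar(s)), perl = TRUE)
        if (m != 1L)
            stop("syntax error on line ", line_no, ": unexpected character ",
                 "at ...", substr(s, pos, min(nchar(s), pos + 10L)))
        tok <- gsub("^\\s+", "", regmatches(substr(s, pos, nchar(s)), m))
        toks <- c(toks, tok)
        pos <- pos + attr(m, "match.length")
    }
    toks
}

# recursive-descent parse to an AST of nested lists
bnet_parse_expr <- function(tokens, line_no) {
    i <- 1L
    peek <- function() if (i <= length(tokens)) tokens[i] else NA_character_
    advance <- function() { t <- tokens[i]; i <<- i + 1L; t }
    fail <- function(what)
        stop("syntax error on line ", line_no, ": ", what)
    parse_or <- function() {
        node <- parse_and()
        while (!is.na(peek()) && peek() == "|") {
            advance()
            node <- list(op = "or", left = node, right = parse_and())
        }
        node
    }
    parse_and <- function() {
        node <- parse_not()
        while (!is.na(peek()) && peek() == "&") {
            advance()
            node <- list(op = "and", left = node, right = parse_not())
        }
        node
    }
    parse_not <- function() {
        if (!is.na(peek()) && peek() == "!") {
            advance()
            return(list(op = "not", arg = parse_not()))
        }
        parse_atom()
    }
    parse_atom <- function() {
        t <- peek()
        if (is.na(t)) fail("unexpected end of expression")
        if (t == "(") {
            advance()
            node <- parse_or()
            if (is.na(peek()) || peek() != ")") fail("missing ')'")
            advance()
            return(node)
        }
        if (t %in% c("0", "1")) {
            advance()
            return(list(op = "const", value = as.integer(t)))
        }
        if (grepl("^[A-Za-z_]", t)) {
            advance()
            return(list(op = "var", name = t))
        }
        fail(paste0("unexpected token '", t, "'"))
    }
    ast <- parse_or()
    if (i <= length(tokens))
        fail(paste0("trailing tokens starting at '", tokens[i], "'"))
    ast
}

ast_vars <- function(ast) {
    switch(ast$op,
           var = ast$name,
           const = character(0),
           not = ast_vars(ast$arg),
           unique(c(ast_vars(ast$left), ast_vars(ast$right))))
}

# vectorized evaluation over an environment of logical vectors
ast_eval <- function(ast, env) {
    switch(ast$op,
           var = env[[ast$name]],
           const = rep(ast$value == 1L, max(1L, length(env[[1L]]))),
           not = !ast_eval(ast$arg, env),
           and = ast_eval(ast$left, env) & ast_eval(ast$right, env),
           or = ast_eval(ast$left, env) | ast_eval(ast$right, env))
}

#' Read a `.bnet` Boolean model
#'
#' Parses the BoolNet text dialect: an optional `targets, factors` header,
#' `#` comments, and one `name, expression` line per node with operators
#' `!`, `&`, `|`, parentheses and constants 0/1.  Node order follows file
#' order.
#'
#' @param path file to read.
#' @return object of class `bnet_model`: list with `names` (character),
#'   `exprs` (expression strings), `asts` (parsed trees).
#' @export
read_bnet <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    names <- character(0)
    exprs <- character(0)
    asts <- list()
    for (ln in seq_along(lines)) {
        raw <- sub("#.*$", "", lines[ln])
        if (!nzchar(trimws(raw))) next
        if (length(names) == 0L &&
            grepl("^\\s*targets\\s*,\\s*factors\\s*$", raw,
                  ignore.case = TRUE)) next
        comma <- regexpr(",", raw, fixed = TRUE)
        if (comma < 1L)
            stop("parse error on line ", ln, ": expected 'name, expression'")
        name <- trimws(substr(raw, 1L, comma - 1L))
        expr <- trimws(substr(raw, comma + 1L, nchar(raw)))
        if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", name))
            stop("parse error on line ", ln, ": invalid target name '",
                 name, "'")
        if (name %in% names)
            stop("parse error on line ", ln, ": duplicate target '", name, "'")
        if (!nzchar(expr))
            stop("syntax error on line ", ln, ": empty expression")
        toks <- bnet_tokenize(expr, ln)
        ast <- bnet_parse_expr(toks, ln)
        names <- c(names, name)
        exprs <- c(exprs, expr)
        asts[[length(asts) + 1L]] <- ast
    }
    if (length(names) == 0L) stop("no node definitions found in ", path)
    for (j in seq_along(asts)) {
        unknown <- setdiff(ast_vars(asts[[j]]), names)
        if (length(unknown) > 0L)
            stop("unknown symbol(s) in rule for '", names[j], "': ",
                 paste(unknown, collapse = ", "))
    }
    structure(list(names = names, exprs = exprs, asts = asts),
              class = "bnet_model")
}

#' @export
print.bnet_model <- function(x, ...) {
    cat("bnet_model with", length(x$names), "nodes:",
        paste(utils::head(x$names, 8L), collapse = " "),
        if (length(x$names) > 8L) "..." else "", "\n")
    invisible(x)
}

#' Compile a `.bnet` model to truth tables
#'
#' Each node's inputs are the variables appearing in its expression
#' (ordered by node declaration order); the truth table is filled by
#' exhaustive evaluation over all input patterns.
#'
#' @param model a `bnet_model`.
#' @param max_inputs cap on per-node in-degree (table size `2^k`).
#' @return a [boolean_function_network].
#' @export
compile_bnet <- function(model, max_inputs = 16L) {
    stopifnot(inherits(model, "bnet_model"))
    n <- length(model$names)
    inputs <- vector("list", n)
    tables <- vector("list", n)
    for (j in seq_len(n)) {
        vars <- intersect(model$names, ast_vars(model$asts[[j]]))
        k <- length(vars)
        if (k > max_inputs)
            stop("node '", model$names[j], "' has ", k,
                 " inputs; the compilation cap is ", max_inputs)
        inputs[[j]] <- match(vars, model$names)
        if (k == 0L) {
            env <- list(.dummy = logical(1L))
            tables[[j]] <- as.integer(ast_eval(model$asts[[j]], env))
        } else {
            pats <- 0:(2^k - 1L)
            env <- setNames(lapply(seq_len(k), function(t)
                bitwAnd(bitwShiftR(pats, t - 1L), 1L) == 1L), vars)
            tables[[j]] <- as.integer(ast_eval(model$asts[[j]], env))
        }
    }
    boolean_function_network(inputs, tables, names = model$names)
}

#' Write a `.bnet` model
#'
#' @param model a `bnet_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bnet <- function(model, path) {
    stopifnot(inherits(model, "bnet_model"))
    writeLines(c("targets, factors",
                 paste0(model$names, ", ", model$exprs)), path)
    invisible(path)
}

# disjunctive normal form over input names for a truth table
dnf_expression <- function(input_names, table) {
    k <- length(input_names)
    if (k == 0L) return(as.character(table[1L]))
    ones <- which(table == 1L) - 1L
    if (length(ones) == 0L) return("0")
    if (length(ones) == 2^k) return("1")
    terms <- vapply(ones, function(p) {
        lits <- vapply(seq_len(k), function(t) {
            if (bitwAnd(bitwShiftR(p, t - 1L), 1L) == 1L) input_names[t]
            else paste0("!", input_names[t])
        }, "")
        paste(lits, collapse = " & ")
    }, "")
    paste(terms, collapse = " | ")
}

bnet_from_strings <- function(names, exprs) {
    asts <- lapply(seq_along(exprs),
                   function(j) bnet_parse_expr(bnet_tokenize(exprs[j], j), j))
    structure(list(names = names, exprs = exprs, asts = asts),
              class = "bnet_model")
}

#' Express a Boolean-function network as a `.bnet` model
#'
#' Writes each node's truth table as a disjunctive normal form over its
#' input names; compiling the result reproduces the original tables.
#'
#' @param net a [boolean_function_network].
#' @return a `bnet_model`.
#' @export
bfn_to_bnet <- function(net) {
    stopifnot(inherits(net, "bfn"))
    exprs <- vapply(seq_len(net$n), function(j)
        dnf_expression(net$names[net$inputs[[j]]], net$tables[[j]]), "")
    bnet_from_strings(net$names, exprs)
}

#' Express the threshold rule as a `.bnet` model
#'
#' For each node of a signed network, enumerates its inputs' activity
#' patterns and emits the disjunction of the patterns whose signed sum is
#' strictly positive, so the compiled model's dynamics equal the threshold
#' update on every state.  Nodes are named `v0, v1, ...`.
#'
#' @param net a `signed_network` with per-node in-degree at most
#'   `max_inputs`.
#' @param max_inputs cap on per-node in-degree.
#' @return a `bnet_model`.
#' @export
threshold_to_bnet <- function(net, max_inputs = 16L) {
    stopifnot(inherits(net, "signed_network"))
    n <- net$n
    names <- paste0("v", seq_len(n) - 1L)
    exprs <- vapply(seq_len(n), function(j) {
        src <- which(net$W[, j] != 0L)
        k <- length(src)
        if (k == 0L) return("0")
        if (k > max_inputs)
            stop("node ", j, " has in-degree ", k, " > cap ", max_inputs)
        wts <- net$W[src, j]
        pats <- 0:(2^k - 1L)
        bits <- vapply(seq_len(k), function(t)
            bitwAnd(bitwShiftR(pats, t - 1L), 1L), integer(2^k))
        bits <- matrix(bits, ncol = k)
        sums <- as.vector(bits %*% wts)
        dnf_expression(names[src], as.integer(sums > 0))
    }, "")
    bnet_from_strings(names, exprs)
}
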