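#' Construct a signed interaction network
#'
#' A signed network is an `n x n` matrix `W` with entries in `{-1, 0, 1}`:
#' `W[i, j]` is the sign of the directed edge from node `i` to node `j`
#' (+1 excitatory, -1 inhibitory, 0 absent).  Self-loops live on the
#' diagonal.
#'
#' @param W square integer (or numeric) matrix with entries in `{-1, 0, 1}`.
#' @return An object of class `signed_network` with fields `n` and `W`.
#' @examples
#' net <- signed_network(rbind(c(-1, 1), c(1, -1)))
#' net$n
#' @export
signed_network <- function(W) {
    W <- as.matrix(W)
    if (nrow(W) != ncol(W) || nrow(W) < 1L)
        stop("W must be a square matrix with n >= 1")
    if (!all(W %in% c(-1, 0, 1)))
        stop("all entries of W must be in {-1, 0, 1}")
    storage.mode(W) <- "integer"
    dimnames(W) <- NULL
    structure(list(n = nrow(W), W = W), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
    cat("signed_network with", x$n, "nodes,",
        sum(x$W != 0L), "edges\n")
    invisible(x)
}

#' Construct a Boolean-function network
#'
#' General synchronous Boolean network given by one truth table per node.
#' Node `j` reads the ordered input list `inputs[[j]]`; its next state is
#' `tables[[j]][p + 1]` where `p` is the inputs' current bit pattern with
#' the first input as least-significant bit.
#'
#' @param inputs list of integer vectors of 1-based node indices.
#' @param tables list of 0/1 integer vectors, `tables[[j]]` of length
#'   `2^length(inputs[[j]])`.
#' @param names optional character vector of node names.
#' @return An object of class `bfn` with fields `n`, `inputs`, `tables`,
#'   `names`.
#' @export
boolean_function_network <- function(inputs, tables, names = NULL) {
    n <- length(inputs)
    if (length(tables) != n) stop("inputs and tables must have equal length")
    for (j in seq_len(n)) {
        k <- length(inputs[[j]])
        if (length(tables[[j]]) != 2^k)
            stop("truth table of node ", j, " must have 2^", k, " entries")
        if (!all(tables[[j]] %in% c(0L, 1L)))
            stop("truth tables must be 0/1")
        if (k > 0L && (any(inputs[[j]] < 1L) || any(inputs[[j]] > n)))
            stop("input indices of node ", j, " out of range")
    }
    if (is.null(names)) names <- paste0("v", seq_len(n) - 1L)
    structure(list(n = n,
                   inputs = lapply(inputs, as.integer),
                   tables = lapply(tables, as.integer),
                   names = as.character(names)),
              class = "bfn")
}

#' @export
print.bfn <- function(x, ...) {
    cat("boolean_function_network with", x$n, "nodes; in-degrees:",
        paste(vapply(x$inputs, length, 1L), collapse = " "), "\n")
    invisible(x)
}

network_size <- function(net) {
    if (!is.list(net) || is.null(net$n)) stop("not a network object")
    net$n
}

#' Encode and decode integer states
#'
#' States of an `n`-node network are bit vectors `(x0, x1, ..., x_{n-1})`
#' encoded as integers LSB-first: `s = sum(x_i * 2^i)`, so node 0 is the
#' least significant bit.
#'
#' @param bits 0/1 vector `(x0, ..., x_{n-1})`.
#' @param s integer state in `[0, 2^n)`.
#' @param n number of nodes.
#' @return `encode_state` returns the integer; `decode_state` the 0/1
#'   integer vector.
#' @examples
#' encode_state(c(0, 1, 1, 0))  # 6
#' decode_state(9L, 4L)         # c(1, 0, 0, 1)
#' @export
encode_state <- function(bits) {
    bits <- as.integer(bits)
    if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
    if (length(bits) > 30L) stop("integer encoding supports n <= 30")
    sum(bits * bitwShiftL(1L, seq_along(bits) - 1L))
}

#' @rdname encode_state
#' @export
decode_state <- function(s, n) {
    s <- as.integer(s)
    n <- as.integer(n)
    if (s < 0L || (n <= 30L && s >= bitwShiftL(1L, n)))
        stop("state out of range for n = ", n)
    bitwAnd(bitwShiftR(s, seq_len(n) - 1L), 1L)
}

#' Bitwise complement of a state
#'
#' Applies the NOT gate to every node: the state `(0,1,1,0)` becomes
#' `(1,0,0,1)`.  On integer states this is `(2^n - 1) - s`.
#'
#' @param x either a 0/1 vector or an integer state.
#' @param n number of nodes; required when `x` is an integer state.
#' @return The complemented state, in the same representation as `x`.
#' @export
negate_state <- function(x, n = NULL) {
    if (length(x) > 1L || !is.null(attr(x, "bits"))) return(1L - as.integer(x))
    if (is.null(n)) stop("n is required for integer states")
    n <- as.integer(n)
    s <- as.integer(x)
    if (s < 0L || s >= bitwShiftL(1L, n)) stop("state out of range")
    bitwShiftL(1L, n) - 1L - s
}

#' One synchronous update step
#'
#' Applies the transition map tau once.  For a [signed_network] node `j`
#' becomes active iff `sum_i W[i, j] * x_i > 0` (a tied sum of zero maps to
#' inactive); for a [boolean_function_network] each node looks up its truth
#' table at its inputs' current pattern.
#'
#' @param net a `signed_network` or `bfn`.
#' @param x a 0/1 state vector of length `net$n`, or an integer state.
#' @return The successor state, in the same representation as `x`.
#' @examples
#' net <- signed_network(rbind(c(-1, 1), c(1, -1)))
#' state_transition(net, c(1, 0))  # c(0, 1)
#' @export
state_transition <- function(net, x) {
    n <- network_size(net)
    if (length(x) == 1L && n > 1L) {
        bits <- decode_state(x, n)
        return(encode_state(drop(state_transition_batch(net, matrix(bits, 1L)))))
    }
    if (length(x) != n) stop("state has wrong length")
    if (!all(x %in% c(0, 1))) stop("state must be 0/1")
    drop(state_transition_batch(net, matrix(as.integer(x), 1L)))
}

#' Vectorized update of many states
#'
#' @param net a `signed_network` or `bfn`.
#' @param X integer 0/1 matrix, one state per row (`ncol(X) == net$n`).
#' @return matrix of successor states, same shape as `X`.
#' @export
state_transition_batch <- function(net, X) {
    n <- network_size(net)
    X <- as.matrix(X)
    if (ncol(X) != n) stop("states must have ", n, " columns")
    if (inherits(net, "signed_network")) {
        sums <- X %*% net$W
        return(matrix(as.integer(sums > 0), nrow(X), n))
    }
    if (inherits(net, "bfn")) {
        out <- matrix(0L, nrow(X), n)
        for (j in seq_len(n)) {
            idx <- net$inputs[[j]]
            k <- length(idx)
            if (k == 0L) {
                out[, j] <- net$tables[[j]][1L]
            } else {
                pat <- as.vector(X[, idx, drop = FALSE] %*%
                                     bitwShiftL(1L, seq_len(k) - 1L))
                out[, j] <- net$tables[[j]][pat + 1L]
            }
        }
        return(out)
    }
    stop("unsupported network class")
}

#' Iterate the dynamics from a start state
#'
#' Repeatedly applies [state_transition], stopping at the first revisited
#' state or after `t_max` steps, whichever comes first.
#'
#' @param net a network object.
#' @param x0 start state (0/1 vector or integer).
#' @param t_max maximum number of update steps (>= 0).
#' @return list with `states` (integer vector of visited states, starting
#'   at `x0`), `repeated` (logical: did the walk close on a revisited
#'   state), and `repeat_index` (1-based index in `states` of the state the
#'   walk returned to, or `NA`).
#' @export
state_trajectory <- function(net, x0, t_max) {
    n <- network_size(net)
    if (t_max < 0) stop("t_max must be >= 0")
    if (n > 30L) stop("integer trajectories support n <= 30")
    s <- if (length(x0) > 1L) encode_state(x0) else as.integer(x0)
    if (s < 0L || s >= bitwShiftL(1L, n)) stop("state out of range")
    # a repeat is forced within 2^n steps, so never allocate more than that
    states <- integer(min(t_max, bitwShiftL(1L, min(n, 30L))) + 1L)
    states[1L] <- s
    seen <- new.env(hash = TRUE, parent = emptyenv())
    assign(as.character(s), 1L, envir = seen)
    for (t in seq_len(t_max)) {
        s <- state_transition(net, s)
        key <- as.character(s)
        if (!is.null(prev <- seen[[key]])) {
            return(list(states = states[seq_len(t)], repeated = TRUE,
                        repeat_index = prev))
        }
        states[t + 1L] <- s
        assign(key, t + 1L, envir = seen)
    }
    list(states = states, repeated = FALSE, repeat_index = NA_integer_)
}
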