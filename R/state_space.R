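#' Materialize the full transition map
#'
#' Builds the functional graph tau over all `2^n` states: entry `s + 1` of
#' the successor table holds `tau(s)` (states are 0-based integers,
#' LSB-first node encoding).
#'
#' @param net a `signed_network` or `bfn`.
#' @param cap largest admissible `n`; defaults to
#'   `getOption("boolsym.state_cap", 22)`.  Above the cap the map is
#'   refused (use [sampled_symmetry] and friends instead).
#' @return object of class `transition_map`: list with `n` and 0-based
#'   integer vector `successor` of length `2^n`.
#' @export
transition_map <- function(net, cap = NULL) {
    n <- network_size(net)
    cap <- state_cap(cap)
    if (n > cap)
        stop("n = ", n, " exceeds the state-space cap (", cap,
             "); use sampled methods for networks this large")
    if (inherits(net, "signed_network")) {
        succ <- tm_signed_cpp(net$W)
    } else if (inherits(net, "bfn")) {
        N <- bitwShiftL(1L, n)
        S <- 0:(N - 1L)
        succ <- integer(N)
        for (j in seq_len(n)) {
            idx <- net$inputs[[j]]
            k <- length(idx)
            if (k == 0L) {
                bit <- rep(net$tables[[j]][1L], N)
            } else {
                pat <- integer(N)
                for (t in seq_len(k))
                    pat <- pat + bitwShiftL(
                        bitwAnd(bitwShiftR(S, idx[t] - 1L), 1L), t - 1L)
                bit <- net$tables[[j]][pat + 1L]
            }
            succ <- succ + bitwShiftL(bit, j - 1L)
        }
    } else {
        stop("unsupported network class")
    }
    structure(list(n = n, successor = as.integer(succ)),
              class = "transition_map")
}

#' @export
print.transition_map <- function(x, ...) {
    cat("transition_map over", length(x$successor), "states (n =", x$n, ")\n")
    invisible(x)
}

as_transition_map <- function(x, cap = NULL) {
    if (inherits(x, "transition_map")) return(x)
    transition_map(x, cap = cap)
}

#' Attractors and basins of a transition map
#'
#' Every state of a finite deterministic system eventually falls onto a
#' directed cycle of tau (a fixed point being a cycle of length 1).  This
#' finds all cycles and the exact size of each basin of attraction by
#' iterative pointer chasing, in time linear in the number of states.
#'
#' @param tmap a `transition_map` (or a network, which is materialized
#'   first).
#' @return object of class `attractor_set`: list with `n`, `cycles` (list
#'   of 0-based integer state vectors, each a directed cycle of tau) and
#'   `basin_size` (integer vector, one entry per cycle; sums to `2^n`).
#' @examples
#' net <- signed_network(rbind(c(-1, 1), c(1, -1)))
#' att <- find_attractors(transition_map(net))
#' lengths(att$cycles)  # 1 2
#' @export
find_attractors <- function(tmap) {
    tmap <- as_transition_map(tmap)
    res <- attractors_cpp(tmap$successor)
    structure(list(n = tmap$n, cycles = res$cycles,
                   basin_size = res$basin_size),
              class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
    cat("attractor_set:", length(x$cycles), "attractor(s); cycle lengths",
        paste(lengths(x$cycles), collapse = " "), "\n")
    invisible(x)
}

#' Length of the longest attractor cycle
#'
#' @param net a network or `transition_map`.
#' @param cap state-space cap, see [transition_map].
#' @return integer >= 1 (fixed points count as length-1 cycles).
#' @export
max_cycle_length <- function(net, cap = NULL) {
    if (inherits(net, "signed_network")) {
        # fast path: batch kernel on a single network
        g <- matrix(t(net$W), nrow = 1L)
        cap <- state_cap(cap)
        if (net$n > cap)
            stop("n exceeds the state-space cap (", cap, ")")
        return(batch_max_cycle_cpp(g, net$n)[1L])
    }
    att <- find_attractors(as_transition_map(net, cap = cap))
    max(lengths(att$cycles))
}

#' Maximum cycle lengths of a batch of signed networks
#'
#' Evaluates [max_cycle_length] for many networks at once; the workhorse
#' behind the sampling surveys and the genetic algorithm.
#'
#' @param genomes integer matrix, one network per row, `n^2` trits
#'   row-major (see [genome_encode]).
#' @param n node count.
#' @return integer vector of maximum cycle lengths.
#' @export
batch_max_cycle <- function(genomes, n) {
    genomes <- as.matrix(genomes)
    storage.mode(genomes) <- "integer"
    batch_max_cycle_cpp(genomes, as.integer(n))
}

#' Fully symmetric transition counts for a batch of signed networks
#'
#' For each network, counts the states `x` with `tau(!x) = !tau(x)` over
#' the whole state space -- the batch companion of
#' [full_symmetric_fraction] used in evolved-versus-random population
#' contrasts.
#'
#' @inheritParams batch_max_cycle
#' @return integer vector of fully symmetric state counts (out of `2^n`).
#' @export
batch_full_symmetric <- function(genomes, n) {
    genomes <- as.matrix(genomes)
    storage.mode(genomes) <- "integer"
    batch_full_sym_cpp(genomes, as.integer(n))
}

#' Effect of single-edge perturbations on the maximum cycle length
#'
#' For each trial one matrix position is drawn uniformly and its trit is
#' changed to one of the two other values (uniformly); the decrement
#' `max_cycle(original) - max_cycle(perturbed)` is recorded.  Positive
#' values mean the perturbation destroyed cycle length.
#'
#' @param net a `signed_network`.
#' @param trials number of perturbations to sample.
#' @param existing_only if `TRUE`, only currently nonzero entries are
#'   eligible (the edge is re-signed or deleted); if `FALSE` (default) any
#'   of the `n^2` positions may be altered, including absent edges.
#' @param cap state-space cap.
#' @return list with `decrements` (integer vector of length `trials`),
#'   `mean`, and `original` (the unperturbed maximum cycle length).
#'   Uses the R random number generator; seed with [set.seed] for
#'   reproducibility.
#' @export
edge_perturbation_decrement <- function(net, trials, existing_only = FALSE,
                                        cap = NULL) {
    stopifnot(inherits(net, "signed_network"), trials >= 1)
    n <- net$n
    orig <- max_cycle_length(net, cap = cap)
    positions <- if (existing_only) which(net$W != 0L) else seq_len(n * n)
    if (length(positions) == 0L)
        stop("no eligible positions to perturb")
    pick <- sample(positions, trials, replace = TRUE)
    trits <- c(-1L, 0L, 1L)
    genomes <- matrix(rep(as.integer(t(net$W)), each = trials),
                      nrow = trials)
    for (t in seq_len(trials)) {
        i <- (pick[t] - 1L) %% n + 1L      # row (source) index
        j <- (pick[t] - 1L) %/% n + 1L     # column (target) index
        old <- net$W[i, j]
        new <- sample(trits[trits != old], 1L)
        genomes[t, (i - 1L) * n + j] <- new
    }
    perturbed <- batch_max_cycle_cpp(genomes, n)
    dec <- orig - perturbed
    list(decrements = dec, mean = mean(dec), original = orig)
}

#' Export an attractor set as JSON
#'
#' Cycles are written both as integer states and as decoded bit tuples
#' `(node0, node1, ...)` to avoid any endianness confusion.
#'
#' @param att an `attractor_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_attractors_json <- function(att, path) {
    stopifnot(inherits(att, "attractor_set"))
    cyc <- lapply(att$cycles, function(states) {
        list(states = as.integer(states),
             bits = lapply(as.integer(states),
                           function(s) decode_state(s, att$n)))
    })
    obj <- list(n = att$n, n_attractors = length(att$cycles),
                cycle_length = lengths(att$cycles),
                basin_size = att$basin_size, cycles = cyc)
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
    invisible(path)
}
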