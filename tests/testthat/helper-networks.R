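# Shared fixtures and independent oracles.

toggle_net <- function() signed_network(rbind(c(-1L, 1L), c(1L, -1L)))

zero_net <- function(n) signed_network(matrix(0L, n, n))

# one-excites-two, two-inhibits-one
relay_net <- function() signed_network(rbind(c(0L, 1L), c(-1L, 0L)))

# Brute-force attractor oracle: iterate the single-step update from every
# start state until a state repeats; collect cycles (as sorted state-set
# keys) and basin sizes.  Independent of the transition-map / C code path.
oracle_attractors <- function(net) {
    n <- net$n
    N <- bitwShiftL(1L, n)
    basin <- integer(0)
    cycles <- list()
    for (s0 in 0:(N - 1L)) {
        pos <- new.env(hash = TRUE, parent = emptyenv())
        path <- integer(0)
        s <- s0
        repeat {
            key <- as.character(s)
            if (!is.null(pos[[key]])) {
                cycle <- path[pos[[key]]:length(path)]
                break
            }
            path <- c(path, s)
            pos[[key]] <- length(path)
            bits <- decode_state(s, n)
            s <- encode_state(drop(state_transition_batch(net,
                                                          matrix(bits, 1L))))
        }
        ck <- paste(sort(cycle), collapse = ",")
        if (is.null(cycles[[ck]])) {
            cycles[[ck]] <- cycle
            basin[ck] <- 0L
        }
        basin[ck] <- basin[ck] + 1L
    }
    list(cycles = cycles, basin = basin)
}

attractor_keys <- function(att) {
    vapply(att$cycles, function(cy) paste(sort(cy), collapse = ","), "")
}

# random node relabeling of a signed network
relabel_net <- function(net, perm = sample(net$n)) {
    signed_network(net$W[perm, perm])
}
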