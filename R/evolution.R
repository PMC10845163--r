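#' Genome encoding of a signed network
#'
#' A genome is the row-major flattening of `W` into `n^2` trits, the
#' representation the genetic algorithm mutates and recombines.
#'
#' @param net a `signed_network`.
#' @param g integer vector of `n^2` trits.
#' @param n node count.
#' @return `genome_encode` returns the trit vector; `genome_decode` the
#'   `signed_network`.
#' @export
genome_encode <- function(net) {
    stopifnot(inherits(net, "signed_network"))
    as.integer(t(net$W))
}

#' @rdname genome_encode
#' @export
genome_decode <- function(g, n) {
    if (length(g) != n * n) stop("genome must have n^2 entries")
    signed_network(matrix(as.integer(g), n, n, byrow = TRUE))
}

#' Pareto dominance on (cycle length, edge count)
#'
#' `a` dominates `b` when it is at least as good on both objectives
#' (cycle length maximized, edges minimized) and strictly better on one.
#'
#' @param a,b lists or named vectors with `cycle_len` and `edges`.
#' @return logical.
#' @export
dominates <- function(a, b) {
    (a$cycle_len >= b$cycle_len && a$edges <= b$edges) &&
        (a$cycle_len > b$cycle_len || a$edges < b$edges)
}

#' Objectives of a genome
#'
#' @param g genome (trit vector of length `n^2`).
#' @param n node count.
#' @param cap state-space cap.
#' @return list with `cycle_len` (maximum attractor cycle length) and
#'   `edges` (nonzero trit count).
#' @export
evaluate_genome <- function(g, n, cap = NULL) {
    if (n > state_cap(cap)) stop("n exceeds the state-space cap")
    list(cycle_len = batch_max_cycle_cpp(matrix(as.integer(g), 1L), n)[1L],
         edges = sum(g != 0L))
}

# fast non-dominated sort; returns integer ranks (1 = first front)
nds_rank <- function(cyc, edg) {
    m <- length(cyc)
    dom_count <- integer(m)
    dominated_by_me <- vector("list", m)
    for (i in seq_len(m)) {
        better <- cyc >= cyc[i] & edg <= edg[i] & (cyc > cyc[i] | edg < edg[i])
        dom_count[i] <- sum(better)
        dominated_by_me[[i]] <- which(cyc[i] >= cyc & edg[i] <= edg &
                                          (cyc[i] > cyc | edg[i] < edg))
    }
    rank <- integer(m)
    front <- which(dom_count == 0L)
    r <- 0L
    while (length(front) > 0L) {
        r <- r + 1L
        rank[front] <- r
        dec <- tabulate(unlist(dominated_by_me[front]), nbins = m)
        dom_count <- dom_count - dec
        dom_count[front] <- -1L              # retired
        front <- which(dom_count == 0L)
    }
    rank
}

# crowding distance within one front (larger = more isolated)
crowding_distance <- function(cyc, edg) {
    m <- length(cyc)
    if (m <= 2L) return(rep(Inf, m))
    d <- numeric(m)
    for (obj in list(cyc, edg)) {
        o <- order(obj)
        rng <- obj[o[m]] - obj[o[1L]]
        d[o[c(1L, m)]] <- Inf
        if (rng > 0)
            d[o[2:(m - 1L)]] <- d[o[2:(m - 1L)]] +
                (obj[o[3:m]] - obj[o[1:(m - 2L)]]) / rng
    }
    d
}

# 2D hypervolume of a non-dominated set w.r.t. reference (cycle 0,
# edges n^2 + 1): area dominated in (cycle up, edges down) space
front_hypervolume <- function(cyc, edg, n) {
    o <- order(edg, -cyc)
    keep <- !duplicated(edg[o])
    cyc <- cyc[o][keep]
    edg <- edg[o][keep]
    e_next <- c(edg[-1L], n^2 + 1)
    sum(cyc * (e_next - edg))
}

#' Pareto genetic algorithm for long cycles at low density
#'
#' Evolves a population of trit-string genomes under two objectives:
#' maximize the network's maximum attractor cycle length and minimize its
#' edge count.  The machinery is standard non-dominated-sorting GA:
#' binary-tournament selection on (rank, crowding distance), uniform
#' crossover, per-locus mutation to a uniformly chosen different trit, and
#' elitist mu+lambda survivor selection.
#'
#' @param n node count.
#' @param pop_size population size (>= 4), default 100.
#' @param generations number of generations (>= 1), default 200.
#' @param crossover_rate probability a parent pair recombines, default 0.7.
#' @param mutation_rate per-locus mutation probability, default `1/n^2`.
#' @param seed optional integer seed; the run is fully reproducible from
#'   it.
#' @param init optional initial population (matrix, one genome per row);
#'   default uniform random trits.
#' @param cap state-space cap.
#' @return object of class `pareto_front`: list with `n`, `members`
#'   (list: `genomes` matrix, `cycle_len`, `edges` -- the non-dominated
#'   subset of the final population, duplicates removed), `history`
#'   (data.frame: `generation`, `best_cycle`, `front_size`,
#'   `hypervolume`), and `params`.
#' @export
evolve_pareto <- function(n, pop_size = 100L, generations = 200L,
                          crossover_rate = 0.7, mutation_rate = 1 / n^2,
                          seed = NULL, init = NULL, cap = NULL) {
    stopifnot(pop_size >= 4L, generations >= 1L)
    if (n > state_cap(cap)) stop("n exceeds the state-space cap")
    if (!is.null(seed)) set.seed(seed)
    L <- n * n
    trits <- c(-1L, 0L, 1L)
    P <- if (is.null(init)) {
        matrix(sample(trits, pop_size * L, replace = TRUE), pop_size, L)
    } else {
        stopifnot(ncol(init) == L)
        matrix(as.integer(init), nrow(init), L)
    }
    pop_size <- nrow(P)
    cyc <- batch_max_cycle_cpp(P, n)
    edg <- as.integer(rowSums(P != 0L))
    history <- data.frame(generation = integer(generations),
                          best_cycle = integer(generations),
                          front_size = integer(generations),
                          hypervolume = numeric(generations))
    for (gen in seq_len(generations)) {
        rank <- nds_rank(cyc, edg)
        crowd <- numeric(pop_size)
        for (r in unique(rank)) {
            idx <- which(rank == r)
            crowd[idx] <- crowding_distance(cyc[idx], edg[idx])
        }
        # binary tournaments: lower rank wins, ties by larger crowding
        pick <- function(k) {
            a <- sample.int(pop_size, k, replace = TRUE)
            b <- sample.int(pop_size, k, replace = TRUE)
            win_a <- rank[a] < rank[b] |
                (rank[a] == rank[b] & crowd[a] >= crowd[b])
            ifelse(win_a, a, b)
        }
        p1 <- pick(pop_size)
        p2 <- pick(pop_size)
        C1 <- P[p1, , drop = FALSE]
        C2 <- P[p2, , drop = FALSE]
        do_x <- runif(pop_size) < crossover_rate
        mask <- matrix(runif(pop_size * L) < 0.5, pop_size, L) & do_x
        off <- C1
        off[mask] <- C2[mask]
        mut <- matrix(runif(pop_size * L) < mutation_rate, pop_size, L)
        if (any(mut)) {
            shift <- sample.int(2L, sum(mut), replace = TRUE)
            off[mut] <- trits[(match(off[mut], trits) - 1L + shift) %% 3L + 1L]
        }
        ocyc <- batch_max_cycle_cpp(off, n)
        oedg <- as.integer(rowSums(off != 0L))
        # elitist mu+lambda truncation
        Q <- rbind(P, off)
        qcyc <- c(cyc, ocyc)
        qedg <- c(edg, oedg)
        qrank <- nds_rank(qcyc, qedg)
        qcrowd <- numeric(length(qcyc))
        for (r in unique(qrank)) {
            idx <- which(qrank == r)
            qcrowd[idx] <- crowding_distance(qcyc[idx], qedg[idx])
        }
        keep <- order(qrank, -qcrowd)[seq_len(pop_size)]
        P <- Q[keep, , drop = FALSE]
        cyc <- qcyc[keep]
        edg <- qedg[keep]
        fr <- which(nds_rank(cyc, edg) == 1L)
        history[gen, ] <- list(gen, max(cyc), length(fr),
                               front_hypervolume(cyc[fr], edg[fr], n))
    }
    fr <- which(nds_rank(cyc, edg) == 1L)
    fr <- fr[!duplicated(P[fr, , drop = FALSE])]
    structure(list(n = n,
                   members = list(genomes = P[fr, , drop = FALSE],
                                  cycle_len = cyc[fr], edges = edg[fr]),
                   history = history,
                   params = list(pop_size = pop_size,
                                 generations = generations,
                                 crossover_rate = crossover_rate,
                                 mutation_rate = mutation_rate,
                                 seed = seed)),
              class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
    cat("pareto_front (n =", x$n, "):", length(x$members$cycle_len),
        "members; best cycle", max(x$members$cycle_len), "\n")
    invisible(x)
}

#' Write a Pareto front as JSON
#'
#' @param front a `pareto_front`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_front_json <- function(front, path) {
    stopifnot(inherits(front, "pareto_front"))
    obj <- list(n = front$n,
                members = lapply(seq_along(front$members$cycle_len),
                                 function(i) list(
                                     genome = front$members$genomes[i, ],
                                     cycle_len = front$members$cycle_len[i],
                                     edges = front$members$edges[i])),
                params = front$params)
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
    invisible(path)
}
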