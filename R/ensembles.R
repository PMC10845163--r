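#' Random network generators
#'
#' `random_uniform_network` draws every entry of `W` i.i.d. uniform on
#' `{-1, 0, 1}` (expected density 2/3).  `random_density_network` places
#' exactly `edge_count` nonzero entries uniformly at random, each
#' inhibitory with probability `inhibitory_fraction`.  `random_genomes`
#' returns a whole batch of uniform networks in genome form (one row per
#' network, `n^2` trits row-major) for the batch kernels.
#'
#' All generators use the R random number generator; seed with
#' [set.seed] for reproducibility.
#'
#' @param n node count.
#' @param m batch size.
#' @param edge_count number of nonzero entries in `[0, n^2]`.
#' @param inhibitory_fraction probability a placed edge is inhibitory.
#' @return a `signed_network`, or an `m x n^2` integer matrix for
#'   `random_genomes`.
#' @export
random_uniform_network <- function(n) {
    signed_network(matrix(sample(c(-1L, 0L, 1L), n * n, replace = TRUE),
                          n, n))
}

#' @rdname random_uniform_network
#' @export
random_genomes <- function(n, m) {
    matrix(sample(c(-1L, 0L, 1L), m * n * n, replace = TRUE), m, n * n)
}

#' @rdname random_uniform_network
#' @export
random_density_network <- function(n, edge_count, inhibitory_fraction = 0.5) {
    stopifnot(edge_count >= 0L, edge_count <= n * n)
    W <- matrix(0L, n, n)
    if (edge_count > 0L) {
        pos <- sample.int(n * n, edge_count)
        W[pos] <- ifelse(runif(edge_count) < inhibitory_fraction, -1L, 1L)
    }
    signed_network(W)
}

# batch of fixed-density genomes; edge_counts recycled over rows
density_genomes <- function(n, m, edge_counts, inhibitory_fraction = 0.5) {
    L <- n * n
    edge_counts <- rep_len(as.integer(edge_counts), m)
    G <- matrix(0L, m, L)
    for (i in seq_len(m)) {
        k <- edge_counts[i]
        if (k > 0L) {
            pos <- sample.int(L, k)
            G[i, pos] <- ifelse(runif(k) < inhibitory_fraction, -1L, 1L)
        }
    }
    G
}

#' Kauffman NK random Boolean network
#'
#' Each node receives `K` distinct inputs chosen uniformly at random and a
#' uniformly random truth table (each of the `2^K` output bits an
#' independent fair coin flip) -- the classic null model for random
#' Boolean dynamics.
#'
#' @param n node count.
#' @param K in-degree, `1 <= K <= n`.
#' @return a [boolean_function_network].
#' @export
kauffman_network <- function(n, K) {
    stopifnot(K >= 1L, K <= n)
    inputs <- lapply(seq_len(n), function(i) sample.int(n, K))
    tables <- lapply(seq_len(n),
                     function(i) as.integer(runif(2^K) < 0.5))
    boolean_function_network(inputs, tables)
}

#' Simple directed circuits of the interaction graph
#'
#' Enumerates all simple directed cycles (no repeated nodes; self-loops
#' count as length-1 circuits) of the nonzero pattern of `W`.  A circuit
#' is excitatory when the product of its edge signs is +1 and inhibitory
#' when it is -1.
#'
#' @param net a `signed_network`.
#' @param max_n guard against combinatorial blow-up (default 10).
#' @return list with `n_circuits`, `mean_length` (`NA` when there are no
#'   circuits), `excitatory`, `inhibitory` (counts by sign),
#'   `self_activation` and `self_inhibition` (diagonal entries by sign),
#'   and `lengths` (integer vector).
#' @export
circuit_stats <- function(net, max_n = 10L) {
    stopifnot(inherits(net, "signed_network"))
    n <- net$n
    if (n > max_n)
        stop("circuit enumeration is limited to n <= ", max_n)
    W <- net$W
    adj <- lapply(seq_len(n), function(i) which(W[i, ] != 0L))
    lens <- integer(0)
    signs <- integer(0)
    # DFS rooted at the smallest vertex of each circuit so that every
    # simple cycle is enumerated exactly once
    for (root in seq_len(n)) {
        stack <- list(list(node = root, sign = 1L, path = root))
        while (length(stack) > 0L) {
            top <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            for (nxt in adj[[top$node]]) {
                s <- top$sign * W[top$node, nxt]
                if (nxt == root) {
                    lens <- c(lens, length(top$path))
                    signs <- c(signs, s)
                } else if (nxt > root && !(nxt %in% top$path)) {
                    stack[[length(stack) + 1L]] <-
                        list(node = nxt, sign = s, path = c(top$path, nxt))
                }
            }
        }
    }
    diagW <- diag(W)
    list(n_circuits = length(lens),
         mean_length = if (length(lens)) mean(lens) else NA_real_,
         excitatory = sum(signs == 1L),
         inhibitory = sum(signs == -1L),
         self_activation = sum(diagW == 1L),
         self_inhibition = sum(diagW == -1L),
         lengths = lens)
}

#' Sampling survey of maximum cycle length
#'
#' Draws random networks, computes each one's maximum attractor cycle
#' length, and aggregates by a structural grouping: edge density, the
#' excitatory/inhibitory edge mix, the mean length of simple interaction
#' circuits, or the number of self-loops by sign.  The survey behind the
#' observations that denser networks cycle longer and that self-inhibition
#' (but not self-excitation) favors long cycles.
#'
#' @param n node count.
#' @param samples number of random networks to draw.
#' @param group_by one of `"density"` (edge count), `"edge_mix"`
#'   (excitatory x inhibitory counts), `"circuit_length"` (mean simple
#'   circuit length, binned to 0.5), `"self_loops"` (positive x negative
#'   diagonal counts).
#' @param generator `"uniform"` (i.i.d. trits) or a function `(n)` that
#'   returns a `signed_network`.
#' @return object of class `survey_result`: list with `group_by`,
#'   `summary` (data.frame: `group`, `mean_max_cycle`, `max_max_cycle`,
#'   `count`), `samples` (per-network data.frame), `n`, `n_samples`.
#'   Uses the R random number generator; seed with [set.seed].
#' @export
cycle_length_survey <- function(n, samples,
                                group_by = c("density", "edge_mix",
                                             "circuit_length", "self_loops"),
                                generator = "uniform") {
    group_by <- match.arg(group_by)
    stopifnot(samples >= 1L)
    if (is.function(generator)) {
        nets <- lapply(seq_len(samples), function(i) generator(n))
        G <- do.call(rbind, lapply(nets, function(x) as.integer(t(x$W))))
    } else if (identical(generator, "uniform")) {
        G <- random_genomes(n, samples)
        nets <- NULL
    } else stop("unknown generator")
    maxcyc <- batch_max_cycle_cpp(G, n)
    df <- data.frame(max_cycle = maxcyc,
                     edges = as.integer(rowSums(G != 0L)))
    diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)   # row-major diagonal
    D <- G[, diag_idx, drop = FALSE]
    df$self_activation <- as.integer(rowSums(D == 1L))
    df$self_inhibition <- as.integer(rowSums(D == -1L))
    df$excitatory <- as.integer(rowSums(G == 1L))
    df$inhibitory <- as.integer(rowSums(G == -1L))
    if (group_by == "circuit_length") {
        if (is.null(nets))
            nets <- lapply(seq_len(samples),
                           function(i) genome_decode(G[i, ], n))
        df$mean_circuit_length <-
            vapply(nets, function(x) circuit_stats(x)$mean_length, 0)
    }
    group <- switch(group_by,
        density = df$edges,
        edge_mix = sprintf("e%d_i%d", df$excitatory, df$inhibitory),
        circuit_length = round(df$mean_circuit_length * 2) / 2,
        self_loops = sprintf("p%d_n%d", df$self_activation,
                             df$self_inhibition))
    ok <- !is.na(group)
    agg <- aggregate(df$max_cycle[ok], by = list(group = group[ok]),
                     FUN = function(v) c(mean = mean(v), max = max(v),
                                         count = length(v)))
    summary <- data.frame(group = agg$group,
                          mean_max_cycle = agg$x[, "mean"],
                          max_max_cycle = agg$x[, "max"],
                          count = as.integer(agg$x[, "count"]),
                          stringsAsFactors = FALSE)
    structure(list(group_by = group_by, summary = summary, samples = df,
                   n = n, n_samples = samples),
              class = "survey_result")
}

#' @export
print.survey_result <- function(x, ...) {
    cat("survey_result (n =", x$n, ",", x$n_samples, "samples) grouped by",
        x$group_by, "\n")
    print(utils::head(x$summary, 12L))
    invisible(x)
}

#' Write a survey summary as TSV
#'
#' @param survey a `survey_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_survey_tsv <- function(survey, path) {
    stopifnot(inherits(survey, "survey_result"))
    write.table(survey$summary, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Two-sample comparison of summary statistics
#'
#' Standard two-sample z or Welch t statistic used to compare cycle-length
#' or symmetry distributions between populations.
#'
#' @param values_a,values_b numeric samples (nonempty).
#' @param test `"z"` (normal approximation with sample variances) or
#'   `"t"` (Welch).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (alternative
#'   about `mean(values_a) - mean(values_b)`).
#' @return list with `statistic`, `p_value`, `mean_a`, `mean_b`, and
#'   `degenerate` (`TRUE` when both samples have zero variance, in which
#'   case `p_value` is 1 for equal means and 0 otherwise).
#' @export
compare_populations <- function(values_a, values_b, test = c("z", "t"),
                                alternative = c("two.sided", "less",
                                                "greater")) {
    test <- match.arg(test)
    alternative <- match.arg(alternative)
    stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
    ma <- mean(values_a); mb <- mean(values_b)
    va <- if (length(values_a) > 1L) var(values_a) else 0
    vb <- if (length(values_b) > 1L) var(values_b) else 0
    if (va == 0 && vb == 0) {
        equal <- isTRUE(all.equal(ma, mb))
        stat <- if (equal) 0 else sign(ma - mb) * Inf
        p <- if (equal) 1 else {
            if (alternative == "two.sided") 0
            else if (alternative == "less" && ma < mb) 0
            else if (alternative == "greater" && ma > mb) 0
            else 1
        }
        return(list(statistic = stat, p_value = p, mean_a = ma, mean_b = mb,
                    degenerate = TRUE))
    }
    if (test == "z") {
        se <- sqrt(va / length(values_a) + vb / length(values_b))
        z <- (ma - mb) / se
        p <- switch(alternative,
                    two.sided = 2 * pnorm(-abs(z)),
                    less = pnorm(z),
                    greater = pnorm(z, lower.tail = FALSE))
        return(list(statistic = z, p_value = p, mean_a = ma, mean_b = mb,
                    degenerate = FALSE))
    }
    tt <- t.test(values_a, values_b, alternative = alternative)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         mean_a = ma, mean_b = mb, degenerate = FALSE)
}
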