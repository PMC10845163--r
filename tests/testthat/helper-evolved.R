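# Evolved 7-node populations are expensive to regenerate, so replicate GA
# runs are computed once per session and shared across the tests that
# compare evolved networks with random baselines.

.evolved_cache <- new.env(parent = emptyenv())

evolved_fronts <- function(n_runs = 20L, pop_size = 100L,
                           generations = 200L, n = 7L) {
    key <- sprintf("f_%d_%d_%d_%d", n, n_runs, pop_size, generations)
    if (is.null(.evolved_cache[[key]])) {
        .evolved_cache[[key]] <- lapply(seq_len(n_runs), function(r)
            evolve_pareto(n, pop_size = pop_size,
                          generations = generations, seed = 1000L + r))
    }
    .evolved_cache[[key]]
}

# all final-front genomes pooled over runs, as one matrix
front_genomes <- function(fronts) {
    do.call(rbind, lapply(fronts, function(f) f$members$genomes))
}

# suppressed-motif set regenerated from the evolved fronts against a
# density-matched random baseline census
suppressed_motifs_from <- function(fronts, baseline_size = 10000L,
                                   seed = 99L) {
    key <- sprintf("sup_%d_%d", baseline_size, seed)
    if (is.null(.evolved_cache[[key]])) {
        G <- front_genomes(fronts)
        n <- fronts[[1L]]$n
        target_nets <- lapply(seq_len(nrow(G)),
                              function(i) genome_decode(G[i, ], n))
        set.seed(seed)
        edges <- rowSums(G != 0L)
        BG <- density_genomes_for_tests(n, baseline_size,
                                        sample(edges, baseline_size,
                                               replace = TRUE))
        baseline_nets <- lapply(seq_len(baseline_size),
                                function(i) genome_decode(BG[i, ], n))
        enr <- motif_enrichment(motif_census(target_nets),
                                motif_census(baseline_nets),
                                delta = 0.05, min_support = 50L)
        .evolved_cache[[key]] <- list(enrichment = enr,
                                      baseline_genomes = BG)
    }
    .evolved_cache[[key]]
}

# fixed-density genome batch (mirrors the package generator but kept here
# so tests control the RNG stream explicitly)
density_genomes_for_tests <- function(n, m, edge_counts,
                                      inhibitory_fraction = 0.5) {
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
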