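test_that("uniform sampling has the expected nonzero fraction", {
    set.seed(401)
    G <- random_genomes(5L, 2000L)
    frac <- mean(G != 0L)
    se <- sqrt(2 / 3 * 1 / 3 / length(G))
    expect_lt(abs(frac - 2 / 3), 3 * se)

    set.seed(411); a <- random_uniform_network(4L)
    set.seed(411); b <- random_uniform_network(4L)
    expect_identical(a$W, b$W)
})

test_that("fixed-density generation places exactly the requested edges", {
    set.seed(421)
    expect_identical(sum(random_density_network(4L, 0L)$W != 0L), 0L)
    allneg <- random_density_network(3L, 9L, inhibitory_fraction = 1)
    expect_true(all(allneg$W == -1L))
    for (k in c(1L, 7L, 16L)) {
        net <- random_density_network(4L, k, inhibitory_fraction = 0.3)
        expect_identical(sum(net$W != 0L), k)
    }
})

test_that("density-matched uniform draws look like uniform draws", {
    set.seed(431)
    n <- 5L
    G1 <- random_genomes(n, 3000L)
    ks <- rbinom(3000L, n * n, 2 / 3)
    G2 <- density_genomes_for_tests(n, 3000L, ks)
    c1 <- batch_max_cycle(G1, n)
    c2 <- batch_max_cycle(G2, n)
    cmp <- compare_populations(c1, c2, test = "z")
    expect_gt(cmp$p_value, 0.001)
    expect_lt(abs(mean(rowSums(G2 != 0L)) - mean(rowSums(G1 != 0L))), 0.5)
})

test_that("Kauffman networks have K inputs and fair-coin tables", {
    set.seed(441)
    net <- kauffman_network(8L, 3L)
    expect_true(all(vapply(net$inputs, length, 1L) == 3L))
    expect_true(all(vapply(net$inputs, anyDuplicated, 1L) == 0L))
    expect_true(all(lengths(net$tables) == 8L))
    bits <- unlist(lapply(1:200, function(i)
        kauffman_network(5L, 2L)$tables))
    expect_lt(abs(mean(bits) - 0.5), 3 * sqrt(0.25 / length(bits)))
})

test_that("circuit enumeration handles hand-worked graphs", {
    expect_identical(circuit_stats(zero_net(3L))$n_circuits, 0L)

    selfinh <- circuit_stats(signed_network(matrix(-1L)))
    expect_identical(selfinh$n_circuits, 1L)
    expect_identical(selfinh$inhibitory, 1L)
    expect_identical(selfinh$lengths, 1L)
    expect_identical(selfinh$self_inhibition, 1L)

    two <- circuit_stats(signed_network(rbind(c(0L, 1L), c(1L, 0L))))
    expect_identical(two$n_circuits, 1L)
    expect_identical(two$excitatory, 1L)
    expect_identical(two$mean_length, 2)

    # toggle: the 2-circuit has sign +1, both self-loops are inhibitory
    tg <- circuit_stats(toggle_net())
    expect_identical(tg$n_circuits, 3L)
    expect_identical(tg$excitatory, 1L)
    expect_identical(tg$inhibitory, 2L)
    expect_identical(sort(tg$lengths), c(1L, 1L, 2L))
})

test_that("surveys aggregate and reproduce the density trend", {
    zero_gen <- function(n) zero_net(n)
    sv <- cycle_length_survey(4L, 30L, group_by = "density",
                              generator = zero_gen)
    expect_identical(nrow(sv$summary), 1L)
    expect_identical(sv$summary$mean_max_cycle, 1)

    # sweep the full density range, as the density survey does
    set.seed(451)
    gen <- function(n) random_density_network(n, sample(0:(n * n), 1L))
    sv <- cycle_length_survey(7L, 4000L, group_by = "density",
                              generator = gen)
    expect_identical(sum(sv$summary$count), 4000L)
    # denser networks cycle longer: strong positive rank correlation
    well <- sv$summary[sv$summary$count >= 30L, ]
    expect_gt(cor(well$group, well$mean_max_cycle, method = "spearman"),
              0.7)
})

test_that("self-inhibition helps and self-excitation hurts cycle length", {
    set.seed(461)
    sv <- cycle_length_survey(7L, 6000L, group_by = "self_loops")
    d <- sv$samples
    expect_gt(cor(d$self_inhibition, d$max_cycle), 0)
    expect_lt(cor(d$self_activation, d$max_cycle), 0)
})

test_that("population comparisons handle standard and degenerate cases", {
    x <- c(1, 2, 3, 4, 5)
    same <- compare_populations(x, x, test = "z")
    expect_equal(same$p_value, 1, tolerance = 1e-12)
    expect_equal(same$statistic, 0)

    set.seed(471)
    a <- rnorm(200L, mean = 10)
    b <- rnorm(200L, mean = 0)
    expect_lt(compare_populations(a, b, test = "z")$p_value, 1e-4)
    expect_lt(compare_populations(a, b, test = "t")$p_value, 1e-4)
    expect_lt(compare_populations(b, a, test = "z",
                                  alternative = "less")$p_value, 1e-4)

    deg <- compare_populations(rep(1, 5), rep(1, 5))
    expect_true(deg$degenerate)
    expect_identical(deg$p_value, 1)
    deg2 <- compare_populations(rep(2, 5), rep(1, 5))
    expect_identical(deg2$p_value, 0)
})

test_that("survey TSV export writes the summary table", {
    set.seed(481)
    sv <- cycle_length_survey(4L, 100L, group_by = "edge_mix")
    path <- tempfile(fileext = ".tsv")
    write_survey_tsv(sv, path)
    back <- read.table(path, sep = "\t", header = TRUE)
    expect_identical(nrow(back), nrow(sv$summary))
    expect_identical(sum(back$count), 100L)
})
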