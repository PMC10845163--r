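test_that("canonical form is a relabeling invariant and idempotent", {
    zero_id <- canonical_motif_id(matrix(0L, 3, 3))
    expect_identical(motif_id_to_matrix(zero_id), matrix(0L, 3, 3))
    expect_error(canonical_motif_id(matrix(2L, 3, 3)), "-1, 0, 1")
    set.seed(201)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (r in 1:100) {
        M <- matrix(sample(c(-1L, 0L, 1L), 9L, replace = TRUE), 3, 3)
        id <- canonical_motif_id(M)
        p <- perms[[sample.int(6L, 1L)]]
        expect_identical(canonical_motif_id(M[p, p]), id)
        # idempotence: the canonical representative canonicalizes to itself
        expect_identical(canonical_motif_id(motif_id_to_matrix(id)), id)
        # minimality: the id is the smallest over the explicit orbit
        orbit <- vapply(perms, function(q)
            sum((as.integer(t(M[q, q])) + 1) * 3^(8:0)), 0)
        expect_identical(id, as.integer(min(orbit)))
    }
})

test_that("motif id/string/matrix conversions round-trip", {
    set.seed(211)
    ids <- vapply(1:20, function(i)
        canonical_motif_id(matrix(sample(c(-1L, 0L, 1L), 9L, TRUE), 3, 3)),
        1L)
    s <- motif_id_to_string(ids)
    expect_true(all(nchar(s) == 9L))
    expect_identical(motif_string_to_id(s), as.numeric(ids))
    for (i in seq_along(ids))
        expect_identical(canonical_motif_id(motif_id_to_matrix(ids[i])),
                         ids[i])
})

test_that("class enumeration splits into connected and disconnected", {
    all_ids <- enumerate_motif_classes(connected_only = FALSE)
    conn <- enumerate_motif_classes(connected_only = TRUE)
    expect_length(all_ids, 3411L)
    expect_length(conn, 3284L)
    expect_length(setdiff(all_ids, conn), 127L)
    expect_true(all(conn %in% all_ids))
})

test_that("network scans count exactly the connected triads", {
    z <- zero_net(6L)
    cz <- motif_census(z)
    expect_length(cz$counts, 0L)
    expect_identical(cz$triples_scanned, as.integer(choose(6, 3)))

    # a 3-node network that is one connected motif
    M <- rbind(c(0L, 1L, -1L), c(0L, 0L, 1L), c(-1L, 0L, 0L))
    cm <- motif_census(signed_network(M))
    expect_identical(sum(cm$counts), 1L)
    expect_identical(names(cm$counts), as.character(canonical_motif_id(M)))

    set.seed(221)
    for (r in 1:5) {
        net <- random_uniform_network(6L)
        a <- motif_census(net)
        b <- motif_census(relabel_net(net))
        expect_identical(a$counts[order(names(a$counts))],
                         b$counts[order(names(b$counts))])
        expect_lte(sum(a$counts), a$triples_scanned)
    }
})

test_that("population censuses sum per-network counts", {
    set.seed(231)
    nets <- lapply(1:4, function(i) random_uniform_network(5L))
    pop <- motif_census(nets)
    expect_identical(pop$triples_scanned, as.integer(4L * choose(5, 3)))
    expect_identical(sum(pop$counts),
                     sum(vapply(nets, function(x) sum(motif_census(x)$counts),
                                1L)))
})

test_that("enrichment flags absent motifs and nothing when equal", {
    set.seed(241)
    nets <- lapply(1:300, function(i) random_uniform_network(6L))
    base <- motif_census(nets)
    same <- motif_enrichment(base, base, delta = 0.99, min_support = 5L)
    expect_length(same$suppressed, 0L)
    expect_true(all(abs(same$report$ratio - 1) < 1e-12))

    # knock one well-supported motif out of the target
    victim <- names(base$counts)[which.max(base$counts)]
    target <- base
    target$counts[victim] <- 0L
    enr <- motif_enrichment(target, base, delta = 0.05, min_support = 5L)
    expect_true(as.numeric(victim) %in% enr$suppressed)

    empty <- structure(list(counts = integer(0), triples_scanned = 0L),
                       class = "motif_census")
    expect_error(motif_enrichment(base, empty), "empty")
})

test_that("gluing stamps motifs up to the target density", {
    # the all-zero motif can never add density
    zero_id <- canonical_motif_id(matrix(0L, 3, 3))
    set.seed(251)
    res <- glue_network(5L, zero_id, target_density = 0.5, max_stamps = 50L)
    expect_false(res$reached)
    expect_identical(sum(res$net$W != 0L), 0L)
    expect_identical(res$stamps, 50L)

    # one fully nonzero motif on n = 3 is a relabeling of itself
    full <- canonical_motif_id(matrix(c(1L, -1L, 1L, 1L, 1L, -1L,
                                        -1L, 1L, 1L), 3, 3))
    set.seed(261)
    res <- glue_network(3L, full, target_density = 1)
    expect_true(res$reached)
    expect_identical(canonical_motif_id(res$net$W), full)

    set.seed(271)
    res <- glue_network(7L, enumerate_motif_classes(TRUE)[2:10],
                        target_density = 0.6)
    expect_true(res$reached)
    expect_gte(mean(res$net$W != 0L), 0.6)
})

test_that("census TSV and motif lists round-trip", {
    set.seed(281)
    census <- motif_census(random_uniform_network(6L))
    path <- tempfile(fileext = ".tsv")
    write_census_tsv(census, path)
    back <- read_census_tsv(path)
    expect_identical(back$triples_scanned, census$triples_scanned)
    expect_identical(back$counts[order(names(back$counts))],
                     census$counts[order(names(census$counts))])

    ids <- enumerate_motif_classes(TRUE)[1:25]
    lp <- tempfile(fileext = ".txt")
    write_motif_ids(ids, lp)
    expect_identical(read_motif_ids(lp), as.integer(ids))
})
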