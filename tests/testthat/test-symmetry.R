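test_that("symmetry metrics match hand-worked values", {
    self_ex <- signed_network(matrix(1L))   # tau(0)=0, tau(1)=1
    expect_identical(full_symmetric_fraction(self_ex)$fraction, 1)
    expect_identical(partial_symmetry_ratio(self_ex), 1)

    z <- zero_net(3L)                       # constant map, maximally asymmetric
    expect_identical(full_symmetric_fraction(z)$fraction, 0)
    expect_identical(partial_symmetry_ratio(z), 0)

    tg <- toggle_net()
    fs <- full_symmetric_fraction(tg)
    expect_identical(fs$count, 2L)
    expect_identical(fs$fraction, 0.5)
    expect_identical(partial_symmetry_ratio(tg), 0.5)
})

test_that("no state is its own complement", {
    for (n in 1:6) {
        s <- 0:(2^n - 1L)
        comp <- bitwShiftL(1L, n) - 1L - s
        expect_true(all(comp != s))
    }
})

test_that("the full-symmetry indicator is equal on complementary pairs", {
    set.seed(101)
    for (r in 1:20) {
        n <- sample(2:7, 1L)
        succ <- transition_map(random_uniform_network(n))$successor
        mask <- bitwShiftL(1L, n) - 1L
        ind <- succ[(mask - (0:mask)) + 1L] == mask - succ
        expect_identical(ind, rev(ind))     # ind[x] == ind[!x]
        # summing one state per pair and doubling gives the full count
        half <- sum(ind[seq_len(2^(n - 1L))])
        expect_identical(2L * half, sum(ind))
    }
})

test_that("p_sr dominates the fully symmetric fraction", {
    set.seed(111)
    for (r in 1:40) {
        n <- sample(2:7, 1L)
        net <- if (r %% 2L == 0L) random_uniform_network(n)
               else kauffman_network(n, sample.int(min(n, 3L), 1L))
        rep <- symmetry_report(net, method = "exact")
        expect_gte(rep$p_sr, rep$full_sym_fraction)
        expect_gte(rep$p_sr, 0); expect_lte(rep$p_sr, 1)
        expect_identical(rep$full_sym_fraction == 1, rep$p_sr == 1)
    }
})

test_that("a mirrored transition diagram is fully symmetric", {
    set.seed(121)
    for (n in c(3L, 5L)) {
        N <- bitwShiftL(1L, n)
        mask <- N - 1L
        succ <- integer(N)
        lower <- 0:(N / 2 - 1L)
        succ[lower + 1L] <- sample(0:mask, N / 2, replace = TRUE)
        succ[(mask - lower) + 1L] <- mask - succ[lower + 1L]
        tm <- structure(list(n = n, successor = succ),
                        class = "transition_map")
        expect_identical(full_symmetric_fraction(tm)$fraction, 1)
        expect_identical(partial_symmetry_ratio(tm), 1)
    }
})

test_that("exact metrics agree between a threshold net and its compiled bfn", {
    set.seed(131)
    for (r in 1:10) {
        net <- random_uniform_network(4L)
        bfn <- compile_bnet(threshold_to_bnet(net))
        expect_equal(full_symmetric_fraction(bfn)$count,
                     full_symmetric_fraction(net)$count)
        expect_equal(partial_symmetry_ratio(bfn),
                     partial_symmetry_ratio(net))
    }
})

test_that("sampled estimates are deterministic and converge", {
    z <- zero_net(5L)
    set.seed(141)
    rep <- sampled_symmetry(z, m = 500L)
    expect_identical(rep$full_sym_fraction, 0)
    expect_identical(rep$p_sr, 0)

    tg <- toggle_net()
    set.seed(151)
    rep <- sampled_symmetry(tg, m = 10000L)
    se <- sqrt(0.5 * 0.5 / 10000)
    expect_lt(abs(rep$full_sym_fraction - 0.5), 3 * se)
    expect_lt(abs(rep$p_sr - 0.5), 3 * se)
    expect_identical(rep$method, "sampled")
    expect_gt(rep$ci_halfwidth, 0)

    set.seed(161); a <- sampled_symmetry(tg, m = 200L)
    set.seed(161); b <- sampled_symmetry(tg, m = 200L)
    expect_identical(a, b)

    # sampling works beyond the exact cap (n = 40 here)
    set.seed(171)
    big <- kauffman_network(40L, 2L)
    rep <- sampled_symmetry(big, m = 300L)
    expect_true(rep$p_sr >= 0 && rep$p_sr <= 1)
})

test_that("symmetry_report switches method at the cap", {
    tg <- toggle_net()
    expect_identical(symmetry_report(tg)$method, "exact")
    set.seed(181)
    expect_identical(symmetry_report(tg, cap = 1L, m = 100L)$method,
                     "sampled")
})

test_that("the symmetry screen reads mixed formats end-to-end", {
    dir <- tempfile(); dir.create(dir)
    write_network_tsv(toggle_net(), file.path(dir, "toggle.tsv"))
    write_network_json(relay_net(), file.path(dir, "relay.json"))
    set.seed(191)
    write_bnet(bfn_to_bnet(kauffman_network(4L, 2L)),
               file.path(dir, "k42.bnet"))
    df <- symmetry_screen(dir)
    expect_identical(nrow(df), 3L)
    expect_identical(df$p_sr[df$model == "toggle.tsv"], 0.5)
    expect_true(all(df$method == "exact"))
    expect_identical(df$n[df$model == "k42.bnet"], 4L)
})
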