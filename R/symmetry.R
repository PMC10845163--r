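#' Exact count of fully reflection-symmetric transitions
#'
#' A state `x` transitions fully symmetrically when `tau(!x) = !tau(x)`,
#' with `!` the bitwise NOT: the mirror image of the transition is itself a
#' transition of the system.  Counts such states over the whole state
#' space.
#'
#' @param net a network or `transition_map`.
#' @param cap state-space cap, see [transition_map].
#' @return list with `count` (states satisfying the condition) and
#'   `fraction` (`count / 2^n`).
#' @examples
#' toggle <- signed_network(rbind(c(-1, 1), c(1, -1)))
#' full_symmetric_fraction(toggle)$fraction  # 0.5
#' @export
full_symmetric_fraction <- function(net, cap = NULL) {
    tmap <- as_transition_map(net, cap = cap)
    succ <- tmap$successor
    N <- length(succ)
    mask <- N - 1L
    comp_succ <- succ[(mask - (0:mask)) + 1L]  # tau(!x) for each x
    count <- sum(comp_succ == mask - succ)
    list(count = count, fraction = count / N)
}

#' Partial symmetry ratio
#'
#' The per-bit relaxation of full reflection symmetry: bit `i` of state `x`
#' transitions symmetrically when `f(x)_i != f(!x)_i`, i.e. the bit lands
#' on complementary values from complementary starts.  The partial symmetry
#' ratio is the fraction of all `2^n * n` (state, bit) pairs that are
#' symmetric; it equals 1 exactly when every transition is fully symmetric.
#'
#' @inheritParams full_symmetric_fraction
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' partial_symmetry_ratio(signed_network(matrix(1)))  # 1 (self-excitation)
#' @export
partial_symmetry_ratio <- function(net, cap = NULL) {
    tmap <- as_transition_map(net, cap = cap)
    succ <- tmap$successor
    n <- tmap$n
    N <- length(succ)
    mask <- N - 1L
    diffbits <- bitwXor(succ[(mask - (0:mask)) + 1L], mask - succ)
    # popcount of xor(tau(x), tau(!x)) ... symmetric bits differ, so count
    # set bits of xor(tau(!x), !tau(x)) complement: a bit is symmetric iff
    # tau(!x)_i == 1 - tau(x)_i, i.e. xor(tau(!x), !tau(x))_i == 0.
    total <- 0
    for (b in 0:(n - 1L))
        total <- total + sum(bitwAnd(bitwShiftR(diffbits, b), 1L))
    1 - total / (N * n)
}

#' Monte-Carlo symmetry estimates for networks of any size
#'
#' Draws `m` states uniformly at random and evaluates the full-symmetry
#' indicator and the per-bit symmetric fraction on the sample; unbiased
#' estimators of the exact quantities, usable far beyond the state-space
#' cap (biological models reach hundreds of nodes).
#'
#' @param net a `signed_network` or `bfn` of any size.
#' @param m number of state draws (default `1e4`).
#' @param conf confidence level for the binomial half-widths.
#' @return a `symmetry_report`, see [symmetry_report].
#'   Uses the R random number generator; seed with [set.seed].
#' @export
sampled_symmetry <- function(net, m = 10000L, conf = 0.95) {
    n <- network_size(net)
    stopifnot(m >= 1)
    X <- matrix(as.integer(runif(m * n) < 0.5), m, n)
    Y <- state_transition_batch(net, X)
    Yc <- state_transition_batch(net, 1L - X)
    sym_bits <- Y != Yc                 # bit transitions symmetrically
    full <- rowSums(sym_bits) == n
    p_full <- mean(full)
    p_sr <- mean(sym_bits)
    z <- qnorm(1 - (1 - conf) / 2)
    new_symmetry_report(n = n,
                        full_sym_fraction = p_full,
                        full_sym_count = NA_real_,
                        p_sr = p_sr,
                        method = "sampled",
                        sample_count = as.integer(m),
                        ci_halfwidth = z * sqrt(p_full * (1 - p_full) / m),
                        p_sr_ci_halfwidth = z * sqrt(p_sr * (1 - p_sr) / m))
}

new_symmetry_report <- function(n, full_sym_fraction, full_sym_count, p_sr,
                                method, sample_count = NA_integer_,
                                ci_halfwidth = NA_real_,
                                p_sr_ci_halfwidth = NA_real_) {
    structure(list(n = n,
                   full_sym_fraction = full_sym_fraction,
                   full_sym_count = full_sym_count,
                   p_sr = p_sr,
                   method = method,
                   sample_count = sample_count,
                   ci_halfwidth = ci_halfwidth,
                   p_sr_ci_halfwidth = p_sr_ci_halfwidth),
              class = "symmetry_report")
}

#' Symmetry report for a network
#'
#' Computes both reflection-symmetry metrics -- the fully symmetric
#' transition fraction and the partial symmetry ratio -- exactly when the
#' state space fits under the cap, and by Monte-Carlo sampling otherwise.
#'
#' @param net a `signed_network` or `bfn`.
#' @param method `"auto"` (default; exact when `n <= cap`), `"exact"`, or
#'   `"sampled"`.
#' @param m sample count for the sampled method.
#' @param cap state-space cap.
#' @return object of class `symmetry_report` with fields `n`,
#'   `full_sym_fraction`, `full_sym_count` (NA when sampled), `p_sr`,
#'   `method`, `sample_count`, `ci_halfwidth`, `p_sr_ci_halfwidth`.
#' @export
symmetry_report <- function(net, method = c("auto", "exact", "sampled"),
                            m = 10000L, cap = NULL) {
    method <- match.arg(method)
    n <- network_size(net)
    if (method == "auto")
        method <- if (n <= state_cap(cap)) "exact" else "sampled"
    if (method == "sampled") return(sampled_symmetry(net, m = m))
    tmap <- transition_map(net, cap = cap)
    fs <- full_symmetric_fraction(tmap)
    new_symmetry_report(n = n,
                        full_sym_fraction = fs$fraction,
                        full_sym_count = fs$count,
                        p_sr = partial_symmetry_ratio(tmap),
                        method = "exact")
}

#' @export
print.symmetry_report <- function(x, ...) {
    cat(sprintf("symmetry_report (n = %d, %s): full_sym = %.4f, p_sr = %.4f\n",
                x$n, x$method, x$full_sym_fraction, x$p_sr))
    invisible(x)
}

#' @export
format.symmetry_report <- function(x, ...) {
    sprintf("full_sym=%.4f p_sr=%.4f (%s)",
            x$full_sym_fraction, x$p_sr, x$method)
}

#' Write a symmetry report as JSON
#'
#' @param report a `symmetry_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_symmetry_json <- function(report, path) {
    stopifnot(inherits(report, "symmetry_report"))
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Batch symmetry screen over model files
#'
#' Reads every network in `paths` (or every `.bnet`/`.tsv`/`.json` file in
#' a directory) and emits one row per model with both symmetry metrics --
#' the screen used to compare curated Boolean models of biological systems
#' against random baselines.
#'
#' @param paths character vector of files, or a single directory.
#' @param method,m,cap forwarded to [symmetry_report].
#' @return data.frame with columns `model`, `n`, `mean_in_degree`,
#'   `full_sym_fraction`, `p_sr`, `method`, `sample_count`,
#'   `ci_halfwidth`.
#' @export
symmetry_screen <- function(paths, method = "auto", m = 10000L, cap = NULL) {
    if (length(paths) == 1L && dir.exists(paths))
        paths <- list.files(paths, pattern = "\\.(bnet|tsv|json)$",
                            full.names = TRUE)
    if (length(paths) == 0L) stop("no model files found")
    rows <- lapply(paths, function(p) {
        net <- read_network(p)
        rep <- symmetry_report(net, method = method, m = m, cap = cap)
        indeg <- if (inherits(net, "signed_network")) {
            colSums(net$W != 0L)
        } else {
            vapply(net$inputs, length, 1L)
        }
        data.frame(model = basename(p), n = rep$n,
                   mean_in_degree = mean(indeg),
                   full_sym_fraction = rep$full_sym_fraction,
                   p_sr = rep$p_sr, method = rep$method,
                   sample_count = rep$sample_count,
                   ci_halfwidth = rep$ci_halfwidth,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
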