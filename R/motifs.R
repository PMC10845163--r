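# 3-node signed motifs.  A motif is a 3x3 trit matrix considered up to
# simultaneous row/column permutation (node relabeling).  The canonical id
# of a motif is the lexicographically smallest row-major flattening over
# the 6 permutations, with trit order -1 < 0 < 1; ids are stored as the
# base-3 integer of that flattening (digit = trit + 1, first matrix entry
# most significant), which preserves lexicographic order.

perm3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

# column indices that realize each permutation on a row-major flattening
perm3_cols <- lapply(perm3, function(p) {
    as.vector(t(outer(p, p, function(a, b) (a - 1L) * 3L + b)))
})

pow3 <- 3^(8:0)

# canonical ids for a batch of flattened motifs (rows = row-major 9 trits)
canonical_id_batch <- function(flat) {
    flat <- flat + 1L                        # digits 0..2
    best <- rep(Inf, nrow(flat))
    for (cols in perm3_cols) {
        v <- as.vector(flat[, cols, drop = FALSE] %*% pow3)
        best <- pmin(best, v)
    }
    as.integer(best)
}

#' Canonical form of a 3-node signed motif
#'
#' @param M 3x3 matrix with entries in `{-1, 0, 1}`, or its row-major
#'   flattening of length 9.
#' @return Integer canonical id: the base-3 value (digits = trit + 1) of
#'   the lexicographically smallest row-major flattening over all 6 node
#'   relabelings.  Identical for any two relabelings of the same motif and
#'   idempotent under [motif_id_to_matrix].
#' @examples
#' # any relabeling of a motif has the same id
#' M <- rbind(c(0, 1, 0), c(0, 0, -1), c(1, 0, 0))
#' canonical_motif_id(M) == canonical_motif_id(M[c(2, 3, 1), c(2, 3, 1)])
#' @export
canonical_motif_id <- function(M) {
    flat <- if (is.matrix(M)) {
        if (!all(dim(M) == c(3L, 3L))) stop("M must be 3x3")
        as.integer(t(M))
    } else {
        if (length(M) != 9L) stop("flattened motif must have 9 entries")
        as.integer(M)
    }
    if (!all(flat %in% c(-1L, 0L, 1L))) stop("entries must be in {-1, 0, 1}")
    canonical_id_batch(matrix(flat, 1L))
}

#' Convert between motif ids, matrices and signed-digit strings
#'
#' The string form spells the row-major flattening with characters `-`,
#' `0`, `+` (e.g. `"0+000-000"`), the on-disk format for motif lists.
#'
#' @param id integer motif id (base-3 encoding of the flattening).
#' @param s 9-character string over `-0+`.
#' @param M 3x3 trit matrix.
#' @return the corresponding matrix, string, or id.
#' @export
motif_id_to_matrix <- function(id) {
    digits <- (id %/% pow3) %% 3L - 1L
    matrix(as.integer(digits), 3L, 3L, byrow = TRUE)
}

#' @rdname motif_id_to_matrix
#' @export
motif_id_to_string <- function(id) {
    vapply(id, function(x) {
        digits <- (x %/% pow3) %% 3L
        paste(c("-", "0", "+")[digits + 1L], collapse = "")
    }, "")
}

#' @rdname motif_id_to_matrix
#' @export
motif_string_to_id <- function(s) {
    vapply(s, function(x) {
        ch <- strsplit(x, "")[[1L]]
        if (length(ch) != 9L || !all(ch %in% c("-", "0", "+")))
            stop("motif string must be 9 characters over -0+")
        sum((match(ch, c("-", "0", "+")) - 1L) * pow3)
    }, 0, USE.NAMES = FALSE)
}

# rows of all 19683 labeled 3x3 trit matrices (row-major flattening)
all_motif_flats <- function() {
    v <- 0:19682
    flat <- matrix(0L, 19683L, 9L)
    for (p in 1:9) flat[, p] <- as.integer((v %/% pow3[p]) %% 3L) - 1L
    flat
}

# TRUE per row when some node has no inter-node edge in either direction
# (self-loops do not confer connectivity)
triad_disconnected <- function(flat) {
    iso <- function(a) {
        others <- setdiff(1:3, a)
        cols <- c((a - 1L) * 3L + others, (others - 1L) * 3L + a)
        rowSums(flat[, cols, drop = FALSE] != 0L) == 0L
    }
    iso(1L) | iso(2L) | iso(3L)
}

#' Enumerate all 3-motif equivalence classes
#'
#' Brute-force enumeration of all `3^9 = 19683` labeled 3x3 trit matrices,
#' reduced to canonical ids.  With `connected_only = TRUE`, classes in
#' which some node has no incoming or outgoing edge to the other two nodes
#' (self-loops ignored) are discarded, which leaves the 3284-class universe
#' used by the network scans.
#'
#' @param connected_only drop classes containing an isolated node.
#' @return sorted integer vector of canonical ids.
#' @export
enumerate_motif_classes <- function(connected_only = FALSE) {
    flat <- all_motif_flats()
    if (connected_only) flat <- flat[!triad_disconnected(flat), , drop = FALSE]
    sort(unique(canonical_id_batch(flat)))
}

new_motif_census <- function(counts, triples_scanned) {
    structure(list(counts = counts, triples_scanned = triples_scanned),
              class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
    cat("motif_census:", sum(x$counts), "connected triads in",
        x$triples_scanned, "scanned, across", length(x$counts),
        "motif classes\n")
    invisible(x)
}

#' Census of 3-motifs in a network
#'
#' Examines every node triple, extracts the induced 3x3 submatrix, and
#' counts its canonical motif class.  Disconnected triads (some node with
#' no edge to the other two) are scanned but not counted, so counts live in
#' the connected-class universe.
#'
#' @param net a `signed_network` with at least 3 nodes, or a list of such
#'   networks (a population census sums the per-network counts).
#' @return object of class `motif_census`: `counts` (named integer vector,
#'   names = canonical ids) and `triples_scanned`.
#' @export
motif_census <- function(net) {
    if (inherits(net, "signed_network")) net <- list(net)
    stopifnot(length(net) >= 1L)
    idx_cache <- list()
    vals_list <- vector("list", length(net))
    scanned <- 0L
    for (w in seq_along(net)) {
        nw <- net[[w]]
        stopifnot(inherits(nw, "signed_network"))
        if (nw$n < 3L) stop("motif census requires n >= 3")
        key <- as.character(nw$n)
        if (is.null(idx_cache[[key]])) {
            triples <- combn(nw$n, 3L)
            idx_cache[[key]] <- matrix(apply(triples, 2L, function(tr) {
                as.vector(t(outer(tr, tr,
                                  function(a, b) (b - 1L) * nw$n + a)))
            }), nrow = 9L)                   # 9 x T, row-major within motif
        }
        idx <- idx_cache[[key]]
        vals_list[[w]] <- matrix(as.vector(nw$W)[idx], ncol = 9L,
                                 byrow = TRUE)
        scanned <- scanned + ncol(idx)
    }
    vals <- do.call(rbind, vals_list)
    keep <- !triad_disconnected(vals)
    vals <- vals[keep, , drop = FALSE]
    if (nrow(vals) == 0L) return(new_motif_census(integer(0), scanned))
    ids <- canonical_id_batch(vals)
    tab <- table(ids)
    total <- setNames(as.integer(tab), names(tab))
    total <- total[order(as.numeric(names(total)))]
    new_motif_census(total, scanned)
}

#' Motif enrichment and suppressed motifs
#'
#' Compares per-triple motif rates between a target and a baseline census.
#' Motifs with adequate baseline support whose rate ratio falls below
#' `delta` are flagged as suppressed -- the signature of motifs that
#' evolution discards when selecting for long cycles.
#'
#' @param target,baseline `motif_census` objects over the same class
#'   universe (e.g. population censuses of evolved and random networks).
#' @param delta suppression threshold on `target_rate / baseline_rate`.
#' @param min_support minimum baseline count for a motif to be assessed.
#' @return list with `report` (data.frame: `canonical_id`, `id_string`,
#'   `target_count`, `baseline_count`, `target_rate`, `baseline_rate`,
#'   `ratio`, `suppressed`) and `suppressed` (integer ids).
#' @export
motif_enrichment <- function(target, baseline, delta = 0.05,
                             min_support = 50L) {
    stopifnot(inherits(target, "motif_census"),
              inherits(baseline, "motif_census"))
    if (baseline$triples_scanned == 0L || sum(baseline$counts) == 0L)
        stop("baseline census is empty")
    ids <- names(baseline$counts)[baseline$counts >= min_support]
    if (length(ids) == 0L)
        return(list(report = data.frame(), suppressed = integer(0)))
    t_count <- ifelse(ids %in% names(target$counts),
                      target$counts[ids], 0L)
    t_count[is.na(t_count)] <- 0L
    b_count <- baseline$counts[ids]
    t_rate <- t_count / target$triples_scanned
    b_rate <- b_count / baseline$triples_scanned
    ratio <- t_rate / b_rate
    rep <- data.frame(canonical_id = as.numeric(ids),
                      id_string = motif_id_to_string(as.numeric(ids)),
                      target_count = as.integer(t_count),
                      baseline_count = as.integer(b_count),
                      target_rate = t_rate, baseline_rate = b_rate,
                      ratio = ratio, suppressed = ratio < delta,
                      stringsAsFactors = FALSE, row.names = NULL)
    rep <- rep[order(rep$ratio), ]
    list(report = rep,
         suppressed = as.integer(rep$canonical_id[rep$suppressed]))
}

#' Build a network by gluing motifs onto random triples
#'
#' Starting from the empty matrix, repeatedly draws a uniform node triple
#' and a uniform motif from `motif_ids` (in a uniformly random labeling of
#' its class) and stamps its 9 entries onto the induced submatrix,
#' overwriting whatever was there, until the nonzero-entry fraction first
#' reaches `target_density` or the stamp budget is exhausted.
#'
#' @param n node count (>= 3).
#' @param motif_ids integer canonical ids to glue from.
#' @param target_density desired fraction of nonzero entries in `(0, 1]`.
#' @param max_stamps stamp budget, default `50 * n^2`.
#' @return list with `net` (a `signed_network`), `stamps` (number
#'   applied), and `reached` (`FALSE` when the budget ran out before the
#'   density was met, e.g. for motif sets too sparse to get there).
#'   Uses the R random number generator; seed with [set.seed].
#' @export
glue_network <- function(n, motif_ids, target_density,
                         max_stamps = 50L * n^2) {
    stopifnot(n >= 3L, length(motif_ids) >= 1L,
              target_density > 0, target_density <= 1)
    mats <- lapply(motif_ids, motif_id_to_matrix)
    W <- matrix(0L, n, n)
    stamps <- 0L
    while (mean(W != 0L) < target_density && stamps < max_stamps) {
        tr <- sample.int(n, 3L)              # ordered triple = random labeling
        M <- mats[[sample.int(length(mats), 1L)]]
        W[tr, tr] <- M
        stamps <- stamps + 1L
    }
    list(net = signed_network(W), stamps = stamps,
         reached = mean(W != 0L) >= target_density)
}

#' Read and write motif censuses and motif-id lists
#'
#' The census TSV has columns `id_string`, `count`, `rate` plus a header
#' comment carrying `triples_scanned`; motif lists are newline-delimited
#' 9-character signed-digit strings, the format consumed by
#' [glue_network].
#'
#' @param census a `motif_census`.
#' @param path file path.
#' @param ids integer canonical ids.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_census_tsv <- function(census, path) {
    stopifnot(inherits(census, "motif_census"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# triples_scanned\t", census$triples_scanned), con)
    df <- data.frame(id_string = motif_id_to_string(as.numeric(names(census$counts))),
                     count = as.integer(census$counts),
                     rate = as.integer(census$counts) / census$triples_scanned)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_census_tsv
#' @export
read_census_tsv <- function(path) {
    first <- readLines(path, n = 1L)
    scanned <- as.integer(sub("^# triples_scanned\t", "", first))
    df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     colClasses = c("character", "integer", "numeric"))
    counts <- setNames(df$count, as.character(motif_string_to_id(df$id_string)))
    new_motif_census(counts, scanned)
}

#' @rdname write_census_tsv
#' @export
write_motif_ids <- function(ids, path) {
    writeLines(motif_id_to_string(as.numeric(ids)), path)
    invisible(path)
}

#' @rdname write_census_tsv
#' @export
read_motif_ids <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    as.integer(motif_string_to_id(trimws(lines)))
}
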