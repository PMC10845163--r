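#' Read and write signed networks
#'
#' TSV files hold the bare `n x n` trit matrix (tab-separated, no header,
#' rows = source node); JSON files hold `{"n": ..., "W": [[...]]}`.
#' `read_network` dispatches on the file extension and also accepts
#' `.bnet` models, which are compiled to a [boolean_function_network].
#'
#' @param net a `signed_network`.
#' @param path file path.
#' @return readers return the network object; writers return `path`
#'   invisibly.
#' @export
read_network <- function(path) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           tsv = read_network_tsv(path),
           json = read_network_json(path),
           bnet = compile_bnet(read_bnet(path)),
           stop("unrecognized network format: .", ext,
                " (expected .tsv, .json or .bnet)"))
}

#' @rdname read_network
#' @export
read_network_tsv <- function(path) {
    M <- as.matrix(read.table(path, sep = "\t", header = FALSE))
    signed_network(M)
}

#' @rdname read_network
#' @export
write_network_tsv <- function(net, path) {
    stopifnot(inherits(net, "signed_network"))
    write.table(net$W, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname read_network
#' @export
read_network_json <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$W)) stop("JSON network must have a 'W' field")
    net <- signed_network(obj$W)
    if (!is.null(obj$n) && obj$n != net$n)
        stop("JSON 'n' disagrees with the shape of 'W'")
    net
}

#' @rdname read_network
#' @export
write_network_json <- function(net, path) {
    stopifnot(inherits(net, "signed_network"))
    jsonlite::write_json(list(n = net$n, W = net$W), path,
                         auto_unbox = TRUE)
    invisible(path)
}
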