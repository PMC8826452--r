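#' Construct a weighted PPI network object
#'
#' Nodes are opaque identifiers (typically Ensembl protein IDs) stored in
#' lexicographic order so that vector indices are reproducible across runs.
#' Edges are undirected, unique per unordered pair, carry an integer
#' confidence score in \[1, 999\] (STRING convention) and never form
#' self-loops.
#'
#' @param nodes character vector of node identifiers (sorted internally).
#' @param edges data.frame with columns `from`, `to` (identifiers) and
#'   `confidence` (integer in \[1, 999\]).
#' @return An object of class `ppi_network` with elements `nodes` (sorted
#'   character vector) and `edges` (data.frame `i`, `j`, `confidence` with
#'   `i < j`, integer indices into `nodes`).
#' @export
ppi_network <- function(nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  if (length(nodes) == 0L) stop_input("network must contain at least one node")
  if (nrow(edges) > 0L) {
    i <- match(as.character(edges$from), nodes)
    j <- match(as.character(edges$to), nodes)
    if (anyNA(i) || anyNA(j)) stop_input("edge endpoint not in node set")
    conf <- as.integer(edges$confidence)
    if (anyNA(conf) || any(conf < 1L | conf > 999L))
      stop_input("confidence scores must be integers in [1, 999]")
    if (any(i == j)) stop_input("self-loops are not allowed")
    lo <- pmin(i, j); hi <- pmax(i, j)
    if (anyDuplicated(paste(lo, hi)))
      stop_input("duplicate edges for the same unordered pair")
    ord <- order(lo, hi)
    edf <- data.frame(i = lo[ord], j = hi[ord], confidence = conf[ord])
  } else {
    edf <- data.frame(i = integer(), j = integer(), confidence = integer())
  }
  structure(list(nodes = nodes, edges = edf), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges, %d components\n",
              length(x$nodes), nrow(x$edges),
              length(unique(component_labels(x)))))
  invisible(x)
}

#' Read a STRING-style protein links file
#'
#' Parses whitespace-separated records `protein1 protein2 combined_score`
#' (one optional header line; gzip input auto-detected from a `.gz`
#' extension) into an undirected weighted network. STRING files list each
#' interaction twice (`a b s` and `b a s`); duplicate records for the same
#' unordered pair collapse to a single edge keeping the maximum score.
#' Edges with confidence below `min_confidence` are dropped, but every
#' identifier seen in the file is retained as a node (possibly isolated) so
#' that heat-vector indices stay aligned with the input node universe.
#'
#' @param path path to a links file, optionally gzipped.
#' @param min_confidence integer; edges with a lower combined score are
#'   discarded (default 1, i.e. keep all).
#' @return A [ppi_network()]. A parse summary (node count, edge count,
#'   component count, lines read) is attached as attribute `"log"`.
#' @export
read_string_links <- function(path, min_confidence = 1L) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_input("no records in %s", path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")

  is_int <- function(s) grepl("^[0-9]+$", s)
  start <- 1L
  f1 <- fields[[1L]]
  if (length(f1) == 3L && !is_int(f1[3L])) start <- 2L  # header line
  if (start > length(lines)) stop_input("no records after header in %s", path)

  n_rec <- length(lines) - start + 1L
  p1 <- character(n_rec); p2 <- character(n_rec); sc <- integer(n_rec)
  for (r in seq_len(n_rec)) {
    k <- start + r - 1L
    f <- fields[[k]]
    if (length(f) != 3L)
      stop_input("line %d: expected 3 whitespace-separated fields, got %d",
                 lineno[k], length(f))
    if (!is_int(f[3L]))
      stop_input("line %d: combined score '%s' is not an integer",
                 lineno[k], f[3L])
    s <- as.integer(f[3L])
    if (s < 1L || s > 999L)
      stop_input("line %d: combined score %d outside [1, 999]", lineno[k], s)
    if (f[1L] == f[2L])
      stop_input("line %d: self-interaction '%s'", lineno[k], f[1L])
    p1[r] <- f[1L]; p2[r] <- f[2L]; sc[r] <- s
  }

  nodes <- sort(unique(c(p1, p2)))
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(sc, key, max)
  pair <- strsplit(names(conf), "\r", fixed = TRUE)
  edf <- data.frame(from = vapply(pair, `[`, "", 1L),
                    to = vapply(pair, `[`, "", 2L),
                    confidence = as.integer(conf))
  edf <- edf[edf$confidence >= min_confidence, , drop = FALSE]
  if (nrow(edf) == 0L)
    stop_input("no edges remain at min_confidence = %d", min_confidence)
  net <- ppi_network(nodes, edf)
  attr(net, "log") <- data.frame(
    node_count = length(net$nodes), edge_count = nrow(net$edges),
    components = length(unique(component_labels(net))),
    records = n_rec)
  net
}

#' Write a network back to the STRING links dialect
#'
#' Each edge is written once as `a b confidence` with a header line.
#' Isolated nodes cannot be represented in this format and are omitted.
#'
#' @param net a [ppi_network()].
#' @param path output path.
#' @export
write_string_links <- function(net, path) {
  e <- net$edges
  lines <- c("protein1 protein2 combined_score",
             sprintf("%s %s %d", net$nodes[e$i], net$nodes[e$j], e$confidence))
  writeLines(lines, path)
  invisible(path)
}

#' Connected-component labels
#'
#' @param net a [ppi_network()].
#' @return Integer vector named by node: two nodes share a label iff they
#'   are connected by a path. Labels start at 1 in order of first
#'   appearance over the sorted node list.
#' @export
component_labels <- function(net) {
  n <- length(net$nodes)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(net$edges) > 0L)
    g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j))
  lab <- as.integer(igraph::components(g)$membership)
  names(lab) <- net$nodes
  lab
}

#' Weighted adjacency matrix of a network
#'
#' @param net a [ppi_network()].
#' @param weight_mode `"scaled"` (confidence / 1000, the default used for
#'   diffusion so timescales are O(1)), `"raw"` (confidence), or `"binary"`.
#' @return Symmetric sparse `dgCMatrix` with zero diagonal.
#' @export
adjacency_matrix <- function(net, weight_mode = c("scaled", "raw", "binary")) {
  weight_mode <- match.arg(weight_mode)
  n <- length(net$nodes)
  e <- net$edges
  w <- switch(weight_mode,
              scaled = e$confidence / 1000,
              raw = as.numeric(e$confidence),
              binary = rep(1, nrow(e)))
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i), x = c(w, w),
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}

#' Build the graph-Laplacian diffusion operator L = D - A
#'
#' `D` is the diagonal of weighted degrees and `A` the weighted adjacency
#' under `weight_mode`. The operator carries everything `propagate()` needs:
#' the sparse Laplacian, its largest diagonal entry (the uniformization
#' rate), and the component labels used to detect the washed-out uniform
#' limit.
#'
#' @param net a [ppi_network()].
#' @inheritParams adjacency_matrix
#' @return An object of class `lhd_laplacian`.
#' @export
build_laplacian <- function(net, weight_mode = c("scaled", "raw", "binary")) {
  weight_mode <- match.arg(weight_mode)
  bump_counter("laplacian_builds")
  A <- adjacency_matrix(net, weight_mode)
  d <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(x = d) - A
  L <- as(L, "CsparseMatrix")
  structure(list(L = L, n = length(net$nodes), nodes = net$nodes,
                 degree = d, lambda = max(d, 0),
                 weight_mode = weight_mode,
                 components = component_labels(net)),
            class = "lhd_laplacian")
}

#' @export
print.lhd_laplacian <- function(x, ...) {
  cat(sprintf("<lhd_laplacian> n = %d, weight_mode = %s, max degree = %.4g\n",
              x$n, x$weight_mode, x$lambda))
  invisible(x)
}
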