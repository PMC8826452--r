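#' Functional-term catalog
#'
#' @param terms character vector of term identifiers (order preserved; this
#'   order fixes the layout of enrichment-score vectors).
#' @param members list of character vectors, one deduplicated gene set per
#'   term.
#' @param source catalog label, e.g. `"GO"` or `"KEGG"`.
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(terms, members, source = "catalog") {
  terms <- as.character(terms)
  if (length(terms) != length(members))
    stop_input("terms and members must have equal length")
  if (anyDuplicated(terms)) stop_input("duplicate term identifiers")
  members <- lapply(members, function(m) unique(as.character(m)))
  names(members) <- terms
  structure(list(terms = terms, members = members,
                 source = as.character(source)),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("<annotation_catalog> '%s': %d terms, median size %g\n",
              x$source, length(x$terms),
              stats::median(lengths(x$members))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: tab-separated lines `term<TAB>description<TAB>gene...`.
#' Member genes are deduplicated within a term; terms with fewer than two
#' members are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @param source catalog label stored on the result (default: file name).
#' @return An [annotation_catalog()].
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  terms <- character(0)
  members <- list()
  dropped <- character(0)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 3L)
      stop_input("line %d: GMT record needs term, description and >= 1 gene",
                 lineno[k])
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) < 2L) {
      dropped <- c(dropped, f[1L])
      next
    }
    terms <- c(terms, f[1L])
    members[[length(members) + 1L]] <- genes
  }
  if (length(dropped) > 0L)
    warning(sprintf("dropped %d term(s) with < 2 members: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  if (length(terms) == 0L) stop_input("no usable terms in %s", path)
  annotation_catalog(terms, members, source = source)
}

#' Write a catalog as GMT
#'
#' @param catalog an [annotation_catalog()].
#' @param path output path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(catalog$terms, function(tm) {
    paste(c(tm, catalog$source, catalog$members[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Enrichment context: universe size and neighborhood cutoff
#'
#' @param universe_size total number of genes `N` in the hypergeometric
#'   universe; defaults downstream to the network node count.
#' @param neighbor_confidence_cutoff minimum edge confidence for a neighbor
#'   to enter a gene's interaction set `G` (default 400, the STRING
#'   medium-confidence convention).
#' @param score_cap cap on -log10(p) so cosine computations stay finite
#'   (default 300).
#' @return An object of class `enrichment_context`.
#' @export
enrichment_context <- function(universe_size,
                               neighbor_confidence_cutoff = 400L,
                               score_cap = 300) {
  if (universe_size < 1) stop_input("universe_size must be >= 1")
  if (neighbor_confidence_cutoff < 1L || neighbor_confidence_cutoff > 999L)
    stop_input("neighbor_confidence_cutoff must be in [1, 999]")
  structure(list(universe_size = as.integer(universe_size),
                 neighbor_confidence_cutoff =
                   as.integer(neighbor_confidence_cutoff),
                 score_cap = as.numeric(score_cap)),
            class = "enrichment_context")
}

#' Interaction neighborhood of a gene
#'
#' The set `G` of the function test: the gene itself plus every neighbor
#' connected with confidence at least `ctx$neighbor_confidence_cutoff`.
#'
#' @param net a [ppi_network()].
#' @param g a node identifier present in `net`.
#' @param ctx an [enrichment_context()].
#' @return Character vector of gene identifiers (sorted, includes `g`).
#' @export
neighbor_set <- function(net, g, ctx) {
  gi <- match(g, net$nodes)
  if (is.na(gi)) stop_input("gene '%s' not in network", g)
  e <- net$edges
  hit <- (e$i == gi | e$j == gi) & e$confidence >= ctx$neighbor_confidence_cutoff
  other <- ifelse(e$i[hit] == gi, e$j[hit], e$i[hit])
  sort(unique(c(g, net$nodes[other])))
}

#' Hypergeometric enrichment score of two gene sets
#'
#' The upper-tail hypergeometric p-value of observing at least
#' `m = |G intersect F|` members of `F` (size `M`) in a draw of size
#' `n = |G|` from a universe of `N` genes, returned as `-log10(p)` (capped
#' at `ctx$score_cap`). Computed in log space via [stats::phyper()], so
#' extreme overlaps do not underflow.
#'
#' @param G gene set of the query gene and its strong interactors.
#' @param F_set gene set annotated by one functional term.
#' @param ctx an [enrichment_context()]; supplies the universe size `N`.
#' @return Nonnegative enrichment score; 0 when `m = 0` (p = 1 bound on the
#'   whole support) or when the overlap is unremarkable.
#' @export
enrichment_score <- function(G, F_set, ctx) {
  N <- ctx$universe_size
  M <- length(unique(F_set))
  n <- length(unique(G))
  if (M > N || n > N)
    stop_input("set sizes (M = %d, n = %d) exceed universe N = %d", M, n, N)
  m <- length(intersect(G, F_set))
  if (m == 0L) return(0)
  logp <- stats::phyper(m - 1L, M, N - M, n, lower.tail = FALSE, log.p = TRUE)
  min(-logp / log(10), ctx$score_cap)
}

#' Enrichment-score profile of one gene
#'
#' One enrichment score per functional term, across one or more catalogs
#' concatenated in their deterministic term order. This is the vector
#' `ES(g)` whose pairwise cosine similarity feeds the function test.
#'
#' @param net a [ppi_network()].
#' @param g a node identifier present in `net`.
#' @param catalogs an [annotation_catalog()] or a list of them.
#' @param ctx an [enrichment_context()].
#' @return Named nonnegative numeric vector, one entry per term.
#' @export
enrichment_profile <- function(net, g, catalogs, ctx) {
  if (inherits(catalogs, "annotation_catalog")) catalogs <- list(catalogs)
  if (length(catalogs) == 0L) stop_input("at least one catalog is required")
  G <- neighbor_set(net, g, ctx)
  out <- unlist(lapply(catalogs, function(cat) {
    vapply(cat$terms, function(tm) enrichment_score(G, cat$members[[tm]], ctx),
           numeric(1))
  }))
  names(out) <- unlist(lapply(catalogs, `[[`, "terms"))
  out
}
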