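#' Screen configuration
#'
#' Defaults follow the staged screen's standard operating point: 500
#' permutations, empirical p < 0.05 (strict), maximum association score
#' (MAS) >= 400, maximum function score (MFS) >= 0.3.
#'
#' @param n_permutations number of random seed sets for the permutation
#'   test (default 500).
#' @param p_cutoff significance cutoff, applied strictly (`p < p_cutoff`).
#' @param mas_cutoff minimum MAS, applied inclusively (`MAS >= mas_cutoff`).
#' @param mfs_cutoff minimum MFS, applied inclusively.
#' @param rng_seed integer seed fully determining the permutation draws.
#' @param pseudo_count use the `(Heat_> + 1) / (n + 1)` estimator instead of
#'   `Heat_> / n` for users worried about p = 0 artifacts (default FALSE,
#'   matching the plain empirical definition).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_permutations = 500L, p_cutoff = 0.05,
                          mas_cutoff = 400L, mfs_cutoff = 0.3,
                          rng_seed = 1L, pseudo_count = FALSE) {
  if (n_permutations < 1L) stop_input("n_permutations must be >= 1")
  if (p_cutoff < 0) stop_input("p_cutoff must be nonnegative")
  if (mfs_cutoff < 0 || mfs_cutoff > 1) stop_input("mfs_cutoff must be in [0, 1]")
  structure(list(n_permutations = as.integer(n_permutations),
                 p_cutoff = p_cutoff, mas_cutoff = as.integer(mas_cutoff),
                 mfs_cutoff = mfs_cutoff, rng_seed = as.integer(rng_seed),
                 pseudo_count = isTRUE(pseudo_count)),
            class = "screen_config")
}

# Heat_> / n (or the +1 pseudo-count variant); kept as a pure function so
# the arithmetic is testable independently of the diffusion machinery
empirical_pvalue <- function(exceed_count, n_permutations,
                             pseudo_count = FALSE) {
  if (pseudo_count) (exceed_count + 1) / (n_permutations + 1)
  else exceed_count / n_permutations
}

#' Permutation-test p-values for candidate heats
#'
#' For each of `cfg$n_permutations` replicates, draws `seed_size` nodes
#' uniformly without replacement from all network nodes, diffuses heat from
#' them at the same time `t` as the actual run, and records each
#' candidate's heat. The p-value of candidate `g` is the fraction of
#' replicates whose heat at `g` is strictly greater than its actual heat.
#' The RNG stream is fully determined by `cfg$rng_seed` and independent of
#' candidate ordering.
#'
#' @param lap an [build_laplacian()] operator (built once and reused across
#'   replicates).
#' @param net the [ppi_network()] the operator was built from (sampling
#'   universe).
#' @param candidates data.frame with columns `gene`, `heat` (actual heats).
#' @param seed_size number of nodes per replicate seed set (the size of the
#'   level's validated driver list).
#' @param t diffusion time of the actual run; replicate heats are only
#'   comparable to actual heats at equal `t`.
#' @param cfg a [screen_config()].
#' @return Numeric p-values named by candidate gene, each a multiple of
#'   `1 / n_permutations` in \[0, 1\].
#' @export
permutation_pvalues <- function(lap, net, candidates, seed_size, t,
                                cfg = screen_config()) {
  n <- lap$n
  if (seed_size > n)
    stop_input("seed_size %d exceeds node count %d", seed_size, n)
  idx <- match(candidates$gene, lap$nodes)
  if (anyNA(idx)) stop_input("candidate gene not in network")
  if (length(idx) == 0L) return(stats::setNames(numeric(0), character(0)))
  actual <- candidates$heat
  exceed <- integer(length(idx))
  local_seed(cfg$rng_seed, {
    for (r in seq_len(cfg$n_permutations)) {
      s <- sample.int(n, seed_size)
      v <- numeric(n)
      v[s] <- 1 / seed_size
      hr <- propagate(lap, heat_vector(v, t = 0), t)
      exceed <- exceed + (hr$values[idx] > actual)
    }
  })
  p <- empirical_pvalue(exceed, cfg$n_permutations, cfg$pseudo_count)
  names(p) <- candidates$gene
  p
}

#' Maximum association score (MAS)
#'
#' The largest edge confidence between `g` and any reference (validated
#' driver) gene, `g` itself excluded from the reference; 0 when `g` has no
#' edge to any reference gene.
#'
#' @param net a [ppi_network()].
#' @param g a node identifier present in `net`.
#' @param reference a [seed_set()] of validated drivers.
#' @return Integer in `{0} U [1, 999]`.
#' @export
max_association_score <- function(net, g, reference) {
  gi <- match(g, net$nodes)
  if (is.na(gi)) stop_input("gene '%s' not in network", g)
  ref <- setdiff(reference$genes, g)
  e <- net$edges
  hit <- e$i == gi | e$j == gi
  if (!any(hit)) return(0L)
  other <- net$nodes[ifelse(e$i[hit] == gi, e$j[hit], e$i[hit])]
  conf <- e$confidence[hit][other %in% ref]
  if (length(conf) == 0L) 0L else max(conf)
}

#' Functional linkage between two enrichment profiles
#'
#' Cosine similarity of two enrichment-score vectors; defined as 0 when
#' either vector is all-zero (no functional signal, no linkage).
#'
#' @param es1,es2 equal-length nonnegative numeric vectors.
#' @return Similarity in \[0, 1\] (profiles are nonnegative).
#' @export
linkage <- function(es1, es2) {
  if (length(es1) != length(es2))
    stop_input("profile lengths differ (%d vs %d)", length(es1), length(es2))
  n1 <- sqrt(sum(es1^2)); n2 <- sqrt(sum(es2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(es1 * es2) / (n1 * n2)
}

#' Maximum function score (MFS)
#'
#' The largest functional linkage between `g`'s enrichment profile and the
#' profile of any reference gene other than `g`.
#'
#' @param g a gene identifier.
#' @param reference a [seed_set()] of validated drivers.
#' @param profiles named list of enrichment profiles covering `g` and every
#'   usable reference gene (see [enrichment_profile()]).
#' @return MFS in \[0, 1\].
#' @export
max_function_score <- function(g, reference, profiles) {
  ref <- setdiff(intersect(reference$genes, names(profiles)), g)
  if (length(ref) == 0L)
    stop_input("no usable reference profile for gene '%s'", g)
  if (is.null(profiles[[g]]))
    stop_input("no profile available for gene '%s'", g)
  max(vapply(ref, function(r) linkage(profiles[[g]], profiles[[r]]),
             numeric(1)))
}

#' Run the three-stage screen on diffusion candidates
#'
#' Stages are applied in order — permutation test, association test,
#' function test — with MAS and MFS computed only for survivors of the
#' preceding stage. Per-stage survivor counts are attached as attribute
#' `"counts"` (raw, permutation, association, function); they are
#' non-increasing by construction.
#'
#' @param candidates data.frame `gene`, `heat` from [select_candidates()].
#' @param lap an [build_laplacian()] operator.
#' @param net the underlying [ppi_network()].
#' @param seeds the level's validated-driver [seed_set()] (permutation
#'   `seed_size`, MAS/MFS reference).
#' @param catalogs an [annotation_catalog()] or list of them.
#' @param ctx an [enrichment_context()]; default universe = node count.
#' @param cfg a [screen_config()].
#' @param t diffusion time of the actual run.
#' @return A `screen_table`: data.frame with columns `gene`, `heat`,
#'   `p_value`, `mas`, `mfs` (NA where a stage was not reached),
#'   `stage_reached` (`"raw"`, `"permutation"`, `"association"`,
#'   `"function"`) and `latent` (passed all three stages).
#' @export
run_screen <- function(candidates, lap, net, seeds, catalogs,
                       ctx = NULL, cfg = screen_config(), t) {
  if (is.null(ctx)) ctx <- enrichment_context(length(net$nodes))
  seed_size <- length(intersect(seeds$genes, net$nodes))
  out <- data.frame(gene = candidates$gene, heat = candidates$heat,
                    p_value = NA_real_, mas = NA_integer_, mfs = NA_real_,
                    stage_reached = "raw", latent = FALSE,
                    stringsAsFactors = FALSE)

  p <- permutation_pvalues(lap, net, candidates, seed_size, t, cfg)
  out$p_value <- as.numeric(p)
  s1 <- out$p_value < cfg$p_cutoff
  out$stage_reached[s1] <- "permutation"

  if (any(s1)) {
    out$mas[s1] <- vapply(out$gene[s1],
                          function(g) as.integer(max_association_score(net, g, seeds)),
                          integer(1))
  }
  s2 <- s1 & !is.na(out$mas) & out$mas >= cfg$mas_cutoff
  out$stage_reached[s2] <- "association"

  if (any(s2)) {
    ref_present <- intersect(seeds$genes, net$nodes)
    need <- unique(c(out$gene[s2], ref_present))
    profiles <- lapply(need, function(g) enrichment_profile(net, g, catalogs, ctx))
    names(profiles) <- need
    out$mfs[s2] <- vapply(out$gene[s2],
                          function(g) max_function_score(g, seeds, profiles),
                          numeric(1))
  }
  s3 <- s2 & !is.na(out$mfs) & out$mfs >= cfg$mfs_cutoff
  out$stage_reached[s3] <- "function"
  out$latent <- s3

  counts <- c(raw = nrow(out), permutation = sum(s1),
              association = sum(s2), fun = sum(s3))
  names(counts) <- c("raw", "permutation", "association", "function")
  attr(out, "counts") <- counts
  attr(out, "config") <- cfg
  class(out) <- c("screen_table", "data.frame")
  out
}

#' @export
print.screen_table <- function(x, ...) {
  cn <- attr(x, "counts")
  cat(sprintf("<screen_table> %d raw -> %d permutation -> %d association -> %d function\n",
              cn["raw"], cn["permutation"], cn["association"], cn["function"]))
  NextMethod()
}
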