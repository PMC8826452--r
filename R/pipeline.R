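#' Run diffusion plus the three-stage screen for one omics level
#'
#' Initializes heat uniformly over the level's seed genes, diffuses to
#' stability, thresholds heat to get raw candidates, then applies the
#' permutation, association and function tests. The staged survivor counts
#' are available via `attr(result$table, "counts")`.
#'
#' @param net a [ppi_network()].
#' @param seeds the level's validated-driver [seed_set()].
#' @param catalogs an [annotation_catalog()] or list of them.
#' @param ctx an [enrichment_context()] or NULL (universe = node count).
#' @param dcfg a [diffusion_config()].
#' @param scfg a [screen_config()].
#' @param weight_mode adjacency weighting for the Laplacian (see
#'   [build_laplacian()]).
#' @param lap optional prebuilt operator (reused across levels by
#'   [run_all_levels()]).
#' @return An object of class `level_result`: list with `level`, `latent`
#'   (character vector of screen survivors), `table` (the `screen_table`),
#'   `t` (chosen diffusion time), `converged`, and the config snapshot.
#' @export
run_level <- function(net, seeds, catalogs, ctx = NULL,
                      dcfg = diffusion_config(), scfg = screen_config(),
                      weight_mode = "scaled", lap = NULL) {
  if (is.null(lap)) lap <- build_laplacian(net, weight_mode)
  h0 <- initial_heat(net, seeds)
  st <- propagate_until_stable(lap, h0, dcfg)
  candidates <- select_candidates(st$heat, seeds, dcfg)
  tab <- run_screen(candidates, lap, net, seeds, catalogs, ctx, scfg, st$t)
  structure(list(level = seeds$level,
                 latent = sort(tab$gene[tab$latent]),
                 table = tab, t = st$t, converged = st$converged,
                 dcfg = dcfg, scfg = scfg,
                 weight_mode = lap$weight_mode),
            class = "level_result")
}

#' @export
print.level_result <- function(x, ...) {
  cn <- attr(x$table, "counts")
  cat(sprintf("<level_result> '%s': t = %.4g, %d -> %d -> %d -> %d latent\n",
              x$level, x$t, cn["raw"], cn["permutation"], cn["association"],
              cn["function"]))
  invisible(x)
}

#' Run all omics levels with common thresholds
#'
#' One Laplacian is built and shared; the same diffusion and screen
#' configuration applies to every level (common thresholds for all
#' measurements) unless per-level configs are supplied.
#'
#' @param net a [ppi_network()].
#' @param seed_sets list of [seed_set()] objects, one per level.
#' @inheritParams run_level
#' @return Named list of `level_result` objects (by level label).
#' @export
run_all_levels <- function(net, seed_sets, catalogs, ctx = NULL,
                           dcfg = diffusion_config(), scfg = screen_config(),
                           weight_mode = "scaled") {
  if (length(seed_sets) < 1L) stop_input("at least one seed set is required")
  lap <- build_laplacian(net, weight_mode)
  res <- lapply(seed_sets, function(s)
    run_level(net, s, catalogs, ctx, dcfg, scfg, lap = lap))
  names(res) <- vapply(res, `[[`, "", "level")
  res
}

#' Pairwise intersection of latent gene lists across levels
#'
#' @param results list of >= 2 `level_result` objects.
#' @return An object of class `intersection_result`: list with `pairs`
#'   (data.frame `level_a`, `level_b`, `n_shared`, one row per unordered
#'   pair — `choose(k, 2)` rows for `k` levels) and `genes` (named list of
#'   sorted shared gene vectors, keyed `"a|b"`).
#' @export
intersect_levels <- function(results) {
  if (length(results) < 2L)
    stop_input("intersection requires at least two levels")
  labels <- vapply(results, `[[`, "", "level")
  if (anyDuplicated(labels)) stop_input("duplicate level labels")
  pr <- utils::combn(length(results), 2L)
  genes <- list()
  pairs <- data.frame(level_a = character(0), level_b = character(0),
                      n_shared = integer(0))
  for (k in seq_len(ncol(pr))) {
    a <- pr[1L, k]; b <- pr[2L, k]
    shared <- sort(intersect(results[[a]]$latent, results[[b]]$latent))
    genes[[paste(labels[a], labels[b], sep = "|")]] <- shared
    pairs <- rbind(pairs, data.frame(level_a = labels[a], level_b = labels[b],
                                     n_shared = length(shared)))
  }
  structure(list(pairs = pairs, genes = genes), class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("<intersection_result> %d level pairs\n", nrow(x$pairs)))
  print(x$pairs)
  invisible(x)
}

#' Latent-vs-validated interaction-confidence summary
#'
#' For each latent gene, counts the validated (seed) genes adjacent to it
#' at each confidence bin: by default medium (>= 400), high (>= 700) and
#' highest (>= 900) confidence. Counts are non-increasing across stricter
#' bins.
#'
#' @param net a [ppi_network()].
#' @param latent character vector of latent gene identifiers.
#' @param seeds the level's validated-driver [seed_set()].
#' @param bins increasing confidence cutoffs (default `c(400, 700, 900)`).
#' @return data.frame with column `gene` plus one `n_ge_<bin>` count column
#'   per bin.
#' @export
interaction_confidence_summary <- function(net, latent, seeds,
                                           bins = c(400L, 700L, 900L)) {
  if (any(diff(bins) <= 0)) stop_input("bins must be strictly increasing")
  e <- net$edges
  ref_idx <- match(intersect(seeds$genes, net$nodes), net$nodes)
  out <- data.frame(gene = as.character(latent))
  counts <- matrix(0L, nrow = length(latent), ncol = length(bins))
  for (r in seq_along(latent)) {
    gi <- match(latent[r], net$nodes)
    if (is.na(gi)) stop_input("latent gene '%s' not in network", latent[r])
    hit <- e$i == gi | e$j == gi
    other <- ifelse(e$i[hit] == gi, e$j[hit], e$i[hit])
    conf <- e$confidence[hit][other %in% ref_idx]
    counts[r, ] <- vapply(bins, function(b) sum(conf >= b), integer(1))
  }
  colnames(counts) <- sprintf("n_ge_%d", bins)
  cbind(out, as.data.frame(counts))
}
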