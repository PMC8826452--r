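#' Specification for a planted-module benchmark fixture
#'
#' Describes a desk-scale random network with one or more dense "driver
#' neighborhood" modules planted in a sparse background, matching the
#' structure the diffusion screen assumes: cohesive modules wired with
#' high-confidence edges, background wired sparsely with low-confidence
#' edges, module-specific annotation terms, and per-level seed lists drawn
#' from modules. Everything is fully determined by `rng_seed`.
#'
#' @param n_nodes total node count (default 200).
#' @param modules list of module specs, each a list with `size`, `p_in`
#'   (within-module edge probability) and `conf_in` (integer confidence
#'   range `c(lo, hi)`). Default: one module of 20 nodes, `p_in = 0.7`,
#'   confidences 700–999.
#' @param p_out background edge probability (default 0.02).
#' @param conf_out background confidence range (default `c(150, 400)`).
#' @param seed_fraction default fraction of a module sampled as one level's
#'   seeds (default 0.5).
#' @param terms_per_module annotation terms dedicated to each module
#'   (default 3).
#' @param coverage fraction of a module's members carried by each of its
#'   terms (default 0.8).
#' @param background_terms number of unstructured terms (default 15).
#' @param background_term_size genes per background term (default 8).
#' @param rng_seed integer seed (default 1).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_nodes = 200L,
                         modules = list(list(size = 20L, p_in = 0.7,
                                             conf_in = c(700L, 999L))),
                         p_out = 0.02, conf_out = c(150L, 400L),
                         seed_fraction = 0.5,
                         terms_per_module = 3L, coverage = 0.8,
                         background_terms = 15L, background_term_size = 8L,
                         rng_seed = 1L) {
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  probs <- c(p_out, vapply(modules, `[[`, numeric(1), "p_in"))
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must be in [0, 1]")
  ranges <- c(list(conf_out), lapply(modules, `[[`, "conf_in"))
  for (rg in ranges)
    if (rg[1] < 1 || rg[2] > 999 || rg[1] > rg[2])
      stop_input("confidence ranges must lie within [1, 999]")
  if (sum(sizes) > n_nodes)
    stop_input("module sizes (%d) exceed n_nodes (%d)", sum(sizes), n_nodes)
  structure(list(n_nodes = as.integer(n_nodes), modules = modules,
                 p_out = p_out, conf_out = as.integer(conf_out),
                 seed_fraction = seed_fraction,
                 terms_per_module = as.integer(terms_per_module),
                 coverage = coverage,
                 background_terms = as.integer(background_terms),
                 background_term_size = as.integer(background_term_size),
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

#' Generate a network with planted dense modules
#'
#' Module `m` occupies a consecutive block of the (lexicographically
#' sorted) node list; within-module pairs receive an edge with probability
#' `p_in` and a confidence drawn uniformly from the module's high range,
#' all other pairs with probability `p_out` from the low background range.
#'
#' @param spec a [fixture_spec()].
#' @return List with `network` (a [ppi_network()]) and `membership`
#'   (integer vector named by node: module index, 0 for background).
#' @export
planted_module_graph <- function(spec) {
  n <- spec$n_nodes
  nodes <- sprintf("g%04d", seq_len(n))
  membership <- integer(n)
  names(membership) <- nodes
  at <- 1L
  for (m in seq_along(spec$modules)) {
    sz <- as.integer(spec$modules[[m]]$size)
    membership[at:(at + sz - 1L)] <- m
    at <- at + sz
  }
  pairs <- utils::combn(n, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  same <- membership[i] > 0L & membership[i] == membership[j]
  mod_of_pair <- ifelse(same, membership[i], 0L)
  p_edge <- ifelse(same,
                   vapply(spec$modules, `[[`, numeric(1), "p_in")[pmax(mod_of_pair, 1L)],
                   spec$p_out)
  local_seed(spec$rng_seed, {
    u <- runif(length(i))
    keep <- u < p_edge
    ki <- i[keep]; kj <- j[keep]; kmod <- mod_of_pair[keep]
    conf <- integer(length(ki))
    for (m in sort(unique(kmod))) {
      rg <- if (m == 0L) spec$conf_out else as.integer(spec$modules[[m]]$conf_in)
      sel <- kmod == m
      conf[sel] <- sample(seq.int(rg[1], rg[2]), sum(sel), replace = TRUE)
    }
    net <- ppi_network(nodes, data.frame(from = nodes[ki], to = nodes[kj],
                                         confidence = conf))
    list(network = net, membership = membership)
  })
}

#' Generate a module-consistent annotation catalog
#'
#' Each module receives `terms_per_module` dedicated terms, each covering a
#' `coverage` fraction of the module's members (sampled independently);
#' background terms draw members uniformly from all nodes. Deterministic
#' under the spec's `rng_seed` (offset so the draws are independent of the
#' graph's).
#'
#' @param membership module membership map from [planted_module_graph()].
#' @param spec a [fixture_spec()].
#' @return An [annotation_catalog()] labelled `"synthetic"`.
#' @export
synthetic_catalog <- function(membership, spec) {
  nodes <- names(membership)
  terms <- character(0)
  members <- list()
  local_seed(spec$rng_seed + 1009L, {
    for (m in seq_along(spec$modules)) {
      mod_nodes <- nodes[membership == m]
      k <- max(2L, round(spec$coverage * length(mod_nodes)))
      for (j in seq_len(spec$terms_per_module)) {
        terms <- c(terms, sprintf("MOD%d_T%d", m, j))
        members[[length(members) + 1L]] <- sort(sample(mod_nodes, k))
      }
    }
    for (j in seq_len(spec$background_terms)) {
      terms <- c(terms, sprintf("BG_T%d", j))
      members[[length(members) + 1L]] <-
        sort(sample(nodes, spec$background_term_size))
    }
  })
  annotation_catalog(terms, members, source = "synthetic")
}

#' Sample one omics level's seed genes from a module
#'
#' Stands in for a level's validated driver list: a `fraction` of the
#' designated module, sampled without replacement. Levels sharing a module
#' (with different `rng_seed`s) produce overlapping neighborhoods and hence
#' non-empty latent intersections downstream.
#'
#' @param membership module membership map from [planted_module_graph()].
#' @param level level label.
#' @param fraction fraction of the module to sample, in (0, 1].
#' @param module module index (default 1).
#' @param rng_seed integer seed for the draw.
#' @return A [seed_set()].
#' @export
make_level_seeds <- function(membership, level, fraction, module = 1L,
                             rng_seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop_input("seed fraction must be in (0, 1]")
  mod_nodes <- names(membership)[membership == module]
  if (length(mod_nodes) == 0L) stop_input("module %d has no members", module)
  k <- max(1L, round(fraction * length(mod_nodes)))
  local_seed(rng_seed, seed_set(sort(sample(mod_nodes, k)), level = level))
}

#' Generate a complete fixture bundle
#'
#' Network, membership map, annotation catalog, and one seed set per
#' requested level. Per-level seed draws use `rng_seed + level index` so
#' levels sharing a module sample different (overlapping) subsets.
#'
#' @param spec a [fixture_spec()].
#' @param levels named list mapping level label to module index, e.g.
#'   `list(epigenomics = 1, genomics = 1)`.
#' @return List with `network`, `membership`, `catalog`, `seeds` (named
#'   list of [seed_set()]), and `spec`.
#' @export
simulate_fixture <- function(spec = fixture_spec(),
                             levels = list(epigenomics = 1L, genomics = 1L)) {
  gm <- planted_module_graph(spec)
  catalog <- synthetic_catalog(gm$membership, spec)
  seeds <- lapply(seq_along(levels), function(k)
    make_level_seeds(gm$membership, names(levels)[k], spec$seed_fraction,
                     module = levels[[k]], rng_seed = spec$rng_seed + k))
  names(seeds) <- names(levels)
  list(network = gm$network, membership = gm$membership,
       catalog = catalog, seeds = seeds, spec = spec)
}
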