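#' Write a heat vector as TSV
#'
#' Two columns (`identifier`, `heat`) preceded by a `#`-comment header
#' recording the diffusion time, weight mode and a hash of the seed list,
#' so runs are attributable. Output is byte-deterministic for identical
#' inputs.
#'
#' @param heat a [heat_vector()].
#' @param path output path.
#' @param weight_mode adjacency weighting used for the run.
#' @param seeds optional [seed_set()]; hashed into the header.
#' @export
write_heat_tsv <- function(heat, path, weight_mode = "scaled", seeds = NULL) {
  seed_hash <- if (is.null(seeds)) "NA" else content_hash(sort(seeds$genes))
  header <- sprintf("# t=%.10g\tweight_mode=%s\tseed_hash=%s",
                    heat$t, weight_mode, seed_hash)
  body <- sprintf("%s\t%.10e", names(heat$values), heat$values)
  writeLines(c(header, "identifier\theat", body), path)
  invisible(path)
}

#' Write a screen table as TSV
#'
#' Columns: gene, heat, p_value, mas, mfs, stage_reached.
#'
#' @param tab a `screen_table` from [run_screen()].
#' @param path output path.
#' @export
write_screen_table <- function(tab, path) {
  out <- data.frame(gene = tab$gene,
                    heat = sprintf("%.10e", tab$heat),
                    p_value = sprintf("%.6g", tab$p_value),
                    mas = ifelse(is.na(tab$mas), "NA", as.character(tab$mas)),
                    mfs = ifelse(is.na(tab$mfs), "NA",
                                 sprintf("%.6g", tab$mfs)),
                    stage_reached = tab$stage_reached)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write Table-1-style staged survivor counts as TSV
#'
#' One row per level with the survivor count after the diffusion heat
#' threshold and after each screen stage.
#'
#' @param results named list of `level_result` objects.
#' @param path output path.
#' @export
write_counts_tsv <- function(results, path) {
  rows <- lapply(results, function(r) {
    cn <- attr(r$table, "counts")
    data.frame(level = r$level, lhd_algorithm = cn[["raw"]],
               permutation_test = cn[["permutation"]],
               association_test = cn[["association"]],
               function_test = cn[["function"]])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write pairwise intersections as TSV
#'
#' One row per shared gene: `level_a`, `level_b`, `gene`; pairs with no
#' shared genes contribute no rows.
#'
#' @param ir an `intersection_result` from [intersect_levels()].
#' @param path output path.
#' @export
write_intersection_tsv <- function(ir, path) {
  lines <- "level_a\tlevel_b\tgene"
  for (k in seq_len(nrow(ir$pairs))) {
    g <- ir$genes[[paste(ir$pairs$level_a[k], ir$pairs$level_b[k], sep = "|")]]
    if (length(g) > 0L)
      lines <- c(lines, sprintf("%s\t%s\t%s", ir$pairs$level_a[k],
                                ir$pairs$level_b[k], g))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records every cutoff, the RNG seed, the chosen diffusion time per level
#' and content hashes of the inputs, so a run can be audited and repeated.
#' Contains nothing time- or host-dependent: identical runs produce
#' byte-identical manifests.
#'
#' @param results named list of `level_result` objects.
#' @param net the [ppi_network()] used.
#' @param path output path.
#' @export
write_run_manifest <- function(results, net, path) {
  r1 <- results[[1L]]
  manifest <- list(
    network = list(nodes = length(net$nodes), edges = nrow(net$edges),
                   hash = content_hash(c(net$nodes,
                                         sprintf("%d %d %d", net$edges$i,
                                                 net$edges$j,
                                                 net$edges$confidence)))),
    diffusion = list(stability_tol = r1$dcfg$stability_tol,
                     heat_threshold = r1$dcfg$heat_threshold,
                     exclude_seeds = r1$dcfg$exclude_seeds),
    screen = list(n_permutations = r1$scfg$n_permutations,
                  p_cutoff = r1$scfg$p_cutoff,
                  mas_cutoff = r1$scfg$mas_cutoff,
                  mfs_cutoff = r1$scfg$mfs_cutoff,
                  rng_seed = r1$scfg$rng_seed),
    weight_mode = r1$weight_mode,
    levels = lapply(results, function(r)
      list(level = r$level, t = r$t, converged = r$converged,
           n_latent = length(r$latent))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write a one-identifier-per-line seed list
#'
#' @param path file path.
#' @param level level label for the resulting [seed_set()].
#' @return [seed_set()] for the reader.
#' @export
read_seed_list <- function(path, level = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  seed_set(lines[nzchar(lines)], level = level)
}

#' @rdname read_seed_list
#' @param seeds a [seed_set()] to write.
#' @export
write_seed_list <- function(seeds, path) {
  writeLines(seeds$genes, path)
  invisible(path)
}
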