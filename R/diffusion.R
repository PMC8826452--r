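#' Seed gene set for one omics level
#'
#' @param genes character vector of node identifiers (deduplicated).
#' @param level label for the omics level (e.g. `"epigenomics"`,
#'   `"genomics"`, `"transcriptomics"`, `"post-transcriptomics"`).
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(genes, level = "level1") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop_input("seed set '%s' is empty", level)
  structure(list(level = as.character(level), genes = genes),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> level '%s': %d genes\n", x$level, length(x$genes)))
  invisible(x)
}

#' Node-aligned heat vector
#'
#' @param values numeric vector of nonnegative heat values, named by node.
#' @param t elapsed diffusion time (dimensionless).
#' @return An object of class `heat_vector` with elements `values` and `t`.
#' @export
heat_vector <- function(values, t = 0) {
  if (t < 0) stop_input("diffusion time must be nonnegative")
  if (any(values < -1e-12)) stop_input("heat values must be nonnegative")
  structure(list(values = values, t = as.numeric(t)), class = "heat_vector")
}

#' @export
print.heat_vector <- function(x, ...) {
  cat(sprintf("<heat_vector> n = %d, t = %.4g, total = %.6g, max = %.4g\n",
              length(x$values), x$t, sum(x$values), max(x$values)))
  invisible(x)
}

#' Diffusion configuration
#'
#' The stopping rule walks a geometric time schedule `t_k = t0 * 2^k` and
#' stops at the first `t_k` whose heat vector is within `stability_tol` (L1
#' norm) of the previous one.
#'
#' @param t0 first diffusion time of the schedule (default 0.1).
#' @param n_steps number of schedule steps (default 30).
#' @param t_schedule strictly increasing time sequence; overrides
#'   `t0`/`n_steps` when given.
#' @param stability_tol L1 tolerance declaring two consecutive heat vectors
#'   "close enough" (default 1e-6).
#' @param heat_threshold minimum heat for a node to become a raw candidate
#'   (default 1e-5).
#' @param exclude_seeds drop seed nodes from the candidate list
#'   (default TRUE; the goal is novel genes).
#' @return An object of class `diffusion_config`.
#' @export
diffusion_config <- function(t0 = 0.1, n_steps = 30L,
                             t_schedule = t0 * 2^(seq_len(n_steps) - 1L),
                             stability_tol = 1e-6, heat_threshold = 1e-5,
                             exclude_seeds = TRUE) {
  if (length(t_schedule) == 0L) stop_input("t_schedule must be non-empty")
  if (any(diff(t_schedule) <= 0) || any(t_schedule <= 0))
    stop_input("t_schedule must be positive and strictly increasing")
  if (stability_tol < 0 || heat_threshold < 0)
    stop_input("tolerances must be nonnegative")
  structure(list(t_schedule = t_schedule, stability_tol = stability_tol,
                 heat_threshold = heat_threshold,
                 exclude_seeds = isTRUE(exclude_seeds)),
            class = "diffusion_config")
}

#' Initial heat distribution over seed nodes
#'
#' Seeds present in the network each receive `1 / |S|` where `S` is the set
#' of present seeds; all other nodes get zero. Seeds missing from the
#' network are dropped with a warning (real gene lists always have mapping
#' dropouts); it is an error if none remain.
#'
#' @param net a [ppi_network()].
#' @param seeds a [seed_set()].
#' @return A [heat_vector()] at `t = 0` summing to 1.
#' @export
initial_heat <- function(net, seeds) {
  present <- intersect(seeds$genes, net$nodes)
  missing <- setdiff(seeds$genes, net$nodes)
  if (length(present) == 0L)
    stop_input("no seed of level '%s' is in the network (missing: %s)",
               seeds$level, paste(missing, collapse = ", "))
  if (length(missing) > 0L)
    warning(sprintf("%d seed(s) not in network, renormalizing over %d: %s",
                    length(missing), length(present),
                    paste(missing, collapse = ", ")), call. = FALSE)
  v <- numeric(length(net$nodes))
  names(v) <- net$nodes
  v[present] <- 1 / length(present)
  heat_vector(v, t = 0)
}

# action of exp(-L t) on a vector by uniformization: with rate
# lambda = max_i L_ii, P = I - L/lambda is substochastic-free (nonnegative,
# unit column sums), and exp(-Lt) v = sum_k dpois(k; lambda t) P^k v.
# Every term is nonnegative and mass-preserving, so conservation and
# nonnegativity hold to machine precision; the Poisson series is summed in
# substeps with lambda*dt <= 100 to avoid weight underflow.
expm_action <- function(L, lambda, v, t, mu_max = 100) {
  if (t == 0 || lambda == 0) return(v)
  nsub <- ceiling(lambda * t / mu_max)
  dt <- t / nsub
  mu <- lambda * dt
  kmax <- ceiling(mu + 12 * sqrt(mu) + 30)
  for (s in seq_len(nsub)) {
    w <- v
    coef <- exp(-mu)
    acc <- coef * v
    cum <- coef
    k <- 0L
    while (cum < 1 - 1e-16 && k < kmax) {
      k <- k + 1L
      w <- w - as.numeric(L %*% w) / lambda
      coef <- coef * mu / k
      acc <- acc + coef * w
      cum <- cum + coef
    }
    v <- acc / cum  # renormalize the truncated Poisson weights
  }
  v
}

#' Propagate heat for a time interval
#'
#' Computes \eqn{H(t_0 + t) = H(t_0) e^{-Lt}} (the Laplacian is symmetric,
#' so row- and column-vector conventions coincide). Total heat is conserved
#' and entries stay nonnegative. The elapsed time accumulates on the
#' returned vector, so `propagate(lap, propagate(lap, h, t1), t2)` equals
#' `propagate(lap, h, t1 + t2)` (semigroup property).
#'
#' @param lap an [build_laplacian()] operator.
#' @param h a [heat_vector()] (or bare named numeric vector, taken at t = 0).
#' @param t nonnegative time increment.
#' @return A [heat_vector()] at time `h$t + t`.
#' @export
propagate <- function(lap, h, t) {
  if (!inherits(h, "heat_vector")) h <- heat_vector(h, t = 0)
  if (t < 0) stop_input("diffusion time increment must be nonnegative")
  if (length(h$values) != lap$n)
    stop_input("heat vector length %d does not match operator dimension %d",
               length(h$values), lap$n)
  bump_counter("propagations")
  out <- expm_action(lap$L, lap$lambda, as.numeric(h$values), t)
  names(out) <- lap$nodes
  heat_vector(out, t = h$t + t)
}

# per-component uniform limit of a heat vector: component mass spread
# evenly over the component's nodes
uniform_limit <- function(h, components) {
  mass <- tapply(h$values, components, sum)
  size <- tapply(rep(1, length(components)), components, sum)
  as.numeric((mass / size)[as.character(components)])
}

#' Run diffusion until the heat distribution stabilizes
#'
#' Walks the geometric time schedule (incrementally, via the semigroup
#' property) and stops at the first `t_k` with
#' \eqn{\lVert H(t_k) - H(t_{k-1}) \rVert_1 <} `stability_tol`. If the
#' stabilized vector is also within tolerance of the per-component uniform
#' distribution, a warning is raised: on a connected graph the exact
#' \eqn{t \to \infty} limit is uniform and carries no seed information.
#'
#' @param lap an [build_laplacian()] operator.
#' @param h0 initial [heat_vector()] (see [initial_heat()]).
#' @param cfg a [diffusion_config()].
#' @return List with `heat` (the stabilized [heat_vector()]), `t` (the
#'   chosen schedule time), and `converged` (logical; FALSE when the
#'   schedule was exhausted without meeting the tolerance).
#' @export
propagate_until_stable <- function(lap, h0, cfg = diffusion_config()) {
  if (!inherits(h0, "heat_vector")) h0 <- heat_vector(h0, t = 0)
  sched <- cfg$t_schedule
  prev_vals <- h0$values
  cur <- h0
  converged <- FALSE
  chosen_t <- sched[length(sched)]
  last_t <- 0
  for (tk in sched) {
    cur <- propagate(lap, cur, tk - last_t)
    last_t <- tk
    if (sum(abs(cur$values - prev_vals)) < cfg$stability_tol) {
      converged <- TRUE
      chosen_t <- tk
      break
    }
    prev_vals <- cur$values
  }
  unif <- uniform_limit(cur, lap$components)
  if (sum(abs(cur$values - unif)) < cfg$stability_tol)
    warning(paste("stabilized heat is within tolerance of the per-component",
                  "uniform distribution: diffusion has washed out seed",
                  "information"), call. = FALSE)
  list(heat = cur, t = chosen_t, converged = converged)
}

#' Select raw candidates by heat threshold
#'
#' @param heat a [heat_vector()].
#' @param seeds optional [seed_set()] to exclude (when
#'   `cfg$exclude_seeds`).
#' @param cfg a [diffusion_config()]; uses `heat_threshold` and
#'   `exclude_seeds`.
#' @return data.frame with columns `gene`, `heat`, sorted by heat
#'   descending then identifier ascending (deterministic tie-break).
#' @export
select_candidates <- function(heat, seeds = NULL, cfg = diffusion_config()) {
  v <- heat$values
  keep <- v >= cfg$heat_threshold
  if (cfg$exclude_seeds && !is.null(seeds))
    keep <- keep & !(names(v) %in% seeds$genes)
  out <- data.frame(gene = names(v)[keep], heat = as.numeric(v[keep]))
  out <- out[order(-out$heat, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no candidate reached the heat threshold", call. = FALSE)
  out
}
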