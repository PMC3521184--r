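#' Uniform sampling of the feasible flux space (ACHR)
#'
#' Artificial-centered hit-and-run sampling of the steady-state flux
#' polytope \eqn{\{v : Sv = 0,\ l \le v \le u\}}. Bounds are first
#' tightened to the effective constraints by flux variability analysis;
#' the FVA optima double as warm-up vertices, and the warm-up set is
#' filled to `n_warmup` points with random convex combinations of them.
#' The chain then repeatedly draws a direction through the running center
#' (stored point minus center), computes the admissible segment in both
#' senses from the bounds, and jumps to a uniform point on it. The
#' direction set lies in the null space of S, so every iterate satisfies
#' mass balance; accumulated round-off is removed by periodic orthogonal
#' re-projection onto the null space.
#'
#' @param model A feasible `stoich_model`.
#' @param n_warmup Number of warm-up points (default 5000).
#' @param n_points Number of points returned for analysis (default 2000).
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @param thin Chain steps between retained points.
#' @param burn Discarded initial chain steps.
#' @return A `sample_ensemble`: list with `points`
#'   (`n_points` x n_reactions matrix), `seed`, `n_warmup`, `n_points`,
#'   `model_label`, and `degenerate` (TRUE when the feasible space is a
#'   single point, which is then replicated with a warning).
#' @export
achr_sample <- function(model, n_warmup = 5000, n_points = 2000, seed = 1,
                        thin = 5, burn = 200) {
  stopifnot(n_points > 1, n_warmup >= 2)
  S <- stoich_matrix(model)
  n <- ncol(S)
  fr_pts <- fva_vertices(model)
  if (fr_pts$status != "optimal") stop("model is ", fr_pts$status)
  lb <- fr_pts$min_flux
  ub <- fr_pts$max_flux
  rids <- colnames(S)
  if (max(ub - lb) < 1e-9) {
    warning("feasible space is a single point; replicating it")
    pts <- matrix(rep((lb + ub) / 2, each = n_points), nrow = n_points,
                  dimnames = list(NULL, rids))
    return(structure(list(points = pts, seed = seed, n_warmup = n_warmup,
                          n_points = n_points, model_label = model$model_label,
                          degenerate = TRUE), class = "sample_ensemble"))
  }
  # orthonormal null-space basis of S for drift re-projection
  dec <- svd(S, nu = 0, nv = n)
  rank <- sum(dec$d > max(dim(S)) * max(dec$d, 0) * 1e-12)
  Nb <- dec$v[, seq(rank + 1, n), drop = FALSE]

  withr::local_seed(seed)
  W <- fr_pts$vertices                      # 2n x n matrix of FVA vertices
  extra <- n_warmup - nrow(W)
  if (extra > 0) {
    k <- nrow(W)
    wts <- matrix(stats::rexp(extra * k), extra, k)
    wts <- wts / rowSums(wts)
    W <- rbind(W, wts %*% W)
  } else {
    W <- W[seq_len(n_warmup), , drop = FALSE]
  }
  center <- colMeans(W)
  x <- W[1, ]
  pts <- matrix(0, n_points, n, dimnames = list(NULL, rids))
  kept <- 0L
  step <- 0L
  n_steps <- burn + thin * n_points
  tol <- 1e-10
  while (kept < n_points) {
    step <- step + 1L
    u <- W[sample.int(nrow(W), 1L), ] - center
    # keep the direction exactly inside the null space of S; the running
    # center accumulates round-off that would otherwise feed back and grow
    u <- as.vector(Nb %*% crossprod(Nb, u))
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) next
    u <- u / nu
    # admissible alpha range from the bounds
    amin <- -Inf; amax <- Inf
    pos <- u > tol
    negd <- u < -tol
    if (any(pos)) {
      amax <- min(amax, min((ub[pos] - x[pos]) / u[pos]))
      amin <- max(amin, max((lb[pos] - x[pos]) / u[pos]))
    }
    if (any(negd)) {
      amax <- min(amax, min((lb[negd] - x[negd]) / u[negd]))
      amin <- max(amin, max((ub[negd] - x[negd]) / u[negd]))
    }
    if (!is.finite(amin) || !is.finite(amax) || amax - amin < 1e-12) next
    alpha <- stats::runif(1, amin, amax)
    x <- x + alpha * u
    if (step %% 50L == 0L) {
      x <- as.vector(Nb %*% crossprod(Nb, x))   # re-project onto Sv = 0
      x <- pmin(pmax(x, lb), ub)
    }
    center <- center + (x - center) / (nrow(W) + step)
    if (step > burn && (step - burn) %% thin == 0L) {
      kept <- kept + 1L
      pts[kept, ] <- x
    }
  }
  structure(list(points = pts, seed = seed, n_warmup = n_warmup,
                 n_points = n_points, model_label = model$model_label,
                 degenerate = FALSE), class = "sample_ensemble")
}

# FVA that also returns the optimizing flux vectors (warm-up vertices)
fva_vertices <- function(model) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  verts <- matrix(0, 2 * n, n)
  mins <- maxs <- numeric(n)
  for (j in seq_len(n)) {
    ej <- numeric(n); ej[j] <- 1
    lo <- solve_lp(S, ej, lb, ub, maximize = FALSE)
    hi <- solve_lp(S, ej, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      return(list(status = lo$status))
    }
    mins[j] <- lo$value; maxs[j] <- hi$value
    verts[2 * j - 1, ] <- lo$fluxes
    verts[2 * j, ] <- hi$fluxes
  }
  list(status = "optimal", min_flux = pmin(mins, maxs),
       max_flux = pmax(mins, maxs), vertices = verts)
}

#' @export
print.sample_ensemble <- function(x, ...) {
  cat(sprintf("<sample_ensemble '%s'>  %d points x %d reactions (warmup %d, seed %d%s)\n",
              x$model_label, nrow(x$points), ncol(x$points), x$n_warmup,
              x$seed, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
tidy.sample_ensemble <- function(x, ...) {
  tibble::as_tibble(x$points) |>
    dplyr::mutate(point = dplyr::row_number()) |>
    tidyr::pivot_longer(-"point", names_to = "reaction_id", values_to = "flux")
}

#' Correlated reaction sets from a sample ensemble
#'
#' Reactions whose sampled fluxes are (near-)perfectly linearly correlated
#' are co-utilized in fixed stoichiometric ratios; grouping them partitions
#' the network into coupled modules. Absolute Pearson correlation is used
#' (anticorrelation is coupling with a negative ratio, since reversibility
#' conventions fix signs arbitrarily), and the partition is the connected-
#' component closure of the \eqn{|\rho| \ge} `threshold` relation.
#' Zero-variance reactions (blocked or fixed fluxes) are excluded into a
#' reported invariant pool.
#'
#' @param ensemble A `sample_ensemble` with at least 2 points.
#' @param threshold Absolute-correlation threshold in (0, 1]; the default
#'   `1 - 1e-8` detects exact stoichiometric coupling.
#' @return A `correlated_sets` object: list with `sets` (tibble: `set_id`,
#'   `reaction_id`, `representative_id`, `min_abs_correlation`) and
#'   `invariant` (character vector of zero-variance reaction ids).
#' @export
correlated_sets <- function(ensemble, threshold = 1 - 1e-8) {
  stopifnot(inherits(ensemble, "sample_ensemble"),
            threshold > 0, threshold <= 1)
  P <- ensemble$points
  if (nrow(P) < 2) stop("need at least 2 sample points")
  sdv <- apply(P, 2, stats::sd)
  invariant <- colnames(P)[sdv <= 1e-9 * max(1, max(abs(P)))]
  keep <- setdiff(colnames(P), invariant)
  sets <- tibble::tibble(set_id = integer(), reaction_id = character(),
                         representative_id = character(),
                         min_abs_correlation = numeric())
  if (length(keep) >= 2) {
    C <- abs(stats::cor(P[, keep, drop = FALSE]))
    adj <- C >= threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    grp <- split(keep, comp$membership)
    grp <- grp[vapply(grp, length, integer(1)) >= 2]
    if (length(grp)) {
      grp <- grp[order(vapply(grp, length, integer(1)), decreasing = TRUE)]
      sets <- dplyr::bind_rows(purrr::imap(grp, function(members, i) {
        members <- sort(members)
        sub <- C[members, members, drop = FALSE]
        tibble::tibble(set_id = as.integer(i), reaction_id = members,
                       representative_id = members[1],
                       min_abs_correlation = min(sub))
      }))
    }
  }
  structure(list(sets = sets, invariant = invariant,
                 threshold = threshold, model_label = ensemble$model_label),
            class = "correlated_sets")
}

#' @export
print.correlated_sets <- function(x, ...) {
  ns <- if (nrow(x$sets)) max(x$sets$set_id) else 0L
  cat(sprintf("<correlated_sets '%s'>  %d set(s), %d coupled reaction(s), %d invariant\n",
              x$model_label, ns, nrow(x$sets), length(x$invariant)))
  invisible(x)
}

#' @export
tidy.correlated_sets <- function(x, ...) x$sets

#' @export
glance.correlated_sets <- function(x, ...) {
  tibble::tibble(model_label = x$model_label,
                 n_sets = if (nrow(x$sets)) max(x$sets$set_id) else 0L,
                 n_coupled = nrow(x$sets),
                 largest_set = if (nrow(x$sets)) max(table(x$sets$set_id)) else 0L,
                 n_invariant = length(x$invariant),
                 threshold = x$threshold)
}
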