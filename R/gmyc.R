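# Single-threshold generalized mixed Yule-coalescent model.
#
# Interval bookkeeping: internal-node heights t_1 > ... > t_{n-1} (root
# first); inter-event intervals i = 1..n-2 with duration x_i = t_i - t_{i+1}.
# The root event is conditioned on, so the first interval starts at the
# root's first descendant slab and there are n-2 event terms. During an
# interval, k = number of branches crossing the threshold T ("species"
# lineages; all branches when the interval lies above T, zero when T is at
# or above the root) and n_j = branch count of coalescent cluster j (the
# subtree hanging from each T-crossing branch). The total branching rate is
#   b = lambda_S * k^p_S + lambda_C * sum_j [n_j (n_j - 1)]^p_C
# and logL = sum_i (ln b_i - b_i x_i), the event term taken from the slab
# directly above each event. Zero-length slabs (simultaneous nodes)
# contribute the event term only.

# elementary slabs between consecutive distinct breakpoints (node heights
# and T), with per-slab duration x, species-lineage count k, cluster branch
# counts ns, and the event heights whose term uses this slab
.gmyc_slabs <- function(tree, T) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  node_h <- h[(n + 1L):(n + tree$Nnode)]
  root_h <- max(node_h)
  # all internal heights, descending; drop the single root entry
  all_h <- sort(node_h, decreasing = TRUE)
  events <- all_h[-1L]                       # n-2 event heights (may tie)
  breaks <- sort(unique(c(all_h, if (T > min(all_h) && T < root_h) T)),
                 decreasing = TRUE)
  if (T >= root_h) {
    # no branch crosses T: the whole tree is a single coalescent cluster
    k_below <- 0L
    cluster_of <- rep(1L, n + tree$Nnode)
  } else {
    k_below <- entities_at_threshold(tree, T)$n_entities
    cluster_of <- if (T > 0) {
      .propagate_entities(tree, .crossing_edges(tree, h, T))
    } else NULL                              # T <= 0: every slab lies above T
  }
  child <- tree$edge[, 2L]
  parent <- tree$edge[, 1L]
  slabs <- vector("list", length(breaks) - 1L)
  for (i in seq_len(length(breaks) - 1L)) {
    hi <- breaks[i]
    lo <- breaks[i + 1L]
    mid <- (hi + lo) / 2
    cross <- which(h[child] < mid & h[parent] > mid)
    if (mid >= T) {
      k <- length(cross)
      ns <- integer(0)
    } else {
      k <- k_below
      ns <- as.integer(table(cluster_of[child[cross]]))
    }
    slabs[[i]] <- list(x = hi - lo, k = k, ns = ns, lower = lo)
  }
  list(slabs = slabs, events = events, root_h = root_h)
}

# per-slab Yule and coalescent rate factors for given exponents
.slab_AB <- function(slabs, p_S, p_C) {
  A <- vapply(slabs, function(s) if (s$k > 0L) s$k^p_S else 0, numeric(1L))
  B <- vapply(slabs, function(s) {
    if (length(s$ns) == 0L) return(0)
    pairs <- s$ns * (s$ns - 1)
    sum(ifelse(pairs > 0, pairs^p_C, 0))
  }, numeric(1L))
  list(A = A, B = B)
}

# map each event height to the slab whose lower bound equals it
.event_slab_index <- function(slabs, events) {
  lowers <- vapply(slabs, `[[`, numeric(1L), "lower")
  idx <- match(round(events, 12L), round(lowers, 12L))
  stopifnot(!anyNA(idx))
  idx
}

.MIN_LOGLIK <- -1e100

#' Log-likelihood of the single-threshold GMYC model
#'
#' Mixed branching-process likelihood on an ultrametric tree: lineages older
#' than the threshold `T` branch under a generalized Yule process with rate
#' `lambda_S * k^p_S`, lineages younger than `T` coalesce within the
#' clusters defined by the branches crossing `T`, at rate
#' `lambda_C * sum_j [n_j (n_j - 1)]^p_C`. At `p_S = p_C = 1` these reduce
#' to the constant-rate Yule process and the neutral coalescent. With `T`
#' at or above the root the model collapses to the one-process null of
#' [gmyc_null_loglik()].
#'
#' @param tree Ultrametric `phylo` with at least 3 tips.
#' @param T Threshold height, >= 0.
#' @param lambda_S,lambda_C Branching parameters (events/time), > 0.
#' @param p_S,p_C Scaling exponents in `[0, 2]`. Default 1 (pure
#'   Yule/coalescent behavior).
#' @return Log-likelihood (finite, or a flagged minimal value when an event
#'   falls in a slab of zero total rate).
#' @export
gmyc_loglik <- function(tree, T, lambda_S, lambda_C, p_S = 1, p_C = 1) {
  stopifnot(lambda_S > 0, lambda_C > 0, p_S >= 0, p_S <= 2, p_C >= 0, p_C <= 2)
  if (ape::Ntip(tree) < 3L) .stop_input("GMYC needs at least 3 tips")
  st <- .gmyc_slabs(tree, T)
  ab <- .slab_AB(st$slabs, p_S, p_C)
  x <- vapply(st$slabs, `[[`, numeric(1L), "x")
  b <- lambda_S * ab$A + lambda_C * ab$B
  ev <- .event_slab_index(st$slabs, st$events)
  if (any(b[ev] <= 0)) return(.MIN_LOGLIK)
  sum(log(b[ev])) - sum(b * x)
}

#' Log-likelihood of the GMYC null model
#'
#' One branching process over the whole tree with rate
#' `lambda0 * [N (N - 1)]^p0`, `N` the number of lineages in each
#' inter-event interval. This is the model the threshold alternative nests
#' into (it equals [gmyc_loglik()] with `T` at or above the root).
#'
#' @param tree Ultrametric `phylo` with at least 3 tips.
#' @param lambda0 Branching parameter, > 0.
#' @param p0 Scaling exponent in `[0, 2]`.
#' @return Log-likelihood.
#' @export
gmyc_null_loglik <- function(tree, lambda0, p0 = 1) {
  stopifnot(lambda0 > 0, p0 >= 0, p0 <= 2)
  if (ape::Ntip(tree) < 3L) .stop_input("GMYC needs at least 3 tips")
  st <- .gmyc_slabs(tree, max(node_heights(tree)) * 2 + 1)
  x <- vapply(st$slabs, `[[`, numeric(1L), "x")
  C <- vapply(st$slabs, function(s) {
    pairs <- sum(s$ns) * (sum(s$ns) - 1)
    if (pairs > 0) pairs^p0 else 0
  }, numeric(1L))
  b <- lambda0 * C
  ev <- .event_slab_index(st$slabs, st$events)
  if (any(b[ev] <= 0)) return(.MIN_LOGLIK)
  sum(log(b[ev])) - sum(b * x)
}

# maximize sum_e log(lS*A_e + lC*B_e) - lS*SA - lC*SB over positive lambdas
.fit_lambdas <- function(Ae, Be, SA, SB) {
  m <- length(Ae)
  pureS <- all(Be == 0) && SB == 0
  pureC <- all(Ae == 0) && SA == 0
  if (pureS) {
    lS <- m / SA
    return(list(lambda_S = lS, lambda_C = NA_real_,
                logL = m * log(lS) + sum(log(Ae)) - m))
  }
  if (pureC) {
    lC <- m / SB
    return(list(lambda_S = NA_real_, lambda_C = lC,
                logL = m * log(lC) + sum(log(Be)) - m))
  }
  nll <- function(par) {
    lS <- exp(par[1L]); lC <- exp(par[2L])
    b <- lS * Ae + lC * Be
    if (any(b <= 0)) return(1e100)
    -(sum(log(b)) - lS * SA - lC * SB)
  }
  init <- log(c(max(m / (SA + SB), 1e-8), max(m / (SA + SB), 1e-8)))
  fit <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(-34, -34), upper = c(34, 34),
                      control = list(maxit = 500L))
  if (fit$convergence != 0L) {
    # retry from event-count-based starts before giving up
    alt <- stats::optim(init + c(2, -2), nll, method = "Nelder-Mead",
                        control = list(maxit = 2000L))
    if (alt$value < fit$value) fit <- alt
  }
  list(lambda_S = exp(fit$par[1L]), lambda_C = exp(fit$par[2L]),
       logL = -fit$value)
}

# profile logL at one threshold; optionally optimize exponents
.gmyc_profile_T <- function(tree, T, estimate_p) {
  st <- .gmyc_slabs(tree, T)
  x <- vapply(st$slabs, `[[`, numeric(1L), "x")
  ev <- .event_slab_index(st$slabs, st$events)
  eval_p <- function(p_S, p_C) {
    ab <- .slab_AB(st$slabs, p_S, p_C)
    .fit_lambdas(ab$A[ev], ab$B[ev], sum(ab$A * x), sum(ab$B * x))
  }
  if (!estimate_p) {
    res <- eval_p(1, 1)
    return(c(res, list(p_S = 1, p_C = 1)))
  }
  obj <- function(p) -eval_p(p[1L], p[2L])$logL
  fit <- stats::optim(c(1, 1), obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(2, 2))
  res <- eval_p(fit$par[1L], fit$par[2L])
  c(res, list(p_S = fit$par[1L], p_C = fit$par[2L]))
}

#' Fit the single-threshold GMYC model
#'
#' Scans candidate thresholds at the midpoints between consecutive distinct
#' node heights (tips included, so one candidate lies below every internal
#' node) plus one candidate above the root (the null boundary); the
#' likelihood is piecewise in `T` between node heights, so this scan is
#' exhaustive. At each candidate the branching parameters (and optionally
#' the scaling exponents) are maximized numerically; the null model is
#' maximized separately and compared by a likelihood-ratio test.
#'
#' @param tree Ultrametric `phylo`. At least 4 tips recommended (a warning
#'   is issued below that).
#' @param estimate_p Also estimate the scaling exponents `p_S`, `p_C`
#'   (and `p0` for the null) in `[0, 2]`? Default `FALSE`: exponents fixed
#'   at 1, the stable choice for trees of modest size.
#' @param df Degrees of freedom of the chi-square likelihood-ratio test.
#'   Default 3 (threshold plus two branching parameters against one).
#' @return A `gmyc_fit` object: threshold `T_hat`, parameters, `logL_alt`,
#'   `logL_null`, `LR`, `p_value`, `n_entities`, `n_clusters`,
#'   `n_singletons`, `cluster_map`, and the threshold `scan` table.
#' @export
gmyc_fit <- function(tree, estimate_p = FALSE, df = 3) {
  tree <- as_ultrametric(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) .stop_input("GMYC needs at least 3 tips")
  if (n < 4L) warning("GMYC fit on fewer than 4 tips is poorly informed")
  h <- node_heights(tree)
  node_h <- sort(unique(h[(n + 1L):(n + tree$Nnode)]))
  root_h <- max(node_h)
  grid <- sort(unique(c(0, node_h)))
  cand <- (grid[-1L] + grid[-length(grid)]) / 2    # midpoints, incl. below all nodes
  cand <- c(cand, root_h * 1.5 + 1)                # null boundary, above the root
  # null model
  null_fit <- if (estimate_p) {
    op <- stats::optimize(function(p0) -gmyc_null_p_profile(tree, p0),
                          c(0, 2), maximum = FALSE)
    list(p0 = op$minimum, logL = -op$objective)
  } else {
    list(p0 = 1, logL = gmyc_null_p_profile(tree, 1))
  }
  scan <- lapply(cand, function(T) {
    pr <- .gmyc_profile_T(tree, T, estimate_p)
    data.frame(T = T, logL = pr$logL, lambda_S = pr$lambda_S,
               lambda_C = pr$lambda_C, p_S = pr$p_S, p_C = pr$p_C)
  })
  scan <- do.call(rbind, scan)
  best <- which.max(scan$logL)
  logL_alt <- max(scan$logL, null_fit$logL)   # alt nests the null
  LR <- max(0, 2 * (logL_alt - null_fit$logL))
  ent <- entities_at_threshold(tree, scan$T[best])
  structure(list(T_hat = scan$T[best],
                 lambda_S = scan$lambda_S[best],
                 lambda_C = scan$lambda_C[best],
                 p_S = scan$p_S[best], p_C = scan$p_C[best],
                 lambda0 = NA_real_, p0 = null_fit$p0,
                 logL_alt = logL_alt, logL_null = null_fit$logL,
                 LR = LR, df = df,
                 p_value = stats::pchisq(LR, df, lower.tail = FALSE),
                 n_entities = ent$n_entities,
                 n_clusters = ent$n_clusters,
                 n_singletons = ent$n_singletons,
                 cluster_map = ent$cluster_map,
                 scan = scan),
            class = "gmyc_fit")
}

# profile null log-likelihood over lambda0 (closed form) at fixed p0
gmyc_null_p_profile <- function(tree, p0) {
  st <- .gmyc_slabs(tree, max(node_heights(tree)) * 2 + 1)
  x <- vapply(st$slabs, `[[`, numeric(1L), "x")
  C <- vapply(st$slabs, function(s) {
    pairs <- sum(s$ns) * (sum(s$ns) - 1)
    if (pairs > 0) pairs^p0 else 0
  }, numeric(1L))
  ev <- .event_slab_index(st$slabs, st$events)
  m <- length(ev)
  if (any(C[ev] <= 0)) return(.MIN_LOGLIK)
  lambda0 <- m / sum(C * x)
  m * log(lambda0) + sum(log(C[ev])) - m
}

#' Extract the GMYC entity partition
#'
#' @param fit A `gmyc_fit`.
#' @return A `delim_partition` over the tree's tips.
#' @export
gmyc_partition <- function(fit) {
  stopifnot(inherits(fit, "gmyc_fit"))
  new_partition(names(fit$cluster_map), unname(fit$cluster_map))
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("Single-threshold GMYC fit\n")
  cat(sprintf("  threshold T_hat : %.6g\n", x$T_hat))
  cat(sprintf("  entities        : %d (%d cluster(s), %d singleton(s))\n",
              x$n_entities, x$n_clusters, x$n_singletons))
  cat(sprintf("  logL alt / null : %.4f / %.4f\n", x$logL_alt, x$logL_null))
  cat(sprintf("  LR = %.4f, df = %g, p = %.4g\n", x$LR, x$df, x$p_value))
  invisible(x)
}
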