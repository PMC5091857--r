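# Independent brute-force oracles and in-code fixtures shared across tests.

# site-pattern-counting K2P oracle: plain loops, no shared code with the
# package implementation
oracle_k2p <- function(a, b) {
  a <- toupper(strsplit(a, "")[[1]])
  b <- toupper(strsplit(b, "")[[1]])
  nt <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  n <- 0L
  ts <- 0L
  tv <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% nt && b[i] %in% nt) {
      n <- n + 1L
      if (a[i] != b[i]) {
        if ((a[i] %in% purine) == (b[i] %in% purine)) ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  list(P = P, Q = Q, sites = n,
       saturated = w1 <= 0 || w2 <= 0,
       distance = if (w1 > 0 && w2 > 0) -0.5 * log(w1) - 0.25 * log(w2)
                  else NA_real_)
}

random_seq <- function(L, gap_frac = 0) {
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (gap_frac > 0) {
    k <- rbinom(1, L, gap_frac)
    if (k > 0) s[sample(L, k)] <- sample(c("-", "N"), k, replace = TRUE)
  }
  paste(s, collapse = "")
}

# wrap a plain symmetric distance matrix as a k2p_dist (for planted-gap
# tests that do not involve sequences)
fake_dist <- function(d, ids = NULL) {
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, saturated = is.na(d) & row(d) != col(d),
                 sites_used = matrix(100L, nrow(d), ncol(d),
                                     dimnames = dimnames(d))),
            class = "k2p_dist")
}

# symmetric matrix from block structure: within-block values drawn in
# `within`, between-block values in `between[[i,j]]` ranges
planted_matrix <- function(block_sizes, within = c(0, 0.01),
                           between = c(0.10, 0.11)) {
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      rng <- if (block[i] == block[j]) within else between
      d[i, j] <- d[j, i] <- runif(1, rng[1], rng[2])
    }
  }
  list(dist = fake_dist(d), block = block)
}

# brute-force connected components (BFS on the d < t adjacency)
oracle_components <- function(d, t) {
  n <- nrow(d)
  seen <- rep(FALSE, n)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp[v] <- cur
      nb <- which(d[v, ] < t & !seen)
      queue <- c(queue, nb)
    }
  }
  comp
}

# brute-force barcode-gap scan: among ranks at or after the prior boundary,
# the split point with the maximal gap (for planted data with one dominant
# gap this is the gap the detector must find)
oracle_max_gap_rank <- function(sorted_d, prior_P) {
  above <- which(sorted_d > prior_P)
  if (length(above) == 0) return(NULL)
  start <- max(above[1] - 1, 1)
  gaps <- diff(sorted_d)
  cand <- seq.int(start, length(sorted_d) - 1)
  cand[which.max(gaps[cand])]
}

# do two partitions of the same ids describe the same set partition?
same_partition <- function(assign_a, assign_b) {
  ids <- sort(names(assign_a))
  if (!setequal(ids, names(assign_b))) return(FALSE)
  ga <- split(ids, assign_a[ids])
  gb <- split(ids, assign_b[ids])
  length(ga) == length(gb) &&
    all(vapply(ga, function(u) {
      any(vapply(gb, function(v) setequal(u, v), logical(1)))
    }, logical(1)))
}

# exhaustive (T, lambda) grid for the GMYC alternative on a small tree:
# coarse log-spaced lambda grid plus a local refinement around the best cell
oracle_gmyc_grid <- function(tree) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  node_h <- sort(unique(h[(n + 1):(n + tree$Nnode)]))
  grid_T <- c((c(0, node_h[-length(node_h)]) + node_h) / 2,
              max(node_h) * 1.5 + 1)
  lam <- exp(seq(log(1e-2), log(1e3), length.out = 40))
  best <- -Inf
  best_at <- NULL
  for (T in grid_T) {
    for (lS in lam) {
      for (lC in lam) {
        ll <- gmyc_loglik(tree, T, lS, lC)
        if (ll > best) {
          best <- ll
          best_at <- c(T, lS, lC)
        }
      }
    }
  }
  for (rep in 1:2) {
    lamS <- exp(seq(log(best_at[2]) - 0.3, log(best_at[2]) + 0.3,
                    length.out = 15))
    lamC <- exp(seq(log(best_at[3]) - 0.3, log(best_at[3]) + 0.3,
                    length.out = 15))
    for (lS in lamS) {
      for (lC in lamC) {
        ll <- gmyc_loglik(tree, best_at[1], lS, lC)
        if (ll > best) {
          best <- ll
          best_at <- c(best_at[1], lS, lC)
        }
      }
    }
  }
  best
}

# paths of the published-results fixture
scinax_fixture <- function() {
  dir <- system.file("extdata", "scinax_pmir", package = "delimkit")
  list(abgd = file.path(dir, "partition_abgd.csv"),
       gmyc = file.path(dir, "partition_gmyc.csv"),
       pairs = file.path(dir, "evidence_pairs.csv"),
       lineages = file.path(dir, "lineages.csv"))
}

load_scinax <- function() {
  fx <- scinax_fixture()
  list(abgd = read_partition_csv(fx$abgd),
       gmyc = read_partition_csv(fx$gmyc),
       ev = read_evidence_csv(fx$pairs, fx$lineages))
}

# study conditions used by the simulation experiments (kept in one place so
# unit tests and acceptance tests agree)
study_config <- function(seed, n_species = 8L, samples = 4L) {
  sim_config(n_species = n_species, speciation_rate = 0.1,
             samples_per_species = samples, theta = 0.2,
             min_depth = if (n_species > 1) 3.2 else NULL,
             seq_length = 750L, subst_rate = 7.35e-3, kappa = 4,
             seed = seed)
}

tmp_file <- function(ext = "") tempfile(fileext = ext)
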