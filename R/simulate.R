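#' Simulation configuration
#'
#' Study conditions for the synthetic multispecies-coalescent generator.
#' Time is in millions of years (My); `subst_rate` converts time to expected
#' substitutions/site (default 7.35e-3 /site/My, a published 16S rRNA clock
#' for hylid frogs).
#'
#' @param n_species Number of species, >= 1.
#' @param speciation_rate Yule speciation rate (events/My/lineage).
#' @param samples_per_species Sequences sampled per species.
#' @param theta Within-species coalescent depth scale (My): the expected
#'   time to coalescence of a pair of lineages within a species.
#' @param min_depth Optional floor (My) on the shallowest species
#'   divergence; the species tree is redrawn until every divergence exceeds
#'   it (conditioning the Yule process). `NULL` = unconditioned.
#' @param seq_length Alignment length (sites).
#' @param subst_rate Total substitution rate (substitutions/site/My).
#' @param kappa Transition/transversion rate ratio (per-target), > 0.
#' @param p_morph,p_acoust Probability that a species pair is recorded as
#'   morphologically / bioacoustically differentiable.
#' @param frac_named Fraction of species carrying nominal names.
#' @param seed Integer seed; every simulator is reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 8L, speciation_rate = 0.1,
                       samples_per_species = 4L, theta = 0.2,
                       min_depth = NULL, seq_length = 750L,
                       subst_rate = 7.35e-3, kappa = 4,
                       p_morph = 0.7, p_acoust = 0.7, frac_named = 0.25,
                       seed = 1L) {
  stopifnot(n_species >= 1, speciation_rate > 0, samples_per_species >= 1,
            theta > 0, seq_length >= 1, subst_rate >= 0, kappa > 0,
            p_morph >= 0, p_morph <= 1, p_acoust >= 0, p_acoust <= 1,
            frac_named >= 0, frac_named <= 1)
  structure(list(n_species = as.integer(n_species),
                 speciation_rate = speciation_rate,
                 samples_per_species = as.integer(samples_per_species),
                 theta = theta, min_depth = min_depth,
                 seq_length = as.integer(seq_length),
                 subst_rate = subst_rate, kappa = kappa,
                 p_morph = p_morph, p_acoust = p_acoust,
                 frac_named = frac_named, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Yule species tree
#'
#' Forward pure-birth simulation: starting from the root split (two
#' lineages), with `k` lineages the waiting time to the next speciation is
#' exponential with rate `k * rate`; a uniformly chosen lineage splits. The
#' present is set one further exponential wait after the `n`-th lineage
#' appears, so the youngest divergence has an Exp(`n * rate`) age. With
#' `min_depth` set, trees are redrawn until the youngest divergence is at
#' least `min_depth` (rejection sampling, i.e. the Yule process conditioned
#' on a minimum divergence).
#'
#' @param n_species Number of tips, >= 1.
#' @param rate Speciation rate (events/time/lineage).
#' @param seed Optional integer seed.
#' @param min_depth Optional minimum species-divergence age.
#' @return An ultrametric `phylo` with tips `sp1..spn` (a single-tip tree
#'   of height 0 for `n_species = 1`).
#' @export
sim_yule_tree <- function(n_species, rate = 0.1, seed = NULL, min_depth = NULL) {
  stopifnot(n_species >= 1, rate > 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_species == 1L) {
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          edge.length = 0, Nnode = 1L, tip.label = "sp1"),
                     class = "phylo"))
  }
  n <- as.integer(n_species)
  repeat {
    # internal node 1 = root (time 0); node j >= 2 = the (j-1)-th split.
    # active lineages are tracked by the internal node they descend from.
    active <- c(1L, 1L)
    parent_node <- integer(n - 1L)           # parent internal node of node j
    node_time <- numeric(n - 1L)
    t <- 0
    next_node <- 2L
    while (length(active) < n) {
      t <- t + stats::rexp(1L, length(active) * rate)
      i <- sample.int(length(active), 1L)
      parent_node[next_node] <- active[i]
      node_time[next_node] <- t
      active[i] <- next_node
      active <- c(active, next_node)
      next_node <- next_node + 1L
    }
    present <- t + stats::rexp(1L, n * rate)
    if (is.null(min_depth) || (present - t) >= min_depth) break
  }
  children <- rep(list(integer(0)), n - 1L)
  if (n >= 3L) {
    for (j in seq.int(2L, n - 1L)) {
      children[[parent_node[j]]] <- c(children[[parent_node[j]]], j)
    }
  }
  for (m in seq_len(n)) {
    children[[active[m]]] <- c(children[[active[m]]], -m)
  }
  .phylo_from_nodes(paste0("sp", seq_len(n)), children, present - node_time)
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Within each species-tree branch, gene lineages coalesce backwards in time
#' with per-pair rate `1 / theta` (so a pair within one species has expected
#' coalescence time `theta`); lineages that fail to coalesce before the top
#' of the branch are passed to the parent branch, and the root branch
#' extends until a single lineage remains. Every interspecific coalescence
#' is therefore at least as old as the corresponding species divergence,
#' and the output is ultrametric.
#'
#' @param species_tree Ultrametric `phylo` (tips = species).
#' @param samples_per_species Gene copies sampled per species, >= 1.
#' @param theta Coalescent depth scale (expected pair coalescence time), in
#'   the species tree's time units.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` with tips `<species>_<i>`.
#' @export
sim_msc_gene_tree <- function(species_tree, samples_per_species, theta,
                              seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"), samples_per_species >= 1,
            theta > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(samples_per_species)
  nsp <- ape::Ntip(species_tree)
  N <- nsp * m
  tip_labels <- as.vector(t(outer(species_tree$tip.label, seq_len(m),
                                  paste, sep = "_")))
  if (N == 1L) {
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          edge.length = 0, Nnode = 1L,
                          tip.label = tip_labels),
                     class = "phylo"))
  }
  sp_h <- node_heights(species_tree)
  # parent species node of every species node (0 for the root)
  par_of <- integer(nsp + species_tree$Nnode)
  par_of[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  # pools of gene-lineage refs entering each species node from below
  pools <- rep(list(integer(0)), nsp + species_tree$Nnode)
  for (s in seq_len(nsp)) pools[[s]] <- -(((s - 1L) * m) + seq_len(m))
  children <- list()
  heights <- numeric(0)
  ord <- order(sp_h[seq_len(nsp + species_tree$Nnode)])
  for (v in ord) {
    pool <- pools[[v]]
    if (length(pool) == 0L && v > nsp) next   # defensive; internal always fed
    t <- sp_h[v]
    top <- if (par_of[v] == 0L) Inf else sp_h[par_of[v]]
    while (length(pool) > 1L) {
      k <- length(pool)
      t <- t + stats::rexp(1L, k * (k - 1) / 2 / theta)
      if (t >= top) break
      pick <- sample.int(k, 2L)
      children[[length(children) + 1L]] <- pool[pick]
      heights <- c(heights, t)
      pool <- c(pool[-pick], length(children))
    }
    if (par_of[v] == 0L) {
      pools[[v]] <- pool                     # fully coalesced at the root
    } else {
      pools[[par_of[v]]] <- c(pools[[par_of[v]]], pool)
    }
  }
  .phylo_from_nodes(tip_labels, children, heights)
}

#' Simulate sequence evolution under the K2P model
#'
#' The root sequence is uniform over `{A,C,G,T}`; along each branch, sites
#' evolve independently under the Kimura two-parameter continuous-time
#' model with transition rate `kappa`-fold the per-target transversion rate
#' and total substitution rate `subst_rate`. Per-branch substitution
#' probabilities use the closed-form K80 transition kernel, so arbitrarily
#' long branches are exact.
#'
#' @param gene_tree Rooted `phylo` with branch lengths in time units.
#' @param seq_length Sites, >= 1.
#' @param subst_rate Total substitution rate (substitutions/site/time).
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param seed Optional integer seed.
#' @return A `barcode_alignment` over the tree's tips.
#' @export
sim_k2p_sequences <- function(gene_tree, seq_length, subst_rate, kappa = 4,
                              seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), seq_length >= 1, subst_rate >= 0,
            kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(seq_length)
  n <- ape::Ntip(gene_tree)
  nnode <- n + gene_tree$Nnode
  seqs <- matrix(NA_integer_, nnode, L)
  seqs[n + 1L, ] <- sample.int(4L, L, replace = TRUE)
  ts_partner <- c(3L, 4L, 1L, 2L)            # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)                   # first transversion target
  tv2 <- c(4L, 3L, 4L, 3L)                   # second transversion target
  ord <- order(ape::node.depth.edgelength(gene_tree)[gene_tree$edge[, 2L]])
  for (e in ord) {
    par <- gene_tree$edge[e, 1L]
    ch <- gene_tree$edge[e, 2L]
    d <- subst_rate * gene_tree$edge.length[e]
    s <- seqs[par, ]
    if (d > 0) {
      e1 <- exp(-4 * d / (kappa + 2))
      e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
      p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
      p_tv <- 0.25 - 0.25 * e1               # per target; two targets
      u <- stats::runif(L)
      i_ts <- u < p_ts
      i_v1 <- !i_ts & u < p_ts + p_tv
      i_v2 <- !i_ts & !i_v1 & u < p_ts + 2 * p_tv
      s[i_ts] <- ts_partner[s[i_ts]]
      s[i_v1] <- tv1[s[i_v1]]
      s[i_v2] <- tv2[s[i_v2]]
    }
    seqs[ch, ] <- s
  }
  mat <- matrix(c("A", "C", "G", "T")[seqs[seq_len(n), , drop = FALSE]],
                nrow = n)
  barcode_alignment(gene_tree$tip.label, mat)
}

#' Simulate a pairwise evidence table
#'
#' Each species pair is independently recorded as morphologically
#' differentiable with probability `p_morph` (flag `yes`, otherwise `no`)
#' and bioacoustically differentiable with probability `p_acoust`;
#' `reference_split` is `unknown` throughout. A seeded fraction
#' `frac_named` of species receive nominal names (`nominalis_<i>`).
#'
#' @param species Character vector of species labels.
#' @param p_morph,p_acoust Differentiability probabilities.
#' @param frac_named Fraction of named species.
#' @param seed Optional integer seed.
#' @return An `evidence_table` (see [evidence_table()]).
#' @export
sim_evidence_table <- function(species, p_morph = 0.7, p_acoust = 0.7,
                               frac_named = 0.25, seed = NULL) {
  stopifnot(length(species) >= 1, !anyDuplicated(species))
  if (!is.null(seed)) set.seed(seed)
  n <- length(species)
  n_named <- round(frac_named * n)
  named <- sort(sample.int(n, n_named))
  nominal <- rep(NA_character_, n)
  nominal[named] <- paste0("nominalis_", seq_len(n_named))
  lineages <- data.frame(lineage = species, nominal_name = nominal,
                         has_morph_data = TRUE, has_acoustic_data = TRUE,
                         stringsAsFactors = FALSE)
  if (n >= 2L) {
    pr <- t(utils::combn(species, 2L))
    npr <- nrow(pr)
    pairs <- data.frame(
      lineage_a = pr[, 1L], lineage_b = pr[, 2L],
      morph_diff = ifelse(stats::runif(npr) < p_morph, "yes", "no"),
      acoustic_diff = ifelse(stats::runif(npr) < p_acoust, "yes", "no"),
      reference_split = "unknown", stringsAsFactors = FALSE)
  } else {
    pairs <- NULL
  }
  evidence_table(pairs, lineages)
}

#' Generate a complete synthetic dataset
#'
#' Chains the four simulators -- Yule species tree, multispecies-coalescent
#' gene tree, K2P sequence evolution, and evidence table -- and optionally
#' writes the files (species/gene Newick, aligned FASTA, evidence and
#' lineage CSVs, and a ground-truth JSON echoing the configuration).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return A `synthetic_dataset` list: `species_tree`, `gene_tree`,
#'   `alignment`, `species_map` (named vector sequence id -> species),
#'   `evidence`, `config`, and `files` (paths, when `dir` was given).
#' @export
make_dataset <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, 4L)
  sp_tree <- sim_yule_tree(cfg$n_species, cfg$speciation_rate,
                           seed = seeds[1L], min_depth = cfg$min_depth)
  gene_tree <- sim_msc_gene_tree(sp_tree, cfg$samples_per_species,
                                 cfg$theta, seed = seeds[2L])
  aln <- sim_k2p_sequences(gene_tree, cfg$seq_length, cfg$subst_rate,
                           cfg$kappa, seed = seeds[3L])
  ev <- sim_evidence_table(sp_tree$tip.label, cfg$p_morph, cfg$p_acoust,
                           cfg$frac_named, seed = seeds[4L])
  species_map <- stats::setNames(sub("_[0-9]+$", "", aln$ids), aln$ids)
  out <- structure(list(species_tree = sp_tree, gene_tree = gene_tree,
                        alignment = aln, species_map = species_map,
                        evidence = ev, config = cfg, files = NULL),
                   class = "synthetic_dataset")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      species_tree = file.path(dir, "species_tree.nwk"),
      gene_tree = file.path(dir, "gene_tree.nwk"),
      alignment = file.path(dir, "alignment.fasta"),
      evidence_pairs = file.path(dir, "evidence_pairs.csv"),
      lineages = file.path(dir, "lineages.csv"),
      species_map = file.path(dir, "species_map.csv"),
      truth = file.path(dir, "truth.json"))
    write_ultrametric(sp_tree, files$species_tree)
    write_ultrametric(gene_tree, files$gene_tree)
    write_fasta(aln, files$alignment)
    write_evidence_csv(ev, files$evidence_pairs, files$lineages)
    utils::write.csv(data.frame(id = names(species_map),
                                lineage = unname(species_map)),
                     files$species_map, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(cfg), files$truth, auto_unbox = TRUE,
                         digits = NA, null = "null")
    out$files <- files
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", x$config$n_species, "species x",
      x$config$samples_per_species, "samples,",
      x$config$seq_length, "sites (seed", paste0(x$config$seed, ")\n"))
  invisible(x)
}
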