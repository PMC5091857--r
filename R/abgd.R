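#' Configuration for barcode-gap delimitation
#'
#' Parameters of the recursive barcode-gap partitioner. `prior_P` is the
#' maximal prior intraspecific divergence (substitutions/site): distances at
#' or below it are never treated as interspecific, so the gap search starts
#' just below the first rank exceeding it. `gap_width_X` is the relative gap
#' width: a candidate gap must exceed `gap_width_X` times the local gap scale
#' (the mean of the preceding gaps inside a sliding window covering
#' `window_frac` of the ranked distances). Recursion re-applies the search
#' inside every unit of at least `min_group_size_to_split` sequences, up to
#' `max_rounds` rounds.
#'
#' The windowed local-scale gap test is this package's normative definition
#' of the barcode gap; it preserves the published inputs (prior intraspecific
#' divergence, relative gap width, recursion depth) of barcode-gap discovery.
#'
#' @param prior_P Maximal prior intraspecific divergence, in (0, 1).
#'   Default 0.03 (the 3% divergence conventionally used for 16S rRNA in
#'   frog barcoding).
#' @param gap_width_X Relative gap width, > 0. Default 1.0.
#' @param max_rounds Recursion cap, in 1..50. Default 10.
#' @param window_frac Local-slope window as a fraction of the ranked
#'   distances. Default 0.1.
#' @param min_group_size_to_split Units smaller than this are never re-split
#'   (a 2-member unit has a single distance: no gap is definable). Default 3.
#' @return An `abgd_config` list.
#' @export
abgd_config <- function(prior_P = 0.03, gap_width_X = 1.0, max_rounds = 10L,
                        window_frac = 0.1, min_group_size_to_split = 3L) {
  stopifnot(prior_P > 0, prior_P < 1, gap_width_X > 0,
            max_rounds >= 1, max_rounds <= 50,
            window_frac > 0, window_frac <= 1, min_group_size_to_split >= 2)
  structure(list(prior_P = prior_P, gap_width_X = gap_width_X,
                 max_rounds = as.integer(max_rounds),
                 window_frac = window_frac,
                 min_group_size_to_split = as.integer(min_group_size_to_split)),
            class = "abgd_config")
}

#' Ranked pairwise distances within a subset of sequences
#'
#' All within-subset pairwise distances, sorted ascending. Saturated pairs
#' rank last, at `Inf`: barcode-gap clustering only needs the ordering, and
#' a saturated pair is greater than any finite distance.
#'
#' @param m A `k2p_dist` object.
#' @param subset Character vector of at least two sequence ids (default: all).
#' @return Ascending numeric vector of length `choose(length(subset), 2)`.
#' @export
rank_distances <- function(m, subset = m$ids) {
  stopifnot(inherits(m, "k2p_dist"))
  missing_ids <- setdiff(subset, m$ids)
  if (length(missing_ids) > 0L) {
    .stop_input("unknown ids: ", paste(missing_ids, collapse = ", "))
  }
  if (length(subset) < 2L) .stop_input("need at least 2 sequences to rank distances")
  d <- .k2p_inf(m)[subset, subset, drop = FALSE]
  sort(d[upper.tri(d)])
}

#' Locate the barcode gap in a ranked distance distribution
#'
#' Scans the ascending distances for the first gap that is wide relative to
#' the local gap scale, starting at the last rank not exceeding the prior
#' intraspecific divergence. Procedure: let `i0` be the smallest rank with
#' `sorted_d[i0] > prior_P` (no such rank: no gap). For each rank
#' `i >= max(i0 - 1, 1)` the gap is `g_i = sorted_d[i+1] - sorted_d[i]` and
#' the local scale `s_i` is the mean of the gaps in the window of
#' `W = max(2, ceiling(window_frac * m))` ranks ending at `i`, excluding
#' `g_i` itself. The barcode gap is the first `i` with
#' `g_i > gap_width_X * s_i` and `g_i > 0`; the returned threshold is the
#' midpoint `(sorted_d[i] + sorted_d[i+1]) / 2`.
#'
#' @param sorted_d Ascending numeric vector of pairwise distances
#'   (`Inf` allowed for saturated pairs).
#' @param cfg An [abgd_config()].
#' @return The threshold (substitutions/site), or `NULL` when no rank
#'   qualifies.
#' @export
find_barcode_gap <- function(sorted_d, cfg = abgd_config()) {
  m <- length(sorted_d)
  if (m < 2L) .stop_input("need at least 2 distances")
  if (is.unsorted(sorted_d, na.rm = FALSE)) .stop_input("distances must be ascending")
  above <- which(sorted_d > cfg$prior_P)
  if (length(above) == 0L) return(NULL)
  i0 <- above[1L]
  W <- max(2L, ceiling(cfg$window_frac * m))
  gaps <- diff(sorted_d)             # gaps[i] = sorted_d[i+1] - sorted_d[i]
  for (i in seq.int(max(i0 - 1L, 1L), m - 1L)) {
    g <- gaps[i]
    if (!is.finite(g)) next          # gap into a saturated block: undefined width
    lo <- max(1L, i - W + 1L)
    win <- if (lo <= i - 1L) gaps[lo:(i - 1L)] else numeric(0)
    win <- win[is.finite(win)]
    if (length(win) == 0L) next      # no local scale available at this rank
    # strict inequality up to floating noise (constant ladders are not gaps)
    if (g > 0 && (g - cfg$gap_width_X * mean(win)) > 1e-9 * max(g, 1e-12)) {
      return((sorted_d[i] + sorted_d[i + 1L]) / 2)
    }
  }
  NULL
}

#' Partition sequences at a distance threshold (single linkage)
#'
#' Connects every pair with distance strictly below `t`; connected components
#' are the units. This realizes the barcode-gap grouping criterion: any
#' between-group distance exceeds `t`, while within a group each sequence is
#' linked by a chain of sub-threshold distances. Saturated pairs never link.
#'
#' @param m A `k2p_dist` object.
#' @param subset Ids to partition (default: all).
#' @param t Threshold, >= 0.
#' @return A `delim_partition` object (see [abgd_delimit()]).
#' @export
partition_at_threshold <- function(m, subset = m$ids, t) {
  stopifnot(inherits(m, "k2p_dist"), t >= 0)
  d <- .k2p_inf(m)[subset, subset, drop = FALSE]
  comp <- .single_linkage_components(d, t)
  new_partition(subset, paste0("U", comp))
}

# union-find single-linkage components: link pairs with d < t (strict)
.single_linkage_components <- function(d, t) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (d[i, j] < t) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

#' Construct a delimitation partition
#'
#' @param ids Character vector of sequence ids.
#' @param units Unit label per id.
#' @param trace Optional data frame of threshold decisions
#'   (`round`, `subgroup`, `threshold`).
#' @return A `delim_partition`: list with `assignment` (named character
#'   vector id -> unit), `n_units`, and `trace`.
#' @export
new_partition <- function(ids, units, trace = NULL) {
  stopifnot(length(ids) == length(units), !anyDuplicated(ids))
  assignment <- stats::setNames(as.character(units), ids)
  if (is.null(trace)) {
    trace <- data.frame(round = integer(0), subgroup = character(0),
                        threshold = numeric(0))
  }
  structure(list(assignment = assignment,
                 n_units = length(unique(assignment)),
                 trace = trace),
            class = "delim_partition")
}

#' @export
print.delim_partition <- function(x, ...) {
  cat("Delimitation:", length(x$assignment), "sequences in", x$n_units,
      "unit(s)\n")
  invisible(x)
}

#' Units of a partition as a list of id vectors
#'
#' @param x A `delim_partition`.
#' @return Named list of character vectors, one per unit.
#' @export
partition_units <- function(x) {
  stopifnot(inherits(x, "delim_partition"))
  split(names(x$assignment), x$assignment)
}

#' Recursive barcode-gap delimitation (ABGD-style)
#'
#' Round 1 applies [find_barcode_gap()] and [partition_at_threshold()] to the
#' full distance matrix; every later round re-applies the procedure within
#' each current unit of at least `min_group_size_to_split` members, using
#' only within-unit distances, until no unit splits or `max_rounds` is
#' reached. Deterministic: identical input and configuration give an
#' identical partition and trace.
#'
#' @param m A `k2p_dist` object over at least two sequences.
#' @param cfg An [abgd_config()].
#' @return A `delim_partition`; `$trace` records, for every examined
#'   (sub)group, the round, the subgroup label and the threshold applied
#'   (`NA` when no gap was found).
#' @export
abgd_delimit <- function(m, cfg = abgd_config()) {
  stopifnot(inherits(m, "k2p_dist"), inherits(cfg, "abgd_config"))
  if (length(m$ids) < 2L) .stop_input("need at least 2 sequences")
  assignment <- stats::setNames(rep("U1", length(m$ids)), m$ids)
  trace <- list()
  for (round in seq_len(cfg$max_rounds)) {
    units <- split(names(assignment), assignment)
    units <- units[order(names(units))]      # deterministic visit order
    any_split <- FALSE
    for (lab in names(units)) {
      ids <- units[[lab]]
      if (round > 1L && length(ids) < cfg$min_group_size_to_split) next
      sorted_d <- tryCatch(rank_distances(m, ids), error = function(e) {
        .stop_input("unit ", lab, ": ", conditionMessage(e))
      })
      t <- find_barcode_gap(sorted_d, cfg)
      trace[[length(trace) + 1L]] <-
        data.frame(round = round, subgroup = lab,
                   threshold = if (is.null(t)) NA_real_ else t)
      if (is.null(t)) next
      sub <- partition_at_threshold(m, ids, t)
      if (sub$n_units > 1L) {
        any_split <- TRUE
        assignment[ids] <- paste0(lab, ".", match(sub$assignment[ids],
                                                  unique(sub$assignment[ids])))
      }
    }
    if (!any_split) break
  }
  # stable renumbering by first appearance
  final <- paste0("U", match(assignment, unique(assignment)))
  new_partition(names(assignment), final, do.call(rbind, trace))
}

#' Sweep the prior intraspecific divergence
#'
#' Runs [abgd_delimit()] once per prior value and reports the resulting unit
#' counts, the conventional diagnostic for prior sensitivity.
#'
#' @param m A `k2p_dist` object.
#' @param priors Numeric vector of `prior_P` values.
#' @param cfg Base configuration; its `prior_P` is replaced per run.
#' @return Data frame with columns `prior_P` and `n_units`.
#' @export
abgd_prior_sweep <- function(m, priors, cfg = abgd_config()) {
  stopifnot(length(priors) >= 1L, all(priors > 0), all(priors < 1))
  res <- lapply(priors, function(p) {
    cfg$prior_P <- p
    abgd_delimit(m, cfg)$n_units
  })
  data.frame(prior_P = priors, n_units = unlist(res))
}

#' Read/write a partition as CSV
#'
#' Columns: `id`, `unit`, and (when available) `round_assigned` -- the first
#' round in which the id's final unit appeared.
#'
#' @param x A `delim_partition`.
#' @param path CSV file path.
#' @return `write_partition_csv()`: `path` invisibly;
#'   `read_partition_csv()`: a `delim_partition`.
#' @export
write_partition_csv <- function(x, path) {
  stopifnot(inherits(x, "delim_partition"))
  utils::write.csv(data.frame(id = names(x$assignment),
                              unit = unname(x$assignment)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  if (!file.exists(path)) .stop_input("partition file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "unit") %in% names(df))) {
    .stop_input("partition CSV needs columns 'id' and 'unit': ", path)
  }
  new_partition(df$id, df$unit)
}
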