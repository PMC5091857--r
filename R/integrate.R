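# Reconciliation and classification of molecular delimitations.
#
# The conservatism rule: where two delimitations disagree, the grouping with
# fewer units (the "lumping" side) is kept, unless morphological,
# bioacoustic or prior-reference evidence positively supports the split --
# in which case the finer grouping is kept.

# lineage label of a unit: the unique mapped label of its members, the unit
# label itself when no map is given, NA when members map to several labels
.unit_lineage <- function(ids, unit_label, id_map) {
  if (is.null(id_map)) return(unit_label)
  labs <- unique(id_map[ids])
  if (length(labs) == 1L && !is.na(labs)) labs else NA_character_
}

#' Reconcile two molecular delimitations
#'
#' Computes the join of the two partitions into maximal conflict components
#' (groups of units connected by shared sequences). Concordant components
#' pass through unchanged. Within a discordant component where one
#' delimitation refines the other, the coarser grouping is chosen unless
#' any pair of finer units that the coarser side merges has
#' `morph_diff = yes`, `acoustic_diff = yes` or `reference_split = yes`, in
#' which case the finer grouping is chosen. Non-nested conflicts (neither
#' side refines the other) fall back to the coarsest common coarsening --
#' the whole component as one unit -- with a warning, preserving
#' conservatism while flagging the case for review.
#'
#' @param p_a,p_b Two `delim_partition`s over the same sequence ids
#'   (e.g. distance-based and tree-based delimitations).
#' @param ev An [evidence_table()] keyed by lineage labels.
#' @param id_map Optional named character vector mapping sequence ids to
#'   lineage labels (for evidence lookup). Default: unit labels are
#'   themselves the lineage labels.
#' @return A `delim_partition` of consensus units; `$decision_log` is a data
#'   frame recording, per component, the rule that fired.
#' @export
reconcile_partitions <- function(p_a, p_b, ev, id_map = NULL) {
  stopifnot(inherits(p_a, "delim_partition"), inherits(p_b, "delim_partition"),
            inherits(ev, "evidence_table"))
  ids_a <- names(p_a$assignment)
  ids_b <- names(p_b$assignment)
  if (!setequal(ids_a, ids_b)) {
    .stop_input("partitions cover different ids: ",
                paste(c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a)),
                      collapse = ", "))
  }
  ids <- sort(ids_a)
  a <- p_a$assignment[ids]
  b <- p_b$assignment[ids]
  # join: connected components over shared membership in either partition
  comp <- .join_components(a, b)
  chosen_units <- list()   # per component: named list label -> ids
  log <- list()
  add_log <- function(cidx, rule, chosen, n_units, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(component = cidx, rule = rule,
                                           chosen = chosen, n_units = n_units,
                                           detail = detail)
  }
  same_grouping <- function(ua, ub) {
    length(ua) == length(ub) &&
      all(vapply(ua, function(u) {
        any(vapply(ub, function(v) setequal(u, v), logical(1L)))
      }, logical(1L)))
  }
  for (cidx in sort(unique(comp))) {
    sel <- ids[comp == cidx]
    ua <- split(sel, a[sel])
    ub <- split(sel, b[sel])
    if (same_grouping(ua, ub)) {
      chosen_units[[length(chosen_units) + 1L]] <- ua
      add_log(cidx, "concordant", "both", length(ua))
      next
    }
    coarse <- if (length(ua) <= length(ub)) ua else ub
    fine <- if (length(ua) <= length(ub)) ub else ua
    nested <- length(coarse) < length(fine) &&
      all(vapply(fine, function(u) {
        any(vapply(coarse, function(v) all(u %in% v), logical(1L)))
      }, logical(1L)))
    if (!nested) {
      # neither refines the other: coarsest common coarsening, flagged
      warning("non-nested conflict in component ", cidx,
              "; using the coarsest common coarsening", call. = FALSE)
      lab <- paste(sort(names(coarse)), collapse = "+")
      chosen_units[[length(chosen_units) + 1L]] <-
        stats::setNames(list(sel), lab)
      add_log(cidx, "non_nested_coarsening", "merged", 1L, lab)
      next
    }
    # evidence check: pairs of finer units merged by the coarser side
    override <- ""
    for (v in coarse) {
      inner <- names(fine)[vapply(fine, function(u) all(u %in% v), logical(1L))]
      if (length(inner) < 2L) next
      for (pq in utils::combn(inner, 2L, simplify = FALSE)) {
        la <- .unit_lineage(fine[[pq[1L]]], pq[1L], id_map)
        lb <- .unit_lineage(fine[[pq[2L]]], pq[2L], id_map)
        if (is.na(la) || is.na(lb)) next
        fl <- .pair_flags(ev, la, lb)
        hit <- names(which(unlist(fl) == "yes"))
        if (length(hit) > 0L) {
          override <- paste0(la, " vs ", lb, ": ", paste(hit, collapse = ","))
          break
        }
      }
      if (override != "") break
    }
    chosen_units[[length(chosen_units) + 1L]] <-
      if (override != "") fine else coarse
    add_log(cidx,
            if (override != "") "evidence_override_finer"
            else "conservative_coarser",
            if (override != "") "finer" else "coarser",
            if (override != "") length(fine) else length(coarse), override)
  }
  # assemble; the two partitions may reuse label strings across components,
  # so disambiguate any collision
  assignment <- stats::setNames(rep(NA_character_, length(ids)), ids)
  used <- character(0)
  for (ci in seq_along(chosen_units)) {
    for (lab in names(chosen_units[[ci]])) {
      final_lab <- lab
      while (final_lab %in% used) final_lab <- paste0(final_lab, ".c", ci)
      used <- c(used, final_lab)
      assignment[chosen_units[[ci]][[lab]]] <- final_lab
    }
  }
  out <- new_partition(ids, assignment[ids])
  out$decision_log <- do.call(rbind, log)
  out
}

.join_components <- function(a, b) {
  ids <- names(a)
  idx <- seq_along(ids)
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link_groups <- function(groups) {
    for (g in groups) {
      g <- match(g, ids)
      for (i in g[-1L]) {
        r1 <- find(g[1L]); r2 <- find(i)
        if (r1 != r2) parent[max(r1, r2)] <<- min(r1, r2)
      }
    }
  }
  link_groups(split(ids, a))
  link_groups(split(ids, b))
  roots <- vapply(idx, find, integer(1L))
  match(roots, unique(roots))
}

#' Classify delimited units as NS / CCS / UCS / DCL
#'
#' Applies the candidate-species rules, in order, to every unit of the
#' consensus molecular delimitation:
#'
#' 1. **NS** (nominal species): the unit carries a nominal name.
#' 2. **DCL** (deep conspecific lineage): an unnamed unit for which at least
#'    one NS comparator has recorded evidence (morphology and/or acoustics)
#'    and every recorded flag is `no` -- genetically divergent but not
#'    differentiable from that nominal species, to which it is attached.
#' 3. **CCS** (confirmed candidate species): an unnamed unit with
#'    `morph_diff = yes` or `acoustic_diff = yes` against every nominal
#'    comparator (against every other unit when no NS exists).
#' 4. **UCS** (unconfirmed candidate species): an unnamed unit with no
#'    recorded morphological or bioacoustic evidence (no data, or all flags
#'    `unknown`), or -- when no nominal comparator exists -- no positive
#'    differentiation evidence at all.
#'
#' A unit matching no rule (genuinely mixed evidence) is an error carrying
#' the unit's evidence snapshot; nothing is silently defaulted.
#'
#' @param partition A `delim_partition` of final (consensus) units.
#' @param ev An [evidence_table()]; every unit's lineage must appear in
#'   `ev$lineages`.
#' @param id_map Optional named vector mapping sequence ids to lineage
#'   labels (see [reconcile_partitions()]).
#' @return An `otu_classification`: data frame `units` (`unit`, `lineage`,
#'   `category`, `attached_to`, `rule`), plus `counts` (named vector over
#'   NS/CCS/UCS/DCL) and `n_units`.
#' @export
classify_units <- function(partition, ev, id_map = NULL) {
  stopifnot(inherits(partition, "delim_partition"),
            inherits(ev, "evidence_table"))
  units <- partition_units(partition)
  lineage <- vapply(names(units), function(lab) {
    .unit_lineage(units[[lab]], lab, id_map)
  }, character(1L))
  if (anyNA(lineage)) {
    .stop_input("units spanning several lineages cannot be classified: ",
                paste(names(units)[is.na(lineage)], collapse = ", "))
  }
  info <- do.call(rbind, lapply(lineage, function(l) .lineage_row(ev, l)))
  named <- !is.na(info$nominal_name)
  ns_lineages <- lineage[named]
  rows <- vector("list", length(units))
  for (i in seq_along(units)) {
    li <- lineage[i]
    if (named[i]) {
      rows[[i]] <- data.frame(unit = names(units)[i], lineage = li,
                              category = "NS",
                              attached_to = NA_character_,
                              rule = "nominal name assigned")
      next
    }
    comparators <- setdiff(ns_lineages, li)
    has_data <- isTRUE(info$has_morph_data[i]) ||
      isTRUE(info$has_acoustic_data[i])
    flags_vs <- lapply(comparators, function(cl) {
      fl <- .pair_flags(ev, li, cl)
      c(fl$morph_diff, fl$acoustic_diff)
    })
    # DCL: some NS with recorded, uniformly negative differentiation
    dcl_at <- which(vapply(flags_vs, function(f) {
      any(f != "unknown") && !any(f == "yes")
    }, logical(1L)))
    if (length(comparators) > 0L && length(dcl_at) > 0L) {
      att <- comparators[min(dcl_at)]
      rows[[i]] <- data.frame(unit = names(units)[i], lineage = li,
                              category = "DCL", attached_to = att,
                              rule = paste0("not differentiable from NS '",
                                            att, "'"))
      next
    }
    # CCS: positive differentiation against every comparator
    ccs_targets <- if (length(comparators) > 0L) comparators
                   else setdiff(lineage, li)
    ccs_flags <- lapply(ccs_targets, function(cl) {
      fl <- .pair_flags(ev, li, cl)
      c(fl$morph_diff, fl$acoustic_diff)
    })
    if (length(ccs_targets) > 0L &&
        all(vapply(ccs_flags, function(f) any(f == "yes"), logical(1L)))) {
      rows[[i]] <- data.frame(unit = names(units)[i], lineage = li,
                              category = "CCS", attached_to = NA_character_,
                              rule = "differentiable from all comparators")
      next
    }
    # UCS: no recorded evidence, or no NS to confirm against and nothing
    # positive recorded
    all_unknown <- length(flags_vs) == 0L ||
      all(vapply(flags_vs, function(f) all(f == "unknown"), logical(1L)))
    no_yes_anywhere <- all(vapply(ccs_flags, function(f) !any(f == "yes"),
                                  logical(1L)))
    if (!has_data || all_unknown ||
        (length(comparators) == 0L && no_yes_anywhere)) {
      rows[[i]] <- data.frame(unit = names(units)[i], lineage = li,
                              category = "UCS", attached_to = NA_character_,
                              rule = if (!has_data || all_unknown)
                                       "no corroborating data"
                                     else "no nominal comparator, no positive evidence")
      next
    }
    snapshot <- paste(vapply(seq_along(comparators), function(j) {
      paste0(comparators[j], ": [", paste(flags_vs[[j]], collapse = ","), "]")
    }, character(1L)), collapse = "; ")
    .stop_input("unit '", names(units)[i], "' (lineage '", li,
                "') matches no classification rule; evidence vs nominal ",
                "comparators: ", snapshot)
  }
  units_df <- do.call(rbind, rows)
  rownames(units_df) <- NULL
  counts <- vapply(c("NS", "CCS", "UCS", "DCL"),
                   function(k) sum(units_df$category == k), integer(1L))
  structure(list(units = units_df, counts = counts,
                 n_units = nrow(units_df)),
            class = "otu_classification")
}

#' @export
print.otu_classification <- function(x, ...) {
  cat("OTU classification:", x$n_units, "unit(s) --",
      paste(sprintf("%d %s", x$counts, names(x$counts)), collapse = ", "),
      "\n")
  invisible(x)
}

# round half away from zero (so 81.82 -> 82, 42.86 -> 43, 0.5 -> 1)
.round_half_up <- function(x) floor(x + 0.5)

#' Cryptic-diversity richness statistics
#'
#' Given a classification, counts the undescribed species-level units
#' `U = |CCS| + |UCS|` (deep conspecific lineages are not counted as
#' species) and, against a baseline of `D` described species, reports the
#' percentage of the total richness that is undescribed,
#' `100 * U / (U + D)`, and the percentage increase over the described
#' richness, `100 * U / D`, both rounded half-up to integers.
#'
#' @param classification An `otu_classification` (or a list with a `counts`
#'   element), or directly an integer `U` via the `U` argument.
#' @param baseline_D Number of described baseline species, >= 1. The
#'   appropriate denominator is context-dependent (e.g. regional nominal
#'   species vs a wider faunal list).
#' @param U Optional explicit count of undescribed species-level units,
#'   overriding `classification`.
#' @return A `richness_summary` list: `U`, `D`, `percent_undescribed`,
#'   `percent_increase`.
#' @export
richness_stats <- function(classification = NULL, baseline_D, U = NULL) {
  if (is.null(U)) {
    stopifnot(inherits(classification, "otu_classification"))
    U <- unname(classification$counts["CCS"] + classification$counts["UCS"])
  }
  U <- as.integer(U)
  if (length(baseline_D) != 1L || is.na(baseline_D) || baseline_D < 1) {
    .stop_input("baseline_D must be a single integer >= 1")
  }
  D <- as.integer(baseline_D)
  stopifnot(U >= 0)
  structure(list(U = U, D = D,
                 percent_undescribed = .round_half_up(100 * U / (U + D)),
                 percent_increase = .round_half_up(100 * U / D)),
            class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("Richness: U = %d undescribed vs D = %d described\n", x$U, x$D))
  cat(sprintf("  %d%% of total richness undescribed; +%d%% over described\n",
              x$percent_undescribed, x$percent_increase))
  invisible(x)
}
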