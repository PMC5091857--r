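#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P distance `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`
#' where `P` and `Q` are the transition and transversion proportions over
#' pairwise-complete sites (both characters in `{A,C,G,T}`). Sites with a gap
#' or `N` in either sequence are excluded (pairwise deletion). When
#' `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the distance is undefined under the
#' model (saturation); it is then flagged rather than reported as a number.
#'
#' @param a,b Equal-length nucleotide strings or character vectors over
#'   `{A,C,G,T,-,N}` (case-insensitive).
#' @return A list with elements `distance` (substitutions/site, `NA` if
#'   saturated), `P`, `Q`, `sites` (comparable sites) and `saturated`
#'   (logical).
#' @examples
#' k2p_distance("AAAAAAAAAA", "GAAAAAAAAA")$distance  # -log(0.8)/2
#' @export
k2p_distance <- function(a, b) {
  a <- .as_nt_vector(a)
  b <- .as_nt_vector(b)
  if (length(a) != length(b)) .stop_input("sequences differ in length")
  .k2p_core(match(a, c("A", "C", "G", "T")), match(b, c("A", "C", "G", "T")))
}

.as_nt_vector <- function(x) {
  if (length(x) == 1L && !is.matrix(x)) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0L) .stop_input("invalid characters: ", paste(bad, collapse = ", "))
  x
}

# core on integer-coded sequences (1..4, NA = missing)
.k2p_core <- function(ca, cb) {
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n == 0L) .stop_input("no comparable sites (all gaps/N in one sequence)")
  ca <- ca[ok]
  cb <- cb[ok]
  diff <- ca != cb
  # transitions: A<->G (1,3), C<->T (2,4); purines odd, pyrimidines even
  ts <- diff & ((ca %% 2L) == (cb %% 2L))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(distance = NA_real_, P = P, Q = Q, sites = n, saturated = TRUE))
  }
  # "+ 0" normalizes the negative zero of log(1) for identical sequences
  list(distance = -0.5 * log(w1) - 0.25 * log(w2) + 0, P = P, Q = Q,
       sites = n, saturated = FALSE)
}

#' Pairwise K2P distance matrix with pairwise deletion
#'
#' Computes all pairwise K2P distances for an alignment. Saturated pairs
#' (where the K2P correction is undefined) are flagged in `$saturated` and
#' carry `NA` in `$d`; they are never reported as silent numbers. Per-pair
#' comparable-site counts are recorded in `$sites_used`.
#'
#' @param aln A `barcode_alignment` (see [read_fasta()]).
#' @return A `k2p_dist` object: list with `ids`, `d` (symmetric numeric
#'   matrix, zero diagonal, `NA` where saturated), `saturated` (logical
#'   matrix) and `sites_used` (integer matrix).
#' @export
k2p_matrix <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  code <- .encode_nt(aln$mat)
  n <- aln$n
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  sites <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(sites) <- as.integer(rowSums(!is.na(code)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        res <- tryCatch(.k2p_core(code[i, ], code[j, ]), error = function(e) {
          .stop_input("pair (", aln$ids[i], ", ", aln$ids[j], "): ",
                      conditionMessage(e))
        })
        d[i, j] <- d[j, i] <- res$distance
        sat[i, j] <- sat[j, i] <- res$saturated
        sites[i, j] <- sites[j, i] <- res$sites
      }
    }
  }
  structure(list(ids = aln$ids, d = d, saturated = sat, sites_used = sites),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  cat("K2P distance matrix:", n, "sequences,",
      sum(x$saturated[upper.tri(x$saturated)]), "saturated pair(s)\n")
  if (n >= 2L) {
    off <- x$d[upper.tri(x$d)]
    if (any(!is.na(off))) {
      cat(sprintf("  finite distances: %.4f - %.4f\n",
                  min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' Write a K2P distance matrix
#'
#' `write_k2p_tsv()` writes a square tab-separated matrix with an id header
#' row and column, `NA` marking saturated pairs. `write_k2p_phylip()` writes
#' the square PHYLIP dialect (sequence count on the first line, names
#' truncated/padded to 10 characters) for interoperability.
#'
#' @param x A `k2p_dist` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_k2p_tsv <- function(x, path) {
  stopifnot(inherits(x, "k2p_dist"))
  df <- data.frame(id = x$ids, x$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_k2p_tsv
#' @export
write_k2p_phylip <- function(x, path) {
  stopifnot(inherits(x, "k2p_dist"))
  nm <- formatC(substr(x$ids, 1L, 10L), width = 10L, flag = "-")
  rows <- vapply(seq_along(x$ids), function(i) {
    paste(nm[i], paste(sprintf("%.8f", x$d[i, ]), collapse = "  "))
  }, character(1L))
  writeLines(c(sprintf("%5d", length(x$ids)), rows), path)
  invisible(path)
}

# distances as a plain matrix with saturated pairs at +Inf (ordering only)
.k2p_inf <- function(x) {
  d <- x$d
  d[x$saturated] <- Inf
  d
}
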