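#' Read and validate an aligned barcode FASTA file
#'
#' Reads an aligned FASTA file into a `barcode_alignment` object. Sequences
#' must all have the same length, identifiers must be unique, and only the
#' characters `A`, `C`, `G`, `T`, `-` and `N` are accepted (lowercase input
#' is normalized to uppercase). `-` and `N` are both treated as missing data
#' downstream (pairwise deletion); `N` is deliberately not treated as a
#' wildcard.
#'
#' @param path Path to an aligned FASTA file.
#' @return A `barcode_alignment` object: a list with elements `ids`
#'   (character vector), `mat` (character matrix, one row per sequence),
#'   `n` (number of sequences) and `length` (alignment columns).
#' @seealso [k2p_matrix()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stop_input("FASTA file not found: ", path)
  seqs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(seqs) || length(seqs) == 0L) {
    .stop_input("empty or unreadable FASTA file: ", path)
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    .stop_input("sequences are not aligned: lengths range ",
                min(lens), "-", max(lens))
  }
  chr <- toupper(as.character(as.matrix(seqs)))
  barcode_alignment(rownames(chr), chr)
}

#' Construct a barcode alignment from identifiers and sequences
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character matrix (rows = sequences) or character vector of
#'   equal-length sequence strings over `{A,C,G,T,-,N}`.
#' @return A `barcode_alignment` object.
#' @export
barcode_alignment <- function(ids, seqs) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (length(unique(nchar(seqs))) != 1L) {
      .stop_input("sequences are not aligned: unequal lengths")
    }
    seqs <- toupper(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
  }
  ids <- as.character(ids)
  if (anyNA(ids) || any(ids == "")) .stop_input("missing sequence identifier")
  if (anyDuplicated(ids)) {
    .stop_input("duplicate sequence ids: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (nrow(seqs) != length(ids)) .stop_input("ids and sequences differ in number")
  if (ncol(seqs) < 1L) .stop_input("alignment must have at least one column")
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0L) {
    .stop_input("invalid characters in alignment: ",
                paste(bad, collapse = ", "))
  }
  dimnames(seqs) <- list(ids, NULL)
  structure(list(ids = ids, mat = seqs, n = length(ids), length = ncol(seqs)),
            class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("Barcode alignment:", x$n, "sequences x", x$length, "sites\n")
  invisible(x)
}

#' Write a barcode alignment to FASTA
#'
#' @param aln A `barcode_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "barcode_alignment"))
  lines <- character(2L * aln$n)
  lines[seq(1L, by = 2L, length.out = aln$n)] <- paste0(">", aln$ids)
  lines[seq(2L, by = 2L, length.out = aln$n)] <-
    apply(aln$mat, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# integer coding A=1 C=2 G=3 T=4, NA for - and N
.encode_nt <- function(mat) {
  code <- matrix(match(mat, c("A", "C", "G", "T")), nrow = nrow(mat))
  rownames(code) <- rownames(mat)
  code
}
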