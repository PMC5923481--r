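# Alignment trimming, Walker A anchoring, domain splitting and sequence
# logos. Columns are 0-based half-open throughout; the column carrying the
# first Walker A residue is the first column of the helicase block.

#' Trim gappy alignment columns
#'
#' Retains exactly the columns whose non-gap fraction is at least
#' `gap_keep_fraction` (boundary kept), mirroring TrimAl's gap-threshold
#' column filter. Record order is preserved and the operation is idempotent.
#'
#' @param aln Aligned sequence tibble (`id`, `seq`, equal lengths).
#' @param gap_keep_fraction Minimum non-gap fraction to keep a column,
#'   in (0, 1].
#' @return The trimmed alignment tibble, with an attribute `kept_columns`
#'   giving the retained 0-based source-column indices.
#' @export
trim_columns <- function(aln, gap_keep_fraction = 0.2) {
  aln <- validate_seqs(aln, aligned = TRUE, min_records = 2L)
  stopifnot(gap_keep_fraction > 0, gap_keep_fraction <= 1)
  m <- aln_matrix(aln)
  nongap <- colMeans(m != "-")
  keep <- which(nongap >= gap_keep_fraction)
  if (length(keep) == 0L) {
    stop("trimming removed every column (gap_keep_fraction = ",
         gap_keep_fraction, ")", call. = FALSE)
  }
  out <- matrix_aln(m[, keep, drop = FALSE])
  if ("description" %in% names(aln)) out$description <- aln$description
  attr(out, "kept_columns") <- keep - 1L
  out
}

# Column-wise majority consensus: most frequent non-gap residue per column,
# ties broken alphabetically; all-gap columns give '-'.
consensus_sequence <- function(aln) {
  m <- aln_matrix(aln)
  cons <- apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("-")
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max takes the first = alphabetical min
  })
  paste0(cons, collapse = "")
}

#' Locate the Walker A motif column in an alignment
#'
#' Scans the column-wise majority-consensus sequence for the Walker A P-loop
#' pattern (default `[GA]-x(4)-G-K-[ST]`), restricted to the C-terminal half
#' of the ungapped consensus since the helicase domain is C-terminal. The
#' first residue of the match, mapped back through gap columns, is returned
#' as the 0-based split column.
#'
#' @param aln Aligned sequence tibble.
#' @param pattern Residue-class pattern in PROSITE-like syntax; letters,
#'   bracketed classes `[GA]`, and `x(4)`-style wildcards are supported.
#' @return Integer 0-based alignment column of the first Walker A residue.
#'   If several matches fall in the C-terminal half, the first is used and a
#'   warning is emitted.
#' @export
locate_walker_a <- function(aln, pattern = "[GA]-x(4)-G-K-[ST]") {
  aln <- validate_seqs(aln, aligned = TRUE, min_records = 2L)
  cons <- consensus_sequence(aln)
  cons_chars <- strsplit(cons, "", fixed = TRUE)[[1L]]
  nongap_cols <- which(cons_chars != "-")
  ungapped <- paste0(cons_chars[nongap_cols], collapse = "")
  n <- nchar(ungapped)
  rx <- prosite_to_regex(pattern)
  starts <- gregexpr(rx, ungapped, perl = TRUE)[[1L]]
  starts <- starts[starts > 0]
  half <- floor(n / 2)
  starts <- starts[starts > half]
  if (length(starts) == 0L) {
    stop("Walker A motif (", pattern, ") not found in the C-terminal half ",
         "of the consensus: ", ungapped, call. = FALSE)
  }
  if (length(starts) > 1L) {
    warning("multiple Walker A matches in the C-terminal half at ungapped ",
            "positions ", paste(starts - 1L, collapse = ", "),
            "; using the first", call. = FALSE)
  }
  # Map the ungapped match position back to an alignment column (0-based).
  nongap_cols[starts[1L]] - 1L
}

# PROSITE-like pattern -> PCRE: "[GA]-x(4)-G-K-[ST]" -> "[GA].{4}GK[ST]".
prosite_to_regex <- function(pattern) {
  p <- gsub("-", "", pattern, fixed = TRUE)
  p <- gsub("x\\((\\d+)\\)", ".{\\1}", p)
  gsub("x", ".", p, fixed = TRUE)
}

#' Split a full-length alignment into nuclease and helicase blocks
#'
#' Partitions the alignment columns at `split_column` (0-based): the nuclease
#' block takes columns `[0, split_column)`, the helicase block takes
#' `[split_column, L)`, so the split column itself — the first Walker A
#' residue — starts the helicase block. Per-record concatenation of the two
#' blocks reconstructs the input exactly.
#'
#' @param aln Aligned sequence tibble.
#' @param split_column 0-based column index, `0 < split_column < L`.
#' @return A list of class `domain_split` with elements `split_column`,
#'   `nuclease` and `helicase` (aligned tibbles with identical record order).
#' @export
split_alignment <- function(aln, split_column) {
  aln <- validate_seqs(aln, aligned = TRUE, min_records = 2L)
  L <- aln_length(aln)
  split_column <- as.integer(split_column)
  if (is.na(split_column) || split_column <= 0L || split_column >= L) {
    stop("split_column must satisfy 0 < split_column < ", L,
         "; got ", split_column, call. = FALSE)
  }
  nuc <- tibble::tibble(id = aln$id,
                        seq = substr(aln$seq, 1L, split_column))
  hel <- tibble::tibble(id = aln$id,
                        seq = substr(aln$seq, split_column + 1L, L))
  structure(
    list(split_column = split_column, nuclease = nuc, helicase = hel),
    class = "domain_split"
  )
}

#' @export
print.domain_split <- function(x, ...) {
  cat(sprintf(
    "Domain split at column %d: nuclease %d col, helicase %d col, %d records\n",
    x$split_column, aln_length(x$nuclease), aln_length(x$helicase),
    nrow(x$nuclease)))
  invisible(x)
}

#' Position probability matrix and information content of a motif window
#'
#' Computes per-column amino-acid frequencies over non-gap residues and the
#' information content `log2(20) - H` in bits, where `H` is the column's
#' Shannon entropy. No small-sample correction is applied by default.
#' All-gap columns get zero information and are flagged.
#'
#' @param aln Aligned sequence tibble (typically a domain block).
#' @param window Integer vector of 0-based column indices (range within the
#'   block); default all columns.
#' @param motif_name Label carried into the result.
#' @return A tibble of class `logo_matrix` in long format with columns
#'   `column` (0-based, within the source block), `residue`, `prob`,
#'   `information` (bits, repeated per column) and `all_gap`.
#' @export
logo_matrix <- function(aln, window = NULL, motif_name = "motif") {
  aln <- validate_seqs(aln, aligned = TRUE, min_records = 2L)
  L <- aln_length(aln)
  if (is.null(window)) window <- seq.int(0L, L - 1L)
  window <- as.integer(window)
  if (any(window < 0L | window >= L)) {
    stop("window columns must lie in [0, ", L - 1L, "]", call. = FALSE)
  }
  m <- aln_matrix(aln)[, window + 1L, drop = FALSE]
  per_col <- lapply(seq_along(window), function(j) {
    col <- m[, j]
    col <- col[col != "-" & col != "X"]
    probs <- stats::setNames(rep(0, 20L), AA20)
    if (length(col) == 0L) {
      info <- 0
      all_gap <- TRUE
    } else {
      tab <- table(factor(col, levels = AA20))
      probs[] <- as.numeric(tab) / sum(tab)
      nz <- probs[probs > 0]
      info <- log2(20) - sum(-nz * log2(nz))
      all_gap <- FALSE
    }
    tibble::tibble(column = window[j], residue = AA20,
                   prob = unname(probs), information = info,
                   all_gap = all_gap)
  })
  out <- dplyr::bind_rows(per_col)
  attr(out, "motif_name") <- motif_name
  class(out) <- c("logo_matrix", class(out))
  out
}
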