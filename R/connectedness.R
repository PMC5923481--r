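# Domain "connectedness": all-against-all per-domain similarity ranking and
# the hit-set overlap score. A protein whose nuclease and helicase domains
# co-evolved finds essentially the same proteins among its best hits when
# either domain is used as the query; a chimera does not.

# Degap a vector of (possibly aligned) sequences.
degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Local-alignment similarity of one query against a set of subjects.
# BLOSUM62 with affine gaps (open 11, extend 1) — the standard protein
# search scoring; any monotone E-value-like ranking satisfies the contract.
local_scores <- function(query_seq, subject_seqs) {
  pat <- Biostrings::AAStringSet(degap(subject_seqs))
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = pat,
    subject = Biostrings::AAString(degap(query_seq)),
    type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE
  ))
}

# Full all-against-all score matrix (rows = queries, cols = subjects).
similarity_matrix <- function(seqs) {
  seqs <- validate_seqs(seqs)
  n <- nrow(seqs)
  s <- matrix(NA_real_, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n)) {
    s[i, ] <- local_scores(seqs$seq[i], seqs$seq)
  }
  s
}

#' Rank database hits for one query domain sequence
#'
#' Scores the query against every database record by local alignment
#' (BLOSUM62, affine gaps) and returns the non-self hits in strictly
#' deterministic order: score descending, then subject id ascending.
#'
#' @param query One-row sequence tibble (`id`, `seq`), or a query id present
#'   in `database`.
#' @param database Sequence tibble of the searchable records (may include the
#'   query itself; self hits are excluded by id).
#' @param domain Label, `"nuclease"` or `"helicase"`, carried into the table.
#' @return A tibble with columns `query_id`, `subject_id`, `score`, `rank`
#'   and `domain`.
#' @export
rank_hits <- function(query, database, domain = "nuclease") {
  database <- validate_seqs(database)
  if (is.character(query) && length(query) == 1L) {
    if (!query %in% database$id) {
      stop("query id '", query, "' not in database", call. = FALSE)
    }
    query <- database[database$id == query, ]
  }
  query <- validate_seqs(query)
  stopifnot(nrow(query) == 1L)
  if (nrow(database) < 6L) {
    stop("database must contain at least 6 records", call. = FALSE)
  }
  if (nchar(degap(query$seq)) < 10L) {
    stop("query '", query$id, "' shorter than 10 residues", call. = FALSE)
  }
  db <- database[database$id != query$id, ]
  scores <- local_scores(query$seq, db$seq)
  ord <- order(-scores, db$id, method = "radix")
  tibble::tibble(
    query_id = query$id,
    subject_id = db$id[ord],
    score = scores[ord],
    rank = seq_along(ord),
    domain = domain
  )
}

#' Extract the top fraction of hits
#'
#' Returns the ids of the best `k = max(1, floor(fraction * H))` hits, where
#' `H` is the number of non-self hits — the "top 20% of hits" set by default.
#' The clamp to at least 1 keeps small databases scoreable.
#'
#' @param hit_table Tibble as from [rank_hits()].
#' @param fraction Fraction of hits to keep, in (0, 1].
#' @return Character vector of subject ids (a set, in rank order).
#' @export
top_fraction <- function(hit_table, fraction = 0.2) {
  stopifnot(is.data.frame(hit_table), fraction > 0, fraction <= 1)
  h <- nrow(hit_table)
  if (h == 0L) stop("empty hit table", call. = FALSE)
  k <- max(1L, floor(fraction * h))
  ht <- hit_table[order(hit_table$rank), ]
  ht$subject_id[seq_len(k)]
}

#' Connectedness of a protein's two domain hit sets
#'
#' The connectedness score is the number of ids common to the nuclease and
#' helicase top-hit sets divided by the top-set size (or by the union size if
#' `denominator = "jaccard"`). It estimates the probability that the best
#' hits found with either domain are the same proteins: near 1 for
#' co-evolving domains, below the threshold (default 0.2) for likely
#' recombinants.
#'
#' @param nuclease_top,helicase_top Character vectors of top-hit ids.
#' @param score_threshold Flagging threshold; `flagged <- score < threshold`.
#' @param denominator `"k"` (top-set size; if the two sets differ in size,
#'   the larger) or `"jaccard"` (union size).
#' @return A one-row tibble: `k`, `common`, `score`, `flagged`.
#' @export
connectedness <- function(nuclease_top, helicase_top,
                          score_threshold = 0.2,
                          denominator = c("k", "jaccard")) {
  denominator <- match.arg(denominator)
  nuclease_top <- unique(as.character(nuclease_top))
  helicase_top <- unique(as.character(helicase_top))
  if (length(nuclease_top) == 0L || length(helicase_top) == 0L) {
    stop("empty top-hit set", call. = FALSE)
  }
  common <- length(intersect(nuclease_top, helicase_top))
  k <- max(length(nuclease_top), length(helicase_top))
  denom <- switch(denominator,
                  k = k,
                  jaccard = length(union(nuclease_top, helicase_top)))
  score <- common / denom
  tibble::tibble(k = k, common = common, score = score,
                 flagged = score < score_threshold)
}

#' Connectedness scores for every protein in a domain split
#'
#' Runs the all-against-all comparison for both domains, extracts each
#' protein's top-hit sets and computes its connectedness score.
#'
#' @param split A `domain_split` (from [split_alignment()]) or any list with
#'   sequence tibbles `nuclease` and `helicase` over the same ids.
#' @param config A [rep_config()]; `top_fraction` and `score_threshold` are
#'   used.
#' @param denominator Passed to [connectedness()].
#' @return A tibble with one row per protein: `id`, `k`, `common`, `score`,
#'   `flagged`, plus list-columns `nuclease_top` and `helicase_top`.
#' @export
score_all <- function(split, config = rep_config(),
                      denominator = c("k", "jaccard")) {
  denominator <- match.arg(denominator)
  nuc <- validate_seqs(split$nuclease, min_records = 12L)
  hel <- validate_seqs(split$helicase)
  if (!setequal(nuc$id, hel$id)) {
    stop("nuclease and helicase ids differ", call. = FALSE)
  }
  hel <- hel[match(nuc$id, hel$id), ]
  sm_nuc <- similarity_matrix(nuc)
  sm_hel <- similarity_matrix(hel)
  ids <- nuc$id
  rows <- lapply(seq_along(ids), function(i) {
    others <- ids[-i]
    top_of <- function(sm) {
      sc <- sm[i, -i]
      ord <- order(-sc, others, method = "radix")
      k <- max(1L, floor(config$top_fraction * length(others)))
      others[ord][seq_len(k)]
    }
    nt <- top_of(sm_nuc)
    ht <- top_of(sm_hel)
    res <- connectedness(nt, ht, config$score_threshold, denominator)
    dplyr::mutate(res, id = ids[i],
                  nuclease_top = list(nt), helicase_top = list(ht),
                  .before = 1L)
  })
  dplyr::bind_rows(rows)
}
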