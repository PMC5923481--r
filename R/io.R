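#' Read amino-acid sequences from a FASTA file
#'
#' Reads a (possibly gapped) protein FASTA file into a tibble with one row per
#' record. The id is the header token up to the first whitespace; the rest of
#' the header line is kept as `description`. The alternative gap character
#' `"."` is normalised to `"-"` on read so the rest of the package only ever
#' sees one gap convention.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description` and `seq` (upper-case
#'   residues over the 20 amino-acid letters plus `X` and `-`), in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some rep", "MKL", ">b", "MKV"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(aa) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  bad <- grepl("[^A-Z\\-]", seqs) | !nzchar(seqs)
  if (any(bad)) {
    stop("invalid residues (or empty sequence) in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(id = unname(ids), description = unname(desc),
                 seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' Writes a sequence tibble (as returned by [read_fasta()]) as standard FASTA
#' with 60-column line wrapping. Gap characters are preserved.
#'
#' @param seqs Tibble with columns `id` and `seq` (optionally `description`).
#' @param path Output path.
#' @return The output path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- validate_seqs(seqs)
  if (nrow(seqs) == 0L) stop("no records to write", call. = FALSE)
  hdr <- seqs$id
  if ("description" %in% names(seqs)) {
    has_desc <- !is.na(seqs$description) & nzchar(seqs$description)
    hdr[has_desc] <- paste(seqs$id[has_desc], seqs$description[has_desc])
  }
  x <- Biostrings::BStringSet(seqs$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

# Shared validator: id/seq columns, non-empty, unique ids, legal residues.
validate_seqs <- function(seqs, aligned = FALSE, min_records = 1L) {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    stop("expected a data frame with columns 'id' and 'seq'", call. = FALSE)
  }
  seqs <- tibble::as_tibble(seqs)
  if (nrow(seqs) < min_records) {
    stop("need at least ", min_records, " records, got ", nrow(seqs),
         call. = FALSE)
  }
  if (anyDuplicated(seqs$id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(seqs$id))) stop("empty sequence id", call. = FALSE)
  if (any(!nzchar(seqs$seq))) stop("empty sequence", call. = FALSE)
  if (aligned && length(unique(nchar(seqs$seq))) != 1L) {
    stop("sequences are not aligned: unequal lengths", call. = FALSE)
  }
  seqs
}

# Alignment accessor: number of columns of an aligned sequence tibble.
aln_length <- function(aln) {
  nchar(aln$seq[1L])
}

# Aligned tibble -> character matrix (rows = records, columns = positions).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

# Character matrix -> aligned tibble (ids from rownames).
matrix_aln <- function(m) {
  tibble::tibble(id = rownames(m),
                 seq = unname(apply(m, 1L, paste0, collapse = "")))
}

#' Read a Newick tree with branch supports
#'
#' Reads a Newick file with [ape::read.tree()]. Internal-node labels are
#' interpreted as branch supports; numeric labels in `[0, 1]` (e.g. aBayes
#' posteriors) are rescaled to percentages so that the whole package uses one
#' support scale, 0-100. Missing labels are kept as `NA` ("unknown"), never
#' coerced to 0.
#'
#' @param path Path to a Newick file.
#' @return An object of class `phylo` whose `node.label` is a numeric vector
#'   of percentage supports (with `NA` for unknown).
#' @export
read_newick <- function(path) {
  tr <- tryCatch(
    ape::read.tree(path),
    error = function(e) {
      stop("malformed Newick in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(tr)) stop("malformed Newick in '", path, "'", call. = FALSE)
  normalize_supports(tr)
}

# Coerce node labels to numeric percentage supports; "" -> NA; 0-1 -> 0-100.
normalize_supports <- function(tr) {
  if (is.null(tr$node.label)) {
    tr$node.label <- rep(NA_real_, tr$Nnode)
    return(tr)
  }
  lab <- as.character(tr$node.label)
  lab[!nzchar(lab)] <- NA_character_
  sup <- suppressWarnings(as.numeric(lab))
  finite <- sup[is.finite(sup)]
  if (length(finite) > 0L && all(finite >= 0) && all(finite <= 1) &&
      any(finite > 0 & finite < 1)) {
    sup <- sup * 100
  }
  tr$node.label <- sup
  tr
}

#' Write a tree to a Newick file
#'
#' Supports (numeric `node.label`) are written as internal-node labels;
#' unknown (`NA`) supports are written as empty labels.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return The output path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$node.label)) {
    lab <- as.character(tree$node.label)
    lab[is.na(lab)] <- ""
    tree$node.label <- lab
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Run configuration for the chimera-detection pipeline
#'
#' Bundles every tunable threshold of the pipeline with the defaults used
#' throughout: keep the top 20% of similarity hits per domain, flag
#' connectedness below 0.2, keep alignment columns with at least 20% non-gap
#' residues, collapse branches below 70% support, and flag leaves whose
#' domain-tree neighborhoods differ by a Jaccard distance above 0.8.
#'
#' @param top_fraction Fraction of non-self hits kept per domain, in (0, 1].
#' @param score_threshold Connectedness below which a protein is flagged,
#'   in \[0, 1\].
#' @param gap_keep_fraction Minimum non-gap fraction for an alignment column
#'   to be kept, in (0, 1].
#' @param support_collapse Percentage support below which branches are
#'   collapsed (0-100).
#' @param bootstrap_reps Number of bootstrap replicates for branch support.
#' @param seed Integer seed governing all randomness downstream.
#' @param displacement_threshold Displacement above which a leaf is flagged,
#'   in \[0, 1\].
#' @param neighborhood_min Minimum number of other leaves in a displacement
#'   neighborhood.
#' @return A list of class `rep_config`.
#' @export
rep_config <- function(top_fraction = 0.2,
                       score_threshold = 0.2,
                       gap_keep_fraction = 0.2,
                       support_collapse = 70,
                       bootstrap_reps = 100,
                       seed = 1L,
                       displacement_threshold = 0.8,
                       neighborhood_min = 5L) {
  cfg <- list(
    top_fraction = as.numeric(top_fraction),
    score_threshold = as.numeric(score_threshold),
    gap_keep_fraction = as.numeric(gap_keep_fraction),
    support_collapse = as.numeric(support_collapse),
    bootstrap_reps = as.integer(bootstrap_reps),
    seed = as.integer(seed),
    displacement_threshold = as.numeric(displacement_threshold),
    neighborhood_min = as.integer(neighborhood_min)
  )
  with(cfg, {
    stopifnot(
      top_fraction > 0, top_fraction <= 1,
      score_threshold >= 0, score_threshold <= 1,
      gap_keep_fraction > 0, gap_keep_fraction <= 1,
      support_collapse >= 0, support_collapse <= 100,
      bootstrap_reps >= 1,
      displacement_threshold >= 0, displacement_threshold <= 1,
      neighborhood_min >= 1
    )
  })
  structure(cfg, class = "rep_config")
}

#' Read a key=value configuration file
#'
#' Plain-text `key=value` lines (one per line, `#` comments allowed) override
#' the [rep_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A `rep_config` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && any(!grepl("=", lines, fixed = TRUE))) {
    stop("config lines must be key=value: ",
         paste(lines[!grepl("=", lines, fixed = TRUE)], collapse = "; "),
         call. = FALSE)
  }
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  known <- names(formals(rep_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(rep_config, args)
}

#' @export
print.rep_config <- function(x, ...) {
  cat("Chimera-detection run configuration\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
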