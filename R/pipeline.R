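# End-to-end screen: split -> score -> trees -> call -> purge -> regroup.
# The two detectors are complementary: the connectedness score is sensitive
# to recent domain swaps among close relatives, the tree-displacement
# statistic to older transfers across clades. Their conflicts are never
# auto-resolved; a sequence flagged by exactly one detector lands in a
# "review" tier, mirroring a manual-inspection step.

#' Combine the two detectors into per-protein chimera calls
#'
#' A protein flagged by both the connectedness score and the tree
#' displacement is called `"chimera"`; by exactly one, `"review"`; by
#' neither, `"clean"`. With `strict = TRUE` the review tier is treated as
#' chimera (union rule).
#'
#' @param connectedness_results Tibble from [score_all()].
#' @param displacements Tibble from [leaf_displacement()].
#' @param strict Treat single-flag cases as chimeras.
#' @return A tibble with `id`, `score`, `displacement`, `score_flag`,
#'   `tree_flag`, `tier`.
#' @export
call_chimeras <- function(connectedness_results, displacements,
                          strict = FALSE) {
  cn <- tibble::as_tibble(connectedness_results)
  dp <- tibble::as_tibble(displacements)
  if (!setequal(cn$id, dp$id)) {
    stop("id sets differ between connectedness and displacement results: ",
         paste(c(setdiff(cn$id, dp$id), setdiff(dp$id, cn$id)),
               collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::inner_join(
    dplyr::select(cn, "id", score = "score", score_flag = "flagged"),
    dplyr::select(dp, "id", displacement = "displacement",
                  tree_flag = "flagged"),
    by = "id"
  )
  out <- dplyr::mutate(
    out,
    tier = dplyr::case_when(
      .data$score_flag & .data$tree_flag ~ "chimera",
      .data$score_flag | .data$tree_flag ~ "review",
      TRUE ~ "clean"
    )
  )
  if (strict) {
    out$tier[out$tier == "review"] <- "chimera"
  }
  dplyr::arrange(out, .data$id)
}

#' Purge called chimeras from a sequence set
#'
#' @param records Sequence tibble (`id`, `seq`).
#' @param calls Tibble from [call_chimeras()] covering all record ids.
#' @param mode `"default"` removes tier `"chimera"` only; `"strict"` also
#'   removes `"review"`.
#' @return A list with `kept` (sequence tibble) and `removed` (character
#'   vector of removed ids).
#' @export
purge <- function(records, calls, mode = c("default", "strict")) {
  mode <- match.arg(mode)
  records <- validate_seqs(records)
  calls <- tibble::as_tibble(calls)
  if (!all(records$id %in% calls$id)) {
    stop("calls do not cover record id(s): ",
         paste(setdiff(records$id, calls$id), collapse = ", "),
         call. = FALSE)
  }
  drop_tiers <- if (mode == "strict") c("chimera", "review") else "chimera"
  removed <- calls$id[calls$tier %in% drop_tiers]
  removed <- intersect(records$id, removed)
  list(kept = records[!records$id %in% removed, ],
       removed = removed)
}

#' Dataset-reduction summary line
#'
#' Formats the purge outcome the way dataset filtering is usually reported:
#' e.g. keeping 380 of 647 sequences is "a 41% reduction".
#'
#' @param n_before,n_kept Sequence counts before and after purging.
#' @return A string like `"380 of 647 sequences kept (a 41% reduction)"`.
#' @export
reduction_report <- function(n_before, n_kept) {
  stopifnot(n_before >= n_kept, n_before > 0)
  pct <- round(100 * (1 - n_kept / n_before))
  sprintf("%d of %d sequences kept (a %d%% reduction)", n_kept, n_before, pct)
}

#' Recover well-supported monophyletic groups
#'
#' Contracts every internal edge below `min_support` into a polytomy, then
#' decomposes the collapsed tree from its basal node: a clade whose stem
#' support meets the threshold and which has at least `min_size` leaves is a
#' candidate group; it is reported whole unless it decomposes into two or
#' more candidate groups, or into one candidate group plus at least
#' `min_size` unassigned leaves, in which case the subgroups are reported
#' instead. A well-supported union of two families is thus split into the
#' families, and a large unplaced block is never absorbed into a
#' neighbouring group, while a family that merely contains one supported
#' subclade (plus a few stray leaves) stays whole.
#' After the collapse every internal edge of a reported group meets the
#' threshold, and groups are disjoint by construction.
#'
#' @param tree A `phylo` with numeric percentage `node.label`.
#' @param min_support Minimum internal-edge support percentage.
#' @param min_size Minimum group size in leaves.
#' @return A tibble with `group`, `size`, `min_support` and a list-column
#'   `members`; empty if no clade qualifies.
#' @export
find_supported_groups <- function(tree, min_support = 70, min_size = 5L) {
  stopifnot(inherits(tree, "phylo"))
  # midpoint-root first: the midpoint falls on the long path between
  # divergent groups, never inside a tight one, so no group is left
  # paraphyletic around an arbitrary basal node
  rooted <- tryCatch(
    normalize_supports(phangorn::midpoint(normalize_supports(tree),
                                          node.labels = "support")),
    error = function(e) normalize_supports(tree)
  )
  collapsed <- suppressWarnings(
    collapse_low_support(rooted, min_support)
  )
  nested <- phylo_to_nested(collapsed)
  min_support_of <- function(node) {
    if (is.null(node$children)) return(Inf)
    suppressWarnings(
      min(node$support, vapply(node$children, min_support_of, 0),
          na.rm = TRUE)
    )
  }
  n_leaves <- function(node) length(nested_leaves(node))
  # Groups found strictly inside `node` (node itself is not a candidate).
  collect <- function(node) {
    res <- list()
    for (child in node$children) {
      if (is.null(child$children)) next
      if (!is.na(child$support) && child$support >= min_support &&
          n_leaves(child) >= min_size) {
        sub <- collect(child)
        extra <- n_leaves(child) -
          sum(vapply(sub, function(g) length(g$members), 0L))
        # absorb unassigned leaves only when too few to have formed a
        # group of their own
        if (length(sub) >= 2L || (length(sub) == 1L && extra >= min_size)) {
          res <- c(res, sub)
        } else {
          res <- c(res, list(list(members = sort(nested_leaves(child)),
                                  min_support = min_support_of(child))))
        }
      } else {
        res <- c(res, collect(child))
      }
    }
    res
  }
  groups <- collect(nested)
  if (length(groups) == 0L) {
    return(tibble::tibble(group = character(0), size = integer(0),
                          min_support = numeric(0), members = list()))
  }
  sizes <- vapply(groups, function(g) length(g$members), 0L)
  ord <- order(-sizes, vapply(groups, function(g) g$members[1L], ""))
  groups <- groups[ord]
  tibble::tibble(
    group = sprintf("G%d", seq_along(groups)),
    size = vapply(groups, function(g) length(g$members), 0L),
    min_support = vapply(groups, function(g) g$min_support, 0),
    members = lapply(groups, function(g) g$members)
  )
}

#' Run the full chimera-detection pipeline
#'
#' Executes every stage on an aligned full-length protein set: locate the
#' Walker A anchor and split the alignment; score domain connectedness on
#' the full domain sequences; build per-domain trees from the trimmed domain
#' blocks (NJ + bootstrap), collapse weak branches and measure per-leaf
#' displacement; combine the two detectors into tiered calls; purge called
#' chimeras; rebuild the full-length tree from the purged, trimmed alignment
#' and extract well-supported monophyletic groups; and compute the Walker A
#' logo. With `out_dir` set, the complete report bundle is written as
#' plain-text TSV/FASTA/Newick files plus a run manifest; identical inputs
#' and config produce a byte-identical bundle.
#'
#' @param aln Aligned full-length sequence tibble (or path to an aligned
#'   FASTA file).
#' @param config A [rep_config()].
#' @param out_dir Optional output directory for the report bundle.
#' @param purge_mode Passed to [purge()].
#' @return An object of class `rep_screen`: a list with `calls`,
#'   `connectedness`, `displacement`, `tanglegram`, `split_column`, `trees`
#'   (nuclease/helicase/full, support-labelled), `groups`, `purged`,
#'   `removed`, `logo_walker_a` and `config`.
#' @export
run_pipeline <- function(aln, config = rep_config(), out_dir = NULL,
                         purge_mode = c("default", "strict")) {
  purge_mode <- match.arg(purge_mode)
  if (is.character(aln) && length(aln) == 1L) aln <- read_fasta(aln)
  aln <- validate_seqs(aln, aligned = TRUE, min_records = 12L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  split_col <- stage("split", locate_walker_a(aln))
  split <- stage("split", split_alignment(aln, split_col))

  conn <- stage("connectedness", score_all(split, config))

  nuc_trim <- stage("trees", trim_columns(split$nuclease,
                                          config$gap_keep_fraction))
  hel_trim <- stage("trees", trim_columns(split$helicase,
                                          config$gap_keep_fraction))
  tree_nuc <- stage("trees", bootstrap_support(nuc_trim,
                                               config$bootstrap_reps,
                                               seed = config$seed + 11L))
  tree_hel <- stage("trees", bootstrap_support(hel_trim,
                                               config$bootstrap_reps,
                                               seed = config$seed + 12L))
  coll_nuc <- stage("trees", collapse_low_support(tree_nuc,
                                                  config$support_collapse))
  coll_hel <- stage("trees", collapse_low_support(tree_hel,
                                                  config$support_collapse))

  tangle <- stage("tanglegram", tanglegram_order(coll_nuc, coll_hel))
  disp <- stage("displacement",
                leaf_displacement(coll_nuc, coll_hel,
                                  config$neighborhood_min,
                                  config$displacement_threshold))

  calls <- stage("call", call_chimeras(conn, disp))
  purged <- stage("purge", purge(aln, calls, purge_mode))

  full_trim <- stage("group", trim_columns(purged$kept,
                                           config$gap_keep_fraction))
  tree_full <- stage("group", bootstrap_support(full_trim,
                                                config$bootstrap_reps,
                                                seed = config$seed + 13L))
  groups <- stage("group", find_supported_groups(tree_full,
                                                 config$support_collapse,
                                                 min_size = 5L))

  logo <- stage("logo", logo_matrix(aln,
                                    window = seq.int(split_col,
                                                     split_col + 7L),
                                    motif_name = "Walker A"))

  res <- structure(
    list(calls = calls, connectedness = conn, displacement = disp,
         tanglegram = tangle, split_column = split_col,
         trees = list(nuclease = tree_nuc, helicase = tree_hel,
                      full = tree_full),
         groups = groups, purged = purged$kept, removed = purged$removed,
         logo_walker_a = logo, config = config,
         n_input = nrow(aln)),
    class = "rep_screen"
  )
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

#' @export
print.rep_screen <- function(x, ...) {
  tiers <- table(factor(x$calls$tier, c("chimera", "review", "clean")))
  cat("Chimera screen of", x$n_input, "proteins\n")
  cat(sprintf("  domain split at alignment column %d\n", x$split_column))
  cat(sprintf("  calls: %d chimera, %d review, %d clean\n",
              tiers[["chimera"]], tiers[["review"]], tiers[["clean"]]))
  cat(" ", reduction_report(x$n_input, nrow(x$purged)), "\n")
  cat(sprintf("  %d supported group(s) in the purged full-length tree\n",
              nrow(x$groups)))
  invisible(x)
}

# Deterministic TSV writer: tab-separated, header, no quoting; list-columns
# are collapsed to comma-joined strings.
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) {
      vapply(col, function(x) paste(x, collapse = ","), "")
    } else if (is.numeric(col)) {
      formatC(col, format = "g", digits = 10)
    } else {
      as.character(col)
    }
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Write the full report bundle for a rep_screen into a directory.
write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv_plain(tibble::tibble(split_column = res$split_column,
                                 n_records = res$n_input),
                  p("split_report.tsv"))
  write_tsv_plain(res$connectedness, p("connectedness.tsv"))
  write_newick(res$trees$nuclease, p("nuclease_tree.nwk"))
  write_newick(res$trees$helicase, p("helicase_tree.nwk"))
  write_tsv_plain(tibble::tibble(
    position = seq_along(res$tanglegram$order1),
    nuclease_leaf = res$tanglegram$order1,
    helicase_leaf = res$tanglegram$order2,
    crossings = res$tanglegram$crossings
  ), p("tanglegram.tsv"))
  write_tsv_plain(res$displacement, p("displacement.tsv"))
  write_tsv_plain(res$calls, p("calls.tsv"))
  write_fasta(res$purged, p("purged.fasta"))
  write_newick(res$trees$full, p("purged_tree.nwk"))
  write_tsv_plain(res$groups, p("groups.tsv"))
  write_tsv_plain(res$logo_walker_a, p("logo_walker_a.tsv"))

  cfg_lines <- vapply(names(res$config), function(k) {
    sprintf("%s=%s", k, format(res$config[[k]]))
  }, "")
  tf <- tempfile()
  writeLines(cfg_lines, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest <- c(
    sprintf("package=repchimera %s",
            as.character(utils::packageVersion("repchimera"))),
    cfg_lines,
    sprintf("config_md5=%s", cfg_hash),
    sprintf("n_input=%d", res$n_input),
    sprintf("n_removed=%d", length(res$removed)),
    sprintf("reduction=%s", reduction_report(res$n_input, nrow(res$purged)))
  )
  writeLines(manifest, p("manifest.txt"))
  invisible(out_dir)
}
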