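# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately re-derive results by the most naive route
# available (per-pair scoring, exhaustive enumeration, direct Monte Carlo)
# and never call the code paths they check.

# ---- fixtures -------------------------------------------------------------

# Aligned tibble from a character vector of equal-length strings.
make_aln <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = seqs)
}

# Alignment built column-by-column: `cols` is a list of character vectors,
# one per column, each of length n.
aln_from_columns <- function(cols) {
  m <- do.call(cbind, cols)
  make_aln(apply(m, 1L, paste0, collapse = ""))
}

# Random unaligned protein-like sequences (no gaps).
random_seqs <- function(n, len, seed) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  withr::with_seed(seed, {
    make_aln(replicate(n, paste0(sample(aa, len, TRUE), collapse = "")))
  })
}

# Mutate `k` distinct positions of a sequence to a fixed different residue.
mutate_positions <- function(seq, positions, to = "W") {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ch[positions] <- ifelse(ch[positions] == to, "Y", to)
  paste0(ch, collapse = "")
}

# ---- brute-force connectedness oracle ------------------------------------

oracle_pair_score <- function(a, b) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("-", "", a, fixed = TRUE)),
    Biostrings::AAString(gsub("-", "", b, fixed = TRUE)),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
  ))
}

# Naive per-pair scores, naive sort, naive intersection count.
oracle_connectedness <- function(nuc, hel, top_frac, threshold) {
  ids <- nuc$id
  hel <- hel[match(ids, hel$id), ]
  n <- length(ids)
  top_set <- function(seqs, i) {
    others <- setdiff(seq_len(n), i)
    sc <- vapply(others, function(j) {
      oracle_pair_score(seqs$seq[i], seqs$seq[j])
    }, 0)
    ord <- order(-sc, ids[others], method = "radix")
    k <- max(1L, floor(top_frac * length(others)))
    ids[others][ord][seq_len(k)]
  }
  rows <- lapply(seq_len(n), function(i) {
    nt <- top_set(nuc, i)
    ht <- top_set(hel, i)
    common <- 0L
    for (x in nt) if (any(ht == x)) common <- common + 1L
    k <- max(length(nt), length(ht))
    tibble::tibble(id = ids[i], k = k, common = common, score = common / k,
                   flagged = common / k < threshold)
  })
  dplyr::bind_rows(rows)
}

# ---- exhaustive tanglegram oracle ----------------------------------------

# All leaf orders of a rooted binary phylo reachable by rotating internal
# nodes, derived straight from the edge matrix.
oracle_all_orders <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  rec <- function(node) {
    if (node <= ntip) return(list(tr$tip.label[node]))
    sub <- lapply(kids[[as.character(node)]], rec)
    stopifnot(length(sub) == 2L)
    out <- list()
    for (pm in list(1:2, 2:1)) {
      for (left in sub[[pm[1L]]]) {
        for (right in sub[[pm[2L]]]) {
          out[[length(out) + 1L]] <- c(left, right)
        }
      }
    }
    unique(out)
  }
  rec(ntip + 1L)
}

oracle_crossings <- function(o1, o2) {
  p <- match(o1, o2)
  n <- length(p)
  s <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (p[j] < p[i]) s <- s + 1L
    }
  }
  s
}

oracle_min_crossings <- function(t1, t2) {
  best <- Inf
  for (o1 in oracle_all_orders(t1)) {
    for (o2 in oracle_all_orders(t2)) {
      cr <- oracle_crossings(o1, o2)
      if (cr < best) best <- cr
      if (best == 0L) return(0L)
    }
  }
  best
}

# ---- Monte-Carlo substitution oracle -------------------------------------

# Simulate the per-branch replacement process directly along a path of
# branch lengths and estimate the end-to-end mismatch probability.
oracle_mismatch_prob <- function(branches, n_sites = 40000L, seed = 1L) {
  withr::with_seed(seed, {
    start <- sample.int(20L, n_sites, replace = TRUE)
    cur <- start
    for (t in branches) {
      hit <- stats::runif(n_sites) < (1 - exp(-t))
      cur[hit] <- sample.int(20L, sum(hit), replace = TRUE)
    }
    mean(cur != start)
  })
}

# Observed mismatch fraction between two equal-length ungapped sequences.
p_dist <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca != cb)
}

# ---- shared detection runs (computed once, reused across tests) ----------

.acc_cache <- new.env(parent = emptyenv())

detection_runs <- function() {
  if (!is.null(.acc_cache$runs)) return(.acc_cache$runs)
  runs <- lapply(1:10, function(s) {
    sim <- simulate_rep_family(sim_spec(seed = s))
    res <- run_pipeline(sim$sequences, rep_config(seed = s))
    scored <- dplyr::inner_join(tidy(res),
                                sim$truth[, c("id", "is_chimera",
                                              "nuclease_clade",
                                              "helicase_clade")],
                                by = "id")
    list(sim = sim, res = res, scored = scored)
  })
  .acc_cache$runs <- runs
  runs
}

null_runs <- function() {
  if (!is.null(.acc_cache$null)) return(.acc_cache$null)
  runs <- lapply(1:3, function(s) {
    sim <- simulate_rep_family(sim_spec(chimera_fraction = 0, seed = s))
    res <- run_pipeline(sim$sequences, rep_config(seed = s))
    list(sim = sim, res = res)
  })
  .acc_cache$null <- runs
  runs
}
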