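# Synthetic two-domain protein families with planted domain swaps.
#
# The generator emulates the statistical structure the detector assumes:
# several divergent clades of proteins made of an N-terminal nuclease domain
# (conserved HUH motifs I-III) and a C-terminal helicase domain (Walker A,
# Walker B, motif C, arginine finger), with a controllable fraction of taxa
# whose helicase descends from a different clade than their nuclease.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate expr under a private RNG stream; the caller's RNG is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Conserved-motif masks for the two Rep domains
#'
#' Positions covered by a motif never mutate during simulation, mimicking the
#' strong purifying selection on the HUH endonuclease motifs I-III and on the
#' helicase Walker A / Walker B / motif C / arginine-finger motifs. The
#' helicase mask places Walker A (`GPPGTGKT`, matching the default
#' `[GA]-x(4)-G-K-[ST]` detection pattern) at offset 0, so the helicase domain
#' begins at the Walker A motif exactly as the domain split assumes. The
#' remaining motifs sit at fixed fractions of the domain length, so the masks
#' fit any domain lengths above a few dozen residues.
#'
#' @param nuclease_len,helicase_len Domain lengths the masks must fit.
#' @return A list with elements `nuclease` and `helicase`, each a tibble with
#'   columns `offset` (0-based) and `motif`.
#' @export
default_motif_masks <- function(nuclease_len = 160L, helicase_len = 120L) {
  stopifnot(nuclease_len >= 20L, helicase_len >= 30L)
  list(
    nuclease = tibble::tibble(
      offset = as.integer(round(c(0.10, 0.35, 0.60) * nuclease_len)),
      motif = c("FTLNN", "HLHG", "YSSK")
    ),
    helicase = tibble::tibble(
      offset = c(0L, as.integer(round(c(0.33, 0.62, 0.83) * helicase_len))),
      motif = c("GPPGTGKT", "ILFDDI", "ITSN", "FRR")
    )
  )
}

#' Specify a synthetic two-domain protein family
#'
#' @param n_clades Number of clades (>= 2).
#' @param taxa_per_clade Taxa per clade (>= 3); total taxa must be >= 12.
#' @param chimera_fraction Fraction of taxa whose helicase is swapped in from
#'   another clade, in \[0, 1).
#' @param nuclease_len,helicase_len Domain lengths in residues.
#' @param inter_clade_divergence Expected substitutions/site between taxa of
#'   different clades.
#' @param intra_clade_divergence Expected substitutions/site between taxa of
#'   the same clade; must be smaller than `inter_clade_divergence`.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_clades = 4L,
                     taxa_per_clade = 12L,
                     chimera_fraction = 0.3,
                     nuclease_len = 160L,
                     helicase_len = 120L,
                     inter_clade_divergence = 1.0,
                     intra_clade_divergence = 0.2,
                     seed = 1L) {
  spec <- list(
    n_clades = as.integer(n_clades),
    taxa_per_clade = as.integer(taxa_per_clade),
    chimera_fraction = as.numeric(chimera_fraction),
    nuclease_len = as.integer(nuclease_len),
    helicase_len = as.integer(helicase_len),
    inter_clade_divergence = as.numeric(inter_clade_divergence),
    intra_clade_divergence = as.numeric(intra_clade_divergence),
    seed = as.integer(seed)
  )
  if (spec$n_clades < 2L) {
    stop("n_clades must be >= 2", call. = FALSE)
  }
  if (spec$taxa_per_clade < 3L) {
    stop("taxa_per_clade must be >= 3", call. = FALSE)
  }
  if (spec$n_clades * spec$taxa_per_clade < 12L) {
    stop("total taxa must be >= 12", call. = FALSE)
  }
  if (spec$chimera_fraction < 0 || spec$chimera_fraction >= 1) {
    stop("chimera_fraction must be in [0, 1)", call. = FALSE)
  }
  if (spec$inter_clade_divergence <= spec$intra_clade_divergence) {
    stop("inter_clade_divergence must exceed intra_clade_divergence",
         call. = FALSE)
  }
  structure(spec, class = "sim_spec")
}

#' Simulate the guide tree of a clade-structured family
#'
#' Builds a rooted tree with `n_clades` monophyletic blocks of
#' `taxa_per_clade` leaves each. Within a clade the subtree is a random
#' coalescent scaled so two clade members diverge by about
#' `intra_clade_divergence` substitutions/site; clade stems are set so taxa
#' of different clades diverge by about `inter_clade_divergence`.
#' Tips are labelled `c<k>_t<j>`.
#'
#' @param spec A [sim_spec()].
#' @return A rooted `phylo` object.
#' @export
simulate_clade_tree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    depth <- spec$intra_clade_divergence / 2
    stem <- (spec$inter_clade_divergence - spec$intra_clade_divergence) / 2
    parts <- character(spec$n_clades)
    for (k in seq_len(spec$n_clades)) {
      cl <- ape::rcoal(spec$taxa_per_clade,
                       tip.label = sprintf("c%d_t%d", k,
                                           seq_len(spec$taxa_per_clade)))
      h <- max(ape::node.depth.edgelength(cl))
      cl$edge.length <- cl$edge.length * (depth / h)
      nwk <- sub(";$", "", ape::write.tree(cl))
      parts[k] <- sprintf("%s:%.10f", nwk, stem)
    }
    ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
  })
}

# Positions (1-based) covered by a motif mask.
mask_positions <- function(mask, len) {
  if (is.null(mask) || nrow(mask) == 0L) return(integer(0))
  pos <- unlist(lapply(seq_len(nrow(mask)), function(i) {
    seq(mask$offset[i] + 1L, mask$offset[i] + nchar(mask$motif[i]))
  }))
  if (length(pos) > 0L && max(pos) > len) {
    stop("motif mask extends beyond the sequence (length ", len, ")",
         call. = FALSE)
  }
  sort(unique(pos))
}

# Write the motif strings into a root sequence at their fixed offsets.
apply_mask <- function(seq, mask) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(mask))) {
    m <- strsplit(mask$motif[i], "", fixed = TRUE)[[1L]]
    chars[seq(mask$offset[i] + 1L, mask$offset[i] + length(m))] <- m
  }
  paste0(chars, collapse = "")
}

#' Evolve a protein domain along a tree
#'
#' Per-site amino-acid replacement under an equal-input model: on a branch of
#' length `t` (expected substitutions/site) each unmasked site is replaced
#' with probability `1 - exp(-t)` by a residue drawn uniformly from the 20
#' amino acids (so the equilibrium mismatch probability is 19/20 = 0.95).
#' Positions covered by the motif mask never mutate. No indels are produced,
#' so the leaf sequences are mutually aligned by construction.
#'
#' @param tree A rooted `phylo` object.
#' @param root_sequence Character scalar, the sequence at the root.
#' @param mask Tibble with columns `offset` (0-based) and `motif`, or `NULL`.
#' @param seed Integer seed.
#' @return A tibble with columns `id` (tip labels) and `seq`.
#' @export
evolve_domain <- function(tree, root_sequence, mask = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), is.character(root_sequence))
  len <- nchar(root_sequence)
  masked <- mask_positions(mask, len)
  if (!is.null(mask) && nrow(mask) > 0L) {
    root_sequence <- apply_mask(root_sequence, mask)
  }
  free <- setdiff(seq_len(len), masked)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- ape::reorder.phylo(tree, "cladewise")
  with_seed(seed, {
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- strsplit(root_sequence, "", fixed = TRUE)[[1L]]
    for (i in seq_len(nrow(edges$edge))) {
      parent <- edges$edge[i, 1L]
      child <- edges$edge[i, 2L]
      t <- edges$edge.length[i]
      s <- node_seq[[parent]]
      if (t > 0 && length(free) > 0L) {
        hit <- free[stats::runif(length(free)) < (1 - exp(-t))]
        if (length(hit) > 0L) {
          s[hit] <- sample(AA20, length(hit), replace = TRUE)
        }
      }
      node_seq[[child]] <- s
    }
    tibble::tibble(
      id = tree$tip.label,
      seq = vapply(node_seq[seq_len(ntip)], paste0, "", collapse = "")
    )
  })
}

#' Plant domain-swap chimeras
#'
#' For `floor(fraction * n)` randomly chosen taxa, the helicase domain is
#' replaced by the helicase of a random taxon from a different clade (donor
#' clade uniform over the other clades, then donor taxon uniform within it).
#' The full-length sequence is the concatenation nuclease + helicase.
#'
#' @param nuclease,helicase Sequence tibbles (`id`, `seq`) over the same ids.
#' @param clades Tibble with columns `id` and `clade` giving each taxon's
#'   true clade.
#' @param fraction Fraction of taxa to chimerize, in \[0, 1).
#' @param seed Integer seed.
#' @return A list with `records` (tibble `id`, `seq`: full-length sequences)
#'   and `truth` (tibble `id`, `nuclease_clade`, `helicase_clade`,
#'   `is_chimera`, `donor_id`).
#' @export
plant_chimeras <- function(nuclease, helicase, clades, fraction, seed = 1L) {
  nuclease <- validate_seqs(nuclease)
  helicase <- validate_seqs(helicase)
  if (!setequal(nuclease$id, helicase$id)) {
    stop("nuclease and helicase record ids differ", call. = FALSE)
  }
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  clades <- tibble::as_tibble(clades)
  stopifnot(all(c("id", "clade") %in% names(clades)))
  helicase <- helicase[match(nuclease$id, helicase$id), ]
  clade_of <- clades$clade[match(nuclease$id, clades$id)]
  if (anyNA(clade_of)) stop("clade map does not cover all ids", call. = FALSE)
  n <- nrow(nuclease)
  n_chim <- floor(fraction * n)
  if (n_chim > 0L && length(unique(clade_of)) < 2L) {
    stop("chimeras require at least 2 clades", call. = FALSE)
  }
  truth <- tibble::tibble(
    id = nuclease$id,
    nuclease_clade = clade_of,
    helicase_clade = clade_of,
    is_chimera = FALSE,
    donor_id = NA_character_
  )
  hel_seq <- helicase$seq
  if (n_chim > 0L) {
    with_seed(seed, {
      picks <- sample.int(n, n_chim)
      for (i in picks) {
        other <- setdiff(unique(clade_of), clade_of[i])
        donor_clade <- if (length(other) == 1L) other else sample(other, 1L)
        pool <- which(clade_of == donor_clade)
        donor <- if (length(pool) == 1L) pool else sample(pool, 1L)
        hel_seq[i] <- helicase$seq[donor]
        truth$helicase_clade[i] <- donor_clade
        truth$is_chimera[i] <- TRUE
        truth$donor_id[i] <- helicase$id[donor]
      }
    })
  }
  list(
    records = tibble::tibble(id = nuclease$id,
                             seq = paste0(nuclease$seq, hel_seq)),
    truth = truth
  )
}

#' Simulate a complete two-domain protein family
#'
#' Runs the whole generator: guide tree, motif-constrained evolution of the
#' nuclease and helicase domains from random root sequences, and chimera
#' planting. Everything is reproducible from `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param masks Motif masks as from [default_motif_masks()]; by default they
#'   are sized to the spec's domain lengths.
#' @return A list of class `rep_sim` with elements `sequences` (full-length,
#'   aligned by construction), `nuclease`, `helicase` (per-domain tibbles,
#'   pre-chimera for clean taxa, post-swap helicase for chimeras), `truth`,
#'   `tree` and `spec`.
#' @export
simulate_rep_family <- function(spec = sim_spec(), masks = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(masks)) {
    masks <- default_motif_masks(spec$nuclease_len, spec$helicase_len)
  }
  tree <- simulate_clade_tree(spec)
  roots <- with_seed(spec$seed + 104729L, {
    list(
      nuclease = paste0(sample(AA20, spec$nuclease_len, replace = TRUE),
                        collapse = ""),
      helicase = paste0(sample(AA20, spec$helicase_len, replace = TRUE),
                        collapse = "")
    )
  })
  nuc <- evolve_domain(tree, roots$nuclease, masks$nuclease,
                       seed = spec$seed + 1L)
  hel <- evolve_domain(tree, roots$helicase, masks$helicase,
                       seed = spec$seed + 2L)
  clades <- tibble::tibble(id = tree$tip.label,
                           clade = sub("_.*$", "", tree$tip.label))
  planted <- plant_chimeras(nuc, hel, clades, spec$chimera_fraction,
                            seed = spec$seed + 3L)
  hel_final <- tibble::tibble(
    id = planted$records$id,
    seq = substr(planted$records$seq, spec$nuclease_len + 1L,
                 spec$nuclease_len + spec$helicase_len)
  )
  structure(
    list(sequences = planted$records,
         nuclease = nuc,
         helicase = hel_final,
         truth = planted$truth,
         tree = tree,
         spec = spec),
    class = "rep_sim"
  )
}

#' @export
print.rep_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic Rep family: %d taxa in %d clades, %d planted chimera(s)\n",
    nrow(x$sequences), x$spec$n_clades, sum(x$truth$is_chimera)))
  invisible(x)
}
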