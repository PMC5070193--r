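# End-to-end orchestration: seed alignments -> iterative classification ->
# firm domain segments -> similarity clustering + domain tree -> reconciled
# subgroups -> protein-level family calls and repertoire inputs.

#' Extract firm domain segments as sequences
#'
#' @param assignments data frame from [classify_domains] / [iterate].
#' @param database the scanned [aa_set].
#' @param statuses statuses to keep.
#' @return an [aa_set] of envelope slices, ids `seq_id.segment`, carrying
#'   the parent protein's species; the assigned label travels in the
#'   `label` attribute (same order).
#' @export
domain_segments <- function(assignments, database, statuses = "firm") {
  a <- assignments[assignments$status %in% statuses &
                   !is.na(assignments$label), , drop = FALSE]
  idx <- match(a$seq_id, database$id)
  res <- substr(database$residues[idx], a$start + 1L, a$end)
  out <- aa_set(paste0(a$seq_id, ".", a$segment), res,
                species = database$species[idx],
                lineage = database$lineage[idx])
  attr(out, "label") <- a$label
  out
}

#' Protein-level family calls from domain assignments
#'
#' A protein is called for family F when the majority of its firm segments
#' carry F's subgroup labels; the tandem flag additionally requires a firm
#' F.D1 envelope starting before a firm F.D2 envelope.
#'
#' @param assignments data frame from [classify_domains].
#' @param database the scanned [aa_set] (for species).
#' @return data frame: seq_id, species, family, n_firm_segments, tandem.
#' @export
protein_calls <- function(assignments, database) {
  firm <- assignments[assignments$status == "firm" &
                      !is.na(assignments$label), , drop = FALSE]
  if (nrow(firm) == 0L) {
    return(data.frame(seq_id = character(0), species = character(0),
                      family = character(0), n_firm_segments = integer(0),
                      tandem = logical(0)))
  }
  firm$family <- sub("\\.(D1|D2|N)$", "", firm$label)
  out <- list()
  for (sid in unique(firm$seq_id)) {
    f <- firm[firm$seq_id == sid, , drop = FALSE]
    tab <- sort(table(f$family), decreasing = TRUE)
    fam <- names(tab)[1L]
    d1 <- f[f$label == paste0(fam, ".D1"), , drop = FALSE]
    d2 <- f[f$label == paste0(fam, ".D2"), , drop = FALSE]
    tandem <- nrow(d1) > 0 && nrow(d2) > 0 && min(d1$start) < min(d2$start)
    out[[length(out) + 1L]] <- data.frame(
      seq_id = sid, species = database$species[match(sid, database$id)],
      family = fam, n_firm_segments = nrow(f), tandem = tandem,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Progressive profile-profile join of the filtered per-subgroup alignments
# (the "general AAA domain alignment"), tracking for every subgroup the map
# from its own columns to the merged columns.
profile_join <- function(filtered) {
  stopifnot(length(filtered) >= 1L)
  sub <- blosum62_aax()[1:20, 1:20]
  cur <- filtered[[1L]]
  maps <- list()
  maps[[names(filtered)[1L]]] <- seq_len(cur$ncols)
  for (k in seq_along(filtered)[-1L]) {
    b <- filtered[[k]]
    S <- profile_frequencies(cur) %*% sub %*% t(profile_frequencies(b))
    nm <- .nw_affine_map(S, 11, 1)
    old_to_new <- integer(cur$ncols)
    sel <- !is.na(nm$mapA)
    old_to_new[nm$mapA[sel]] <- which(sel)
    maps <- lapply(maps, function(m) old_to_new[m])
    maps[[names(filtered)[k]]] <- {
      mb <- integer(b$ncols)
      selb <- !is.na(nm$mapB)
      mb[nm$mapB[selb]] <- which(selb)
      mb
    }
    # stack rows on the merged coordinate system
    mA <- msa_matrix(cur); mB <- msa_matrix(b)
    ncolsk <- length(nm$mapA)
    out <- matrix("-", nrow(mA) + nrow(mB), ncolsk,
                  dimnames = list(c(rownames(mA), rownames(mB)), NULL))
    out[seq_len(nrow(mA)), sel] <- mA[, nm$mapA[sel], drop = FALSE]
    out[nrow(mA) + seq_len(nrow(mB)), selb] <- mB[, nm$mapB[selb], drop = FALSE]
    cur <- msa_from_matrix(out)
  }
  list(alignment = cur, maps = maps)
}

# Segment alignment on the joined coordinate system: each segment is
# Viterbi-aligned to its own subgroup model (whose match states are the
# filtered seed columns), and its match-state residues are placed into the
# merged columns through the join maps. Within-subgroup homology comes from
# the subgroup model, between-subgroup homology from the profile join.
segments_msa <- function(segments, labels, library, join) {
  ncols <- join$alignment$ncols
  rows <- vapply(seq_len(nrow(segments)), function(i) {
    s <- segments$residues[[i]]
    model <- library[[labels[i]]]
    map <- join$maps[[labels[i]]]
    v <- viterbi(model, s)
    chars <- rep("-", ncols)
    ok <- which(!is.na(v$matchmap) & map > 0)
    chars[map[ok]] <- vapply(v$matchmap[ok] + 1L,
                             function(p) substr(s, p, p), character(1))
    paste(chars, collapse = "")
  }, character(1))
  names(rows) <- segments$id
  msa(rows)
}

#' Run the full classification pipeline on a dataset
#'
#' Cuts truth-based seed alignments, runs [iterate] to convergence, splits
#' firm proteins into domain segments, builds the all-vs-all similarity
#' graph and its cluster hierarchy, infers the domain NJ tree with
#' bootstrap replicates on a profile-anchored segment alignment, reconciles
#' clusters with supported clades ([reconcile]), and derives protein-level
#' family calls.
#'
#' @param ds a `synth_dataset` (or any list exposing `sequences` and the
#'   seed-alignment interface used here).
#' @param seeds optional named list of seed alignments (default: cut from
#'   the dataset truth, 10 rows per subgroup).
#' @param config classification config overrides (see [iterate]).
#' @param cutoff_levels clustering E-value cutoffs.
#' @param n_boot bootstrap replicates for the domain tree.
#' @param support_min minimal clade support for [reconcile].
#' @param seed RNG seed for calibration and bootstrap.
#' @param max_iter maximum classification iterations (default 10; 1 gives
#'   a single-pass classification).
#' @return list with `state`, `calls`, `segments`, `graph`, `clusters`,
#'   `domain_tree`, `unified`, `n_subgroups`, `n_families`,
#'   `n_families_eukaryotic`.
#' @export
run_pipeline <- function(ds, seeds = NULL, config = list(),
                         cutoff_levels = c(1e-40, 1e-28, 1e-16, 1e-8),
                         n_boot = 50L, support_min = 70, seed = 1L,
                         max_iter = 10L) {
  if (is.null(seeds)) seeds <- seed_alignments(ds, n_per_family = 10L)
  ann <- if (inherits(ds, "synth_dataset")) seed_motif_annotations(ds) else list()
  cfg <- utils::modifyList(list(calibrate_seed = seed, max_iter = max_iter),
                           config)
  state <- iterate(seeds, ds$sequences, cfg, ann)
  calls <- protein_calls(state$assignments, ds$sequences)
  tandem_ids <- calls$seq_id[calls$tandem]
  keep <- state$assignments$status == "firm" &
    state$assignments$seq_id %in% tandem_ids &
    grepl("\\.(D1|D2)$", state$assignments$label)
  segs <- domain_segments(state$assignments[keep, , drop = FALSE],
                          ds$sequences)
  graph <- all_vs_all(segs, cutoff_levels = cutoff_levels)
  clusters <- cluster_at_cutoffs(graph)
  filtered <- lapply(seeds, function(a) filter_alignment(a)$alignment)
  join <- profile_join(filtered)
  smsa <- segments_msa(segs, attr(segs, "label"), state$library, join)
  domtree <- bootstrap(smsa, n_reps = n_boot, seed = seed + 17L,
                       model = "gamma", saturation = "cap",
                       keep_replicates = TRUE)
  unified <- reconcile(clusters, domtree, support_min = support_min)
  fams <- unique(calls$family)
  arch <- if (!is.null(ds$arch_tips)) ds$arch_tips else character(0)
  euk_fams <- unique(calls$family[!(calls$species %in% arch)])
  list(state = state, calls = calls, segments = segs, graph = graph,
       clusters = clusters, segment_msa = smsa, join = join,
       domain_tree = domtree, unified = unified,
       n_subgroups = length(unified$subgroups),
       n_families = length(fams),
       n_families_eukaryotic = length(euk_fams))
}

#' Unified subgroup counts over repeated bootstrap seeds
#'
#' Re-infers the domain tree (NJ + bootstrap on the segment alignment) and
#' the reconciled classification once per seed, returning the subgroup
#' count of every repetition. The similarity graph and cluster hierarchy
#' are deterministic and reused.
#'
#' @param res result of [run_pipeline].
#' @param seeds integer vector of bootstrap seeds.
#' @param n_boot replicates per tree.
#' @param support_min minimal clade support.
#' @return integer vector of unified subgroup counts, one per seed.
#' @export
subgroup_count_replicates <- function(res, seeds = 1:10, n_boot = 50L,
                                      support_min = 70) {
  vapply(seeds, function(s) {
    tr <- bootstrap(res$segment_msa, n_reps = n_boot, seed = s,
                    model = "gamma", saturation = "cap",
                    keep_replicates = TRUE)
    length(reconcile(res$clusters, tr, support_min = support_min)$subgroups)
  }, integer(1))
}
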