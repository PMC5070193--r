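# The core classification loop: all-vs-all similarity graph, clustering at
# E-value cutoffs, reconciliation of cluster components with supported tree
# clades into a unified subgroup hierarchy, per-domain assignment with
# strict/soft bounds and bit-score margins, and iterative model retraining
# to a fixed point.

# Karlin-Altschul-style bit conversion for gapped BLOSUM62 11/1 local
# scores; only the relative ordering of the derived E-values matters for
# clustering.
KA_LAMBDA <- 0.267
KA_K <- 0.1

sw_bits <- function(raw) KA_LAMBDA * raw / log(2)

#' All-vs-all similarity graph of domain segments
#'
#' Smith-Waterman local alignment (BLOSUM62, affine 11/1 gap costs) on
#' every pair; E-values via `E = K * m * n * 2^(-bits)` with fixed `K`.
#' Edges with E-value at most the loosest cutoff are kept, weighted by
#' `-log10(E)` (clamped at 0).
#'
#' @param segments an [aa_set] of domain segments (>= 2; segments shorter
#'   than 10 residues are excluded with a warning).
#' @param cutoff_levels descending-stringency E-value thresholds (the first
#'   is the strictest).
#' @param gap_open,gap_extend affine gap costs.
#' @param K Karlin-Altschul prefactor.
#' @return object of class `similarity_graph`: list with `nodes`, `edges`
#'   (data frame a, b, evalue, weight), `cutoff_levels`.
#' @export
all_vs_all <- function(segments,
                       cutoff_levels = c(1e-40, 1e-28, 1e-16, 1e-8),
                       gap_open = 11, gap_extend = 1, K = KA_K) {
  stopifnot(inherits(segments, "aa_set"))
  short <- nchar(segments$residues) < 10L
  if (any(short)) {
    warning("excluding ", sum(short), " segment(s) shorter than 10 residues")
    segments <- segments[!short, , drop = FALSE]
    class(segments) <- c("aa_set", "data.frame")
  }
  if (nrow(segments) < 2L) stop("need >= 2 segments")
  cutoff_levels <- sort(cutoff_levels)  # strictest first
  enc <- lapply(segments$residues, aa_encode)
  raw <- .sw_allpairs(enc, blosum62_aax(), gap_open, gap_extend)
  pairs <- utils::combn(nrow(segments), 2L)
  lens <- nchar(segments$residues)
  bits <- sw_bits(raw)
  ev <- K * lens[pairs[1, ]] * lens[pairs[2, ]] * 2^(-bits)
  keep <- ev <= max(cutoff_levels)
  edges <- data.frame(a = segments$id[pairs[1, keep]],
                      b = segments$id[pairs[2, keep]],
                      evalue = ev[keep],
                      weight = pmax(0, -log10(ev[keep])),
                      stringsAsFactors = FALSE)
  structure(list(nodes = segments$id, edges = edges,
                 cutoff_levels = cutoff_levels),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, cutoffs ", paste(signif(x$cutoff_levels, 2), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Connected components at each E-value cutoff
#'
#' Components at stricter cutoffs nest inside those at looser cutoffs,
#' giving the cluster-side hierarchy.
#'
#' @param graph a `similarity_graph`.
#' @param cutoff_levels overrides the graph's levels.
#' @return object of class `subgroup_hierarchy`: list with `levels`
#'   (cutoffs, strictest first), `components` (per level, a list of node-id
#'   vectors), `provenance` (NULL on the cluster side).
#' @export
cluster_at_cutoffs <- function(graph, cutoff_levels = graph$cutoff_levels) {
  stopifnot(inherits(graph, "similarity_graph"))
  cutoff_levels <- sort(cutoff_levels)
  comps <- lapply(cutoff_levels, function(cut) {
    e <- graph$edges[graph$edges$evalue <= cut, , drop = FALSE]
    g <- igraph::graph_from_data_frame(e[, c("a", "b")], directed = FALSE,
                                       vertices = graph$nodes)
    mem <- igraph::components(g)$membership
    unname(split(names(mem), mem))
  })
  structure(list(levels = cutoff_levels, components = comps,
                 provenance = NULL),
            class = "subgroup_hierarchy")
}

#' @export
print.subgroup_hierarchy <- function(x, ...) {
  for (i in seq_along(x$levels)) {
    cat(sprintf("cutoff %.2g: %d component(s)\n", x$levels[i],
                length(x$components[[i]])))
  }
  if (!is.null(x$subgroups)) {
    cat("unified subgroups:", length(x$subgroups), "\n")
  }
  invisible(x)
}

#' Reconcile cluster components with supported tree clades
#'
#' A candidate subgroup is a connected cluster at some cutoff that is also
#' monophyletic in the domain tree with bootstrap support at least
#' `support_min` (singletons and the full node set are never subgroups).
#' Candidates are laminar (components nest across cutoffs); walking the
#' component forest from the loosest level down, the first valid set on
#' each path becomes a top-level unified subgroup, and valid sets nested
#' inside it are recorded as children. A component failing the clade test
#' can be repaired from the tree (`conflict = "tree"`): the best-matching
#' supported clade (Jaccard >= `jaccard_min`) replaces it with provenance
#' `"clade-only"`; with `conflict = "cluster"` the component is kept as-is
#' with provenance `"cluster-only"`.
#'
#' @param clusters a `subgroup_hierarchy` from [cluster_at_cutoffs].
#' @param tree domain tree whose leaves are the cluster node ids, with
#'   bootstrap replicate trees attached (attribute `"replicates"`, as from
#'   [bootstrap] with `keep_replicates = TRUE`) or percent supports in
#'   `node.label`.
#' @param support_min minimal percent support for a clade.
#' @param min_size minimal subgroup size.
#' @param conflict resolution when a component is not a supported clade.
#' @param jaccard_min similarity needed for a tree repair.
#' @return the unified `subgroup_hierarchy`: adds `subgroups` (named list
#'   of member-id vectors), `table` (label, size, provenance, parent),
#'   `assignment` (node id -> subgroup label, NA when uncovered).
#' @export
reconcile <- function(clusters, tree, support_min = 70, min_size = 2L,
                      conflict = c("tree", "cluster"), jaccard_min = 0.7) {
  stopifnot(inherits(clusters, "subgroup_hierarchy"))
  conflict <- match.arg(conflict)
  reps <- attr(tree, "replicates")
  leaves <- tree$tip.label
  universe <- unique(unlist(clusters$components[[length(clusters$components)]]))
  extra <- setdiff(universe, leaves)
  if (length(extra) > 0) stop("cluster nodes missing from tree: ",
                              paste(utils::head(extra, 5), collapse = ", "))

  # canonical split keys relative to the reference leaf ordering: a split
  # is stored as the side not containing leaf 1, sorted
  nl <- length(leaves)
  split_key <- function(idx) {
    if (1L %in% idx) idx <- setdiff(seq_len(nl), idx)
    paste(sort(idx), collapse = ",")
  }
  tree_split_keys <- function(tr) {
    ix <- match(tr$tip.label, leaves)
    pp <- ape::prop.part(tr)
    keys <- vapply(pp, function(cl) split_key(ix[cl]), character(1))
    unique(keys[nzchar(keys)])
  }
  ref_keys <- tree_split_keys(tree)
  rep_env <- NULL
  if (!is.null(reps)) {
    rep_env <- new.env(hash = TRUE, parent = emptyenv())
    for (tr in reps) {
      for (k in tree_split_keys(tr)) {
        assign(k, (if (exists(k, rep_env, inherits = FALSE))
          get(k, rep_env) else 0L) + 1L, rep_env)
      }
    }
  }
  # support of an arbitrary leaf set: % of replicate trees containing it as
  # a split (or the reference node label when no replicates are attached)
  clade_support <- function(set) {
    set <- intersect(set, leaves)
    if (length(set) < 2L) return(100)
    key <- split_key(sort(match(set, leaves)))
    if (!(key %in% ref_keys)) return(NA_real_)
    if (!is.null(rep_env)) {
      cnt <- if (exists(key, rep_env, inherits = FALSE)) get(key, rep_env) else 0L
      return(100 * cnt / length(reps))
    }
    if (!is.null(tree$node.label) && length(set) < nl) {
      nd <- ape::getMRCA(tree, set)
      lab <- suppressWarnings(as.numeric(tree$node.label[nd - nl]))
      return(if (is.na(lab)) 100 else lab)
    }
    100
  }
  supported_clades <- NULL
  get_supported_clades <- function() {
    if (is.null(supported_clades)) {
      pp <- ape::prop.part(tree)
      sets <- lapply(pp, function(ix) leaves[ix])
      if (!ape::is.rooted(tree)) {
        sets <- c(sets, lapply(sets, function(s) setdiff(leaves, s)))
      }
      sets <- Filter(function(s) length(s) >= 2 && length(s) < length(leaves),
                     sets)
      keep <- vapply(sets, function(s) {
        sup <- clade_support(s)
        !is.na(sup) && sup >= support_min
      }, logical(1))
      supported_clades <<- sets[keep]
    }
    supported_clades
  }

  # on an unrooted tree both sides of a split are "monophyletic"; a
  # subgroup must be the smaller side, otherwise the complement of any
  # clade would qualify
  unrooted <- !ape::is.rooted(tree)
  valid <- function(set) {
    if (length(set) < min_size || length(set) >= length(universe)) return(FALSE)
    if (unrooted && length(set) > nl / 2) return(FALSE)
    sup <- clade_support(set)
    !is.na(sup) && sup >= support_min
  }

  # walk components from loosest to strictest level: the first valid
  # (cluster-and-clade) set on each path becomes a unified subgroup;
  # only components for which recursion yields nothing are candidates for
  # a tree repair
  nlev <- length(clusters$levels)
  taken <- character(0)
  subgroups <- list()
  table_rows <- list()
  add_subgroup <- function(set, provenance, parent) {
    set <- setdiff(set, taken)
    if (length(set) < min_size) return(NULL)
    label <- sprintf("SG%02d", length(subgroups) + 1L)
    subgroups[[label]] <<- sort(set)
    taken <<- c(taken, set)
    table_rows[[length(table_rows) + 1L]] <<- data.frame(
      label = label, size = length(set), provenance = provenance,
      parent = parent, stringsAsFactors = FALSE)
    label
  }
  children_of <- function(set, lev) {
    if (lev < 1L) return(list())
    Filter(function(s) length(intersect(s, set)) > 0,
           clusters$components[[lev]])
  }
  descend <- function(set, lev, parent) {
    set <- setdiff(set, taken)
    if (length(set) < min_size) return(0L)
    if (length(set) < length(universe) && valid(set)) {
      lab <- add_subgroup(set, "reconciled", parent)
      return(if (is.null(lab)) 0L else 1L)
    }
    created <- 0L
    if (lev >= 2L) {
      for (ch in children_of(set, lev - 1L)) {
        created <- created + descend(intersect(ch, set), lev - 1L, parent)
      }
    }
    if (created == 0L && conflict == "tree" &&
        length(set) < length(universe)) {
      # tree repair: best supported clade close to this component
      best <- NULL; best_j <- 0
      for (cl in get_supported_clades()) {
        j <- length(intersect(set, cl)) / length(union(set, cl))
        if (j > best_j) { best_j <- j; best <- cl }
      }
      if (!is.null(best) && best_j >= jaccard_min) {
        lab <- add_subgroup(intersect(best, union(set, best)), "clade-only",
                            parent)
        if (!is.null(lab)) created <- 1L
      }
    }
    if (created == 0L && conflict == "cluster" &&
        length(set) < length(universe)) {
      lab <- add_subgroup(set, "cluster-only", parent)
      if (!is.null(lab)) created <- 1L
    }
    created
  }
  for (comp in clusters$components[[nlev]]) descend(comp, nlev, NA_character_)

  assignment <- stats::setNames(rep(NA_character_, length(universe)), universe)
  for (lab in names(subgroups)) assignment[subgroups[[lab]]] <- lab
  # re-home uncovered segments whose addition keeps a subgroup a supported
  # clade (a cluster-vs-tree conflict resolved by the tree)
  if (conflict == "tree") {
    for (x in names(assignment)[is.na(assignment)]) {
      fits <- Filter(function(lab) {
        sup <- clade_support(c(subgroups[[lab]], x))
        !is.na(sup) && sup >= support_min
      }, names(subgroups))
      if (length(fits) > 0) {
        sizes <- vapply(fits, function(l) length(subgroups[[l]]), integer(1))
        lab <- fits[which.min(sizes)]
        subgroups[[lab]] <- sort(c(subgroups[[lab]], x))
        assignment[x] <- lab
        table_rows[[length(table_rows) + 1L]] <- data.frame(
          label = lab, size = length(subgroups[[lab]]),
          provenance = "clade-only", parent = lab, stringsAsFactors = FALSE)
      }
    }
  }
  out <- clusters
  out$subgroups <- subgroups
  out$table <- if (length(table_rows)) do.call(rbind, table_rows) else
    data.frame(label = character(0), size = integer(0),
               provenance = character(0), parent = character(0))
  out$assignment <- assignment
  out
}

#' Classify domain segments from scan hits
#'
#' One assignment per envelope group: `firm` when the best model's E-value
#' is at or under its strict bound and the bit-score margin over the
#' second-best model is at least `margin_min`; `ambiguous` when the margin
#' is smaller and at least two models pass their soft bounds;
#' `provisional` when only the soft bound is met; `unclassified` otherwise.
#'
#' @param hits data frame from [scan_sequence] (one or many sequences).
#' @param library named list of calibrated models (for strict/soft bounds).
#' @param margin_min minimal bit-score margin for a firm call.
#' @return data frame: seq_id, segment (ordinal per sequence), start, end,
#'   label, best_bits, margin_bits, evalue, status, second_label.
#' @export
classify_domains <- function(hits, library, margin_min = 10) {
  if (nrow(hits) == 0L) {
    return(data.frame(seq_id = character(0), segment = integer(0),
                      start = integer(0), end = integer(0),
                      label = character(0), best_bits = numeric(0),
                      margin_bits = numeric(0), evalue = numeric(0),
                      status = character(0), second_label = character(0)))
  }
  out <- list()
  for (sid in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == sid, , drop = FALSE]
    for (g in sort(unique(h$group))) {
      hg <- h[h$group == g, , drop = FALSE]
      hg <- hg[order(hg$rank), , drop = FALSE]
      best <- hg[1L, ]
      m <- library[[best$model]]
      second <- if (nrow(hg) >= 2L) hg[2L, ] else NULL
      margin <- if (is.null(second)) Inf else best$bits - second$bits
      n_soft <- sum(vapply(seq_len(nrow(hg)), function(i)
        hg$evalue[i] <= library[[hg$model[i]]]$soft_evalue, logical(1)))
      status <- if (best$evalue > m$soft_evalue) "unclassified"
        else if (best$evalue <= m$strict_evalue && margin >= margin_min) "firm"
        else if (margin < margin_min && n_soft >= 2L) "ambiguous"
        else "provisional"
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid, segment = g, start = best$start, end = best$end,
        label = if (status == "unclassified") NA_character_ else best$model,
        best_bits = best$bits, margin_bits = margin, evalue = best$evalue,
        status = status,
        second_label = if (is.null(second)) NA_character_ else second$model,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve an ambiguous segment against subgroup exemplars
#'
#' Pairwise-aligns the segment (Smith-Waterman, BLOSUM62 11/1) to the `k`
#' nearest exemplars of each candidate subgroup and assigns the subgroup
#' with the highest mean bit score if it leads by at least `gap_min` bits;
#' otherwise the segment stays ambiguous.
#'
#' @param segment residue string.
#' @param candidates character vector of candidate subgroup labels.
#' @param exemplars named list: per label, a character vector of exemplar
#'   residue strings.
#' @param k exemplars per subgroup.
#' @param gap_min minimal mean-bit-score lead.
#' @return list with `label` (NA if still ambiguous), `status`, and
#'   `mean_bits` per candidate.
#' @export
resolve_ambiguous <- function(segment, candidates, exemplars, k = 3L,
                              gap_min = 2) {
  if (length(candidates) < 2L) stop("need >= 2 candidate subgroups")
  sub <- blosum62_aax()
  qs <- aa_encode(segment)
  means <- vapply(candidates, function(lab) {
    ex <- exemplars[[lab]]
    if (is.null(ex) || length(ex) == 0L) return(-Inf)
    sc <- vapply(ex, function(e)
      sw_bits(.sw_score(qs, aa_encode(e), sub, 11, 1)), numeric(1))
    mean(sort(sc, decreasing = TRUE)[seq_len(min(k, length(sc)))])
  }, numeric(1))
  ord <- order(means, decreasing = TRUE)
  lead <- means[ord[1]] - means[ord[2]]
  if (is.finite(lead) && lead >= gap_min) {
    list(label = candidates[ord[1]], status = "firm", mean_bits = means)
  } else {
    list(label = NA_character_, status = "ambiguous", mean_bits = means)
  }
}

# build a calibrated model library from per-subgroup alignments; motif
# annotations given in seed-alignment columns are remapped through the
# column filter
build_library <- function(seeds, annotations = list(), config = list()) {
  cfg <- utils::modifyList(list(
    col_gap_max = 0.5, row_gap_max = 0.5,
    pseudocount_strength = 20, calibrate_n = 5000, calibrate_seed = 1L,
    calibrate_length = 400L, strict_evalue = 1e-5, soft_evalue = 1e-3
  ), config)
  library <- list()
  ann_out <- list()
  filtered <- list()
  for (nm in names(seeds)) {
    filt <- filter_alignment(seeds[[nm]], cfg$col_gap_max, cfg$row_gap_max)
    filtered[[nm]] <- filt$alignment
    hmm <- build_hmm(filt$alignment, name = nm,
                     pseudocount_strength = cfg$pseudocount_strength)
    hmm$strict_evalue <- cfg$strict_evalue
    hmm$soft_evalue <- cfg$soft_evalue
    hmm <- calibrate(hmm, n_random = cfg$calibrate_n,
                     length_law = list(type = "fixed",
                                       length = cfg$calibrate_length),
                     seed = cfg$calibrate_seed)
    library[[nm]] <- hmm
    if (!is.null(annotations[[nm]])) {
      keep <- filt$mask$keep
      newcol <- cumsum(keep)  # 1-based model column per kept seed column
      ann_out[[nm]] <- lapply(annotations[[nm]], function(rng) {
        cols <- (rng[1] + 1L):rng[2]
        kept <- cols[keep[cols]]
        if (length(kept) == 0L) return(NULL)
        c(newcol[kept[1]] - 1L, newcol[kept[length(kept)]])
      })
    }
  }
  list(library = library, annotations = ann_out, filtered = filtered)
}

# scan a whole database with a library; returns the combined hits table
scan_database <- function(database, library, n_database = nrow(database)) {
  all_hits <- lapply(seq_len(nrow(database)), function(i) {
    scan_sequence(aa_subset(database, database$id[i]), library,
                  n_database = n_database)
  })
  do.call(rbind, all_hits)
}

#' Iterative classification to a fixed point
#'
#' Builds and calibrates a model per subgroup from the seed alignments,
#' scans the database, classifies every domain segment, re-aligns firm
#' members to their model and adds them to the training alignments, then
#' rebuilds, until no assignment label or status changes (or `max_iter`).
#' Gumbel calibration is performed once per subgroup at the first build and
#' reused, as the null score distribution is insensitive to the added
#' training rows. Oscillations (a previously seen assignment state) stop
#' the loop and return the state with the smallest change count.
#'
#' @param seeds named list of seed [msa] objects (labels become model
#'   names).
#' @param database an [aa_set] to classify.
#' @param config list of overrides: margin_min, strict_evalue, soft_evalue,
#'   calibrate_n, calibrate_seed, calibrate_length, max_iter,
#'   pseudocount_strength, col/row_gap_max.
#' @param annotations optional motif annotations in seed-alignment columns.
#' @return object of class `classification_state`: list with `iteration`,
#'   `library`, `annotations`, `assignments`, `changed_count`, `converged`,
#'   `log` (per-iteration audit data frame), `training` (named aligned rows
#'   per subgroup: seed rows plus every firm member added so far).
#' @export
iterate <- function(seeds, database, config = list(), annotations = list()) {
  stopifnot(length(seeds) >= 1L, inherits(database, "aa_set"))
  cfg <- utils::modifyList(list(margin_min = 10, max_iter = 10L),
                           config %||% list())
  built <- build_library(seeds, annotations, config)
  library <- built$library
  gumbel <- lapply(library, function(m)
    c(lambda = m$gumbel_lambda, mu = m$gumbel_mu))
  training <- list()
  prev_key <- NULL
  seen <- character(0)
  log_rows <- list()
  best <- NULL
  assignments <- NULL
  for (it in seq_len(cfg$max_iter)) {
    hits <- scan_database(database, library)
    assignments <- classify_domains(hits, library,
                                    margin_min = cfg$margin_min)
    # route ambiguous segments through exemplar comparison; a resolved
    # segment gets its label updated but stays provisional (never trains)
    amb <- which(assignments$status == "ambiguous" &
                 !is.na(assignments$second_label))
    if (length(amb) > 0) {
      exemplars <- lapply(training, function(rows)
        utils::head(gsub("-", "", unlist(rows)), 5))
      if (length(exemplars) == 0) {
        exemplars <- lapply(built$filtered, function(a)
          utils::head(gsub("-", "", a$rows), 5))
      }
      for (i in amb) {
        seg <- substr(database$residues[database$id == assignments$seq_id[i]],
                      assignments$start[i] + 1L, assignments$end[i])
        cand <- c(assignments$label[i], assignments$second_label[i])
        r <- resolve_ambiguous(seg, cand, exemplars)
        if (!is.na(r$label)) {
          assignments$label[i] <- r$label
          assignments$status[i] <- "provisional"
        }
      }
    }
    cur <- stats::setNames(paste(assignments$label, assignments$status),
                           paste(assignments$seq_id, assignments$segment))
    changed <- if (is.null(prev_key)) length(cur) else {
      both <- intersect(names(cur), names(prev_key))
      sum(cur[both] != prev_key[both]) +
        (length(cur) - length(both)) + (length(prev_key) - length(both))
    }
    key <- paste(names(cur), cur, collapse = ";")
    log_rows[[it]] <- data.frame(
      iteration = it, n_segments = nrow(assignments),
      n_firm = sum(assignments$status == "firm"),
      n_ambiguous = sum(assignments$status == "ambiguous"),
      changed_count = changed, timestamp = format(Sys.time()),
      stringsAsFactors = FALSE)
    state <- structure(list(iteration = it, library = library,
                            annotations = built$annotations,
                            assignments = assignments,
                            changed_count = changed,
                            converged = !is.null(prev_key) && changed == 0L,
                            training = training),
                       class = "classification_state")
    if (is.null(best) || changed < best$changed_count) best <- state
    if (!is.null(prev_key) && changed == 0L) {
      state$log <- do.call(rbind, log_rows)
      return(state)
    }
    if (key %in% seen) {
      warning("oscillation detected; returning state with fewest changes")
      best$log <- do.call(rbind, log_rows)
      best$converged <- FALSE
      return(best)
    }
    seen <- c(seen, key)
    prev_key <- cur
    # grow training alignments cumulatively: filtered seed rows plus every
    # firm segment seen so far, re-aligned to the model that first accepted
    # it (seed columns equal model columns, so rows are compatible)
    firm <- assignments[assignments$status == "firm" &
                        !is.na(assignments$label), , drop = FALSE]
    for (nm in names(library)) {
      if (is.null(training[[nm]])) {
        training[[nm]] <- stats::setNames(built$filtered[[nm]]$rows,
                                          paste0("seed.",
                                                 built$filtered[[nm]]$ids))
      }
      fr <- firm[firm$label == nm, , drop = FALSE]
      model <- library[[nm]]
      new_keys <- setdiff(paste0(fr$seq_id, ".", fr$segment),
                          names(training[[nm]]))
      for (i in which(paste0(fr$seq_id, ".", fr$segment) %in% new_keys)) {
        s <- database$residues[database$id == fr$seq_id[i]]
        v <- viterbi(model, s)
        chars <- rep("-", model$L)
        ok <- !is.na(v$matchmap)
        chars[ok] <- vapply(v$matchmap[ok] + 1L,
                            function(p) substr(s, p, p), character(1))
        training[[nm]][[paste0(fr$seq_id[i], ".", fr$segment[i])]] <-
          paste(chars, collapse = "")
      }
      m2 <- build_hmm(msa(unlist(training[[nm]])), name = nm,
                      pseudocount_strength = cfg$pseudocount_strength %||% 20)
      m2$strict_evalue <- library[[nm]]$strict_evalue
      m2$soft_evalue <- library[[nm]]$soft_evalue
      m2$gumbel_lambda <- unname(gumbel[[nm]]["lambda"])
      m2$gumbel_mu <- unname(gumbel[[nm]]["mu"])
      library[[nm]] <- m2
    }
  }
  warning("no convergence within max_iter")
  best$log <- do.call(rbind, log_rows)
  best
}

#' @export
print.classification_state <- function(x, ...) {
  cat("classification_state: iteration ", x$iteration,
      if (x$converged) " (converged)" else "",
      ", ", nrow(x$assignments), " segments, ",
      sum(x$assignments$status == "firm"), " firm\n", sep = "")
  invisible(x)
}
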