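# Desk-scale tree inference and support: corrected pairwise distances,
# neighbor joining, nonparametric bootstrap, outgroup rooting, monophyly
# tests, and a quartet-support surrogate for likelihood mapping (quartets
# are scored by the least-squares fit of the three topologies to pairwise
# distances).

#' Pairwise distance between two aligned rows
#'
#' @param a,b aligned residue strings of equal length (gaps `-`).
#' @param model `"p"` (proportion of mismatches over shared non-gap
#'   columns), `"poisson"` (`-ln(1 - p)`), or `"gamma"`
#'   (`alpha * ((1 - p)^(-1/alpha) - 1)`, rate heterogeneity with shape
#'   `alpha`).
#' @param alpha gamma shape (default 1).
#' @return a nonnegative distance.
#' @export
pairwise_distance <- function(a, b, model = c("p", "poisson", "gamma"),
                              alpha = 1.0) {
  model <- match.arg(model)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("rows have different lengths")
  ok <- ca %in% AA20 & cb %in% AA20
  if (!any(ok)) stop("no shared non-gap column")
  p <- mean(ca[ok] != cb[ok])
  correct_distance(p, model, alpha)
}

correct_distance <- function(p, model, alpha = 1.0, saturation = "error") {
  if (model != "p" && any(p >= 1, na.rm = TRUE)) {
    if (saturation == "error") stop("saturated distance (p >= 1) under correction")
    p <- pmin(p, 0.99)
  }
  switch(model,
         p = p,
         poisson = -log(1 - p),
         gamma = alpha * ((1 - p)^(-1 / alpha) - 1))
}

#' Corrected distance matrix from an alignment
#'
#' @param aln an [msa].
#' @param model,alpha see [pairwise_distance].
#' @param saturation `"error"` (reject p >= 1 under correction) or `"cap"`
#'   (cap p at 0.99; used for diverged domain sets where occasional pairs
#'   approach saturation).
#' @param weights optional per-column multiplicities (bootstrap resampling).
#' @return symmetric matrix with zero diagonal, labelled by row ids.
#' @export
distance_matrix <- function(aln, model = c("gamma", "p", "poisson"),
                            alpha = 1.0, saturation = "error",
                            weights = NULL) {
  model <- match.arg(model)
  enc <- msa_encode(aln)
  enc[enc == 20L] <- -1L  # X carries no distance information
  if (is.null(weights)) weights <- rep(1, ncol(enc))
  p <- .pdist_mat(enc, as.numeric(weights))
  if (anyNA(p)) stop("some pair shares no non-gap column")
  d <- correct_distance(p, model, alpha, saturation)
  diag(d) <- 0
  dimnames(d) <- list(aln$ids, aln$ids)
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj]); negative branch lengths are
#' clamped to zero and flagged in the `clamped` attribute.
#'
#' @param D symmetric distance matrix with zero diagonal and >= 3 labels.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 labels")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("nonzero diagonal")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- sum(neg)
  }
  tr
}

#' Nonparametric bootstrap supports for a tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate, and annotates each internal edge of the reference tree with
#' the percentage of replicates containing the same bipartition.
#'
#' @param aln an [msa].
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed; identical seeds give identical supports.
#' @param model,alpha,saturation distance options for the default NJ builder.
#' @param tree_builder optional function `msa -> phylo`; when supplied, the
#'   resampled alignment is materialized and passed to it.
#' @param keep_replicates attach the replicate trees (attribute
#'   `"replicates"`), used for clade-specific support queries.
#' @return the reference tree with `node.label` giving percent support on
#'   internal nodes.
#' @export
bootstrap <- function(aln, n_reps = 100, seed = 1L,
                      model = "gamma", alpha = 1.0, saturation = "cap",
                      tree_builder = NULL, keep_replicates = FALSE) {
  stopifnot(inherits(aln, "msa"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  L <- aln$ncols
  default_builder <- is.null(tree_builder)
  enc <- NULL
  if (default_builder) {
    ref <- nj_tree(distance_matrix(aln, model = model, alpha = alpha,
                                   saturation = saturation))
  } else {
    ref <- tree_builder(aln)
  }
  reps <- withr_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      if (default_builder) {
        nj_tree(distance_matrix(aln, model = model, alpha = alpha,
                                saturation = saturation, weights = w))
      } else {
        idx <- rep(seq_len(L), w)
        m <- msa_matrix(aln)[, idx, drop = FALSE]
        tree_builder(msa_from_matrix(m))
      }
    })
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- as.character(round(100 * counts / n_reps, 1))
  if (keep_replicates) attr(ref, "replicates") <- reps
  ref
}

# percent of replicate trees in which `labels` forms a split
split_support <- function(replicates, labels, all_labels) {
  hits <- vapply(replicates, function(tr) is_monophyletic(tr, labels),
                 logical(1))
  100 * mean(hits)
}

#' Test whether a label set is monophyletic
#'
#' For a rooted tree, true iff some clade equals the set; for an unrooted
#' tree, true iff some edge bipartitions the leaves into exactly the set
#' and its complement.
#'
#' @param tree an [ape::phylo] tree.
#' @param labels leaf labels (subset of the tree's leaves).
#' @return logical.
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown) > 0L) stop("unknown label(s): ",
                                 paste(unknown, collapse = ", "))
  k <- length(unique(labels))
  if (k <= 1L || k == length(tips)) return(TRUE)
  target <- sort(match(unique(labels), tips))
  clades <- ape::prop.part(tree)
  rooted <- ape::is.rooted(tree)
  for (cl in clades) {
    s <- sort(cl)
    if (identical(s, target)) return(TRUE)
    if (!rooted &&
        identical(sort(setdiff(seq_along(tips), s)), target)) return(TRUE)
  }
  # prop.part omits trivial single-tip clades and includes the root set;
  # complements of cherries etc. are covered by the complement check above
  FALSE
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating a (checked) monophyletic outgroup
#' from the ingroup.
#'
#' @param tree unrooted (or rooted) [ape::phylo] tree.
#' @param outgroup_labels leaf labels of the outgroup.
#' @return a rooted tree.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  tips <- tree$tip.label
  missing <- setdiff(outgroup_labels, tips)
  if (length(missing) > 0L) stop("outgroup label(s) not in tree: ",
                                 paste(missing, collapse = ", "))
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (!is_monophyletic(ut, outgroup_labels)) {
    # identify intruders: leaves pulled into the smallest subtree spanning
    # the outgroup
    r1 <- ape::root(ut, outgroup = setdiff(tips, outgroup_labels)[1L],
                    resolve.root = TRUE)
    mrca <- if (length(outgroup_labels) == 1L) {
      match(outgroup_labels, r1$tip.label)
    } else ape::getMRCA(r1, outgroup_labels)
    below <- ape::extract.clade(r1, mrca)$tip.label
    intruders <- setdiff(below, outgroup_labels)
    stop("outgroup is not monophyletic; intruding leaves: ",
         paste(intruders, collapse = ", "))
  }
  ape::root(ut, outgroup = outgroup_labels, resolve.root = TRUE)
}

# leaf groups induced by an internal edge of an unrooted binary tree:
# the two neighbors on each side define four groups
edge_quartet_groups <- function(tree, edge) {
  ne <- nrow(tree$edge)
  if (edge < 1 || edge > ne) stop("edge index out of range")
  u <- tree$edge[edge, 1L]; v <- tree$edge[edge, 2L]
  ntip <- length(tree$tip.label)
  if (u <= ntip || v <= ntip) stop("edge is not internal")
  adj <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(ne)) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  reach_tips <- function(start, blocked) {
    seen <- c(start, blocked); stack <- start; tips <- integer(0)
    while (length(stack) > 0L) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (x <= ntip) tips <- c(tips, x)
      nxt <- setdiff(adj[[x]], seen)
      seen <- c(seen, nxt); stack <- c(stack, nxt)
    }
    tips
  }
  gu <- setdiff(adj[[u]], v); gv <- setdiff(adj[[v]], u)
  if (length(gu) < 2L || length(gv) < 2L) stop("fewer than 4 edge-induced groups")
  groups <- list(A = reach_tips(gu[1L], u), B = reach_tips(gu[2L], u),
                 C = reach_tips(gv[1L], v), D = reach_tips(gv[2L], v))
  if (length(gu) > 2L) groups$B <- c(groups$B, unlist(lapply(gu[-(1:2)], reach_tips, blocked = u)))
  if (length(gv) > 2L) groups$D <- c(groups$D, unlist(lapply(gv[-(1:2)], reach_tips, blocked = v)))
  lapply(groups, function(g) tree$tip.label[g])
}

#' Quartet support for an internal edge
#'
#' A distance-based surrogate for likelihood mapping: quartets with one
#' leaf per edge-induced group vote for the quartet topology with the
#' smallest least-squares residual against the pairwise distances (for a
#' quartet this is the four-point comparison of the three sum pairs). The
#' first fraction is the tree-concordant topology.
#'
#' @param aln an [msa], or a precomputed labelled distance matrix.
#' @param tree unrooted binary tree.
#' @param edge row index into `tree$edge`; must join two internal nodes.
#' @param n_quartets number of sampled quartets.
#' @param seed RNG seed.
#' @param model,alpha distance options when `aln` is an alignment.
#' @return numeric triple (concordant, alt1, alt2) summing to 1.
#' @export
quartet_support <- function(aln, tree, edge, n_quartets = 1000, seed = 1L,
                            model = "gamma", alpha = 1.0) {
  D <- if (is.matrix(aln)) aln
       else distance_matrix(aln, model = model, alpha = alpha, saturation = "cap")
  groups <- edge_quartet_groups(tree, edge)
  if (any(lengths(groups) == 0L)) stop("fewer than 4 edge-induced groups")
  votes <- withr_seed(seed, {
    v <- c(0, 0, 0)
    for (q in seq_len(n_quartets)) {
      a <- sample(groups$A, 1L); b <- sample(groups$B, 1L)
      cc <- sample(groups$C, 1L); d <- sample(groups$D, 1L)
      s <- c(D[a, b] + D[cc, d],   # AB|CD (tree-concordant)
             D[a, cc] + D[b, d],   # AC|BD
             D[a, d] + D[b, cc])   # AD|BC
      win <- which(s == min(s))
      v[win] <- v[win] + 1 / length(win)
    }
    v
  })
  votes / n_quartets
}
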