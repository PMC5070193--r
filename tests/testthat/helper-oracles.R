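# Hand-built toy models and brute-force oracles, independent of the
# package's dynamic-programming implementations.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# construct a profile_hmm directly from emission/transition tables
toy_hmm <- function(me, tmat = NULL, begin = c(1, 0), bg = rep(1 / 20, 20),
                    name = "toy") {
  L <- nrow(me)
  colnames(me) <- AA
  ie <- matrix(rep(bg, each = L + 1), L + 1, 20, dimnames = list(NULL, AA))
  if (is.null(tmat)) {
    tmat <- matrix(rep(c(1, 0, 0, 1, 0, 1, 0), L), L, 7, byrow = TRUE)
  }
  colnames(tmat) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  structure(list(name = name, L = L, match_emissions = me,
                 insert_emissions = ie,
                 transitions = list(begin = begin, t = tmat),
                 background = stats::setNames(bg, AA),
                 gumbel_lambda = NA_real_, gumbel_mu = NA_real_,
                 strict_evalue = 1e-5, soft_evalue = 1e-3,
                 emission_floor = 0),
            class = "profile_hmm")
}

random_toy_hmm <- function(L) {
  me <- matrix(rexp(L * 20), L, 20)
  me <- me / rowSums(me)
  tm <- matrix(0, L, 7)
  for (j in seq_len(L)) {
    a <- rexp(3); tm[j, 1:3] <- a / sum(a)
    b <- rexp(2); tm[j, 4:5] <- b / sum(b)
    d <- rexp(2); tm[j, 6:7] <- d / sum(d)
  }
  tm[L, ] <- c(1, 0, 0, 1, 0, 1, 0)
  bg <- rexp(20); bg <- bg / sum(bg)
  b <- rexp(2); b <- b / sum(b)
  toy_hmm(me, tm, begin = b, bg = bg)
}

random_peptide <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")

# Exhaustive enumeration of all glocal paths (log2-odds scores): start
# offsets 0..n, match/delete choice per model position, any number of
# inserts between positions; flanking residues are free. Returns the vector
# of path scores.
enumerate_path_scores <- function(hmm, seq) {
  s <- match(strsplit(seq, "")[[1]], AA)
  n <- length(s)
  L <- hmm$L
  lodds_m <- log2(hmm$match_emissions) -
    matrix(log2(hmm$background), L, 20, byrow = TRUE)
  lodds_i <- log2(hmm$insert_emissions) -
    matrix(log2(hmm$background), L + 1, 20, byrow = TRUE)
  tm <- log2(hmm$transitions$t)
  bm <- log2(hmm$transitions$begin)
  scores <- c()
  # prev is "M", "D", or "I" at position j; i = residues consumed
  walk <- function(j, i, prev, acc) {
    if (j > L) { scores <<- c(scores, acc); return(invisible()) }
    # enter M_j (consumes a residue)
    if (i < n) {
      tr <- if (j == 1) bm[1] else switch(prev,
        M = tm[j - 1, "mm"], D = tm[j - 1, "dm"], I = tm[j - 1, "im"])
      after_m <- acc + tr + lodds_m[j, s[i + 1]]
      # optional insert run after M_j (only between positions)
      emit_then_continue(j, i + 1, "M", after_m)
    }
    # enter D_j (no residue)
    tr <- if (j == 1) bm[2] else switch(prev,
      M = tm[j - 1, "md"], D = tm[j - 1, "dd"], I = -Inf)
    if (is.finite(tr) || TRUE) {
      emit_then_continue(j, i, "D", acc + tr)
    }
  }
  emit_then_continue <- function(j, i, st, acc) {
    # continue without inserts
    walk(j + 1, i, st, acc)
    # insert runs I_j (only if j < L); first insert from M or D? plan7 has
    # no D->I: inserts only reachable from M
    if (j < L && st == "M") {
      a <- acc + tm[j, "mi"]
      i2 <- i
      while (i2 < n) {
        a <- a + lodds_i[j + 1, s[i2 + 1]]
        i2 <- i2 + 1
        walk(j + 1, i2, "I", a)
        a <- a + tm[j, "ii"]
      }
    }
  }
  for (start in 0:n) walk(1, start, "B", 0)
  scores[is.finite(scores)]
}

# Least-squares brute-force tree search: all unrooted topologies for <= 6
# taxa, branch lengths by unconstrained least squares, minimal residual
# wins.
all_topologies <- function(labels) {
  n <- length(labels)
  base <- ape::read.tree(text = paste0("(", labels[1], ",", labels[2], ",",
                                       labels[3], ");"))
  trees <- list(base)
  for (k in 4:n) {
    if (k > n) break
    new <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        t2 <- ape::bind.tree(tr,
          ape::read.tree(text = paste0("(", labels[k], ");")),
          where = tr$edge[e, 2], position = 0.5)
        t2$edge.length <- NULL
        new[[length(new) + 1]] <- t2
      }
    }
    trees <- new
  }
  trees
}

ls_fit_residual <- function(tree, D) {
  labels <- tree$tip.label
  n <- length(labels)
  pairs <- utils::combn(n, 2)
  tree$edge.length <- rep(1, nrow(tree$edge))
  X <- matrix(0, ncol(pairs), nrow(tree$edge))
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    path <- ape::nodepath(tree, i, j)
    for (m in seq_len(length(path) - 1)) {
      e <- which((tree$edge[, 1] == path[m] & tree$edge[, 2] == path[m + 1]) |
                 (tree$edge[, 2] == path[m] & tree$edge[, 1] == path[m + 1]))
      X[k, e] <- 1
    }
    y[k] <- D[labels[i], labels[j]]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

brute_force_ls_tree <- function(D) {
  labels <- rownames(D)
  trees <- all_topologies(labels)
  res <- vapply(trees, ls_fit_residual, numeric(1), D = D)
  trees[[which.min(res)]]
}

# distance matrix implied by a tree with branch lengths (additive metric)
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

# Brute-force Dollo: minimal losses over all single-gain placements; the
# gain must be an ancestor of (or equal to) every possessing leaf.
brute_force_dollo <- function(tree, have) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  children <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge)))
    children[[tree$edge[k, 1]]] <- c(children[[tree$edge[k, 1]]],
                                     tree$edge[k, 2])
  leaves_below <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    unlist(lapply(children[[nd]], leaves_below))
  }
  losses_for_gain <- function(g) {
    below <- leaves_below(g)
    if (!all(have %in% below)) return(NA_integer_)
    count <- 0L
    poss <- function(nd) any(have %in% leaves_below(nd))
    rec <- function(nd) {
      for (ch in children[[nd]] %||% list()) {
        if (!poss(ch)) count <<- count + 1L else rec(ch)
      }
    }
    `%||%` <- function(a, b) if (is.null(a)) b else a
    rec(g)
    count
  }
  cand <- if (length(have) == 1) match(have, tree$tip.label) else seq_len(nn)
  losses <- suppressWarnings(vapply(cand, losses_for_gain, integer(1)))
  min(losses, na.rm = TRUE)
}

# simple random alignment fixture
random_msa <- function(nrow = 4, ncol = 12, gap_p = 0.1,
                       ids = paste0("s", seq_len(nrow))) {
  m <- matrix(sample(AA, nrow * ncol, replace = TRUE), nrow, ncol)
  m[matrix(stats::runif(nrow * ncol) < gap_p, nrow, ncol)] <- "-"
  # keep at least one residue per row and column
  for (i in seq_len(nrow)) if (all(m[i, ] == "-")) m[i, 1] <- "A"
  for (j in seq_len(ncol)) if (all(m[, j] == "-")) m[1, j] <- "A"
  rownames(m) <- ids
  rows <- apply(m, 1, paste, collapse = "")
  msa(stats::setNames(rows, ids))
}

# shared small synthetic dataset for the heavier tests (built once per run)
small_synth_config <- function() {
  cfg <- default_config()
  cfg$tree$n_eukaryotes <- 12L
  cfg$tree$n_archaea <- 4L
  cfg$tree$parasite_clade <- 3L
  cfg$tree$duplication_clade <- 3L
  cfg
}

.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .test_cache)) assign(key, force(expr), .test_cache)
  get(key, .test_cache)
}

# topology equality for unrooted comparisons (dist.topo returns a dist)
topo_equal <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))) == 0
}

random_bg_peptide <- function(n, bg) {
  paste(sample(AA, n, replace = TRUE, prob = bg), collapse = "")
}
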