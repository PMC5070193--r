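# similarity graph, clustering, reconciliation, assignment, iteration

test_that("the similarity graph is symmetric with sound E-values", {
  set.seed(2)
  s1 <- random_peptide(100)
  segs <- aa_set(c("a", "b", "c"), c(s1, s1, random_peptide(100)))
  g <- all_vs_all(segs, cutoff_levels = c(1e-10, 1e-3))
  # identical 100-mers share a minimal-E edge present at every cutoff
  e_ab <- g$edges[ (g$edges$a == "a" & g$edges$b == "b"), ]
  expect_equal(nrow(e_ab), 1L)
  expect_lt(e_ab$evalue, 1e-10)
  expect_true(all(g$edges$weight >= 0))
  # symmetric scoring: recomputing with swapped input order gives the
  # same E-value for the pair
  g2 <- all_vs_all(aa_set(c("b", "a"), c(s1, s1)),
                   cutoff_levels = c(1e-10, 1e-3))
  expect_equal(g2$edges$evalue[1], e_ab$evalue, tolerance = 1e-12)
  expect_warning(all_vs_all(aa_set(c("x", "y", "z"),
                                   c("MKVMKVMKVMKV", "MKVMKVMKVMKV", "MKV"))),
                 "shorter")
})

test_that("unrelated random sequences share no significant edge", {
  set.seed(6)
  hits <- replicate(60, {
    segs <- aa_set(c("u", "v"), c(random_peptide(100), random_peptide(100)))
    g <- all_vs_all(segs, cutoff_levels = c(1e-3))
    nrow(g$edges) > 0
  })
  expect_gte(mean(!hits), 0.99)
})

test_that("clustering yields nested components matching brute force", {
  set.seed(12)
  for (rep in 1:10) {
    n <- 12
    ids <- paste0("n", 1:n)
    pairs <- utils::combn(n, 2)
    ev <- 10^stats::runif(ncol(pairs), -30, 0)
    edges <- data.frame(a = ids[pairs[1, ]], b = ids[pairs[2, ]],
                        evalue = ev, weight = pmax(0, -log10(ev)))
    g <- structure(list(nodes = ids, edges = edges,
                        cutoff_levels = c(1e-20, 1e-10, 1e-5)),
                   class = "similarity_graph")
    h <- cluster_at_cutoffs(g)
    # nesting: every strict component is inside one looser component
    for (lv in seq_along(h$levels)[-length(h$levels)]) {
      for (comp in h$components[[lv]]) {
        containers <- Filter(function(s) all(comp %in% s),
                             h$components[[lv + 1]])
        expect_equal(length(containers), 1L)
      }
    }
    # brute-force components at one cutoff via repeated expansion
    cut <- h$levels[2]
    adj <- edges[edges$evalue <= cut, c("a", "b")]
    reach <- function(x) {
      seen <- x
      repeat {
        nb <- unique(c(adj$b[adj$a %in% seen], adj$a[adj$b %in% seen]))
        new <- setdiff(nb, seen)
        if (length(new) == 0) return(sort(seen))
        seen <- c(seen, new)
      }
    }
    comp2 <- unique(lapply(ids, reach))
    got <- lapply(h$components[[2]], sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(comp2, paste, collapse = ","))
  }
})

test_that("two cliques joined by one weak edge split at the strict cutoff", {
  ids <- c(paste0("p", 1:5), paste0("q", 1:5))
  strong <- expand.grid(a = ids[1:5], b = ids[1:5], stringsAsFactors = FALSE)
  strong <- strong[strong$a < strong$b, ]
  strong2 <- expand.grid(a = ids[6:10], b = ids[6:10], stringsAsFactors = FALSE)
  strong2 <- strong2[strong2$a < strong2$b, ]
  edges <- rbind(
    data.frame(strong, evalue = 1e-30),
    data.frame(strong2, evalue = 1e-30),
    data.frame(a = "p1", b = "q1", evalue = 1e-6))
  edges$weight <- -log10(edges$evalue)
  g <- structure(list(nodes = ids, edges = edges,
                      cutoff_levels = c(1e-20, 1e-4)),
                 class = "similarity_graph")
  h <- cluster_at_cutoffs(g)
  expect_equal(length(h$components[[1]]), 2L)
  expect_equal(length(h$components[[2]]), 1L)
})

test_that("reconcile accepts agreeing clusters and resolves by the tree", {
  # 3 planted groups of 4; tree groups them cleanly
  ids <- paste0(rep(c("a", "b", "c"), each = 4), 1:4)
  grp <- rep(c("a", "b", "c"), each = 4)
  txt <- "(((a1,a2),(a3,a4)),((b1,b2),(b3,b4)),((c1,c2),(c3,c4)));"
  tree <- ape::unroot(ape::read.tree(text = txt))
  tree$edge.length <- rep(1, nrow(tree$edge))
  mk_graph <- function(within, between) {
    pairs <- utils::combn(ids, 2)
    same <- grp[match(pairs[1, ], ids)] == grp[match(pairs[2, ], ids)]
    data.frame(a = pairs[1, ], b = pairs[2, ],
               evalue = ifelse(same, within, between),
               weight = -log10(ifelse(same, within, between)))
  }
  g <- structure(list(nodes = ids, edges = mk_graph(1e-30, 1e-6),
                      cutoff_levels = c(1e-20, 1e-4)),
                 class = "similarity_graph")
  h <- cluster_at_cutoffs(g)
  uni <- reconcile(h, tree, support_min = 70)
  expect_equal(length(uni$subgroups), 3L)
  expect_true(all(uni$table$provenance == "reconciled"))
  expect_setequal(uni$subgroups[[1]],
                  ids[grp == grp[match(uni$subgroups[[1]][1], ids)]])
  # a sequence clustered with group a but placed in clade b is re-homed by
  # the tree (clade-only provenance)
  grp2 <- grp; grp2[5] <- "a"   # b1 clusters with the a's
  g2 <- structure(list(nodes = ids, edges = {
    pairs <- utils::combn(ids, 2)
    same <- grp2[match(pairs[1, ], ids)] == grp2[match(pairs[2, ], ids)]
    data.frame(a = pairs[1, ], b = pairs[2, ],
               evalue = ifelse(same, 1e-30, 1e-6),
               weight = -log10(ifelse(same, 1e-30, 1e-6)))
  }, cutoff_levels = c(1e-20, 1e-4)), class = "similarity_graph")
  h2 <- cluster_at_cutoffs(g2)
  uni2 <- reconcile(h2, tree, support_min = 70)
  expect_equal(length(uni2$subgroups), 3L)
  lab_b1 <- uni2$assignment["b1"]
  expect_false(is.na(lab_b1))
  expect_setequal(uni2$subgroups[[lab_b1]], c("b1", "b2", "b3", "b4"))
  expect_true("clade-only" %in% uni2$table$provenance)
})

test_that("classification status rules follow bounds and margins", {
  mk <- function(name) {
    h <- toy_hmm(matrix(1 / 20, 3, 20), name = name)
    h$gumbel_lambda <- 0.7; h$gumbel_mu <- 0
    h$strict_evalue <- 1e-5; h$soft_evalue <- 1e-3
    h
  }
  lib <- list(A = mk("A"), B = mk("B"))
  hits <- data.frame(
    seq_id = "s", model = c("A", "B"), start = 0L, end = 50L,
    bits = c(100, 40), evalue = c(1e-30, 1e-4), rank = 1:2, group = 1L)
  a <- classify_domains(hits, lib, margin_min = 10)
  expect_equal(a$status, "firm")
  expect_equal(a$label, "A")
  expect_equal(a$margin_bits, 60)
  hits2 <- hits; hits2$bits <- c(52, 50); hits2$evalue <- c(1e-6, 1e-5)
  expect_equal(classify_domains(hits2, lib, 10)$status, "ambiguous")
  hits3 <- hits[1, ]; hits3$evalue <- 0.5
  expect_equal(classify_domains(hits3, lib, 10)$status, "unclassified")
  hits4 <- hits[1, ]; hits4$evalue <- 1e-4   # soft only, single model
  expect_equal(classify_domains(hits4, lib, 10)$status, "provisional")
})

test_that("ambiguity resolution prefers the nearer exemplar set", {
  set.seed(41)
  exA <- replicate(3, random_peptide(80))
  exB <- replicate(3, random_peptide(80))
  r <- resolve_ambiguous(exA[1], c("A", "B"),
                         list(A = exA, B = exB))
  expect_equal(r$label, "A")
  expect_equal(r$status, "firm")
  # symmetric construction stays ambiguous
  r2 <- resolve_ambiguous(exA[1], c("A", "B"), list(A = exA, B = exA))
  expect_true(is.na(r2$label))
  expect_equal(r2$status, "ambiguous")
  expect_error(resolve_ambiguous(exA[1], "A", list(A = exA)), ">= 2")
})

test_that("iterate reaches a fixed point when the database is the seeds", {
  ds <- cached("small_ds", synth_dataset(small_synth_config(), seed = 101))
  seeds <- seed_alignments(ds, n_per_family = 6)
  # database = exactly the (degapped) seed segments
  rows <- unlist(lapply(seeds, function(a)
    stats::setNames(gsub("-", "", a$rows), a$ids)))
  db <- aa_set(make.unique(names(rows)), unname(rows))
  st <- iterate(seeds, db,
                config = list(calibrate_n = 1000, calibrate_length = 250,
                              max_iter = 4))
  expect_true(st$converged)
  expect_lte(st$iteration, 3L)
  expect_equal(st$changed_count, 0L)
  # training alignments only ever grow (additive rule)
  expect_true(all(diff(st$log$iteration) == 1))
})
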