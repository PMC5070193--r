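test_that("build_matrix forms presence and copy numbers", {
  calls <- data.frame(
    species = c("sp1", "sp1", "sp1", "sp2", "sp2"),
    family = c("Cdc48", "NSF", "NVL", "Yta7", "Yta7"),
    seq_id = c("a", "b", "c", "d", "e"))
  pa <- build_matrix(calls)
  expect_true(all(pa$presence["sp1", c("Cdc48", "NSF", "NVL")]))
  expect_false(pa$presence["sp1", "Yta7"])
  # two distinct paralogs give copy number 2
  expect_equal(pa$copy_number["sp2", "Yta7"], 2L)
  # empty calls -> all-false matrix over the given universe
  empty <- build_matrix(calls[0, ], species = c("sp1", "sp2"),
                        families = c("Cdc48", "NSF"))
  expect_false(any(empty$presence))
  expect_warning(build_matrix(calls, species = "sp1"), "unmapped")
})

test_that("Dollo places the gain at the MRCA and minimal losses", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  pa <- build_matrix(data.frame(species = c("A", "B", "C"), family = "F",
                                seq_id = 1:3), species = c("A", "B", "C", "D"))
  anc <- dollo_ancestral(pa, tr)
  ev <- anc$events
  expect_equal(ev$type, c("gain", "loss"))
  expect_equal(ev$branch[ev$type == "loss"], "D")
  # present at root under the single-gain constraint
  expect_equal(leca_set(anc), "F")
  # family in all leaves: gain at root, zero losses
  pa2 <- build_matrix(data.frame(species = c("A", "B", "C", "D"),
                                 family = "G", seq_id = 1:4))
  expect_equal(sum(dollo_ancestral(pa2, tr)$events$type == "loss"), 0)
  # family absent everywhere is skipped with a warning
  pa3 <- pa; pa3$presence[, 1] <- FALSE
  expect_warning(dollo_ancestral(pa3, tr), "no species")
})

test_that("Dollo equals exhaustive minimum-loss search on random trees", {
  set.seed(17)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, tip.label = paste0("s", 1:n))
    have <- sample(tr$tip.label, sample(1:n, 1))
    pa <- build_matrix(data.frame(species = have, family = "F",
                                  seq_id = seq_along(have)),
                       species = tr$tip.label)
    anc <- dollo_ancestral(pa, tr)
    losses <- sum(anc$events$type == "loss")
    expect_equal(losses, brute_force_dollo(tr, have),
                 label = paste("tree", k))
    # gain node is the MRCA of possessing leaves
    gain <- anc$events$node[anc$events$type == "gain"]
    mrca <- if (length(have) == 1) match(have, tr$tip.label) else
      ape::getMRCA(tr, have)
    expect_equal(gain, mrca)
  }
})

test_that("the example parasite repertoire yields the 3-member core and an 8-member LECA set", {
  ex <- cdc48_repertoire_example()
  core <- minimal_core(ex$matrix)
  expect_equal(core, c("Cdc48", "NSF", "NVL"))
  anc <- dollo_ancestral(ex$matrix, ex$tree)
  expect_equal(length(leca_set(anc)), 8L)
  # dropping a family everywhere shrinks the LECA set by exactly it
  m2 <- ex$matrix
  m2$presence[, "Spaf"] <- FALSE
  m2$copy_number[, "Spaf"] <- 0L
  anc2 <- suppressWarnings(dollo_ancestral(m2, ex$tree))
  expect_equal(setdiff(leca_set(anc), leca_set(anc2)), "Spaf")
})

test_that("minimal_core is the row intersection and shrinks monotonically", {
  pa <- build_matrix(data.frame(
    species = c("x", "x", "y", "y", "z"),
    family = c("A", "B", "A", "B", "A"),
    seq_id = 1:5))
  expect_equal(minimal_core(pa), "A")
  # single species: its own repertoire
  one <- build_matrix(data.frame(species = "x", family = c("A", "B"),
                                 seq_id = 1:2))
  expect_equal(minimal_core(one), c("A", "B"))
  # disjoint repertoires: empty core
  dis <- build_matrix(data.frame(species = c("x", "y"),
                                 family = c("A", "B"), seq_id = 1:2))
  expect_equal(length(minimal_core(dis)), 0L)
  # adding a species never grows the core
  set.seed(4)
  for (k in 1:10) {
    sp <- paste0("s", 1:4)
    fams <- paste0("f", 1:5)
    calls <- expand.grid(species = sp, family = fams,
                         stringsAsFactors = FALSE)
    calls <- calls[stats::runif(nrow(calls)) < 0.6, ]
    if (nrow(calls) == 0) next
    calls$seq_id <- seq_len(nrow(calls))
    small <- build_matrix(calls[calls$species != "s4", ],
                          species = sp[1:3], families = fams)
    full <- build_matrix(calls, species = sp, families = fams)
    expect_true(all(minimal_core(full) %in% minimal_core(small)))
  }
})

test_that("duplications are reported per cell and mapped to lineages", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  calls <- data.frame(
    species = c("A", "A", "B", "B", "C"),
    family = "Yta7", seq_id = c("a1", "a2", "b1", "b2", "c1"))
  ev <- find_duplications(calls, tr)
  expect_equal(sum(ev$type == "duplication"), 2L)
  lin <- ev[ev$type == "lineage_duplication", ]
  expect_equal(nrow(lin), 1L)
  # MRCA of the multi-copy species A and B
  expect_equal(lin$branch, paste0("node", ape::getMRCA(tr, c("A", "B"))))
  # all single-copy: no events
  none <- find_duplications(data.frame(species = "A", family = "X",
                                       seq_id = "q"), tr)
  expect_equal(nrow(none), 0L)
})

test_that("uncertain absences suppress loss calls", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  pa <- build_matrix(data.frame(species = c("A", "B", "C"), family = "F",
                                seq_id = 1:3), species = c("A", "B", "C", "D"))
  anc <- dollo_ancestral(pa, tr,
                         uncertain = data.frame(species = "D", family = "F"))
  expect_equal(sum(anc$events$type == "loss"), 0L)
})
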