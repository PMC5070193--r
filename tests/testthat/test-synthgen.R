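test_that("default configuration encodes the study design", {
  cfg <- default_config()
  arch <- vapply(cfg$families, function(f) isTRUE(f$archaeal), logical(1))
  expect_equal(sum(!arch), 8L)   # eight eukaryotic families
  expect_equal(sum(arch), 1L)    # one archaeal family
  expect_equal(cfg$losses[[1]]$keep, c("Cdc48", "NSF", "NVL"))
  expect_equal(cfg$tree$root_to_tip, 0.8)
  # YAML round trip
  y <- config_to_yaml(cfg)
  cfg2 <- config_from_yaml(y)
  expect_equal(cfg2, cfg)
})

test_that("profiles are deterministic, motif-true, and scrambled on demand", {
  cfg <- small_synth_config()
  p1 <- make_profiles(cfg, seed = 5)
  p2 <- make_profiles(cfg, seed = 5)
  expect_identical(p1, p2)
  p3 <- make_profiles(cfg, seed = 6)
  expect_false(identical(p1$domains[["Cdc48.D1"]]$residues,
                         p3$domains[["Cdc48.D1"]]$residues))
  # Sensor 2 is GAD in all non-degenerate profiles
  for (nm in names(p1$domains)) {
    d <- p1$domains[[nm]]
    if ("sensor_2" %in% d$degenerate) next
    at <- d$motifs$sensor_2
    expect_equal(tandemaaa:::aa_decode(d$residues[(at[1] + 1):at[2]]), "GAD",
                 label = nm)
  }
  # NSF D2 sensor 2 carries the lysine variant
  at <- p1$domains[["NSF.D2"]]$motifs$sensor_2
  expect_equal(tandemaaa:::aa_decode(
    p1$domains[["NSF.D2"]]$residues[(at[1] + 1):at[2]]), "GAK")
  # scrambled Walker A differs from canonical at >= 4 of 8 positions
  wa <- p1$domains[["Pex1.D1"]]$motifs$walker_a
  obs <- p1$domains[["Pex1.D1"]]$residues[(wa[1] + 1):wa[2]]
  canon <- tandemaaa:::aa_encode("GPPGTGKT")
  expect_gte(sum(obs != canon), 4L)
})

test_that("evolution respects rate 0 and the Poisson site law", {
  cfg <- small_synth_config()
  cfg$evolution$rate <- 0
  cfg$evolution$indel_rate <- 0
  ds0 <- synth_dataset(cfg, seed = 3)
  # all leaves of a family identical at rate 0
  cdc <- ds0$sequences$residues[grepl("_Cdc48$", ds0$sequences$id)]
  expect_equal(length(unique(cdc)), 1L)
  # truth coordinates slice the planted domain exactly (compare against the
  # profile construct)
  prof <- ds0$profiles$domains[["Cdc48.D1"]]
  reg <- ds0$regions
  r <- reg[reg$seq_id == ds0$truth$seq_id[ds0$truth$family == "Cdc48"][1] &
           reg$region == "D1", ]
  seg <- substr(cdc[1], r$start + 1, r$end)
  expect_equal(seg, tandemaaa:::aa_decode(prof$residues))
  # small-branch substitution fraction ~ 1 - exp(-b)
  set.seed(8)
  b <- 0.1
  tab <- data.frame(pos = as.numeric(0:499),
                    res = tandemaaa:::sample_background(500),
                    prot = FALSE)
  frac <- replicate(40, {
    t2 <- tandemaaa:::evolve_branch(tab, b, rate = 1, indel_rate = 0)
    mean(t2$res != tab$res)
  })
  expected <- 1 - exp(-b) * (1 + 0)  # ignoring back-substitution at small b
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - expected), 3 * se + 0.01)
})

test_that("datasets are deterministic under seed and distinct across seeds", {
  cfg <- small_synth_config()
  d1 <- synth_dataset(cfg, seed = 21)
  d2 <- synth_dataset(cfg, seed = 21)
  expect_identical(d1$sequences$residues, d2$sequences$residues)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  d3 <- synth_dataset(cfg, seed = 22)
  expect_false(identical(d1$sequences$residues, d3$sequences$residues))
})

test_that("planted events are visible in the truth ledger", {
  ds <- cached("small_ds", synth_dataset(small_synth_config(), seed = 101))
  # the parasite clade retains only the minimal core
  para <- ds$clades$parasite
  kept <- unique(ds$truth$family[ds$truth$species %in% para])
  expect_setequal(kept, c("Cdc48", "NSF", "NVL"))
  # loss bookkeeping matches the truth matrix
  pa <- build_matrix(ds$truth[, c("species", "family", "seq_id")])
  expect_false(any(pa$presence[para, "Yta7"]))
  expect_true(all(pa$presence[para, "Cdc48"]))
  # planted duplication: two truth rows, same family and species
  dup_sp <- ds$clades$duplication
  expect_true(all(pa$copy_number[dup_sp, "Yta7"] == 2L))
  expect_true(all(ds$truth$copy[ds$truth$species %in% dup_sp &
                                ds$truth$family == "Yta7"] %in% 1:2))
  # no events -> dataset equals the evolve output
  cfg0 <- small_synth_config()
  cfg0$losses <- list(); cfg0$duplications <- list()
  ds0 <- synth_dataset(cfg0, seed = 101)
  expect_equal(nrow(ds0$truth),
               (12 * 8) + 4)  # every eukaryote x family + archaea x VAT
  expect_equal(nrow(ds0$events), 0L)
})

test_that("tandem constructs order N, D1, D2 and terminal motifs", {
  ds <- cached("small_ds", synth_dataset(small_synth_config(), seed = 101))
  reg <- ds$regions
  id <- ds$truth$seq_id[ds$truth$family == "Cdc48"][1]
  r <- reg[reg$seq_id == id, ]
  get <- function(what) r[r$region == what, c("start", "end")]
  expect_lt(get("N")$end, get("D1")$start + 1)
  expect_lte(get("D1")$end, get("D2")$start)
  expect_lte(get("D2")$end, get("tail")$start)
  s <- ds$sequences$residues[ds$sequences$id == id]
  expect_true(detect_hbyx(s))
  # NSF has no tail region planted
  id2 <- ds$truth$seq_id[ds$truth$family == "NSF"][1]
  expect_false("tail" %in% reg$region[reg$seq_id == id2])
})

test_that("truth-based seed alignments degap to planted subsequences", {
  ds <- cached("small_ds", synth_dataset(small_synth_config(), seed = 101))
  seeds <- seed_alignments(ds, n_per_family = 5)
  expect_equal(length(seeds), 18L)
  is_subseq <- function(x, y) {
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    j <- 1L
    for (ch in ys) {
      if (j <= length(xs) && xs[j] == ch) j <- j + 1L
    }
    j > length(xs)
  }
  a <- seeds[["Spaf.D1"]]
  for (i in seq_along(a$ids)) {
    sid <- sub("\\.D1$", "", a$ids[i])
    full <- ds$sequences$residues[ds$sequences$id == sid]
    degap <- gsub("-", "", a$rows[i])
    # the aligned row (ancestral columns only) is a subsequence of the
    # protein's planted D1 segment
    reg <- ds$regions[ds$regions$seq_id == sid & ds$regions$region == "D1", ]
    seg <- substr(full, reg$start + 1, reg$end)
    expect_true(is_subseq(degap, seg), label = a$ids[i])
  }
})
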