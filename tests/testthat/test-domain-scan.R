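# scanning, architecture calls, terminal motifs, motif degeneracy, logos

small_ds <- function() cached("small_ds", synth_dataset(small_synth_config(),
                                                        seed = 101))
small_lib <- function() cached("small_lib", {
  ds <- small_ds()
  tandemaaa:::build_library(
    seed_alignments(ds, n_per_family = 6L),
    tandemaaa:::seed_motif_annotations(ds),
    config = list(calibrate_n = 2000, calibrate_length = 300))
})

test_that("HbYX detection follows the hydrophobic-Y-any rule", {
  expect_true(detect_hbyx("MKVAYG"))
  expect_false(detect_hbyx("MKVGYG"))   # G is not hydrophobic
  expect_false(detect_hbyx("MKVAFG"))   # F != Y under the strict rule
  expect_true(detect_hbyx("MKVAFG", allow_f = TRUE))
  expect_error(detect_hbyx("AY"), "shorter")
})

test_that("logo information content matches closed forms", {
  a <- msa(c(r1 = "GAW", r2 = "GAV", r3 = "GCW", r4 = "GCV"))
  lg <- compute_logo(a)
  expect_equal(lg$info_bits[1], log2(20), tolerance = 1e-9)   # all G
  expect_equal(lg$info_bits[2], log2(20) - 1, tolerance = 1e-9) # half A half C
  expect_equal(lg$info_bits[3], log2(20) - 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(lg$columns) - 1) < 1e-9))
  # uniform column over the 20 residues has zero information
  u <- msa(stats::setNames(AA, paste0("r", 1:20)))
  expect_equal(compute_logo(u)$info_bits[1], 0, tolerance = 1e-9)
  # all-gap columns are flagged, not NaN
  g <- msa(c(r1 = "A-", r2 = "C-"))
  lg2 <- compute_logo(g)
  expect_true(lg2$undefined[2])
  expect_equal(lg2$info_bits[2], 0)
  # letter heights (freq * info) never exceed the stack height
  expect_true(all(lg$columns * lg$info_bits <= lg$info_bits + 1e-12))
})

test_that("scanning a planted protein ranks the true model first", {
  ds <- small_ds()
  lib <- small_lib()
  id <- ds$truth$seq_id[ds$truth$family == "Cdc48"][1]
  h <- scan_sequence(tandemaaa:::aa_subset(ds$sequences, id), lib$library,
                     n_database = nrow(ds$sequences))
  r1 <- h[h$rank == 1, ]
  expect_true("Cdc48.D1" %in% r1$model)
  expect_true("Cdc48.D2" %in% r1$model)
  # tandem: the two rank-1 envelopes are disjoint and ordered D1 before D2
  d1 <- r1[r1$model == "Cdc48.D1", ]; d2 <- r1[r1$model == "Cdc48.D2", ]
  expect_lte(d1$end, d2$start)
  expect_lte(nrow(r1[r1$rank > 4, ]), 0)
  expect_error(scan_sequence("MKV", list(build_hmm(random_msa(3, 8)))),
               "uncalibrated")
})

test_that("random background sequences pass no soft bound", {
  lib <- small_lib()
  set.seed(33)
  nohit <- vapply(1:25, function(i) {
    h <- scan_sequence(random_peptide(400), lib$library, n_database = 100)
    nrow(h) == 0
  }, logical(1))
  expect_gte(mean(nohit), 0.99)
})

test_that("architecture calls recover planted flags and insert lengths", {
  ds <- small_ds()
  lib <- small_lib()
  arch_of <- function(fam) {
    id <- ds$truth$seq_id[ds$truth$family == fam][1]
    seqr <- tandemaaa:::aa_subset(ds$sequences, id)
    h <- scan_sequence(seqr, lib$library, n_database = nrow(ds$sequences))
    call_architecture(seqr, h, lib$library, lib$annotations)
  }
  cdc <- arch_of("Cdc48")
  expect_true(cdc$has_tandem_D1D2)
  expect_true(cdc$has_tail_helix_tyr)
  expect_true(cdc$has_hbyx)
  nsf <- arch_of("NSF")
  expect_true(nsf$has_tandem_D1D2)
  expect_false(nsf$has_tail_helix_tyr)   # tail helix lost in NSF
  expect_false(nsf$has_hbyx)
  # NVL: ~50-residue insert before the terminal helix of D1
  nvl <- arch_of("NVL")
  expect_true(nvl$has_tandem_D1D2)
  expect_equal(nvl$insert_lengths[["D1.pre_terminal_helix"]], 50,
               tolerance = 10 / 50)
  expect_lt(abs(cdc$insert_lengths[["D1.pre_terminal_helix"]]), 10)
})

test_that("tail-helix detection is false when the sequence ends early", {
  d2 <- data.frame(start = 10L, end = 40L)
  expect_false(detect_tail_helix_tyr("MKV", d2))
  s <- paste0(random_peptide(40), "ARELDVSYQTAGLKE")
  expect_true(detect_tail_helix_tyr(s, data.frame(start = 5L, end = 40L)))
})

test_that("motif degeneracy separates intact from scrambled families", {
  cfg <- small_synth_config()
  intact <- synth_star_sample(cfg, "Cdc48", n = 50, divergence = 0.8,
                              seed = 7)
  degen <- synth_star_sample(cfg, "Pex1", n = 50, divergence = 0.8, seed = 8)
  lib <- small_lib()
  # degeneracy of the D1 segment (planted coordinates) under the canonical
  # Walker PFM of the intact reference subgroup
  walker_deg <- function(star, model_name) {
    model <- lib$library[[model_name]]
    ann <- lib$annotations[[model_name]]
    vapply(seq_len(nrow(star$sequences)), function(i) {
      id <- star$sequences$id[i]
      reg <- star$regions[star$regions$seq_id == id &
                          star$regions$region == "D1", ]
      seg <- substr(star$sequences$residues[i], reg$start + 1L, reg$end)
      ms <- extract_motifs(seg, NULL, model, ann[c("walker_a", "walker_b")])
      mean(vapply(ms, `[[`, numeric(1), "degeneracy"))
    }, numeric(1))
  }
  d_int <- walker_deg(intact, "Cdc48.D1")
  d_deg <- walker_deg(degen, "Cdc48.D1")
  wt <- stats::wilcox.test(d_deg, d_int, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  # intact segments sit well below the scrambled ones (absolute degeneracy
  # is bounded away from 0 by the pseudocount smoothing of a 6-row PFM)
  expect_lt(median(d_int) + 0.15, median(d_deg))
})

test_that("degeneracy score hits its limits", {
  # consensus-identical segment under a near-deterministic PFM -> ~0
  me <- matrix(1e-6, 8, 20)
  canon <- strsplit("GPPGTGKT", "")[[1]]
  for (i in 1:8) me[i, match(canon[i], AA)] <- 1
  me <- me / rowSums(me)
  h <- toy_hmm(me)
  ms <- extract_motifs("GPPGTGKT", NULL, h, list(walker_a = c(0L, 8L)))
  expect_lt(ms$walker_a$degeneracy, 1e-3)
  expect_equal(ms$walker_a$observed, "GPPGTGKT")
  # a fully different segment under the same sharp PFM -> ~1
  ms2 <- extract_motifs("VVVVVVVV", NULL, h, list(walker_a = c(0L, 8L)))
  expect_gt(ms2$walker_a$degeneracy, 0.999)
  expect_error(extract_motifs("GPPGTGKT", NULL, h, list(w = c(0L, 9L))),
               "outside")
})
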