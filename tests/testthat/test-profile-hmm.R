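test_that("gap filtering follows the strict more-than-50% rule", {
  # column gap fractions 1/4, 2/4, 1/4, 1/4: exactly 50% is kept
  rows <- c(a = "A-CD", b = "A-CD", c = "AAC-", d = "-A-D")
  filt <- filter_alignment(msa(rows), col_gap_max = 0.5)
  expect_equal(filt$alignment$ncols, 4L)
  expect_equal(filt$mask$keep, rep(TRUE, 4))
  aln <- msa(c(a = "AC", b = "AC", c = "AC", d = "--"))
  # row d is 100% gaps -> removed; columns have 1/4 gaps -> kept
  filt2 <- filter_alignment(aln)
  expect_equal(length(filt2$alignment$ids), 3L)
  # a 4-row column with 3 gaps (0.75) is removed, with exactly 2 (0.5) kept
  aln3 <- msa(c(a = "A-CA", b = "A--A", c = "A-CA", d = "AC-A"))
  filt3 <- filter_alignment(aln3)
  expect_equal(filt3$mask$keep, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("build_hmm satisfies probability invariants and limit cases", {
  set.seed(1)
  a <- random_msa(6, 15, gap_p = 0.15)
  h <- build_hmm(a, "m")
  expect_silent(validate_hmm(h))
  expect_true(all(abs(rowSums(h$match_emissions) - 1) < 1e-9))
  # single-column all-A alignment with vanishing pseudocounts -> P(A) ~ 1
  one <- msa(c(r1 = "A", r2 = "A", r3 = "A"))
  h1 <- build_hmm(one, pseudocount_strength = 1e-9, emission_floor = 1e-12)
  expect_gt(h1$match_emissions[1, "A"], 1 - 1e-6)
  # uniform weighting: duplicating rows does not change the model
  two <- msa(c(r1 = "AC", r2 = "GV"))
  ten <- msa(stats::setNames(rep(c("AC", "GV"), 5), paste0("r", 1:10)))
  h2 <- build_hmm(two, weighting = "uniform")
  h10 <- build_hmm(ten, weighting = "uniform")
  expect_equal(h2$match_emissions, h10$match_emissions, tolerance = 1e-3)
  expect_error(build_hmm(msa(c(r1 = "A-", r2 = "C-"))), "all-gap")
})

test_that("viterbi matches the single-path closed form", {
  me <- matrix(1e-12, 1, 20); me[1, 1] <- 1; me <- me / sum(me)
  h <- toy_hmm(me)
  v <- viterbi(h, "A")
  expect_equal(v$score, log2(20), tolerance = 1e-9)
  expect_equal(unname(v$envelope), c(0L, 1L))
  # mismatch scores the floored emission: log2(eps / 0.05)
  eps <- me[1, 2]
  expect_equal(viterbi(h, "C")$score, log2(eps / 0.05), tolerance = 1e-6)
  # single-path model: forward equals viterbi
  expect_equal(forward_score(h, "A"), v$score, tolerance = 1e-9)
})

test_that("forward and viterbi agree with exhaustive path enumeration", {
  set.seed(11)
  for (L in 1:3) {
    for (rep in 1:4) {
      h <- random_toy_hmm(L)
      s <- random_peptide(sample(1:4, 1))
      scores <- enumerate_path_scores(h, s)
      expect_equal(viterbi(h, s)$score, max(scores), tolerance = 1e-8,
                   label = sprintf("viterbi L=%d seq=%s", L, s))
      expect_equal(forward_score(h, s), log2(sum(2^scores)),
                   tolerance = 1e-8,
                   label = sprintf("forward L=%d seq=%s", L, s))
    }
  }
})

test_that("forward >= viterbi on random model/sequence pairs", {
  set.seed(5)
  for (k in 1:60) {
    h <- random_toy_hmm(sample(2:6, 1))
    s <- random_peptide(sample(1:10, 1))
    expect_gte(forward_score(h, s) + 1e-9, viterbi(h, s)$score)
  }
})

test_that("Gumbel ML fit recovers known parameters within 5%", {
  set.seed(3)
  lambda <- 0.7; mu <- 10
  x <- mu - log(-log(runif(10000))) / lambda
  f <- fit_gumbel(x)
  expect_lt(abs(f$lambda - lambda) / lambda, 0.05)
  expect_lt(abs(f$mu - mu) / abs(mu), 0.05)
  expect_error(fit_gumbel(rep(1, 100)), "degenerate")
})

test_that("calibration fixes the Gumbel location identity P(S >= mu)", {
  set.seed(9)
  a <- random_msa(8, 30, gap_p = 0.05)
  h <- calibrate(build_hmm(a, "m"), n_random = 2000,
                 length_law = list(type = "fixed", length = 200), seed = 4)
  expect_false(is.na(h$gumbel_lambda))
  # fresh nulls from the same background law as the calibration draw
  scores <- tandemaaa:::viterbi_scores(
    h, withr::with_seed(99, replicate(2000, random_bg_peptide(200, h$background))))
  # P(score >= mu) = 1 - exp(-1) for a Gumbel
  frac <- mean(scores >= h$gumbel_mu)
  se <- sqrt(frac * (1 - frac) / 2000)
  expect_lt(abs(frac - (1 - exp(-1))), 3 * se + 0.02)
  expect_error(calibrate(h, n_random = 10), ">= 1000")
})

test_that("E-values are calibrated: P(E < 1) is about 1/N on fresh nulls", {
  set.seed(10)
  a <- random_msa(8, 30, gap_p = 0.05)
  h <- calibrate(build_hmm(a, "m"), n_random = 5000,
                 length_law = list(type = "fixed", length = 200), seed = 4)
  n_db <- 20
  scores <- tandemaaa:::viterbi_scores(
    h, withr::with_seed(77, replicate(3000, random_bg_peptide(200, h$background))))
  frac <- mean(hmm_evalue(h, scores, n_db) < 1)
  p <- 1 / n_db
  se <- sqrt(p * (1 - p) / 3000)
  expect_lt(abs(frac - p), 3 * se + 0.02)
})

test_that("profile-profile alignment: self, pairwise oracle, width", {
  set.seed(21)
  a <- random_msa(4, 18, gap_p = 0)
  self <- align_profiles(a, {
    b <- a; b$ids <- paste0(b$ids, "_b")
    msa(stats::setNames(b$rows, b$ids))
  })
  expect_equal(self$ncols, a$ncols)  # identity mapping, no gaps
  expect_true(all(!grepl("-", self$rows)))
  # two single-row profiles reduce to global pairwise alignment
  s1 <- "MKVLDEAGHKL"; s2 <- "MKVIDEAGKL"
  pa <- align_profiles(msa(c(x = s1)), msa(c(y = s2)))
  ora <- Biostrings::pairwiseAlignment(s1, s2, substitutionMatrix = "BLOSUM62",
                                       gapOpening = 11, gapExtension = 1,
                                       type = "global")
  expect_equal(gsub("-", "", pa$rows[1]), s1)
  expect_equal(gsub("-", "", pa$rows[2]), s2)
  expect_equal(pa$ncols, nchar(as.character(Biostrings::alignedPattern(ora))))
  # output is never narrower than either input
  for (k in 1:5) {
    x <- random_msa(3, sample(8:16, 1), gap_p = 0.1)
    y <- random_msa(3, sample(8:16, 1), gap_p = 0.1,
                    ids = paste0("t", 1:3))
    j <- align_profiles(x, y)
    expect_gte(j$ncols, max(x$ncols, y$ncols))
  }
})

test_that("model JSON serialization round-trips", {
  set.seed(2)
  a <- random_msa(5, 12)
  h <- build_hmm(a, "roundtrip")
  h$gumbel_lambda <- 0.9; h$gumbel_mu <- -12.5
  js <- hmm_to_json(h)
  h2 <- hmm_from_json(js)
  expect_equal(h2$match_emissions, h$match_emissions)
  expect_equal(h2$transitions$t, h$transitions$t)
  expect_equal(h2$gumbel_mu, h$gumbel_mu)
  expect_equal(h2$name, h$name)
})
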