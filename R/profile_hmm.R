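# Per-subgroup profile HMMs: alignment filtering, model construction with
# position-based weighting and background-proportional pseudocounts, exact
# glocal Viterbi/forward scoring, Gumbel E-value calibration, and
# profile-profile alignment for joining domain alignments.
#
# Architecture: plan7-style glocal (global in the model, local in the
# sequence). Match states correspond to alignment columns; insert emissions
# equal the background, so inserted residues score zero log-odds.

#' Filter alignment columns and rows by gap content
#'
#' Columns whose gap fraction strictly exceeds `col_gap_max` are removed
#' first; then rows whose gap fraction over the kept columns strictly
#' exceeds `row_gap_max` are removed. The default 0.5/0.5 drops columns and
#' sequences that are more than 50 % gaps.
#'
#' @param aln an [msa].
#' @param col_gap_max maximum tolerated column gap fraction (exclusive).
#' @param row_gap_max maximum tolerated row gap fraction (exclusive).
#' @return list with `alignment` (filtered [msa]) and `mask` (list with
#'   logical `keep` per original column and `gap_threshold`).
#' @export
filter_alignment <- function(aln, col_gap_max = 0.5, row_gap_max = 0.5) {
  stopifnot(inherits(aln, "msa"))
  m <- msa_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= col_gap_max
  if (!any(keep)) stop("no columns survive the gap filter")
  m2 <- m[, keep, drop = FALSE]
  row_frac <- rowMeans(m2 == "-")
  keep_rows <- row_frac <= row_gap_max
  if (!any(keep_rows)) stop("no rows survive the gap filter")
  out <- msa_from_matrix(m2[keep_rows, , drop = FALSE])
  list(alignment = out,
       mask = list(keep = unname(keep), gap_threshold = col_gap_max))
}

# Henikoff position-based sequence weights, normalized to sum to the number
# of rows. Gap cells contribute nothing.
position_weights <- function(m) {
  n <- nrow(m)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) == 0L) next
    tab <- table(res)
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col]))
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  if (sum(w) == 0) w <- rep(1, n)
  w * n / sum(w)
}

#' Build a profile HMM from a filtered alignment
#'
#' Every alignment column becomes a match state. Match emissions are
#' weighted residue counts plus background-proportional pseudocounts of
#' total strength `pseudocount_strength`, floored at `emission_floor` and
#' renormalized. Insert emissions equal the background. Transitions are
#' weighted observed match/delete moves plus Laplace pseudocounts (insert
#' moves are never observed in a column-complete alignment, so insert
#' transitions come from the pseudocounts alone).
#'
#' @param aln filtered [msa] with at least 2 rows.
#' @param name subgroup label.
#' @param weighting `"position-based"` (Henikoff) or `"uniform"`.
#' @param pseudocount_strength total emission pseudocount mass per column,
#'   distributed proportionally to the background (default 20 times the
#'   background frequency of each residue).
#' @param transition_pseudocount Laplace count added to every transition.
#' @param emission_floor minimum match-emission probability after
#'   normalization.
#' @param background 20-vector of background frequencies.
#' @return an object of class `profile_hmm`.
#' @export
build_hmm <- function(aln, name = "model",
                      weighting = c("position-based", "uniform"),
                      pseudocount_strength = 20,
                      transition_pseudocount = 1,
                      emission_floor = 1e-6,
                      background = AA_BACKGROUND) {
  stopifnot(inherits(aln, "msa"))
  weighting <- match.arg(weighting)
  m <- msa_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 alignment rows")
  if (any(colMeans(m == "-") == 1)) stop("all-gap column in alignment")
  n <- nrow(m); L <- ncol(m)
  w <- if (weighting == "position-based") position_weights(m) else rep(1, n)
  # effective sample size = number of distinct rows, so that duplicating
  # rows never changes the model (count proportionality)
  n_eff <- nrow(unique(m))
  w <- w * n_eff / sum(w)
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-6)

  # match emissions
  me <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- m[, j]
    ok <- col %in% AA20
    if (any(ok)) {
      cnt <- tapply(w[ok], factor(col[ok], levels = AA20), sum)
      cnt[is.na(cnt)] <- 0
      me[j, ] <- cnt
    }
    me[j, ] <- me[j, ] + pseudocount_strength * background
    me[j, ] <- me[j, ] / sum(me[j, ])
    me[j, ] <- pmax(me[j, ], emission_floor)
    me[j, ] <- me[j, ] / sum(me[j, ])
  }
  ie <- matrix(rep(background, each = L + 1L), L + 1L, 20,
               dimnames = list(NULL, AA20))

  # transitions: states per row per column are M (residue) or D (gap)
  isM <- m != "-"
  tp <- transition_pseudocount
  tmat <- matrix(0, L, 7, dimnames = list(NULL,
    c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  for (j in seq_len(L - 1L)) {
    a <- isM[, j]; b <- isM[, j + 1L]
    c_mm <- sum(w[a & b]); c_md <- sum(w[a & !b])
    c_dm <- sum(w[!a & b]); c_dd <- sum(w[!a & !b])
    mrow <- c(c_mm + tp, tp, c_md + tp)
    tmat[j, 1:3] <- mrow / sum(mrow)
    tmat[j, 4:5] <- c(tp, tp) / (2 * tp)
    drow <- c(c_dm + tp, c_dd + tp)
    tmat[j, 6:7] <- drow / sum(drow)
  }
  tmat[L, ] <- c(1, 0, 0, 1, 0, 1, 0)  # exits to E are free
  b_m <- sum(w[isM[, 1L]]) + tp
  b_d <- sum(w[!isM[, 1L]]) + tp
  bm <- c(b_m, b_d) / (b_m + b_d)

  hmm <- structure(list(
    name = name, L = L,
    match_emissions = me, insert_emissions = ie,
    transitions = list(begin = bm, t = tmat),
    background = stats::setNames(as.numeric(background), AA20),
    gumbel_lambda = NA_real_, gumbel_mu = NA_real_,
    strict_evalue = 1e-5, soft_evalue = 1e-3,
    emission_floor = emission_floor
  ), class = "profile_hmm")
  validate_hmm(hmm)
  hmm
}

#' Validate profile HMM probability invariants
#' @param hmm a `profile_hmm`.
#' @param tol tolerance on probability sums.
#' @export
validate_hmm <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (any(abs(rowSums(hmm$match_emissions) - 1) > tol))
    stop("match emission rows must sum to 1")
  if (any(abs(rowSums(hmm$insert_emissions) - 1) > tol))
    stop("insert emission rows must sum to 1")
  if (abs(sum(hmm$background) - 1) > tol) stop("background must sum to 1")
  tm <- hmm$transitions$t
  if (any(abs(rowSums(tm[, 1:3, drop = FALSE]) - 1) > tol) ||
      any(abs(rowSums(tm[, 4:5, drop = FALSE]) - 1) > tol) ||
      any(abs(rowSums(tm[, 6:7, drop = FALSE]) - 1) > tol) ||
      abs(sum(hmm$transitions$begin) - 1) > tol)
    stop("transition rows must sum to 1")
  if (!is.na(hmm$strict_evalue) && !is.na(hmm$soft_evalue) &&
      hmm$strict_evalue > hmm$soft_evalue)
    stop("strict_evalue must be <= soft_evalue")
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$name, "': L = ", x$L,
      if (!is.na(x$gumbel_lambda)) sprintf(", Gumbel(lambda=%.3f, mu=%.2f)",
                                           x$gumbel_lambda, x$gumbel_mu)
      else ", uncalibrated",
      "\n", sep = "")
  invisible(x)
}

# precompute log2-odds matrices for the C scoring kernels
hmm_logodds <- function(hmm) {
  lbg <- log2(hmm$background)
  lm <- cbind(log2(hmm$match_emissions) - rep(lbg, each = hmm$L), X = 0)
  li <- cbind(log2(hmm$insert_emissions) -
                rep(lbg, each = hmm$L + 1L), X = 0)
  tm <- hmm$transitions$t
  ltr <- log2(tm)
  ltr[!is.finite(ltr)] <- -Inf
  list(lm = lm, li = li, lbm = log2(hmm$transitions$begin), ltr = ltr)
}

#' Glocal Viterbi alignment of a sequence to a profile HMM
#'
#' Exact dynamic programming, global in the model and local in the
#' sequence; flanking residues outside the envelope are emitted by a free
#' background loop. The score is the log2 odds of the best path against the
#' background model of the emitted residues.
#'
#' @param hmm a `profile_hmm`.
#' @param seq a residue string, or one row of an [aa_set].
#' @param mode only `"glocal"` is implemented.
#' @return list with `score` (bits), `envelope` (0-based half-open
#'   `c(start, end)`) and `matchmap` (per match state, the 0-based sequence
#'   position it emits, or NA for deletions).
#' @export
viterbi <- function(hmm, seq, mode = "glocal") {
  stopifnot(identical(mode, "glocal"))
  validate_hmm(hmm)
  s <- if (is.character(seq)) seq else seq$residues[[1L]]
  if (nchar(s) < 1L) stop("sequence length must be >= 1")
  lo <- hmm_logodds(hmm)
  r <- .vit_glocal(lo$lm, lo$li, lo$lbm, lo$ltr, aa_encode(s), TRUE)
  mm <- r$matchmap
  mm[mm < 0] <- NA_integer_
  list(score = r$score, envelope = c(start = r$start, end = r$end),
       matchmap = mm)
}

#' Glocal forward score of a sequence under a profile HMM
#'
#' As [viterbi] but summing over all paths in log space; always at least
#' the Viterbi score.
#'
#' @inheritParams viterbi
#' @return score in bits.
#' @export
forward_score <- function(hmm, seq) {
  validate_hmm(hmm)
  s <- if (is.character(seq)) seq else seq$residues[[1L]]
  if (nchar(s) < 1L) stop("sequence length must be >= 1")
  lo <- hmm_logodds(hmm)
  .fwd_glocal(lo$lm, lo$li, lo$lbm, lo$ltr, aa_encode(s))
}

# batch Viterbi scores (bits) for a list of residue strings
viterbi_scores <- function(hmm, residues) {
  lo <- hmm_logodds(hmm)
  .vit_scores_batch(lo$lm, lo$li, lo$lbm, lo$ltr, lapply(residues, aa_encode))
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits the location/scale of a Gumbel (type-I extreme value, maximum)
#' distribution by maximum likelihood.
#'
#' @param x numeric sample.
#' @return list with `lambda` (rate, inverse scale) and `mu` (location).
#' @export
fit_gumbel <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop("too few finite scores for a Gumbel fit")
  if (stats::sd(x) < 1e-12) stop("degenerate score distribution (variance 0)")
  xbar <- mean(x)
  x0 <- min(x)
  g <- function(lam) {
    z <- exp(-lam * (x - x0))  # bounded in (0, 1]
    1 / lam - xbar + sum(x * z) / sum(z)
  }
  lo <- 1e-3 / stats::sd(x); hi <- 1e3 / stats::sd(x)
  lam <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- x0 - log(mean(exp(-lam * (x - x0)))) / lam
  list(lambda = lam, mu = mu)
}

#' Calibrate a profile HMM against random background sequences
#'
#' Scores `n_random` i.i.d. background sequences with glocal Viterbi and
#' fits a Gumbel by maximum likelihood. The resulting `gumbel_lambda` and
#' `gumbel_mu` drive [hmm_evalue]: `E(S, N) = N * (1 - exp(-exp(-lambda *
#' (S - mu))))`.
#'
#' @param hmm a `profile_hmm`.
#' @param n_random number of random sequences (>= 1000).
#' @param length_law list: `list(type = "fixed", length = 400)` or
#'   `list(type = "empirical", lengths = <integer vector>)` to resample
#'   the scanned database's length distribution.
#' @param seed RNG seed for the calibration draw.
#' @return the model with `gumbel_lambda`, `gumbel_mu` set.
#' @export
calibrate <- function(hmm, n_random = 5000,
                      length_law = list(type = "fixed", length = 400),
                      seed = 1L) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (n_random < 1000) stop("n_random must be >= 1000")
  lens <- switch(length_law$type,
    fixed = rep.int(as.integer(length_law$length), n_random),
    empirical = {
      pool <- as.integer(length_law$lengths)
      if (length(pool) == 0L) stop("empty empirical length pool")
      withr_seed(seed * 7L, sample(pool, n_random, replace = TRUE))
    },
    stop("unknown length law: ", length_law$type))
  scores <- withr_seed(seed, {
    seqs <- lapply(lens, function(n)
      sample.int(20L, n, replace = TRUE, prob = hmm$background) - 1L)
    lo <- hmm_logodds(hmm)
    .vit_scores_batch(lo$lm, lo$li, lo$lbm, lo$ltr, seqs)
  })
  fit <- fit_gumbel(scores)
  hmm$gumbel_lambda <- fit$lambda
  hmm$gumbel_mu <- fit$mu
  hmm
}

# evaluate an expression under a local RNG seed without touching the
# caller's RNG stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' E-value of a bit score under a calibrated model
#' @param hmm calibrated `profile_hmm`.
#' @param score bit score(s).
#' @param n_database number of sequences in the scanned database.
#' @return E-value(s).
#' @export
hmm_evalue <- function(hmm, score, n_database) {
  if (is.na(hmm$gumbel_lambda)) stop("model '", hmm$name, "' is not calibrated")
  p <- -expm1(-exp(-hmm$gumbel_lambda * (score - hmm$gumbel_mu)))
  n_database * p
}

# column frequency matrix (L x 20) of an alignment, gaps and X excluded;
# all-gap columns get the background
profile_frequencies <- function(aln, background = AA_BACKGROUND) {
  m <- msa_matrix(aln)
  L <- ncol(m)
  f <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0L) { f[j, ] <- background; next }
    tab <- tabulate(match(col, AA20), 20L)
    f[j, ] <- tab / sum(tab)
  }
  f
}

#' Profile-profile alignment of two multiple alignments
#'
#' Joins two alignments into one by global dynamic programming over their
#' column frequency vectors, with column-pair score
#' `sum_ab fA(a) fB(b) BLOSUM62(a, b)` and affine gaps. All rows of both
#' inputs are stacked on the merged column coordinate system.
#'
#' @param alnA,alnB filtered [msa] objects with disjoint row ids.
#' @param gap_open,gap_extend affine gap costs (a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @return merged [msa].
#' @export
align_profiles <- function(alnA, alnB, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(alnA, "msa"), inherits(alnB, "msa"))
  if (any(alnA$ids %in% alnB$ids)) stop("row ids of the two alignments overlap")
  fA <- profile_frequencies(alnA)
  fB <- profile_frequencies(alnB)
  sub <- blosum62_aax()[1:20, 1:20]
  S <- fA %*% sub %*% t(fB)
  map <- .nw_affine_map(S, gap_open, gap_extend)
  mA <- msa_matrix(alnA); mB <- msa_matrix(alnB)
  k <- length(map$mapA)
  out <- matrix("-", nrow(mA) + nrow(mB), k,
                dimnames = list(c(rownames(mA), rownames(mB)), NULL))
  selA <- !is.na(map$mapA)
  out[seq_len(nrow(mA)), selA] <- t(mA[, map$mapA[selA], drop = FALSE])
  selB <- !is.na(map$mapB)
  out[nrow(mA) + seq_len(nrow(mB)), selB] <- t(mB[, map$mapB[selB], drop = FALSE])
  msa_from_matrix(out)
}

#' Serialize a profile HMM to JSON
#' @param hmm a `profile_hmm`.
#' @param path output file; if `NULL` the JSON string is returned.
#' @export
hmm_to_json <- function(hmm, path = NULL) {
  validate_hmm(hmm)
  obj <- list(schema = "tandemaaa-hmm-1", name = hmm$name, L = hmm$L,
              match_emissions = unname(hmm$match_emissions),
              insert_emissions = unname(hmm$insert_emissions),
              begin = hmm$transitions$begin,
              transitions = unname(hmm$transitions$t),
              background = unname(hmm$background),
              gumbel_lambda = hmm$gumbel_lambda, gumbel_mu = hmm$gumbel_mu,
              strict_evalue = hmm$strict_evalue, soft_evalue = hmm$soft_evalue,
              emission_floor = hmm$emission_floor)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a profile HMM from JSON
#' @param path file or JSON string produced by [hmm_to_json].
#' @return a `profile_hmm`.
#' @export
hmm_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, "tandemaaa-hmm-1")) stop("unknown HMM schema")
  as_mat <- function(x, nr, nc, cn) {
    m <- as.matrix(x)
    stopifnot(nrow(m) == nr, ncol(m) == nc)
    dimnames(m) <- list(NULL, cn)
    m
  }
  tm <- as_mat(obj$transitions, obj$L, 7,
               c("mm", "mi", "md", "im", "ii", "dm", "dd"))
  hmm <- structure(list(
    name = obj$name, L = obj$L,
    match_emissions = as_mat(obj$match_emissions, obj$L, 20, AA20),
    insert_emissions = as_mat(obj$insert_emissions, obj$L + 1L, 20, AA20),
    transitions = list(begin = as.numeric(obj$begin), t = tm),
    background = stats::setNames(as.numeric(obj$background), AA20),
    gumbel_lambda = as.numeric(obj$gumbel_lambda),
    gumbel_mu = as.numeric(obj$gumbel_mu),
    strict_evalue = as.numeric(obj$strict_evalue),
    soft_evalue = as.numeric(obj$soft_evalue),
    emission_floor = as.numeric(obj$emission_floor)
  ), class = "profile_hmm")
  validate_hmm(hmm)
  hmm
}
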