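# Locate D-domains in full-length proteins with a calibrated model library,
# call tandem architectures and terminal motifs (tail-helix tyrosine, HbYX),
# extract annotated AAA+ motifs with a degeneracy score, and compute
# sequence-logo matrices.

HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

#' Scan one protein with a model library
#'
#' Every calibrated model is aligned glocally to the sequence; after each
#' hit passing the model's soft E-value bound, the envelope is masked (to X)
#' and the model re-applied, so that tandem repeats yield one hit per
#' repeat. Hits whose envelopes overlap reciprocally by more than
#' `overlap_min` are grouped; within a group, hits are ranked by E-value
#' and at most `max_reported` are kept (ranks 1..max_reported). Disjoint
#' envelopes are all reported.
#'
#' @param seq residue string or single-row [aa_set].
#' @param library named list of calibrated `profile_hmm` models.
#' @param n_database database size used in the E-value (number of scanned
#'   sequences).
#' @param max_reported hits reported per envelope group.
#' @param max_passes per-model rescan passes (tandem repeats).
#' @param overlap_min reciprocal-overlap fraction that merges two envelopes
#'   into one group.
#' @return data frame with columns seq_id, model, start, end, bits, evalue,
#'   rank, group (0-based half-open envelopes).
#' @export
scan_sequence <- function(seq, library, n_database = length(library),
                          max_reported = 4L, max_passes = 3L,
                          overlap_min = 0.5) {
  if (length(library) == 0L) stop("empty model library")
  s <- if (is.character(seq)) seq else seq$residues[[1L]]
  seq_id <- if (is.character(seq)) "query" else seq$id[[1L]]
  for (m in library) {
    if (is.na(m$gumbel_lambda)) stop("uncalibrated model in library: ", m$name)
  }
  hits <- list()
  for (m in library) {
    cur <- s
    for (pass in seq_len(max_passes)) {
      v <- viterbi(m, cur)
      ev <- hmm_evalue(m, v$score, n_database)
      if (ev > m$soft_evalue || v$envelope[2] <= v$envelope[1]) break
      hits[[length(hits) + 1L]] <- data.frame(
        seq_id = seq_id, model = m$name,
        start = unname(v$envelope[1]), end = unname(v$envelope[2]),
        bits = v$score, evalue = ev, stringsAsFactors = FALSE)
      # mask the envelope so the next pass finds the next repeat
      substr(cur, v$envelope[1] + 1L, v$envelope[2]) <-
        strrep("X", v$envelope[2] - v$envelope[1])
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(seq_id = character(0), model = character(0),
                      start = integer(0), end = integer(0),
                      bits = numeric(0), evalue = numeric(0),
                      rank = integer(0), group = integer(0)))
  }
  h <- do.call(rbind, hits)
  # group by > overlap_min reciprocal overlap (single linkage)
  n <- nrow(h)
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
      if (ov > 0 &&
          ov / (h$end[i] - h$start[i]) > overlap_min &&
          ov / (h$end[j] - h$start[j]) > overlap_min) {
        grp[find(j)] <- find(i)
      }
    }
  }
  h$group <- vapply(seq_len(n), find, integer(1))
  h$group <- match(h$group, unique(h$group[order(h$start)]))
  out <- list()
  for (g in sort(unique(h$group))) {
    hg <- h[h$group == g, , drop = FALSE]
    hg <- hg[order(hg$evalue, hg$model), , drop = FALSE]
    hg <- utils::head(hg, max_reported)
    hg$rank <- seq_len(nrow(hg))
    out[[g]] <- hg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group, res$rank), ]
}

#' Call the domain architecture of a protein
#'
#' Rank-1 hits with E-value at or under the model's strict bound are firm
#' domain calls, between strict and soft bounds provisional. The tandem
#' flag requires a firm D1 call before a firm D2 call; the N-domain flag is
#' set by any `<family>.N` model hit when such models are in the library.
#' Insert lengths are measured between the mapped Sensor 2 anchor and the
#' domain envelope end, minus the canonical tail of the reference domain
#' layout.
#'
#' @param seq residue string or single-row [aa_set].
#' @param hits data frame from [scan_sequence] for the same sequence.
#' @param library the model library used for the scan.
#' @param motif_annotations named list: per model name, a named list of
#'   motif -> model column range (0-based half-open), as produced when the
#'   library is built.
#' @param canonical_tail canonical residue count from the Sensor 2 anchor
#'   end to the domain end (from the reference domain layout).
#' @return object of class `domain_architecture`.
#' @export
call_architecture <- function(seq, hits, library, motif_annotations = list(),
                              canonical_tail = DOMAIN_LENGTH -
                                MOTIF_LAYOUT$sensor_2$at[2]) {
  s <- if (is.character(seq)) seq else seq$residues[[1L]]
  seq_id <- if (is.character(seq)) "query" else seq$id[[1L]]
  calls <- list()
  insert_lengths <- list()
  motif_states <- list()
  if (nrow(hits) > 0L) {
    for (g in unique(hits$group)) {
      hg <- hits[hits$group == g & hits$rank == 1L, , drop = FALSE]
      m <- library[[hg$model]]
      status <- if (hg$evalue <= m$strict_evalue) "firm"
                else if (hg$evalue <= m$soft_evalue) "provisional"
                else next
      dom <- sub("^.*\\.", "", hg$model)
      label <- if (dom %in% c("D1", "D2", "N")) dom else "other"
      calls[[length(calls) + 1L]] <- data.frame(
        seq_id = seq_id, label = label, model = hg$model,
        start = hg$start, end = hg$end, evalue = hg$evalue,
        bits = hg$bits, status = status, stringsAsFactors = FALSE)
      if (label %in% c("D1", "D2")) {
        ann <- motif_annotations[[hg$model]]
        ms <- extract_motifs(s, hg, m, ann)
        motif_states[[paste0(label)]] <- ms
        if (!is.null(ann$sensor_2)) {
          v <- viterbi(m, s)
          anchor_end <- anchored_position(v$matchmap, ann$sensor_2[2] - 1L)
          if (!is.na(anchor_end)) {
            obs <- hg$end - (anchor_end + 1L)
            insert_lengths[[paste0(label, ".pre_terminal_helix")]] <-
              obs - canonical_tail
          }
        }
      }
    }
  }
  cdf <- if (length(calls)) do.call(rbind, calls) else
    data.frame(seq_id = character(0), label = character(0),
               model = character(0), start = integer(0), end = integer(0),
               evalue = numeric(0), bits = numeric(0), status = character(0))
  cdf <- cdf[order(cdf$start), , drop = FALSE]
  firm <- cdf[cdf$status == "firm", , drop = FALSE]
  d1 <- firm[firm$label == "D1", , drop = FALSE]
  d2 <- firm[firm$label == "D2", , drop = FALSE]
  has_tandem <- nrow(d1) > 0 && nrow(d2) > 0 && min(d1$start) < min(d2$start)
  d2_hit <- if (nrow(d2) > 0) d2[which.min(d2$evalue), , drop = FALSE] else NULL
  structure(list(
    seq_id = seq_id,
    calls = cdf,
    has_tandem_D1D2 = has_tandem,
    has_N_domain = any(cdf$label == "N"),
    has_tail_helix_tyr = if (!is.null(d2_hit))
      detect_tail_helix_tyr(s, d2_hit) else FALSE,
    has_hbyx = detect_hbyx(s),
    insert_lengths = insert_lengths,
    motif_states = motif_states
  ), class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat("domain_architecture ", x$seq_id, ": ",
      paste(x$calls$label, collapse = "-"),
      " tandem=", x$has_tandem_D1D2, " N=", x$has_N_domain,
      " tailY=", x$has_tail_helix_tyr, " HbYX=", x$has_hbyx, "\n", sep = "")
  invisible(x)
}

# sequence position mapped by a model column, falling back to the nearest
# mapped column at or before it
anchored_position <- function(matchmap, col0) {
  for (j in seq(col0 + 1L, 1L)) {
    if (!is.na(matchmap[j])) return(matchmap[j])
  }
  NA_integer_
}

#' Detect the C-terminal HbYX motif
#'
#' True iff the last three residues are hydrophobic-Tyr-any. The strict
#' rule requires a tyrosine at the middle position; set `allow_f = TRUE`
#' to additionally accept phenylalanine.
#'
#' @param seq residue string or single-row [aa_set] (length >= 3).
#' @param allow_f accept F in the Y slot.
#' @return logical.
#' @export
detect_hbyx <- function(seq, allow_f = FALSE) {
  s <- if (is.character(seq)) seq else seq$residues[[1L]]
  if (nchar(s) < 3L) stop("sequence shorter than 3 residues")
  tail3 <- strsplit(substr(s, nchar(s) - 2L, nchar(s)), "")[[1]]
  y_ok <- tail3[2] == "Y" || (allow_f && tail3[2] == "F")
  tail3[1] %in% HYDROPHOBIC && y_ok
}

#' Detect the conserved tail-helix tyrosine after the D2 domain
#'
#' Aligns the region following the D2 envelope against the reference
#' tail-helix consensus (local alignment, BLOSUM62) and reports whether the
#' column homologous to the central tyrosine of the consensus carries a
#' tyrosine.
#'
#' @param seq residue string or single-row [aa_set].
#' @param d2_hit one-row data frame with the D2 envelope (`start`, `end`).
#' @param consensus tail-helix consensus (central Y).
#' @param window residues after the D2 end to search.
#' @return logical; FALSE when the sequence ends at or before the envelope.
#' @export
detect_tail_helix_tyr <- function(seq, d2_hit, consensus = TAIL_CONSENSUS,
                                  window = 40L) {
  s <- if (is.character(seq)) seq else seq$residues[[1L]]
  if (nchar(s) <= d2_hit$end) return(FALSE)
  region <- substr(s, d2_hit$end + 1L, min(nchar(s), d2_hit$end + window))
  if (nchar(region) < 3L) return(FALSE)
  y_col <- as.integer(regexpr("Y", consensus, fixed = TRUE))
  al <- Biostrings::pairwiseAlignment(region, consensus,
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 11, gapExtension = 1,
                                      type = "local")
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  # walk the aligned subject to the consensus Y column
  spos <- Biostrings::start(Biostrings::subject(al)) - 1L
  for (k in seq_along(sub)) {
    if (sub[k] != "-") {
      spos <- spos + 1L
      if (spos == y_col) return(pat[k] == "Y")
    }
  }
  FALSE
}

#' Extract annotated motifs from a domain hit
#'
#' Maps each annotated motif's model columns through the Viterbi alignment
#' and returns the observed substring plus a degeneracy score:
#' `1 - mean(per-column frequency of the observed residue under the
#' model's match-emission PFM)`, in \[0, 1\]. Deleted motif columns count
#' as frequency 0.
#'
#' @param seq residue string or single-row [aa_set].
#' @param hit one-row hit data frame (from [scan_sequence]).
#' @param model the `profile_hmm` named by the hit.
#' @param motif_annotations named list motif -> model column range (0-based
#'   half-open).
#' @return named list per motif: list(observed, degeneracy).
#' @export
extract_motifs <- function(seq, hit, model, motif_annotations) {
  if (length(motif_annotations) == 0L) return(list())
  s <- if (is.character(seq)) seq else seq$residues[[1L]]
  v <- viterbi(model, s)
  out <- list()
  for (nm in names(motif_annotations)) {
    rng <- motif_annotations[[nm]]
    if (rng[1] < 0 || rng[2] > model$L) stop("motif range outside model: ", nm)
    cols <- (rng[1] + 1L):rng[2]
    pos <- v$matchmap[cols]
    chars <- rep("-", length(cols))
    chars[!is.na(pos)] <- vapply(pos[!is.na(pos)] + 1L,
                                 function(i) substr(s, i, i), character(1))
    freq <- numeric(length(cols))
    for (k in seq_along(cols)) {
      if (chars[k] %in% AA20) {
        freq[k] <- model$match_emissions[cols[k], chars[k]]
      } else freq[k] <- 0
    }
    out[[nm]] <- list(observed = paste(chars, collapse = ""),
                      degeneracy = 1 - mean(freq))
  }
  out
}

#' Position frequency logo of alignment columns
#'
#' Per column: residue frequencies (gaps excluded) and information content
#' `info_bits = log2(20) - H(column)`. Letter heights in a rendered logo
#' are `frequency * info_bits`. All-gap columns get zero frequencies,
#' `info_bits = 0` and an `undefined` flag.
#'
#' @param aln an [msa] with >= 2 rows.
#' @param column_range 0-based half-open column range (default: all).
#' @param small_sample_correction subtract the small-sample correction
#'   `(19 / (2 ln 2)) / n` from the information content (off by default).
#' @return object of class `motif_logo`: list with `columns` (k x 20
#'   frequency matrix), `info_bits`, `undefined`, `n_sequences`.
#' @export
compute_logo <- function(aln, column_range = NULL,
                         small_sample_correction = FALSE) {
  stopifnot(inherits(aln, "msa"))
  if (length(aln$ids) < 2L) stop("need >= 2 rows")
  m <- msa_matrix(aln)
  if (is.null(column_range)) column_range <- c(0L, ncol(m))
  cols <- (column_range[1] + 1L):column_range[2]
  k <- length(cols)
  freq <- matrix(0, k, 20, dimnames = list(NULL, AA20))
  info <- numeric(k)
  undef <- logical(k)
  for (i in seq_len(k)) {
    col <- m[, cols[i]]
    col <- col[col %in% AA20]
    if (length(col) == 0L) { undef[i] <- TRUE; next }
    f <- tabulate(match(col, AA20), 20L) / length(col)
    freq[i, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    info[i] <- log2(20) - h
    if (small_sample_correction) {
      info[i] <- max(0, info[i] - 19 / (2 * log(2) * length(col)))
    }
  }
  structure(list(columns = freq, info_bits = info, undefined = undef,
                 n_sequences = length(aln$ids)),
            class = "motif_logo")
}
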