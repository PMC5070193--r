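# Readers and writers for the external formats the pipeline touches:
# FASTA protein sets, aligned FASTA / Stockholm alignments, Newick trees,
# and TSV species-to-lineage maps. All coordinates elsewhere in the package
# are 0-based, half-open.

#' Construct a protein sequence set
#'
#' An `aa_set` is a data frame with columns `id`, `species`, `lineage`
#' (semicolon-separated taxon path, possibly empty) and `residues`
#' (uppercase amino-acid letters, `X` allowed, no gaps). It is the
#' in-memory form of a FASTA file whose headers follow the convention
#' `id|species|lineage1;lineage2;...` (fields beyond `id` optional).
#'
#' @param id character vector of unique, nonempty sequence ids.
#' @param residues character vector of residue strings (length >= 1 each).
#' @param species character vector (recycled); `NA` if unknown.
#' @param lineage character vector of `;`-joined taxon paths (recycled).
#' @return an object of class `aa_set` (also a `data.frame`).
#' @export
aa_set <- function(id, residues, species = NA_character_, lineage = "") {
  id <- as.character(id)
  if (length(id) != length(residues)) stop("id and residues lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(nchar(residues) < 1L)) {
    stop("empty record(s): ", paste(id[nchar(residues) < 1L], collapse = ", "))
  }
  residues <- vapply(seq_along(residues), function(i)
    aa_sanitize(residues[[i]], map_to_x = FALSE, context = id[[i]]),
    character(1))
  if (any(grepl("-", residues, fixed = TRUE))) stop("gap characters in residues")
  out <- data.frame(id = id,
                    species = rep_len(as.character(species), length(id)),
                    lineage = rep_len(as.character(lineage), length(id)),
                    residues = residues,
                    stringsAsFactors = FALSE)
  class(out) <- c("aa_set", "data.frame")
  out
}

#' Read protein sequences from FASTA
#'
#' Headers are split on `|` into `id|species|lineage` (extra fields
#' ignored); the lineage field is a `;`-separated taxon path. Letters
#' outside the 20 amino acids are mapped to `X` with a warning when
#' `map_to_x = TRUE`, otherwise they are an error. Duplicate ids and empty
#' records are always errors.
#'
#' @param path FASTA file.
#' @param map_to_x map uncommon letters (U, O, B, Z, J, `*`, `?`) to X.
#' @return an [aa_set].
#' @export
read_fasta <- function(path, map_to_x = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  headers <- names(ss)
  fields <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(fields, `[`, character(1), 1L)
  id <- trimws(id)
  species <- vapply(fields, function(f)
    if (length(f) >= 2L) trimws(f[2L]) else NA_character_, character(1))
  lineage <- vapply(fields, function(f)
    if (length(f) >= 3L) trimws(f[3L]) else "", character(1))
  res <- as.character(ss)
  if (any(!nzchar(res))) {
    stop("empty record(s): ", paste(id[!nzchar(res)], collapse = ", "))
  }
  res <- vapply(seq_along(res), function(i)
    aa_sanitize(res[[i]], map_to_x = map_to_x, context = id[[i]]), character(1))
  aa_set(id = id, residues = res, species = species, lineage = lineage)
}

#' Write protein sequences to FASTA
#'
#' Headers are normalized to `id|species|lineage` (trailing empty fields
#' dropped).
#'
#' @param x an [aa_set].
#' @param path output file.
#' @param width line width for wrapping residues.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "aa_set"))
  hdr <- x$id
  has_sp <- !is.na(x$species) & nzchar(x$species)
  has_lin <- nzchar(x$lineage) & !is.na(x$lineage)
  hdr <- ifelse(has_lin, paste(x$id, ifelse(has_sp, x$species, ""), x$lineage, sep = "|"),
                ifelse(has_sp, paste(x$id, x$species, sep = "|"), x$id))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", hdr[[i]]), con)
    s <- x$residues[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple alignment
#'
#' An `msa` holds equal-length aligned rows over residues plus the gap
#' character `-`. De-gapping any row must yield a valid residue string.
#'
#' @param rows named character vector of aligned rows (unique names).
#' @return an object of class `msa` with elements `ids`, `rows`, `ncols`.
#' @export
msa <- function(rows) {
  ids <- names(rows)
  if (is.null(ids) || any(!nzchar(ids))) stop("alignment rows must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    ref <- stats::median(lens)
    bad <- ids[lens != ref][1L]
    stop("ragged alignment: row '", bad, "' has ", lens[ids == bad][1L],
         " columns, others ", ref)
  }
  if (lens[[1L]] < 1L) stop("alignment has 0 columns")
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  for (i in seq_along(rows)) {
    degap <- gsub("-", "", rows[[i]], fixed = TRUE)
    if (nzchar(degap)) aa_sanitize(degap, map_to_x = FALSE, context = ids[[i]])
  }
  structure(list(ids = ids, rows = unname(rows), ncols = unname(lens[[1L]])),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x$ids), " rows x ", x$ncols, " columns\n", sep = "")
  invisible(x)
}

# alignment as a character matrix (rows x cols)
msa_matrix <- function(a) {
  m <- do.call(rbind, strsplit(a$rows, ""))
  rownames(m) <- a$ids
  m
}

msa_from_matrix <- function(m) {
  rows <- apply(m, 1L, paste, collapse = "")
  names(rows) <- rownames(m)
  msa(rows)
}

# alignment as 0-based integer codes (gap and X -> -1 optionally kept)
msa_encode <- function(a) {
  m <- msa_matrix(a)
  code <- match(m, AAX) - 1L
  code[m == "-"] <- -1L
  matrix(code, nrow = nrow(m), dimnames = dimnames(m))
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA and Stockholm. `.` and lowercase gaps are
#' normalized to `-`; ragged rows are an error naming the offending id.
#'
#' @param path alignment file.
#' @param dialect `"fasta"` or `"stockholm"`; the default sniffs the file.
#' @return an [msa].
#' @export
read_alignment <- function(path, dialect = c("auto", "fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  if (dialect == "stockholm") {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
    if (length(body) == 0L) stop("no alignment rows in ", path)
    parts <- regmatches(body, regexpr("^\\S+", body))
    seqs <- trimws(sub("^\\S+\\s+", "", body))
    rows <- tapply(seqs, factor(parts, levels = unique(parts)), paste, collapse = "")
    rows <- stats::setNames(as.character(rows), names(rows))
  } else {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("no alignment rows in ", path)
    rows <- stats::setNames(as.character(ss),
                            trimws(vapply(strsplit(names(ss), "|", fixed = TRUE),
                                          `[`, character(1), 1L)))
  }
  msa(rows)
}

#' Write a multiple alignment as aligned FASTA
#' @param a an [msa].
#' @param path output file.
#' @export
write_alignment <- function(a, path) {
  stopifnot(inherits(a, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(a$ids)) {
    writeLines(c(paste0(">", a$ids[[i]]), a$rows[[i]]), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree] with strict validation: balanced text, unique
#' leaf labels, nonnegative branch lengths where present.
#'
#' @param path Newick file (single tree).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length(s)")
  }
  invisible(tr)
}

#' Write a Newick tree
#' @param tree an [ape::phylo] tree.
#' @param path output file; if `NULL`, the Newick text is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_tree(tree)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a species-to-lineage map
#'
#' TSV with columns `species` and `lineage_path` (a `;`-joined taxon path).
#'
#' @param path TSV file.
#' @return data frame with columns `species`, `lineage_path`.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "lineage_path")
  if (!all(need %in% names(df))) {
    stop("species map must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$species)) stop("duplicate species in map")
  df[, need]
}

# subset an aa_set by id, preserving class
aa_subset <- function(x, ids) {
  out <- x[match(ids, x$id), , drop = FALSE]
  class(out) <- c("aa_set", "data.frame")
  rownames(out) <- NULL
  out
}
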