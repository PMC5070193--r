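# Phyletic-pattern analytics: species x family presence/absence matrices,
# Dollo ancestral repertoires (single gain, free losses), the root (LECA)
# set, the minimal core shared by all species, and duplication reports.

#' Construct a phyletic pattern (presence/absence matrix)
#'
#' @param calls data frame with columns `species`, `family` and optionally
#'   `seq_id` (distinct proteins; drives copy numbers). One row per
#'   protein-level assignment.
#' @param species optional row universe (species with no calls get
#'   all-false rows).
#' @param families optional column universe.
#' @return object of class `phyletic_pattern`: list with logical matrix
#'   `presence` and integer matrix `copy_number` (species x families).
#' @export
build_matrix <- function(calls, species = NULL, families = NULL) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) > 0 && !all(c("species", "family") %in% names(calls)))
    stop("calls need columns species, family")
  sp <- species %||% sort(unique(calls$species))
  fam <- families %||% sort(unique(calls$family))
  cn <- matrix(0L, length(sp), length(fam), dimnames = list(sp, fam))
  if (nrow(calls) > 0) {
    if (is.null(calls$seq_id)) calls$seq_id <- seq_len(nrow(calls))
    unmapped <- setdiff(unique(calls$species), sp)
    if (length(unmapped) > 0) {
      warning("species not in map, grouped as 'unmapped': ",
              paste(unmapped, collapse = ", "))
      cn <- rbind(cn, unmapped = rep(0L, ncol(cn)))
      calls$species[calls$species %in% unmapped] <- "unmapped"
    }
    agg <- stats::aggregate(seq_id ~ species + family, data = calls,
                            FUN = function(x) length(unique(x)))
    keep <- agg$family %in% fam
    agg <- agg[keep, , drop = FALSE]
    cn[cbind(agg$species, agg$family)] <- as.integer(agg$seq_id)
  }
  structure(list(presence = cn > 0L, copy_number = cn),
            class = "phyletic_pattern")
}

#' @export
print.phyletic_pattern <- function(x, ...) {
  cat("phyletic_pattern: ", nrow(x$presence), " species x ",
      ncol(x$presence), " families\n", sep = "")
  invisible(x)
}

#' Write / read a phyletic pattern as TSV (copy counts)
#' @param pa a `phyletic_pattern`.
#' @param path TSV file.
#' @export
write_matrix_tsv <- function(pa, path) {
  df <- data.frame(species = rownames(pa$copy_number), pa$copy_number,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- as.matrix(df[, -1, drop = FALSE])
  rownames(cn) <- df[[1]]
  storage.mode(cn) <- "integer"
  structure(list(presence = cn > 0L, copy_number = cn),
            class = "phyletic_pattern")
}

#' Dollo ancestral repertoires
#'
#' Under Dollo parsimony each family is gained exactly once, at the most
#' recent common ancestor of the species possessing it, and may then be
#' lost any number of times. The family is present at every node on the
#' paths from that gain to the possessing leaves; a loss event is placed on
#' every maximal branch below the gain whose subtree contains no possessing
#' leaf. This minimizes losses under the single-gain constraint.
#'
#' @param pa a `phyletic_pattern` whose species are all tree leaves.
#' @param tree a rooted [ape::phylo] species tree.
#' @param uncertain optional data frame (`species`, `family`) of cells whose
#'   absence may reflect incomplete genomes; such cells are excluded from
#'   loss calls (the species is dropped from that family's loss
#'   computation), not treated as presence.
#' @return object of class `ancestral_repertoire`: list with
#'   `node_families` (per node id, character vector of families), `events`
#'   (data frame family/branch/type/node), `tree`.
#' @export
dollo_ancestral <- function(pa, tree, uncertain = NULL) {
  stopifnot(inherits(pa, "phyletic_pattern"), inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  sp <- rownames(pa$presence)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing) > 0) stop("species not in tree: ",
                                paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  children <- vector("list", ntip + nnode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    children[[p]] <- c(children[[p]], tree$edge[k, 2L])
  }
  node_name <- c(tree$tip.label,
                 if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
                   tree$node.label
                 else paste0("node", seq_len(nnode) + ntip))
  # internal nodes, children before parents
  internal_post <- unique(tree$edge[ape::postorder(tree), 1L])

  node_fam <- vector("list", ntip + nnode)
  events <- list()
  for (fam in colnames(pa$presence)) {
    have <- sp[pa$presence[, fam]]
    if (length(have) == 0L) {
      warning("family ", fam, " possessed by no species; skipped")
      next
    }
    unc <- if (!is.null(uncertain))
      uncertain$species[uncertain$family == fam] else character(0)
    have_tips <- match(have, tree$tip.label)
    gain <- if (length(have_tips) == 1L) have_tips else
      ape::getMRCA(tree, have_tips)
    # postorder sweeps: poss = subtree has a possessing leaf;
    # unc_only = every leaf below is an uncertain absence
    poss <- logical(ntip + nnode)
    poss[have_tips] <- TRUE
    unc_only <- logical(ntip + nnode)
    unc_only[match(intersect(unc, tree$tip.label), tree$tip.label)] <- TRUE
    unc_only[poss] <- FALSE
    for (nd in internal_post) {
      poss[nd] <- any(poss[children[[nd]]])
      unc_only[nd] <- all(unc_only[children[[nd]]])
    }
    # presence: nodes on paths from gain down to possessing leaves
    present <- logical(ntip + nnode)
    mark <- function(nd) {
      present[nd] <<- TRUE
      for (ch in children[[nd]]) if (poss[ch]) mark(ch)
    }
    mark(gain)
    events[[length(events) + 1L]] <- data.frame(
      family = fam, branch = node_name[gain], node = gain, type = "gain",
      stringsAsFactors = FALSE)
    # losses: maximal branches below the gain into non-possessing subtrees
    desc <- function(nd) {
      out <- integer(0); stack <- nd
      while (length(stack)) {
        x <- stack[[1L]]; stack <- stack[-1L]
        out <- c(out, x); stack <- c(stack, children[[x]])
      }
      out
    }
    for (nd in desc(gain)) {
      if (!present[nd]) next
      for (ch in children[[nd]]) {
        if (!poss[ch]) {
          # a subtree that is entirely "uncertain absence" does not yield
          # a loss call
          if (!unc_only[ch]) {
            events[[length(events) + 1L]] <- data.frame(
              family = fam, branch = node_name[ch], node = ch,
              type = "loss", stringsAsFactors = FALSE)
          }
        }
      }
    }
    for (nd in which(present)) node_fam[[nd]] <- c(node_fam[[nd]], fam)
  }
  names(node_fam) <- node_name
  structure(list(node_families = node_fam,
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(family = character(0),
                                          branch = character(0),
                                          node = integer(0),
                                          type = character(0)),
                 tree = tree, root = root),
            class = "ancestral_repertoire")
}

#' Repertoire at the root (LECA set for a eukaryote tree)
#' @param ancestral an `ancestral_repertoire` from [dollo_ancestral].
#' @return character vector of families inferred present at the root.
#' @export
leca_set <- function(ancestral) {
  stopifnot(inherits(ancestral, "ancestral_repertoire"))
  if (!ape::is.rooted(ancestral$tree)) stop("tree must be rooted")
  sort(ancestral$node_families[[ancestral$root]] %||% character(0))
}

#' Minimal core family set
#'
#' The intersection of the family repertoires of all species: families
#' present in every genome.
#'
#' @param pa a `phyletic_pattern` with >= 1 species.
#' @return character vector of core families.
#' @export
minimal_core <- function(pa) {
  stopifnot(inherits(pa, "phyletic_pattern"))
  if (nrow(pa$presence) < 1L) stop("need at least one species")
  sort(colnames(pa$presence)[colSums(pa$presence) == nrow(pa$presence)])
}

#' Report duplications
#'
#' Copy-number mode: every species x family cell with >= 2 distinct
#' proteins is reported. When a species tree is supplied, families with >=
#' 2 multi-copy species additionally get a lineage-level duplication event
#' mapped to the MRCA of the multi-copy species.
#'
#' @param calls protein-level assignment data frame (`species`, `family`,
#'   `seq_id`).
#' @param tree optional rooted species tree for lineage-level mapping.
#' @return data frame with columns `family`, `branch`, `type`, `species`.
#' @export
find_duplications <- function(calls, tree = NULL) {
  pa <- build_matrix(calls)
  cn <- pa$copy_number
  out <- list()
  idx <- which(cn >= 2L, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    out[[1L]] <- data.frame(family = colnames(cn)[idx[, 2L]],
                            branch = rownames(cn)[idx[, 1L]],
                            type = "duplication",
                            species = rownames(cn)[idx[, 1L]],
                            stringsAsFactors = FALSE)
  }
  if (!is.null(tree)) {
    for (fam in colnames(cn)) {
      multi <- rownames(cn)[cn[, fam] >= 2L]
      multi <- intersect(multi, tree$tip.label)
      if (length(multi) >= 2L) {
        mrca <- ape::getMRCA(tree, multi)
        ntip <- length(tree$tip.label)
        lab <- if (!is.null(tree$node.label) &&
                   nzchar(tree$node.label[mrca - ntip]))
          tree$node.label[mrca - ntip] else paste0("node", mrca)
        out[[length(out) + 1L]] <- data.frame(
          family = fam, branch = lab, type = "lineage_duplication",
          species = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(family = character(0), branch = character(0),
                      type = character(0), species = character(0)))
  do.call(rbind, out)
}

#' Example phyletic pattern: Cdc48-family repertoires of parasitic lineages
#'
#' A species/lineage x family presence matrix for the eight eukaryotic
#' Cdc48-family members (Cdc48, NSF, Pex1, Pex6, Spaf, Spaf-like, NVL,
#' Yta7) across parasitic lineages with reduced repertoires, plus a
#' full-repertoire Homo sapiens row, together with a rooted consensus
#' eukaryote species tree (root between the opisthokont/amoebozoan side and
#' the SAR/excavate side). Giardia and Microsporidia retain only the
#' minimal core {Cdc48, NSF, NVL}; peroxin (Pex1/Pex6) absences track
#' peroxisome losses.
#'
#' @return list with `matrix` (a `phyletic_pattern`) and `tree` (rooted
#'   [ape::phylo]).
#' @export
cdc48_repertoire_example <- function() {
  pa <- read_matrix_tsv(system.file("extdata", "parasite_repertoire.tsv",
                                    package = "tandemaaa", mustWork = TRUE))
  tree <- read_newick(system.file("extdata", "parasite_species_tree.nwk",
                                  package = "tandemaaa", mustWork = TRUE))
  list(matrix = pa, tree = tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
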