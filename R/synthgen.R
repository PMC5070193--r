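# Synthetic tandem double-AAA datasets with machine-readable planted truth:
# a configurable roster of families (eight eukaryotic + one archaeal by
# default) evolved on a species tree under a BLOSUM62-biased substitution
# process with rare indels, planted lineage-specific losses, one planted
# duplication, and planted motif degeneracies. Every emitted protein carries
# truth rows (family, domain and motif coordinates) so that scans,
# classification, trees and repertoire inference can be checked against the
# construction.

# canonical AAA+ motif layout within a 200-residue D-domain (0-based,
# half-open); terminal-helix region occupies the last ~20 residues
MOTIF_LAYOUT <- list(
  walker_a   = list(at = c(20L, 28L),  consensus = "GPPGTGKT"),
  pore_loop  = list(at = c(60L, 65L),  consensus = "AGVRG"),
  walker_b   = list(at = c(90L, 96L),  consensus = "ILFIDE"),
  sensor_1   = list(at = c(120L, 125L), consensus = "VTSNT"),
  arg_finger = list(at = c(150L, 154L), consensus = "RAGR"),
  sensor_2   = list(at = c(170L, 173L), consensus = "GAD")
)
DOMAIN_LENGTH <- 200L

# tail helix consensus (central tyrosine at 0-based position 7) and the
# proteasome-docking C-terminal tripeptide
TAIL_CONSENSUS <- "ARELDVSYQTAGLKE"
HBYX_DEFAULT <- "LYG"

#' Default synthetic-dataset configuration
#'
#' Mirrors the default study design: eight eukaryotic tandem families
#' (Cdc48, NSF, Pex1, Pex6, Spaf, Spaf_like, NVL, Yta7) plus one archaeal
#' family (VAT), a 40-leaf eukaryote tree with a 5-leaf parasite clade
#' retaining only the minimal core (Cdc48, NSF, NVL) and a 6-leaf clade
#' carrying a planted Yta7 duplication, a 6-leaf archaeal outgroup, 0.8
#' expected substitutions per site root-to-tip, planted degeneracies
#' (Pex1/Pex6 D1 Walker A/B and arginine finger scrambled; NSF D2 Sensor 2
#' aspartate replaced by lysine), the ~50-residue NVL D1 insert before the
#' terminal helix and a Pex1 D2 insert, NSF and Yta7 without tail helix,
#' and the HbYX C-terminal motif on Cdc48 and VAT.
#'
#' @return a nested list (round-trips through YAML via [config_to_yaml]).
#' @export
default_config <- function() {
  fam <- function(name, archaeal = FALSE, n = TRUE, tail = TRUE, hbyx = FALSE,
                  degen = NULL, insert = NULL) {
    list(name = name, n_domains = 2L, archaeal = archaeal,
         has_n_domain = n, tail_helix = tail, hbyx = hbyx,
         degenerate_motifs = degen, insert = insert)
  }
  list(
    families = list(
      fam("Cdc48", hbyx = TRUE),
      fam("NSF", tail = FALSE, degen = list(D2 = "sensor_2")),
      fam("Pex1", degen = list(D1 = c("walker_a", "walker_b", "arg_finger")),
          insert = list(domain = "D2", at = 180L, length = 40L)),
      fam("Pex6", degen = list(D1 = c("walker_a", "walker_b", "arg_finger"))),
      fam("Spaf"),
      fam("Spaf_like"),
      fam("NVL", insert = list(domain = "D1", at = 178L, length = 50L)),
      fam("Yta7", tail = FALSE),
      fam("VAT", archaeal = TRUE, hbyx = TRUE)
    ),
    tree = list(n_eukaryotes = 40L, n_archaea = 6L, parasite_clade = 5L,
                duplication_clade = 6L, root_to_tip = 0.8),
    evolution = list(rate = 1.0, indel_rate = 0.005,
                     profile_divergence = 1.0),
    lengths = list(domain = DOMAIN_LENGTH, n_domain = 80L, linker = 12L,
                   tail = nchar(TAIL_CONSENSUS)),
    losses = list(list(clade = "parasite", keep = c("Cdc48", "NSF", "NVL"))),
    duplications = list(list(family = "Yta7", clade = "duplication"))
  )
}

#' Serialize / restore a configuration via YAML
#' @param config a configuration list.
#' @param path optional file; if `NULL`, the YAML string is returned.
#' @export
config_to_yaml <- function(config, path = NULL) {
  txt <- yaml::as.yaml(config)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
}

# BLOSUM62-derived conditional replacement probabilities:
# P(b | a) proportional to p_b * 2^(s_ab / 2), b != a
subst_conditional <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- blosum62_aax()[1:20, 1:20]
      m <- sweep(2^(s / 2), 2, AA_BACKGROUND, "*")
      diag(m) <- 0
      cache <<- m / rowSums(m)
    }
    cache
  }
})

sample_background <- function(n) {
  sample.int(20L, n, replace = TRUE, prob = AA_BACKGROUND) - 1L
}

# mutate a residue-code vector: each unprotected site independently, with
# expected `div` substitution events per site (Poisson; repeat hits allowed)
diverge_codes <- function(codes, div, protected = rep(FALSE, length(codes))) {
  cond <- subst_conditional()
  idx <- which(!protected)
  nsub <- stats::rpois(1L, div * length(idx))
  if (nsub > 0) {
    sites <- sample(idx, nsub, replace = TRUE)
    for (s in sites) {
      codes[s] <- sample.int(20L, 1L, prob = cond[codes[s] + 1L, ]) - 1L
    }
  }
  codes
}

#' Build ancestral family profiles
#'
#' Draws a root AAA domain (canonical motifs planted at fixed coordinates)
#' and a root N-domain, then derives one D1 and one D2 profile per family
#' by diverging all non-motif sites, applying planted motif degeneracies
#' (Sensor 2 aspartate to lysine; other degenerate motifs fully scrambled
#' away from the canonical residues) and planted inserts.
#'
#' @param config a configuration list (see [default_config]).
#' @param seed RNG seed; identical seeds give identical profiles.
#' @return list with `domains` (per profile id: `residues`, `motifs`,
#'   `insert`), `n_domains`, `tail`, `root_domain`.
#' @export
make_profiles <- function(config, seed = 1L) {
  withr_seed(seed, {
    dl <- config$lengths$domain
    root <- sample_background(dl)
    motifs <- list()
    for (nm in names(MOTIF_LAYOUT)) {
      at <- MOTIF_LAYOUT[[nm]]$at
      root[(at[1] + 1L):at[2]] <- aa_encode(MOTIF_LAYOUT[[nm]]$consensus)
      motifs[[nm]] <- at
    }
    prot <- rep(FALSE, dl)
    for (m in motifs) prot[(m[1] + 1L):m[2]] <- TRUE
    root_n <- sample_background(config$lengths$n_domain)
    div <- config$evolution$profile_divergence

    domains <- list()
    n_domains <- list()
    for (f in config$families) {
      for (dom in c("D1", "D2")[seq_len(f$n_domains)]) {
        codes <- diverge_codes(root, div, prot)
        mot <- motifs
        degen <- f$degenerate_motifs[[dom]]
        for (nm in degen %||% character(0)) {
          at <- motifs[[nm]]
          span <- (at[1] + 1L):at[2]
          if (nm == "sensor_2") {
            codes[span] <- aa_encode("GAK")  # aspartate -> lysine
          } else {
            canon <- aa_encode(MOTIF_LAYOUT[[nm]]$consensus)
            codes[span] <- vapply(canon, function(a)
              sample(setdiff(0:19, a), 1L), integer(1))
          }
        }
        insert <- NULL
        if (!is.null(f$insert) && identical(f$insert$domain, dom)) {
          at <- f$insert$at
          len <- f$insert$length
          codes <- append(codes, sample_background(len), after = at)
          insert <- c(at = at, length = len)
          # all motifs lie before the insert points used here
        }
        domains[[paste0(f$name, ".", dom)]] <-
          list(residues = codes, motifs = mot, insert = insert,
               degenerate = degen %||% character(0))
      }
      if (isTRUE(f$has_n_domain)) {
        n_domains[[paste0(f$name, ".N")]] <- diverge_codes(root_n, div)
      }
    }
    list(domains = domains, n_domains = n_domains,
         tail = aa_encode(TAIL_CONSENSUS), root_domain = root)
  })
}

# ancestral full-length protein for a family: residue codes, protection
# flags, and a region table in ancestral coordinates (0-based half-open)
family_construct <- function(f, profiles, config) {
  codes <- integer(0)
  prot <- logical(0)
  regions <- list()
  add <- function(region, x, protected = FALSE, sub_motifs = NULL) {
    off <- length(codes)
    codes <<- c(codes, x)
    prot <<- c(prot, rep(protected, length(x)))
    regions[[region]] <<- c(off, off + length(x))
    for (nm in names(sub_motifs %||% list())) {
      at <- sub_motifs[[nm]]
      regions[[paste0(region, ".", nm)]] <<- off + at
      prot[(off + at[1] + 1L):(off + at[2])] <<- TRUE
    }
  }
  if (isTRUE(f$has_n_domain)) {
    add("N", profiles$n_domains[[paste0(f$name, ".N")]])
    add("linker1", sample_background(config$lengths$linker))
  }
  for (dom in c("D1", "D2")[seq_len(f$n_domains)]) {
    p <- profiles$domains[[paste0(f$name, ".", dom)]]
    add(dom, p$residues, sub_motifs = p$motifs)
    if (dom == "D1" && f$n_domains == 2L) {
      add("linker2", sample_background(config$lengths$linker))
    }
  }
  if (isTRUE(f$tail_helix)) add("tail", profiles$tail, protected = TRUE)
  if (isTRUE(f$hbyx)) add("hbyx", aa_encode(HBYX_DEFAULT), protected = TRUE)
  list(codes = codes, protected = prot, regions = regions)
}

# species tree with named clades; eukaryote subtree scaled to the requested
# mean root-to-tip depth
make_species_tree <- function(config, seed = 1L) {
  withr_seed(seed, {
    tc <- config$tree
    n_rest <- tc$n_eukaryotes - tc$parasite_clade - tc$duplication_clade
    stopifnot(n_rest >= 3L)
    rest <- ape::rtree(n_rest)
    para <- ape::rtree(tc$parasite_clade)
    dup <- ape::rtree(tc$duplication_clade)
    glue <- function(a, b, stem = 0.4) {
      txt <- sprintf("(%s:%f,%s:%f);",
                     sub(";$", "", ape::write.tree(a)), stem,
                     sub(";$", "", ape::write.tree(b)), stem)
      ape::read.tree(text = txt)
    }
    euk <- glue(glue(rest, dup), para)
    depths <- ape::node.depth.edgelength(euk)[seq_along(euk$tip.label)]
    euk$edge.length <- euk$edge.length * tc$root_to_tip / mean(depths)
    arch <- ape::rtree(tc$n_archaea)
    darch <- ape::node.depth.edgelength(arch)[seq_along(arch$tip.label)]
    arch$edge.length <- arch$edge.length * tc$root_to_tip / mean(darch)
    # rename deterministically by tip order (rest, duplication, parasite)
    euk$tip.label <- paste0("E", sprintf("%02d", seq_along(euk$tip.label)))
    arch$tip.label <- paste0("A", sprintf("%02d", seq_along(arch$tip.label)))
    full <- glue(euk, arch, stem = 0.3)
    # identify clades by position: the glue order above puts the parasite
    # clade last among eukaryote tips and the duplication clade after rest
    ntips_rest <- length(rest$tip.label)
    ntips_dup <- length(dup$tip.label)
    euk_tips <- euk$tip.label
    dup_tips <- euk_tips[ntips_rest + seq_len(ntips_dup)]
    para_tips <- euk_tips[(ntips_rest + ntips_dup + 1L):length(euk_tips)]
    list(tree = full, euk = euk, arch_tips = arch$tip.label,
         euk_tips = euk_tips, parasite_tips = para_tips,
         dup_tips = dup_tips,
         clades = list(parasite = para_tips, duplication = dup_tips,
                       eukaryotes = euk_tips))
  })
}

# evolve one site table along a branch: substitutions at unprotected sites
# plus rare indels (insertions between existing sites, deletions of
# unprotected runs); table columns pos (numeric, orderable through
# insertions), res (codes), prot (logical)
evolve_branch <- function(tab, b, rate, indel_rate) {
  n <- nrow(tab)
  tab$res <- diverge_codes(tab$res, rate * b, tab$prot)
  nind <- stats::rpois(1L, indel_rate * b * n)
  for (k in seq_len(nind)) {
    if (stats::runif(1) < 0.5 && any(!tab$prot)) {
      len <- stats::rgeom(1L, 0.35) + 1L
      start <- sample(which(!tab$prot), 1L)
      run <- start
      while (length(run) < len && (last <- run[length(run)] + 1L) <= nrow(tab) &&
             !tab$prot[last]) run <- c(run, last)
      tab <- tab[-run, , drop = FALSE]
    } else {
      len <- stats::rgeom(1L, 0.35) + 1L
      i <- sample.int(nrow(tab), 1L)
      lo <- tab$pos[i]
      hi <- if (i < nrow(tab)) tab$pos[i + 1L] else lo + 1
      newpos <- lo + (hi - lo) * seq_len(len) / (len + 1L)
      ins <- data.frame(pos = newpos, res = sample_background(len),
                        prot = FALSE)
      tab <- rbind(tab[seq_len(i), , drop = FALSE], ins,
                   if (i < nrow(tab)) tab[(i + 1L):nrow(tab), , drop = FALSE])
    }
  }
  rownames(tab) <- NULL
  tab
}

# recursive descent over a phylo subtree from a root state; returns leaf
# site tables and internal node states
evolve_on_tree <- function(tree, root_state, rate, indel_rate) {
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- root_state
  leaf_tabs <- list()
  order <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(order$edge))) {
    p <- order$edge[k, 1L]; ch <- order$edge[k, 2L]
    b <- order$edge.length[k]
    states[[ch]] <- evolve_branch(states[[p]], b, rate, indel_rate)
    if (ch <= ntip) leaf_tabs[[tree$tip.label[ch]]] <- states[[ch]]
  }
  list(leaves = leaf_tabs, states = states)
}

# leaf coordinates (0-based half-open) of an ancestral region
region_leaf_coords <- function(tab, region_range) {
  c(sum(tab$pos < region_range[1]), sum(tab$pos < region_range[2]))
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_profiles], builds the species tree, evolves every family on
#' its domain of life ([evolve]) and applies the configured loss and
#' duplication events ([apply_events]).
#'
#' @param config configuration list, see [default_config].
#' @param seed master RNG seed; the dataset is a deterministic function of
#'   (config, seed).
#' @return object of class `synth_dataset`: list with `sequences`
#'   ([aa_set]), `truth` (per-protein data frame), `regions` (per-protein
#'   region/motif coordinates, 0-based half-open), `tree` (full species
#'   tree), `euk_tree`, `clades`, `events`, `profiles`, `config`,
#'   `site_tables` (per family, per protein: the evolved site table, used
#'   to cut truth-based seed alignments).
#' @export
synth_dataset <- function(config = default_config(), seed = 1L) {
  profiles <- make_profiles(config, seed)
  sp <- make_species_tree(config, seed + 1000L)
  ev <- evolve(profiles, sp, config, seed + 2000L)
  apply_events(ev, config, seed + 3000L)
}

#' Evolve family constructs along the species tree
#'
#' Eukaryotic families evolve on the eukaryote subtree, archaeal families
#' on the archaeal subtree, under a BLOSUM62-biased Poisson substitution
#' process (expected `rate * branch length` events per site) with rare
#' indels outside the protected motif sites.
#'
#' @param profiles output of [make_profiles].
#' @param sp species-tree bundle from the internal tree builder.
#' @param config configuration list.
#' @param seed RNG seed.
#' @return intermediate dataset (pre-events); see [synth_dataset].
#' @export
evolve <- function(profiles, sp, config, seed = 1L) {
  rate <- config$evolution$rate
  indel <- config$evolution$indel_rate
  stopifnot(rate >= 0, indel >= 0)
  arch_tree <- ape::keep.tip(sp$tree, sp$arch_tips)
  withr_seed(seed, {
    fam_out <- list()
    for (f in config$families) {
      cons <- family_construct(f, profiles, config)
      tab0 <- data.frame(pos = as.numeric(seq_along(cons$codes) - 1L),
                         res = cons$codes, prot = cons$protected)
      tr <- if (isTRUE(f$archaeal)) arch_tree else sp$euk
      run <- evolve_on_tree(tr, tab0, rate, indel)
      fam_out[[f$name]] <- list(spec = f, regions = cons$regions,
                                leaves = run$leaves, states = run$states,
                                tree = tr)
    }
    structure(list(families = fam_out, sp = sp, profiles = profiles,
                   config = config), class = "synth_evolved")
  })
}

#' Apply planted loss and duplication events
#'
#' Losses delete the family's gene in every leaf of the named clade (except
#' the configured `keep` families). A duplication re-evolves the family
#' from its state at the clade ancestor, yielding an independent second
#' copy in every clade leaf.
#'
#' @param ev output of [evolve].
#' @param config configuration list.
#' @param seed RNG seed for the duplicated copies' divergence.
#' @return a `synth_dataset`.
#' @export
apply_events <- function(ev, config, seed = 1L) {
  stopifnot(inherits(ev, "synth_evolved"))
  sp <- ev$sp
  events <- list()
  lost <- list() # family -> species vector
  for (ls in config$losses %||% list()) {
    clade_tips <- sp$clades[[ls$clade]]
    if (is.null(clade_tips)) stop("unknown clade: ", ls$clade)
    for (f in config$families) {
      if (isTRUE(f$archaeal) || f$name %in% ls$keep) next
      lost[[f$name]] <- union(lost[[f$name]], clade_tips)
      events[[length(events) + 1L]] <- data.frame(
        family = f$name, branch = ls$clade, type = "loss",
        stringsAsFactors = FALSE)
    }
  }
  dup_rows <- list()
  withr_seed(seed, {
    for (du in config$duplications %||% list()) {
      clade_tips <- sp$clades[[du$clade]]
      if (is.null(clade_tips)) stop("unknown clade: ", du$clade)
      if (any(clade_tips %in% (lost[[du$family]] %||% character(0))))
        stop("duplication of ", du$family, " below a loss of the same family")
      fam <- ev$families[[du$family]]
      if (is.null(fam)) stop("unknown family: ", du$family)
      mrca <- ape::getMRCA(fam$tree, clade_tips)
      sub <- ape::extract.clade(fam$tree, mrca)
      run2 <- evolve_on_tree(sub, fam$states[[mrca]],
                             config$evolution$rate,
                             config$evolution$indel_rate)
      dup_rows[[length(dup_rows) + 1L]] <-
        list(family = du$family, leaves = run2$leaves)
      events[[length(events) + 1L]] <- data.frame(
        family = du$family, branch = du$clade, type = "duplication",
        stringsAsFactors = FALSE)
    }
  })

  seqs <- list(); truth <- list(); regions <- list(); site_tabs <- list()
  lineage_of <- function(species) {
    if (species %in% sp$arch_tips) "Archaea"
    else if (species %in% sp$parasite_tips) "Eukaryota;Parasitica"
    else if (species %in% sp$dup_tips) "Eukaryota;Duplicata"
    else "Eukaryota;Varia"
  }
  emit <- function(family, spec, reg, species, tab, copy) {
    seq_id <- paste0(species, "_", family, if (copy > 1L) paste0("_", copy))
    residues <- aa_decode(tab$res)
    seqs[[length(seqs) + 1L]] <<- data.frame(
      id = seq_id, species = species, lineage = lineage_of(species),
      residues = residues, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      seq_id = seq_id, species = species, family = family, copy = copy,
      length = nrow(tab),
      has_n_domain = isTRUE(spec$has_n_domain),
      tail_helix = isTRUE(spec$tail_helix), hbyx = isTRUE(spec$hbyx),
      stringsAsFactors = FALSE)
    regs <- lapply(names(reg), function(r) {
      co <- region_leaf_coords(tab, reg[[r]])
      data.frame(seq_id = seq_id, region = r, start = co[1], end = co[2],
                 stringsAsFactors = FALSE)
    })
    regions[[length(regions) + 1L]] <<- do.call(rbind, regs)
    site_tabs[[family]][[seq_id]] <<- tab
  }
  for (fname in names(ev$families)) {
    fam <- ev$families[[fname]]
    for (species in names(fam$leaves)) {
      if (species %in% (lost[[fname]] %||% character(0))) next
      emit(fname, fam$spec, fam$regions, species, fam$leaves[[species]], 1L)
    }
  }
  for (d in dup_rows) {
    fam <- ev$families[[d$family]]
    for (species in names(d$leaves)) {
      emit(d$family, fam$spec, fam$regions, species, d$leaves[[species]], 2L)
    }
  }
  sq <- do.call(rbind, seqs)
  sequences <- aa_set(sq$id, sq$residues, sq$species, sq$lineage)
  structure(list(
    sequences = sequences,
    truth = do.call(rbind, truth),
    regions = do.call(rbind, regions),
    tree = sp$tree, euk_tree = sp$euk, clades = sp$clades,
    arch_tips = sp$arch_tips,
    family_regions = lapply(ev$families, `[[`, "regions"),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(family = character(0), branch = character(0),
                 type = character(0)),
    profiles = ev$profiles, config = ev$config,
    site_tables = site_tabs
  ), class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("synth_dataset: ", nrow(x$truth), " proteins, ",
      length(unique(x$truth$family)), " families, ",
      length(x$tree$tip.label), " species\n", sep = "")
  invisible(x)
}

#' Truth-based seed alignments
#'
#' Cuts per-subgroup alignments (family x domain, optionally the N-domain)
#' from the planted homology: columns are the ancestral domain positions;
#' residues inserted after the root construct are omitted, deleted
#' positions appear as gaps. Rows are drawn from `n_per_family` species
#' spread over the tree (first-copy genes only).
#'
#' @param ds a `synth_dataset`.
#' @param n_per_family rows per subgroup alignment.
#' @param include_n also emit `<family>.N` alignments.
#' @return named list of [msa] objects keyed by subgroup label
#'   (`"Cdc48.D1"`, ...).
#' @export
seed_alignments <- function(ds, n_per_family = 10L, include_n = FALSE) {
  stopifnot(inherits(ds, "synth_dataset"))
  out <- list()
  for (fname in names(ds$site_tables)) {
    tabs <- ds$site_tables[[fname]]
    ids <- names(tabs)
    ids <- ids[ds$truth$copy[match(ids, ds$truth$seq_id)] == 1L]
    take <- ids[unique(round(seq(1L, length(ids),
                                 length.out = min(n_per_family, length(ids)))))]
    regs <- ds$family_regions[[fname]]
    doms <- intersect(c("D1", "D2", if (include_n) "N"), names(regs))
    for (dom in doms) {
      rr <- regs[[dom]]
      cols <- seq.int(rr[1], rr[2] - 1L)
      rows <- vapply(take, function(id) {
        tab <- tabs[[id]]
        anc <- tab[tab$pos %in% cols, ]
        res <- rep("-", length(cols))
        res[match(anc$pos, cols)] <- AAX[anc$res + 1L]
        paste(res, collapse = "")
      }, character(1))
      names(rows) <- paste0(take, ".", dom)
      out[[paste0(fname, ".", dom)]] <- msa(rows)
    }
  }
  out
}

# motif column ranges of each subgroup's seed alignment, in seed-alignment
# coordinates (0-based half-open relative to the domain start)
seed_motif_annotations <- function(ds) {
  out <- list()
  for (fname in names(ds$family_regions)) {
    regs <- ds$family_regions[[fname]]
    for (dom in intersect(c("D1", "D2"), names(regs))) {
      off <- regs[[dom]][1]
      mots <- grep(paste0("^", dom, "\\."), names(regs), value = TRUE)
      ann <- lapply(mots, function(m) regs[[m]] - off)
      names(ann) <- sub(paste0("^", dom, "\\."), "", mots)
      out[[paste0(fname, ".", dom)]] <- ann
    }
  }
  out
}

#' Star-sample sequences from one family construct
#'
#' Draws `n` independent leaves at the given divergence from the family's
#' ancestral construct (a star tree). Used for controlled contrasts, e.g.
#' motif-degeneracy comparisons at fixed sample size.
#'
#' @param config,seed as in [synth_dataset].
#' @param family family name.
#' @param n number of sequences.
#' @param divergence expected substitutions per site from the ancestor.
#' @return a `synth_dataset`-shaped list with `sequences`, `regions`,
#'   `site_tables`, `family_regions` for the one family.
#' @export
synth_star_sample <- function(config = default_config(), family, n = 50L,
                              divergence = 0.8, seed = 1L) {
  profiles <- make_profiles(config, seed)
  spec <- NULL
  for (f in config$families) if (f$name == family) spec <- f
  if (is.null(spec)) stop("unknown family: ", family)
  withr_seed(seed + 500L, {
    cons <- family_construct(spec, profiles, config)
    tab0 <- data.frame(pos = as.numeric(seq_along(cons$codes) - 1L),
                       res = cons$codes, prot = cons$protected)
    tabs <- lapply(seq_len(n), function(i)
      evolve_branch(tab0, divergence, config$evolution$rate,
                    config$evolution$indel_rate))
    names(tabs) <- sprintf("S%03d_%s", seq_len(n), family)
    regions <- do.call(rbind, lapply(names(tabs), function(id) {
      do.call(rbind, lapply(names(cons$regions), function(r) {
        co <- region_leaf_coords(tabs[[id]], cons$regions[[r]])
        data.frame(seq_id = id, region = r, start = co[1], end = co[2])
      }))
    }))
    residues <- vapply(tabs, function(t) aa_decode(t$res), character(1))
    list(sequences = aa_set(names(tabs), residues,
                            species = sub("_.*", "", names(tabs))),
         regions = regions,
         site_tables = stats::setNames(list(tabs), family),
         family_regions = stats::setNames(list(cons$regions), family),
         profiles = profiles, config = config)
  })
}
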