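#' @include simulate.R phmm.R
NULL

# Deterministic per-domain sub-seed so a domain's consensus never
# depends on how many other domains are in the library.
domainSeed <- function(seed, name) childSeed(seed, paste0("domain:", name))

#' Synthetic domain library
#'
#' For each domain name, a deterministic consensus sequence and a
#' calibrated profile HMM built from noised copies of it.  Stands in
#' for a real domain-profile database at toy scale; neighbor genes in
#' simulated gene neighborhoods are emitted from these consensi.
#'
#' @param domains Character vector of domain names.
#' @param seed Integer seed.
#' @param length Consensus length in residues.
#' @param nCopies,noise Training copies per model and per-residue
#'   substitution probability used to give the models realistic width.
#' @return Named list with elements \code{consensus} (string) and
#'   \code{hmm} ([ProfileHMM-class]) per domain.
#' @export
syntheticDomainLibrary <- function(domains, seed = 1, length = 110,
                                   nCopies = 8, noise = 0.1) {
  bg <- backgroundFrequencies()
  lib <- list()
  for (dom in domains) {
    lib[[dom]] <- withSeed(domainSeed(seed, dom), {
      for (attempt in 1:20) {
        cons <- sample.int(20L, length, replace = TRUE, prob = bg)
        copies <- vapply(seq_len(nCopies), function(i) {
          x <- cons
          mut <- runif(length) < noise
          x[mut] <- sample.int(20L, sum(mut), replace = TRUE, prob = bg)
          aaDecode(x)
        }, character(1))
        msa <- ProteinMSA(setNames(copies,
                                   paste0(dom, "_t", seq_len(nCopies))))
        hmm <- buildProfileHMM(msa, occupancy = 0.5, pseudocount = 1,
                               name = dom)
        # domains model unrelated families: redraw any consensus with
        # appreciable cross-similarity to an already-drawn domain
        distinct <- all(vapply(lib, function(prev) {
          forwardBits(prev$hmm0, aaDecode(cons)) < 5 &&
            forwardBits(hmm, prev$consensus) < 5
        }, logical(1)))
        if (distinct) break
      }
      list(consensus = aaDecode(cons), hmm0 = hmm,
           hmm = calibrateHMM(hmm, nRandom = 1000,
                              seed = domainSeed(seed, dom)))
    })
  }
  lapply(lib, function(x) x[c("consensus", "hmm")])
}

#' Built-in neighborhood templates
#'
#' Clade-tagged gene-neighborhood layouts: a division-and-cell-wall
#' style cluster for the bacterial domain and a protein-biosynthesis
#' (ribosomal) cluster for the archaeal domain, mirroring the
#' contrasting genome contexts of bacterial and archaeal cell-division
#' genes.  Each row is one gene slot: \code{domain} (\code{"focal"}
#' marks the family gene), \code{gap_bp} intergenic gap before the
#' gene, \code{strand}.
#'
#' @return Named list of template \code{data.frame}s keyed by clade
#'   tag.
#' @export
defaultNeighborhoodTemplates <- function() {
  tpl <- function(doms, focalAt) {
    n <- length(doms) + 1L
    d <- append(doms, "focal", after = focalAt - 1L)
    data.frame(domain = d,
               gap_bp = rep(c(120L, 80L), length.out = n),
               strand = rep(c("+", "-"), length.out = n),
               stringsAsFactors = FALSE)
  }
  list("Bacteria-like" = tpl(c("FtsA", "FtsQ", "FtsW", "Mur_ligase",
                               "MraY"), 3L),
       "Archaea-like" = tpl(c("Ribosomal_L10", "Ribosomal_S9",
                              "tRNA_synt", "RHH_1"), 2L))
}

#' Emit genomes: proteomes, gene tables and taxonomy
#'
#' Embeds every focal family gene in its clade's template neighborhood
#' on a single contig per genome.  Neighbor proteins are emitted from
#' the named domain's consensus with per-residue noise; coordinates
#' are 1-based inclusive; strands follow the template.  Paralogous
#' focal copies get consecutive neighborhood blocks separated by a
#' 10 kb spacer.
#'
#' @param records Family [ProteinSet-class] from [evolveFamily()]
#'   (ids \code{genome|label}).
#' @param taxonomy Taxonomy \code{data.frame} covering every genome.
#' @param templates Named list of templates (see
#'   [defaultNeighborhoodTemplates()]); a record's template is looked
#'   up by, in order, \code{"<domain>|<label>"}, then its domain,
#'   phylum, class and order tags.
#' @param library Domain library from [syntheticDomainLibrary()]
#'   covering every template domain; built automatically when NULL.
#' @param seed Integer seed.
#' @param noise Per-residue substitution probability for neighbor
#'   proteins.
#' @return \code{list(proteome, geneTable, taxonomy, library)}:
#'   \code{proteome} is a [ProteinSet-class] of all emitted proteins
#'   (family + neighbors) with loci; \code{geneTable} has columns
#'   \code{genome, contig, gene_id, start, end, strand, truth_domain}.
#' @export
emitGenomes <- function(records, taxonomy,
                        templates = defaultNeighborhoodTemplates(),
                        library = NULL, seed = 1, noise = 0.1) {
  meta <- recordMeta(records)
  unknown <- setdiff(meta$genome, taxonomy$genome)
  if (length(unknown))
    stop("configuration-error: genomes missing from taxonomy: ",
         paste(unknown, collapse = ", "))
  doms <- unique(unlist(lapply(templates, function(t)
    setdiff(t$domain, "focal"))))
  if (is.null(library))
    library <- syntheticDomainLibrary(doms, seed = seed)
  miss <- setdiff(doms, names(library))
  if (length(miss))
    stop("configuration-error: domains missing from library: ",
         paste(miss, collapse = ", "))

  templateFor <- function(row, label) {
    for (key in c(paste0(row$domain, "|", label), row$domain,
                  row$phylum, row$class, row$order))
      if (!is.null(templates[[key]])) return(templates[[key]])
    stop("configuration-error: no neighborhood template for clade of ",
         row$genome)
  }

  bg <- backgroundFrequencies()
  seqs <- character(0); ids <- character(0)
  gt <- list(); pmeta <- list()
  withSeed(childSeed(seed, "emit"), {
    for (genome in sort(unique(meta$genome))) {
      rows <- which(meta$genome == genome)
      cursor <- 101L                        # 1-based; leading margin
      nbCount <- 0L
      for (ri in rows) {
        id <- names(records)[ri]
        label <- sub("^.*\\|", "", id)
        tpl <- templateFor(meta[ri, ], label)
        for (k in seq_len(nrow(tpl))) {
          cursor <- cursor + tpl$gap_bp[k]
          if (tpl$domain[k] == "focal") {
            prot <- as.character(sequences(records)[[ri]])
            gid <- id
            tdom <- paste0("focal:", label)
          } else {
            cons <- aaEncode(library[[tpl$domain[k]]]$consensus)
            mut <- runif(length(cons)) < noise
            cons[mut] <- sample.int(20L, sum(mut), replace = TRUE,
                                    prob = bg) - 1L
            prot <- aaDecode(cons + 1L)
            nbCount <- nbCount + 1L
            gid <- sprintf("%s_n%02d", genome, nbCount)
            tdom <- tpl$domain[k]
          }
          len <- 3L * nchar(prot)
          gt[[gid]] <- data.frame(genome = genome, contig = "c1",
                                  gene_id = gid, start = cursor,
                                  end = cursor + len - 1L,
                                  strand = tpl$strand[k],
                                  truth_domain = tdom,
                                  stringsAsFactors = FALSE)
          ids <- c(ids, gid); seqs <- c(seqs, prot)
          cursor <- cursor + len
        }
        cursor <- cursor + 10000L           # spacer between paralog blocks
      }
    }
  })
  geneTable <- do.call(rbind, gt)
  rownames(geneTable) <- NULL
  i <- match(geneTable$genome, taxonomy$genome)
  pm <- data.frame(genome = geneTable$genome,
                   domain = taxonomy$domain[i],
                   phylum = taxonomy$phylum[i],
                   class = taxonomy$class[i],
                   order = taxonomy$order[i],
                   contig = geneTable$contig,
                   start = geneTable$start, end = geneTable$end,
                   strand = geneTable$strand,
                   stringsAsFactors = FALSE)
  proteome <- ProteinSet(setNames(seqs, ids), pm)
  list(proteome = proteome, geneTable = geneTable,
       taxonomy = taxonomy[taxonomy$genome %in% meta$genome, ,
                           drop = FALSE],
       library = library)
}

#' Write a simulated corpus to disk
#'
#' FASTA wrapped at 60 columns, gene table / taxonomy / event-log TSV,
#' Newick truth trees.  Identical seeds produce byte-identical files.
#'
#' @param sim Result of [simulateCorpus()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedCorpus <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeProteinFasta(sim$records, file.path(dir, "family.faa"))
  if (!is.null(sim$proteome)) {
    writeProteinFasta(sim$proteome, file.path(dir, "proteome.faa"))
    writeTsv(sim$geneTable, file.path(dir, "genes.tsv"))
  }
  writeTsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  writeTsv(sim$truth$sequences, file.path(dir, "truth_sequences.tsv"))
  if (!is.null(sim$truth$events))
    writeTsv(sim$truth$events, file.path(dir, "events.tsv"))
  ape::write.tree(sim$species$tree, file.path(dir, "species_tree.nwk"))
  gts <- Filter(Negate(is.null), sim$truth$geneTrees)
  if (length(gts))
    ape::write.tree(do.call(c, unname(gts)),
                    file.path(dir, "gene_trees.nwk"))
  invisible(dir)
}

#' One-call simulated study corpus
#'
#' Builds the species tree, evolves the family under a named scenario,
#' and emits genomes with clade-specific neighborhoods.  Scenarios:
#' \describe{
#'   \item{plain}{single-copy family, no events.}
#'   \item{duplication}{one duplication on the stem of the
#'     Archaea-like clade (\code{ftsZ} -> \code{ftsZ} + \code{ftsZ2}),
#'     the family's hallmark pre-diversification duplication.}
#'   \item{cterm}{as \code{duplication}, plus a \code{cetZ}-like copy
#'     of the archaeal paralog (its tail therefore descends from the
#'     archaeal tail) and a \code{tub}-like copy whose tail is
#'     replaced by a fresh lineage — the contrast set for the
#'     C-terminus provenance test.}
#' }
#'
#' @param nTaxa Number of genomes (default 32).
#' @param scenario \code{"plain"}, \code{"duplication"} or
#'   \code{"cterm"}.
#' @param seed Integer seed; stage sub-seeds are derived from it.
#' @param arch Architecture, see [familyArchitecture()].
#' @param templates Neighborhood templates, see
#'   [defaultNeighborhoodTemplates()].
#' @param genomes Emit gene neighborhoods and the domain library
#'   (needed for genomic-context analysis); skipping them makes
#'   family-only studies much faster.
#' @param anchor Build the calibrated N-terminal anchor model.
#' @return List with \code{species, records, truth, schedule} and,
#'   depending on the flags, \code{proteome, geneTable, taxonomy,
#'   library, anchor}.
#' @export
simulateCorpus <- function(nTaxa = 32, scenario = c("duplication",
                                                    "plain", "cterm"),
                           seed = 1, arch = familyArchitecture(),
                           templates = defaultNeighborhoodTemplates(),
                           genomes = TRUE, anchor = TRUE) {
  scenario <- match.arg(scenario)
  species <- simulateSpeciesTree(nTaxa, seed = childSeed(seed, "tree"))
  stem <- stemBranchOf(species, "Archaea-like")
  stemLen <- species$tree$edge.length[species$tree$edge[, 2] == stem]
  schedule <- switch(scenario,
    plain = NULL,
    duplication = simEvent("duplication", stem, 0.25 * stemLen,
                           target = "ftsZ", newLabel = "ftsZ2"),
    cterm = rbind(
      # the archaeal FtsZ subfamily acquires its own (family-specific)
      # tail lineage on the domain stem, then duplicates; the CetZ-like
      # copy therefore inherits the archaeal tail, while the tub-like
      # copy gets a fresh, unrelated tail
      simEvent("cterm_swap", stem, 0.10 * stemLen,
               target = "ftsZ", source = "fresh"),
      simEvent("duplication", stem, 0.25 * stemLen,
               target = "ftsZ", newLabel = "ftsZ2"),
      simEvent("duplication", stem, 0.90 * stemLen,
               target = "ftsZ2", newLabel = "cetZ"),
      simEvent("duplication", stem, 0.90 * stemLen,
               target = "ftsZ2", newLabel = "tub"),
      simEvent("cterm_swap", stem, 0.92 * stemLen,
               target = "tub", source = "fresh")))
  fam <- evolveFamily(species, arch = arch, schedule = schedule,
                      seed = childSeed(seed, "family"))
  out <- c(list(species = species, schedule = schedule), fam)
  if (genomes)
    out <- c(out, emitGenomes(fam$records, species$taxonomy,
                              templates = templates,
                              seed = childSeed(seed, "genomes")))
  else out$taxonomy <- species$taxonomy
  if (anchor)
    out$anchor <- ntermAnchorModel(fam, seed = childSeed(seed, "anchor"))
  out
}

#' N-terminal anchor model of a simulated family
#'
#' Builds the query profile of the shared N-terminal domain from the
#' true segment-1 subsequences of a spread subsample — the simulated
#' analog of the curated domain-database model (e.g. Pfam Tubulin)
#' that the real workflow takes as input.
#'
#' @param fam Result of [evolveFamily()] (\code{records} + \code{truth}).
#' @param nMembers Subsample size (default 12).
#' @param seed Calibration seed.
#' @return A calibrated [ProfileHMM-class] named \code{"TubulinN"}.
#' @export
ntermAnchorModel <- function(fam, nMembers = 12, seed = 1) {
  tr <- fam$truth$sequences
  ids <- names(fam$records)
  pick <- ids[unique(round(seq(1, length(ids),
                               length.out = min(nMembers, length(ids)))))]
  nt <- setNames(substr(as.character(sequences(fam$records[pick])), 1,
                        tr$nterm_length[match(pick, tr$seq_id)]),
                 pick)
  msa <- trimGapThreshold(progressiveAlign(nt), 0.5)
  hmm <- buildProfileHMM(msa, occupancy = 0.5, pseudocount = 1,
                         name = "TubulinN")
  calibrateHMM(hmm, nRandom = 1000, lenMean = mean(nchar(nt)),
               seed = seed)
}
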