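# The two replicate experiments behind the headline simulation checks,
# shared by the acceptance tests and scripts/acceptance.R (which calls
# the same package functions directly).

# Duplication recovery: does the bootstrapped NJ tree contain the two
# archaeal paralog clades, and at what support?
duplicationExperiment <- function(seed, nTaxa = 32, nReps = 100) {
  sim <- simulateCorpus(nTaxa = nTaxa, scenario = "duplication",
                        seed = seed, genomes = FALSE, anchor = FALSE)
  msa <- trimGapThreshold(progressiveAlign(sim$records), 0.2)
  st <- bootstrapSupports(msa, nReps = nReps, seed = seed + 1000)
  phy <- asPhylo(st)
  ntip <- length(phy$tip.label)
  m <- recordMeta(sim$records)
  archG <- unique(m$genome[m$domain == "Archaea-like"])
  keys <- ftszprov:::bipartitionKeys(phy)
  vapply(c("ftsZ", "ftsZ2"), function(lab) {
    key <- paste(sort(paste0(archG, "|", lab)), collapse = "\r")
    i <- match(key, keys)
    if (is.na(i)) return(-1)                     # clade absent
    nodeSupport(st)[as.integer(names(keys)[i]) - ntip]
  }, numeric(1))
}

# C-terminus provenance recovery: is the archaeal source stratum
# flagged, and the bacterial / fresh-tail strata not?
ctermExperiment <- function(seed, nTaxa = 32) {
  sim <- simulateCorpus(nTaxa = nTaxa, scenario = "cterm", seed = seed,
                        genomes = FALSE, anchor = TRUE)
  fam <- sim$records
  ct <- extractCTermSet(fam, sim$anchor)
  groups <- setNames(sub("^.*\\|", "", names(fam)), names(fam))
  cet <- names(ct$tails)[groups[names(ct$tails)] == "cetZ"]
  if (length(cet) < 3) return(NULL)
  mod <- buildGroupModel(ct$tails[cet], name = "CetZ_C",
                         seed = seed + 7, nRandom = 1000)
  hm <- crossSearch(list(mod), fam)
  dom <- setNames(recordMeta(fam)$domain, names(fam))
  rep <- provenanceReport(hm, groups, dom)
  pick <- function(f, d, col) rep[[col]][rep$family == f &
                                           rep$tax_domain == d]
  list(archFlag = isTRUE(pick("ftsZ2", "Archaea-like", "flagged")),
       bactFlag = isTRUE(pick("ftsZ", "Bacteria-like", "flagged")),
       tubFlag = isTRUE(pick("tub", "Archaea-like", "flagged")),
       archMedian = pick("ftsZ2", "Archaea-like", "median_evalue"),
       bactMedian = pick("ftsZ", "Bacteria-like", "median_evalue"))
}

# Context contrast: presence table vs the emitted truth tables, and
# the top-k ranking of template domains.
contextExperiment <- function(seed, nTaxa = 16) {
  sim <- simulateCorpus(nTaxa = nTaxa, scenario = "duplication",
                        seed = seed, anchor = FALSE)
  gt <- sim$geneTable
  nbhs <- annotateNeighborhoods(
    lapply(names(sim$records), extractWindow, geneTable = gt,
           flankBp = 5000),
    sim$library, sim$proteome, 1e-3)
  tab <- domainPresenceTable(nbhs, sim$taxonomy, rank = "phylum")
  truthPairs <- unique(do.call(rbind, lapply(nbhs, function(nh) {
    doms <- unique(gt$truth_domain[match(nh$neighbors$gene_id,
                                         gt$gene_id)])
    data.frame(genome = nh$genome, dom = doms,
               stringsAsFactors = FALSE)
  })))
  truthPairs$phylum <- sim$taxonomy$phylum[match(truthPairs$genome,
                                                 sim$taxonomy$genome)]
  want <- table(truthPairs$dom, truthPairs$phylum)
  exact <- all(dim(tab) == dim(want)) &&
    all(rownames(tab) == sort(rownames(want))) &&
    all(tab[rownames(want), colnames(want)] == want)
  tplDoms <- sort(unique(unlist(lapply(defaultNeighborhoodTemplates(),
                                       function(t)
                                         setdiff(t$domain, "focal")))))
  top <- topDomains(tab, 25)
  list(exact = exact,
       topContainsTemplates = all(tplDoms %in%
                                    utils::head(top$domain,
                                                length(tplDoms))),
       table = tab,
       archPhyla = unique(sim$taxonomy$phylum[
         sim$taxonomy$domain == "Archaea-like"]))
}
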