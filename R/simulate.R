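#' @include proteinset.R
NULL

# ---- species tree -----------------------------------------------------

#' Simulate an ultrametric species tree with a four-rank taxonomy
#'
#' Two birth-only (Yule) subtrees of about equal size — the taxonomic
#' domains \code{"Bacteria-like"} and \code{"Archaea-like"} — are each
#' rescaled to height \code{1 - stemLen} and joined at the root by
#' stem branches, so every root-to-tip path equals 1 and both domains
#' have a proper stem edge (the natural place for
#' pre-diversification events).  Phylum, class and order are assigned
#' by cutting the tree at fixed depths (0.25, 0.5 and 0.75 of the
#' root height): all leaves below one cut edge share the rank label.
#'
#' @param nTaxa Number of genomes (>= 2).
#' @param birthRate Speciation rate per unit time.
#' @param stemLen Length of the two domain stem edges (fraction of the
#'   unit root height; default 0.5 — the inter-domain split is deep
#'   relative to within-domain radiation, as in the prokaryotic
#'   domains).
#' @param seed Integer seed.
#' @return \code{list(tree, taxonomy)}: an ultrametric [ape::phylo]
#'   with leaf labels \code{g01, g02, ...} and a \code{data.frame}
#'   (\code{genome, domain, phylum, class, order}).
#' @export
simulateSpeciesTree <- function(nTaxa, birthRate = 1, stemLen = 0.5,
                                seed = 1) {
  if (nTaxa < 2) stop("invalid-argument: nTaxa must be >= 2")
  subH <- 1 - stemLen
  nB <- ceiling(nTaxa / 2)
  nA <- nTaxa - nB
  phy <- withSeed(seed, {
    yule <- function(n) {
      if (n == 1) return(NULL)
      t <- ape::rphylo(n, birth = birthRate, death = 0)
      t$edge.length <- t$edge.length * subH /
        max(ape::node.depth.edgelength(t)[seq_len(n)])
      t
    }
    nwk <- function(t, stem) {
      if (is.null(t)) return(sprintf("x:%.10g", stem + subH))
      paste0(sub(";$", "", ape::write.tree(t)), ":",
             sprintf("%.10g", stem))
    }
    ape::read.tree(text = paste0("(", nwk(yule(nB), stemLen), ",",
                                 nwk(yule(nA), stemLen), ");"))
  })
  phy$tip.label <- sprintf("g%02d", seq_len(nTaxa))
  depth <- ape::node.depth.edgelength(phy)

  ntip <- nTaxa
  root <- ntip + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  domTag <- c("Bacteria-like", "Archaea-like")
  domain <- setNames(rep(domTag[1], ntip), phy$tip.label)
  below <- function(v) if (v <= ntip) v else
    unlist(phangorn::Descendants(phy, v, "tips"))
  if (length(kids) >= 2)
    domain[phy$tip.label[below(kids[2])]] <- domTag[2]

  # rank groups: for each leaf, the first ancestor strictly deeper than
  # the cut defines its group at that rank
  rankAt <- function(cut, prefix) {
    grp <- integer(ntip)
    seen <- integer(0)
    for (l in seq_len(ntip)) {
      path <- ape::nodepath(phy, root, l)
      anchor <- path[which(depth[path] > cut)[1]]
      if (!anchor %in% seen) seen <- c(seen, anchor)
      grp[l] <- match(anchor, seen)
    }
    sprintf("%s%02d", prefix, grp)
  }
  taxonomy <- data.frame(genome = phy$tip.label,
                         domain = unname(domain),
                         phylum = rankAt(0.25, "P"),
                         class = rankAt(0.50, "C"),
                         order = rankAt(0.75, "O"),
                         stringsAsFactors = FALSE)
  list(tree = phy, taxonomy = taxonomy)
}

#' Stem edge of a named clade
#' @param species Result of [simulateSpeciesTree()].
#' @param tag A taxonomy label at any rank (e.g. "Archaea-like").
#' @return Node id of the child end of the clade's stem edge.
#' @export
stemBranchOf <- function(species, tag) {
  tx <- species$taxonomy
  hit <- tx$genome[tx$domain == tag | tx$phylum == tag |
                   tx$class == tag | tx$order == tag]
  if (!length(hit)) stop("configuration-error: unknown clade tag ", tag)
  if (length(hit) == 1)
    return(match(hit, species$tree$tip.label))
  ape::getMRCA(species$tree, hit)
}

# ---- architecture and events ------------------------------------------

#' Default modular domain architecture of the simulated family
#'
#' Segment 1 is the shared N-terminal domain present in every family
#' member (the tubulin-like GTPase core); the remaining segment is the
#' lineage-diagnostic C-terminal tail.  The per-segment substitution
#' rate multiplier is \code{1 - conservation}.
#'
#' @param ntermLength,ctermLength Segment lengths in residues.
#' @param ntermConservation,ctermConservation Conservation levels in
#'   \[0, 1\].
#' @return \code{data.frame(segment, length, conservation)}.
#' @export
familyArchitecture <- function(ntermLength = 140, ctermLength = 70,
                               ntermConservation = 0.85,
                               ctermConservation = 0.25) {
  data.frame(segment = c("TubulinN", "Cterm"),
             length = c(ntermLength, ctermLength),
             conservation = c(ntermConservation, ctermConservation),
             stringsAsFactors = FALSE)
}

#' Construct one evolutionary event
#'
#' @param kind \code{"duplication"}, \code{"loss"}, \code{"lgt"} or
#'   \code{"cterm_swap"}.
#' @param branch Child-end node id of the species-tree branch the
#'   event sits on (see [stemBranchOf()]).
#' @param time Position along that branch, from its start, in
#'   branch-length units.
#' @param target Paralog label the event acts on.
#' @param newLabel Label of the copy created by duplication/lgt.
#' @param source For \code{cterm_swap}: \code{"fresh"} (a brand-new
#'   random tail lineage) or the label of a coexisting paralog whose
#'   current tail is copied (and then diverges independently).
#' @param donor For \code{lgt}: child-end node id of the donor branch.
#' @return One-row event \code{data.frame}.
#' @export
simEvent <- function(kind, branch, time, target = "ftsZ",
                     newLabel = NA_character_, source = NA_character_,
                     donor = NA_integer_) {
  data.frame(event_id = NA_character_, kind = kind, branch = branch,
             time = time, target = target, new_label = newLabel,
             source = source, donor = donor, stringsAsFactors = FALSE)
}

validateSchedule <- function(species, schedule) {
  if (is.null(schedule) || !nrow(schedule)) return(schedule)
  schedule$event_id <- sprintf("e%02d", seq_len(nrow(schedule)))
  phy <- species$tree
  depth <- ape::node.depth.edgelength(phy)
  parent <- setNames(phy$edge[, 1], phy$edge[, 2])
  elen <- setNames(phy$edge.length, phy$edge[, 2])
  for (i in seq_len(nrow(schedule))) {
    ev <- schedule[i, ]
    if (!as.character(ev$branch) %in% names(elen))
      stop("schedule-error (", ev$event_id, "): branch ", ev$branch,
           " is not a tree edge")
    if (ev$time < 0 || ev$time > elen[[as.character(ev$branch)]])
      stop("schedule-error (", ev$event_id,
           "): event time outside its branch")
    if (ev$kind == "lgt") {
      if (is.na(ev$donor) || ev$donor == ev$branch)
        stop("schedule-error (", ev$event_id,
             "): lgt needs a distinct donor branch")
      tAbs <- depth[parent[[as.character(ev$branch)]]] + ev$time
      d0 <- depth[parent[[as.character(ev$donor)]]]
      d1 <- depth[ev$donor]
      if (tAbs < d0 || tAbs > d1)
        stop("schedule-error (", ev$event_id,
             "): donor branch does not coexist at the event time")
    }
  }
  schedule
}

# ---- sequence evolution -----------------------------------------------

# One gene lineage: label, tail-origin tag, and per-segment residue
# vectors (aa: 1..20) with homology keys (numeric; shared key = shared
# ancestral column).
newRootGene <- function(arch, label, bg) {
  segs <- lapply(seq_len(nrow(arch)), function(s)
    list(key = as.numeric(seq_len(arch$length[s])),
         aa = sample.int(20L, arch$length[s], replace = TRUE, prob = bg)))
  list(label = label, cterm_origin = "root", segs = segs)
}

# Evolve one gene for teff expected substitutions/site per unit rate
# (per segment: teff * rateMultiplier), with indels at 0.02 events per
# substitution, geometric(0.7) lengths, never inside the first 10
# residues of segment 1.
evolveGene <- function(gene, t, rates, model) {
  for (s in seq_along(gene$segs)) {
    teff <- t * rates[s]
    if (teff <= 0) next
    seg <- gene$segs[[s]]
    n <- length(seg$aa)
    if (n == 0) next
    P <- pmatrix(teff, model)
    aa <- seg$aa
    for (val in unique(aa)) {
      idx <- which(aa == val)
      seg$aa[idx] <- sample.int(20L, length(idx), replace = TRUE,
                                prob = P[val, ])
    }
    nIndel <- rpois(1, 0.02 * teff * n)
    protect <- if (s == 1) 10L else 0L
    for (k in seq_len(nIndel)) {
      n <- length(seg$aa)
      if (n <= protect + 1) break
      len <- rgeom(1, 0.7) + 1L
      if (runif(1) < 0.5) {                       # deletion
        cand <- (protect + 1L):n
        pos <- cand[sample.int(length(cand), 1L)]
        drop <- pos:min(n, pos + len - 1L)
        seg$aa <- seg$aa[-drop]; seg$key <- seg$key[-drop]
      } else {                                    # insertion after pos
        cand <- protect:n
        pos <- cand[sample.int(length(cand), 1L)]
        kl <- if (pos >= 1) seg$key[pos] else seg$key[1] - 1
        kr <- if (pos < n) seg$key[pos + 1] else seg$key[n] + 1
        keys <- sort(runif(len, kl, kr))
        aaNew <- sample.int(20L, len, replace = TRUE,
                            prob = backgroundFrequencies())
        seg$aa <- append(seg$aa, aaNew, after = pos)
        seg$key <- append(seg$key, keys, after = pos)
      }
    }
    gene$segs[[s]] <- seg
  }
  gene
}

#' Evolve a modular protein family over a species tree
#'
#' Starting from one root gene, sequences evolve down the species tree
#' under a fixed Dayhoff-like substitution model with per-segment rate
#' multipliers \code{1 - conservation}, geometric indels, and the
#' scheduled duplication / loss / lateral-transfer / tail-replacement
#' events.  Every surviving gene-tree tip yields one protein record.
#'
#' @param species Result of [simulateSpeciesTree()].
#' @param arch Architecture from [familyArchitecture()].
#' @param schedule Event rows from [simEvent()] (rbind'ed), or NULL.
#' @param rootLabel Label of the founding paralog.
#' @param seed Integer seed.
#' @return \code{list(records, truth)}: a [ProteinSet-class] with ids
#'   \code{genome|label}, and a truth list with \code{sequences}
#'   (per-record paralog label, tail origin and true tail start),
#'   \code{events}, \code{keys} (per-record homology keys for
#'   [truthAlignment()]), \code{geneCounts} and \code{geneTrees}.
#' @export
evolveFamily <- function(species, arch = familyArchitecture(),
                         schedule = NULL, rootLabel = "ftsZ", seed = 1) {
  schedule <- validateSchedule(species, schedule)
  phy <- species$tree
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  elen <- setNames(phy$edge.length, phy$edge[, 2])
  children <- split(phy$edge[, 2], phy$edge[, 1])
  parent <- setNames(phy$edge[, 1], phy$edge[, 2])
  depth <- ape::node.depth.edgelength(phy)
  rates <- 1 - arch$conservation
  model <- dayhoffModel()
  freshCounter <- 0L

  withSeed(seed, {
    states <- new.env(parent = emptyenv())
    assign(as.character(root),
           list(newRootGene(arch, rootLabel, model$bf)), envir = states)

    applyEvent <- function(genes, ev, node) {
      tgt <- which(vapply(genes, `[[`, character(1), "label") == ev$target)
      if (ev$kind == "duplication") {
        if (!length(tgt))
          stop("schedule-error (", ev$event_id, "): target '",
               ev$target, "' absent on branch ", node)
        copy <- genes[[tgt[1]]]
        copy$label <- ev$new_label %||% paste0(ev$target, "b")
        if (is.na(copy$label)) copy$label <- paste0(ev$target, "b")
        genes <- c(genes, list(copy))
      } else if (ev$kind == "loss") {
        if (length(tgt)) genes <- genes[-tgt[1]]
      } else if (ev$kind == "cterm_swap") {
        if (!length(tgt))
          stop("schedule-error (", ev$event_id, "): target '",
               ev$target, "' absent on branch ", node)
        g <- genes[[tgt[1]]]
        if (identical(ev$source, "fresh") || is.na(ev$source)) {
          freshCounter <<- freshCounter + 1L
          offs <- 1e6 * freshCounter
          for (s in seq_along(g$segs)[-1]) {
            len <- arch$length[s]
            g$segs[[s]] <- list(key = offs + as.numeric(seq_len(len)) +
                                  (s - 1) * 1e4,
                                aa = sample.int(20L, len, replace = TRUE,
                                                prob = model$bf))
          }
          g$cterm_origin <- paste0("fresh:", ev$event_id)
        } else {
          src <- which(vapply(genes, `[[`, character(1), "label") ==
                         ev$source)
          if (!length(src))
            stop("schedule-error (", ev$event_id, "): swap source '",
                 ev$source, "' absent on branch ", node)
          g$segs[-1] <- genes[[src[1]]]$segs[-1]
          g$cterm_origin <- ev$source
        }
        genes[[tgt[1]]] <- g
      } else if (ev$kind == "lgt") {
        dPar <- parent[[as.character(ev$donor)]]
        tAbs <- depth[parent[[as.character(ev$branch)]]] + ev$time
        donorGenes <- getState(dPar)
        dtgt <- which(vapply(donorGenes, `[[`, character(1), "label") ==
                        ev$target)
        if (!length(dtgt))
          stop("schedule-error (", ev$event_id, "): target '",
               ev$target, "' absent in donor lineage")
        gd <- evolveGene(donorGenes[[dtgt[1]]], tAbs - depth[dPar],
                         rates, model)
        gd$label <- ev$new_label
        if (is.na(gd$label)) gd$label <- paste0(ev$target, "_lgt")
        genes <- c(genes, list(gd))
      }
      genes
    }

    getState <- function(node) {
      key <- as.character(node)
      if (!is.null(st <- mget(key, envir = states,
                              ifnotfound = list(NULL))[[1]]))
        return(st)
      genes <- getState(parent[[key]])
      evs <- if (!is.null(schedule))
        schedule[schedule$branch == node, , drop = FALSE]
      else schedule
      evs <- if (is.null(evs) || !nrow(evs)) NULL
        else evs[order(evs$time), , drop = FALSE]
      t0 <- 0
      if (!is.null(evs)) for (i in seq_len(nrow(evs))) {
        dt <- evs$time[i] - t0
        genes <- lapply(genes, evolveGene, t = dt, rates = rates,
                        model = model)
        genes <- applyEvent(genes, evs[i, ], node)
        t0 <- evs$time[i]
      }
      genes <- lapply(genes, evolveGene,
                      t = elen[[key]] - t0, rates = rates, model = model)
      assign(key, genes, envir = states)
      genes
    }

    # leaves in label order for a reproducible RNG consumption order
    for (l in seq_len(ntip)) getState(l)

    ids <- character(0); seqs <- character(0)
    meta <- list(); keys <- list()
    truthSeq <- list()
    for (l in seq_len(ntip)) {
      genome <- phy$tip.label[l]
      for (g in get(as.character(l), envir = states)) {
        id <- paste0(genome, "|", g$label)
        ids <- c(ids, id)
        seqs <- c(seqs, paste(vapply(g$segs, function(s)
          aaDecode(s$aa), character(1)), collapse = ""))
        tx <- species$taxonomy[species$taxonomy$genome == genome, ]
        meta[[id]] <- data.frame(genome = genome, domain = tx$domain,
                                 phylum = tx$phylum, class = tx$class,
                                 order = tx$order,
                                 stringsAsFactors = FALSE)
        keys[[id]] <- lapply(g$segs, `[[`, "key")
        truthSeq[[id]] <- data.frame(
          seq_id = id, genome = genome, label = g$label,
          cterm_origin = g$cterm_origin,
          nterm_length = length(g$segs[[1]]$aa),
          stringsAsFactors = FALSE)
      }
    }
    records <- ProteinSet(setNames(seqs, ids), do.call(rbind, meta))
    seqTab <- do.call(rbind, truthSeq)
    rownames(seqTab) <- NULL
    labels <- unique(seqTab$label)
    geneTrees <- lapply(setNames(labels, labels), function(lb) {
      gn <- seqTab$genome[seqTab$label == lb]
      if (length(gn) < 2) return(NULL)
      gt <- ape::keep.tip(phy, gn)
      gt$tip.label <- paste0(gt$tip.label, "|", lb)
      gt
    })
    counts <- as.data.frame(table(genome = seqTab$genome),
                            stringsAsFactors = FALSE)
    names(counts) <- c("genome", "n_genes")
    list(records = records,
         truth = list(sequences = seqTab,
                      events = schedule,
                      keys = keys,
                      geneCounts = counts,
                      geneTrees = geneTrees))
  })
}

#' True alignment implied by the simulator's homology keys
#'
#' Residues that descend from the same ancestral column share a key;
#' sorting the union of keys yields the ground-truth alignment
#' (independent insertions occupy their own columns).
#'
#' @param truth Truth list from [evolveFamily()].
#' @param records The matching [ProteinSet-class] (for the residue
#'   letters).
#' @param ids Record ids to include (default all).
#' @return A [ProteinMSA-class].
#' @export
truthAlignment <- function(truth, records, ids = names(truth$keys)) {
  keyed <- lapply(truth$keys[ids], function(ks)
    unlist(lapply(seq_along(ks), function(s) ks[[s]] + s * 1e7)))
  allKeys <- sort(unique(unlist(keyed)))
  seqs <- setNames(as.character(sequences(records)), names(records))
  out <- matrix("-", length(ids), length(allKeys),
                dimnames = list(ids, NULL))
  for (id in ids) {
    pos <- match(keyed[[id]], allKeys)
    out[id, pos] <- strsplit(seqs[[id]], "")[[1]]
  }
  ProteinMSA(setNames(apply(out, 1, paste, collapse = ""), ids))
}
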