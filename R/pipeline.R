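#' @include emit.R context.R cterm.R curate.R align.R
NULL

.configDefaults <- function() list(
  # collection / search
  search_evalue = 1e-3,
  coverage = 0.6,
  # trimming
  trim_gt = 0.7,
  trim_gt_inclusive = 0.2,
  cterm_gt = 0.1,
  entropy_h = 0.55,
  entropy_matrix = "BLOSUM45",
  # tree
  bootstrap_reps = 100,
  collapse_support = 85,
  # context
  flank_bp = 5000,
  top_k = 25,
  # cterm
  min_tail = 20,
  # model building
  occupancy = 0.5,
  pseudocount = 1,
  calibration_n = 1000,
  seed_members = 8,
  # simulation
  n_taxa = 32,
  scenario = "duplication",
  # stage toggles
  stages = list(simulate = TRUE, collect = TRUE, curate = TRUE,
                tree = TRUE, context = TRUE, cterm = TRUE),
  # optional input paths (used when simulate is off)
  proteome_fasta = NULL,
  gene_table = NULL,
  taxonomy = NULL,
  groups_file = NULL,
  include_ids = NULL,
  anchor_hmm = NULL)

.configRanges <- list(
  search_evalue = c(0, Inf), coverage = c(1e-9, 1),
  trim_gt = c(0, 1), trim_gt_inclusive = c(0, 1), cterm_gt = c(0, 1),
  entropy_h = c(1e-9, 1), bootstrap_reps = c(1, Inf),
  collapse_support = c(0, 100), flank_bp = c(1, Inf),
  top_k = c(1, Inf), min_tail = c(1, Inf), occupancy = c(1e-9, 1),
  pseudocount = c(0, Inf), calibration_n = c(100, Inf),
  seed_members = c(3, Inf), n_taxa = c(2, Inf))

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults — every classic
#' workflow threshold (search E-value 1e-3, coverage 0.6, gap trims
#' 0.7/0.2/0.1, entropy 0.55, collapse 85, flank 5000, top 25) is a
#' default — range-checks every numeric key, and rejects unknown keys
#' and missing referenced paths.
#'
#' @param config YAML path or named list.
#' @return Completed configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("validation error: config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  def <- .configDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("validation error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (k == "stages") {
      bad <- setdiff(names(config$stages), names(def$stages))
      if (length(bad))
        stop("validation error: unknown stage(s): ",
             paste(bad, collapse = ", "))
      def$stages[names(config$stages)] <- config$stages
    } else def[[k]] <- config[[k]]
  }
  for (k in names(.configRanges)) {
    v <- def[[k]]
    r <- .configRanges[[k]]
    if (!is.numeric(v) || length(v) != 1 || v < r[1] || v > r[2])
      stop("validation error: ", k, " out of range [", r[1], ", ",
           r[2], "]")
  }
  if (!def$scenario %in% c("plain", "duplication", "cterm"))
    stop("validation error: scenario must be plain/duplication/cterm")
  if (!isTRUE(def$stages$simulate))
    for (k in c("proteome_fasta", "gene_table", "taxonomy"))
      if (is.null(def[[k]]) || !file.exists(def[[k]]))
        stop("validation error: ", k,
             " must point to an existing file when simulate is off")
  def
}

#' Read a group-definition file
#' @param path TSV with columns \code{group, member}.
#' @return Named character vector member id -> group.
#' @export
readGroupFile <- function(path) {
  tab <- readTsv(path)
  setNames(tab$group, tab$member)
}

.log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " INFO ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full provenance pipeline
#'
#' Stages in order: simulate (or load inputs), collect (anchor-model
#' hmmsearch at the E-value threshold + coverage filter), curate
#' (per-class redundancy clustering at the class-size-dependent
#' cutoff), align/trim, tree (bootstrapped NJ, midpoint root, collapse),
#' context (window extraction, domain annotation, presence table,
#' top-k), cterm (tail extraction, group models, thresholdless
#' cross-search, provenance report).  Every stage writes its artifacts
#' under \code{outDir} plus a checksum manifest; identical config and
#' seed reproduce identical artifacts byte for byte.
#'
#' @param config A config list/path, see [validateConfig()].
#' @param outDir Output directory.
#' @param seed Root seed; per-stage sub-seeds are derived by a fixed
#'   labelled-counter scheme so toggling a stage never shifts another
#'   stage's random stream.
#' @return Invisibly, a list with the principal in-memory results
#'   (\code{corpus, collected, msa, tree, contextTable, report, ...}).
#' @export
runPipeline <- function(config = list(), outDir, seed = 1) {
  cfg <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "run.log"), open = "wt")
  on.exit(close(logCon))
  res <- list(config = cfg, seed = seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("stage failure in '", name, "': ", conditionMessage(e),
           call. = FALSE))
    .log(logCon, sprintf("stage %-8s done in %.1fs", name,
                         as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  # -- simulate ---------------------------------------------------------
  if (isTRUE(cfg$stages$simulate)) {
    res$corpus <- stage("simulate", {
      corpus <- simulateCorpus(nTaxa = cfg$n_taxa,
                               scenario = cfg$scenario,
                               seed = childSeed(seed, "simulate"))
      writeSimulatedCorpus(corpus, file.path(outDir, "simulate"))
      corpus
    })
    proteome <- res$corpus$proteome
    geneTable <- res$corpus$geneTable
    taxonomy <- res$corpus$taxonomy
    library <- res$corpus$library
  } else {
    taxonomy <- readTsv(cfg$taxonomy)
    geneTable <- readTsv(cfg$gene_table)
    proteome <- readProteinSet(cfg$proteome_fasta, taxonomy, geneTable)
    library <- NULL
  }

  # -- collect ----------------------------------------------------------
  if (isTRUE(cfg$stages$collect)) {
    collected <- stage("collect", {
      anchor <- if (!is.null(res$corpus)) res$corpus$anchor
      else if (!is.null(cfg$anchor_hmm)) readHMMFile(cfg$anchor_hmm)
      else {
        # no anchor input: derive one from a spread family subsample
        famIds <- grep("\\|", names(proteome), value = TRUE)
        seedIds <- famIds[unique(round(seq(1, length(famIds),
                                           length.out = cfg$seed_members)))]
        seedMsa <- progressiveAlign(proteome[seedIds])
        a <- buildProfileHMM(trimGapThreshold(seedMsa, 0.5),
                             occupancy = cfg$occupancy,
                             pseudocount = cfg$pseudocount,
                             name = "family_anchor")
        calibrateHMM(a, nRandom = cfg$calibration_n,
                     lenMean = mean(nchar(as.character(
                       sequences(proteome[seedIds])))),
                     seed = childSeed(seed, "collect"))
      }
      writeHMMFile(anchor, file.path(outDir, "anchor.hmm"))
      hits <- searchHMM(anchor, proteome, evalueMax = cfg$search_evalue)
      writeHitTable(hits, file.path(outDir, "collect_hits.tsv"))
      list(ids = hits$target, anchor = anchor)
    })
    res$anchor <- collected$anchor
    res$collected <- proteome[collected$ids]
  } else res$collected <- proteome[grep("\\|", names(proteome))]

  # -- curate -----------------------------------------------------------
  if (isTRUE(cfg$stages$curate)) {
    res$kept <- stage("curate", {
      msa0 <- progressiveAlign(res$collected)
      keep <- coverageFilter(trimGapThreshold(msa0, cfg$trim_gt),
                             cfg$coverage)
      recs <- res$collected[keep]
      meta <- recordMeta(recs)
      reps <- unlist(lapply(split(names(recs), meta$class), function(ids) {
        cut <- identityCutoffForClass(length(ids))
        clusterByIdentity(recs[ids], cut)$representatives
      }))
      writeTsv(data.frame(kept = sort(unname(reps))),
               file.path(outDir, "curated_ids.tsv"))
      recs[sort(unname(reps))]
    })
  } else res$kept <- res$collected

  # -- align / trim / tree ---------------------------------------------
  if (isTRUE(cfg$stages$tree)) {
    res$tree <- stage("tree", {
      msa <- progressiveAlign(res$kept)
      msa <- trimGapThreshold(msa, cfg$trim_gt_inclusive)
      res$msa <- msa
      writeMsaFasta(msa, file.path(outDir, "family_trimmed.afa"))
      st <- bootstrapSupports(msa, nReps = cfg$bootstrap_reps,
                              seed = childSeed(seed, "tree"))
      writeSupportNewick(st, file.path(outDir, "family_nj.nwk"))
      rooted <- midpointRoot(st)
      writeSupportNewick(rooted, file.path(outDir,
                                           "family_nj_midpoint.nwk"))
      collapsed <- collapseLowSupport(rooted, cfg$collapse_support)
      writeSupportNewick(collapsed,
                         file.path(outDir, "family_nj_collapsed.nwk"))
      cls <- setNames(recordMeta(res$kept)$phylum, names(res$kept))
      writeItolColorStrip(st, cls,
                          file.path(outDir, "itol_phylum_strip.txt"))
      list(unrooted = st, rooted = rooted, collapsed = collapsed)
    })
  }

  # -- context ----------------------------------------------------------
  if (isTRUE(cfg$stages$context) && !is.null(library)) {
    res$contextTable <- stage("context", {
      focal <- intersect(names(res$collected), geneTable$gene_id)
      nbhs <- annotateNeighborhoods(
        lapply(focal, extractWindow, geneTable = geneTable,
               flankBp = cfg$flank_bp),
        library, proteome, cfg$search_evalue)
      tab <- domainPresenceTable(nbhs, taxonomy, rank = "phylum")
      writeAbundanceMatrix(tab, file.path(outDir, "context_matrix.tsv"))
      writeAbundanceLong(tab, file.path(outDir, "context_long.tsv"))
      writeTsv(topDomains(tab, cfg$top_k),
               file.path(outDir, "context_top.tsv"))
      tab
    })
  }

  # -- cterm ------------------------------------------------------------
  if (isTRUE(cfg$stages$cterm) && isTRUE(cfg$stages$collect)) {
    res$report <- stage("cterm", {
      groups <- if (!is.null(cfg$groups_file))
        readGroupFile(cfg$groups_file)
      else setNames(sub("^.*\\|", "", names(res$collected)),
                    names(res$collected))
      ct <- extractCTermSet(res$collected, res$anchor,
                            minTail = cfg$min_tail,
                            evalueMax = cfg$search_evalue)
      models <- list()
      for (g in sort(unique(groups[names(ct$tails)]))) {
        members <- names(ct$tails)[groups[names(ct$tails)] == g]
        if (length(members) >= 3)
          models[[g]] <- buildGroupModel(
            ct$tails[members], gt = cfg$cterm_gt,
            name = paste0(g, "_C"),
            seed = childSeed(seed, paste0("cterm:", g)),
            nRandom = cfg$calibration_n)
      }
      hm <- crossSearch(models, res$collected)
      writeHitMatrix(hm, file.path(outDir, "cterm_hits.tsv"))
      if (!is.null(res$tree)) {
        # the display tree holds the curated subset; map those leaves
        leaves <- asPhylo(res$tree$unrooted)$tip.label
        sub <- new("HitMatrix",
                   evalue = hm@evalue[, leaves, drop = FALSE],
                   bits = hm@bits[, leaves, drop = FALSE],
                   dbSize = hm@dbSize)
        mapHitsToTree(res$tree$unrooted, sub,
                      path = file.path(outDir, "itol_cterm_heatmap.txt"))
      }
      dom <- setNames(recordMeta(res$collected)$domain,
                      names(res$collected))
      rep <- provenanceReport(hm, groups, dom)
      writeTsv(rep, file.path(outDir, "provenance_report.tsv"))
      res$hitMatrix <- hm
      rep
    })
  }

  # -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        c("run.log", "manifest.tsv")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outDir, files))),
    stringsAsFactors = FALSE)
  attr(manifest, "seed") <- seed
  con <- file(file.path(outDir, "manifest.tsv"), open = "wb")
  writeLines(paste0("# seed=", seed, " package=ftszprov ",
                    as.character(utils::packageVersion("ftszprov"))),
             con, sep = "\n")
  write.table(manifest, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  close(con)
  .log(logCon, "pipeline complete: ", outDir)
  invisible(res)
}
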