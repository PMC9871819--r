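#' @include phmm.R
NULL

#' Extract the gene neighborhood around a focal gene
#'
#' The window spans \code{flankBp} base pairs up- and downstream of
#' the focal gene (0-based half-open internally, clipped at the contig
#' start); a neighbor is any gene on the same genome and contig
#' overlapping the window by at least 1 bp, the focal gene excluded.
#' Membership is strand-agnostic; strand is retained for display.
#'
#' @param geneTable Gene table (\code{genome, contig, gene_id, start,
#'   end, strand}; coordinates 1-based inclusive as in files).
#' @param focalId Focal gene id.
#' @param flankBp Flank size in bp (> 0); 5000 is the conventional
#'   setting (5 kb up/downstream, a 10 kb window plus the gene).
#' @return \code{list(focal_id, genome, contig, window_start,
#'   window_end, neighbors)}: window 0-based half-open, neighbors a
#'   gene-table subset sorted by start.
#' @export
extractWindow <- function(geneTable, focalId, flankBp = 5000) {
  if (flankBp <= 0) stop("invalid-argument: flankBp must be > 0")
  i <- match(focalId, geneTable$gene_id)
  if (is.na(i)) stop("missing-id error: ", focalId)
  focal <- geneTable[i, ]
  ws <- max(0L, focal$start - 1L - flankBp)     # 0-based half-open
  we <- focal$end + flankBp
  same <- geneTable$genome == focal$genome &
    geneTable$contig == focal$contig &
    geneTable$gene_id != focalId
  s0 <- geneTable$start - 1L                     # 0-based starts
  ov <- same & s0 < we & geneTable$end > ws
  nb <- geneTable[ov, , drop = FALSE]
  nb <- nb[order(nb$start), , drop = FALSE]
  rownames(nb) <- NULL
  list(focal_id = focalId, genome = focal$genome, contig = focal$contig,
       window_start = ws, window_end = we, neighbors = nb)
}

#' Annotate neighborhood genes with domain HMMs
#'
#' Every neighbor receives the set of domain names whose calibrated
#' model hits it at \code{evalueMax} or better (best hit per model;
#' presence is a set, never a multiset).  An empty library annotates
#' nothing without error.
#'
#' @param neighborhood Result of [extractWindow()].
#' @param library Named list of domain models — either
#'   [ProfileHMM-class] objects or [syntheticDomainLibrary()] entries.
#' @param proteome A [ProteinSet-class] resolving neighbor protein
#'   sequences by gene id.
#' @param evalueMax E-value ceiling (default 1e-3).
#' @return The neighborhood with an added \code{hits} element: named
#'   list gene id -> character vector of domain names.
#' @export
annotateNeighbors <- function(neighborhood, library, proteome,
                              evalueMax = 1e-3) {
  nb <- neighborhood$neighbors
  hits <- setNames(vector("list", nrow(nb)), nb$gene_id)
  if (nrow(nb)) {
    miss <- setdiff(nb$gene_id, names(proteome))
    if (length(miss))
      stop("data-integrity error: no protein sequence for ",
           paste(miss, collapse = ", "))
    seqs <- setNames(as.character(sequences(proteome[nb$gene_id])),
                     nb$gene_id)
    for (id in nb$gene_id) hits[[id]] <- character(0)
    for (nm in names(library)) {
      hmm <- library[[nm]]
      if (!is(hmm, "ProfileHMM")) hmm <- hmm$hmm
      tab <- searchHMM(hmm, seqs, evalueMax = evalueMax)
      for (id in tab$target)
        hits[[id]] <- sort(unique(c(hits[[id]], hmm@name)))
    }
  }
  neighborhood$hits <- hits
  neighborhood
}

#' Annotate many neighborhoods in one search invocation
#'
#' Searches every library model once against the union of all
#' neighbor proteins (so the E-value database size is the full
#' neighbor set, as when scanning all predicted proteins of a corpus
#' in one run), then distributes the per-gene domain sets back to the
#' neighborhoods.  Equivalent to [annotateNeighbors()] apart from the
#' database-size convention.
#'
#' @param neighborhoods List of [extractWindow()] results.
#' @inheritParams annotateNeighbors
#' @return The neighborhoods, each with its \code{hits} element.
#' @export
annotateNeighborhoods <- function(neighborhoods, library, proteome,
                                  evalueMax = 1e-3) {
  ids <- unique(unlist(lapply(neighborhoods, function(nh)
    nh$neighbors$gene_id)))
  hits <- setNames(lapply(ids, function(i) character(0)), ids)
  if (length(ids) && length(library)) {
    miss <- setdiff(ids, names(proteome))
    if (length(miss))
      stop("data-integrity error: no protein sequence for ",
           paste(miss, collapse = ", "))
    seqs <- setNames(as.character(sequences(proteome[ids])), ids)
    for (nm in names(library)) {
      hmm <- library[[nm]]
      if (!is(hmm, "ProfileHMM")) hmm <- hmm$hmm
      tab <- searchHMM(hmm, seqs, evalueMax = evalueMax)
      for (id in tab$target)
        hits[[id]] <- sort(unique(c(hits[[id]], hmm@name)))
    }
  }
  lapply(neighborhoods, function(nh) {
    nh$hits <- hits[nh$neighbors$gene_id]
    nh
  })
}

#' Presence-only domain abundance per clade
#'
#' Cell (domain, clade) counts the distinct genomes of that clade with
#' at least one annotated neighbor carrying the domain; repeats within
#' a protein, a neighborhood, or among paralogous neighborhoods of the
#' same genome count once.
#'
#' @param neighborhoods List of annotated neighborhoods
#'   ([annotateNeighbors()]).
#' @param taxonomy Taxonomy table covering every neighborhood genome.
#' @param rank Taxonomic rank for the columns (default
#'   \code{"phylum"}).
#' @return Integer matrix, rows = domains (sorted), columns = clades;
#'   idempotent under re-adding a neighborhood.
#' @export
domainPresenceTable <- function(neighborhoods, taxonomy,
                                rank = "phylum") {
  stopifnot(rank %in% c("domain", "phylum", "class", "order"))
  pairs <- unique(do.call(rbind, lapply(neighborhoods, function(nh) {
    doms <- unique(unlist(nh$hits))
    if (is.null(doms) || !length(doms)) return(NULL)
    data.frame(genome = nh$genome, dom = doms, stringsAsFactors = FALSE)
  })))
  if (is.null(pairs) || !nrow(pairs))
    return(matrix(0L, 0, 0))
  i <- match(pairs$genome, taxonomy$genome)
  if (anyNA(i))
    stop("missing-taxonomy error: ",
         paste(unique(pairs$genome[is.na(i)]), collapse = ", "))
  pairs$clade <- taxonomy[[rank]][i]
  tab <- table(pairs$dom, pairs$clade)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m[sort(rownames(m)), sort(colnames(m)), drop = FALSE]
}

#' Top-k domains by total genome count
#'
#' @param table Matrix from [domainPresenceTable()].
#' @param k Number of domains (>= 1); the classic figure setting is
#'   25.  More than available returns the full ranking.
#' @return \code{data.frame(domain, total)} ranked by total count,
#'   ties broken alphabetically.
#' @export
topDomains <- function(table, k = 25) {
  if (k < 1) stop("invalid-argument: k must be >= 1")
  if (!nrow(table)) return(data.frame(domain = character(0),
                                      total = integer(0)))
  tot <- rowSums(table)
  ord <- order(-tot, rownames(table))
  out <- data.frame(domain = rownames(table)[ord],
                    total = as.integer(tot[ord]),
                    stringsAsFactors = FALSE)
  head(out, k)
}

#' Write abundance tables
#'
#' \code{writeAbundanceMatrix} writes the domains-by-clades matrix;
#' \code{writeAbundanceLong} a stacked-bar-ready long form
#' (\code{domain, clade, genomes}).
#'
#' @param table Matrix from [domainPresenceTable()].
#' @param path Output TSV.
#' @export
writeAbundanceMatrix <- function(table, path) {
  df <- data.frame(domain = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  writeTsv(df, path)
}

#' @rdname writeAbundanceMatrix
#' @export
writeAbundanceLong <- function(table, path) {
  long <- expand.grid(domain = rownames(table), clade = colnames(table),
                      stringsAsFactors = FALSE)
  long$genomes <- as.integer(table[cbind(long$domain, long$clade)])
  writeTsv(long[long$genomes > 0, , drop = FALSE], path)
}
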