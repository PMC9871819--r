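#' @include AllGenerics.R
NULL

#' Construct a ProteinSet
#'
#' @param seqs Named character vector or \code{AAStringSet} of
#'   amino-acid sequences (20-letter alphabet plus X).
#' @param meta \code{data.frame}/\code{DataFrame} with one row per
#'   sequence; missing columns among \code{genome, domain, phylum,
#'   class, order, contig, start, end, strand} are filled with NA.
#' @return A [ProteinSet-class] object.
#' @examples
#' ps <- ProteinSet(c(g1_f = "MKV", g2_f = "MRV"),
#'                  data.frame(genome = c("g1", "g2")))
#' length(ps)
#' @export
ProteinSet <- function(seqs, meta = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  n <- length(seqs)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in c("genome", "domain", "phylum", "class", "order",
                "contig", "strand"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  for (col in c("start", "end"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_integer_
  new("ProteinSet", seqs = seqs, meta = S4Vectors::DataFrame(meta))
}

#' @rdname ProteinSet-class
#' @export
setMethod("sequences", "ProteinSet", function(x) x@seqs)

#' @rdname ProteinSet-class
#' @export
setMethod("recordMeta", "ProteinSet",
          function(x) as.data.frame(x@meta, stringsAsFactors = FALSE))

#' @rdname ProteinSet-class
#' @export
setMethod("length", "ProteinSet", function(x) length(x@seqs))

#' @rdname ProteinSet-class
#' @export
setMethod("names", "ProteinSet", function(x) names(x@seqs))

#' @rdname ProteinSet-class
#' @param i index (ids, logical or integer).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    miss <- setdiff(i, names(x@seqs))
    if (length(miss))
      stop("missing-id error: ", paste(miss, collapse = ", "))
    i <- match(i, names(x@seqs))
  }
  new("ProteinSet", seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

#' @rdname ProteinSet-class
#' @export
setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet with", length(object), "records from",
      length(unique(object@meta$genome)), "genomes\n")
  if (length(object)) {
    w <- Biostrings::width(object@seqs)
    cat("  lengths:", min(w), "-", max(w), "aa;",
        "taxonomic domains:",
        paste(unique(stats::na.omit(object@meta$domain)), collapse = ", "),
        "\n")
  }
})

#' Combine two ProteinSets
#' @param x,y ProteinSets with disjoint ids.
#' @return A ProteinSet.
#' @export
concatProteinSets <- function(x, y) {
  if (length(intersect(names(x), names(y))))
    stop("invalid-argument: overlapping ids")
  ProteinSet(setNames(c(as.character(x@seqs), as.character(y@seqs)),
                      c(names(x), names(y))),
             rbind(recordMeta(x), recordMeta(y)))
}

#' Read / write protein FASTA
#'
#' FASTA is written wrapped at 60 columns. \code{readProteinSet}
#' optionally joins a taxonomy table and a gene-coordinate table by
#' genome / gene id.
#'
#' @param path FASTA file.
#' @param taxonomy Optional taxonomy data.frame
#'   (\code{genome, domain, phylum, class, order}).
#' @param geneTable Optional gene table
#'   (\code{genome, contig, gene_id, start, end, strand}).
#' @return \code{readProteinSet}: a [ProteinSet-class].
#' @export
readProteinSet <- function(path, taxonomy = NULL, geneTable = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  meta <- data.frame(row.names = seq_along(ss))
  if (!is.null(geneTable)) {
    i <- match(names(ss), geneTable$gene_id)
    meta$genome <- geneTable$genome[i]
    meta$contig <- geneTable$contig[i]
    meta$start <- geneTable$start[i]
    meta$end <- geneTable$end[i]
    meta$strand <- geneTable$strand[i]
  }
  if (!is.null(taxonomy) && !is.null(meta$genome)) {
    i <- match(meta$genome, taxonomy$genome)
    for (col in c("domain", "phylum", "class", "order"))
      meta[[col]] <- taxonomy[[col]][i]
  }
  ProteinSet(ss, meta)
}

#' @rdname readProteinSet
#' @param x ProteinSet to write.
#' @export
writeProteinFasta <- function(x, path) {
  Biostrings::writeXStringSet(sequences(x), path, width = 60)
  invisible(path)
}
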