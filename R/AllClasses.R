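#' @include utils.R
NULL

setOldClass("phylo")

#' ProteinSet: a collection of protein records with genome linkage
#'
#' The atom of every pipeline stage: amino-acid sequences plus, per
#' record, the source genome, its four-rank taxonomy
#' (domain/phylum/class/order) and the gene locus (contig, 1-based
#' inclusive start/end, strand).
#'
#' @slot seqs An [Biostrings::AAStringSet] of the sequences.
#' @slot meta A [S4Vectors::DataFrame] with one row per sequence and
#'   columns \code{genome, domain, phylum, class, order, contig, start,
#'   end, strand} (locus columns may be \code{NA}).
#' @export
setClass("ProteinSet", representation(seqs = "AAStringSet",
                                      meta = "DataFrame"))

setValidity("ProteinSet", function(object) {
  if (length(object@seqs) != nrow(object@meta))
    return("seqs and meta differ in length")
  need <- c("genome", "domain", "phylum", "class", "order",
            "contig", "start", "end", "strand")
  miss <- setdiff(need, colnames(object@meta))
  if (length(miss))
    return(paste("missing meta columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(names(object@seqs)))
    return("duplicated sequence ids")
  if (any(Biostrings::width(object@seqs) == 0))
    return("empty sequence")
  TRUE
})

#' ProteinMSA: a multiple alignment with column provenance
#'
#' Rows are gapped sequences (gap character \code{-}); the provenance
#' slot maps each current column to its column index in the alignment
#' the object was trimmed from, so trimming operations compose and stay
#' invertible onto kept columns.
#'
#' @slot rows Named character vector of equal-width gapped strings.
#' @slot provenance Strictly increasing integer vector, one entry per
#'   column.
#' @export
setClass("ProteinMSA", representation(rows = "character",
                                      provenance = "integer"))

setValidity("ProteinMSA", function(object) {
  if (!length(object@rows)) return("alignment has no rows")
  w <- unique(nchar(object@rows))
  if (length(w) != 1) return("rows differ in width")
  if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
    return("rows must have unique names")
  if (length(object@provenance) != w)
    return("provenance length != alignment width")
  if (w > 1 && any(diff(object@provenance) <= 0))
    return("provenance must be strictly increasing")
  TRUE
})

#' ProfileHMM: a match/insert/delete profile model
#'
#' Match-state emissions, background (insert) emissions, per-position
#' transition probabilities, and - after [calibrateHMM()] - Gumbel
#' location/scale used to convert forward bit scores into E-values.
#'
#' @slot name Model name.
#' @slot match M x 20 matrix of match emission probabilities
#'   (rows sum to 1).
#' @slot bg Background frequencies (length 20).
#' @slot trans M x 7 matrix, columns \code{MM,MI,MD,IM,II,DM,DD}:
#'   transition probabilities out of position k into position k+1.
#' @slot mu,lambda Gumbel location and scale (NA until calibrated).
#' @slot consensus The model consensus sequence (argmax emission per
#'   match state).
#' @export
setClass("ProfileHMM", representation(name = "character",
                                      match = "matrix",
                                      bg = "numeric",
                                      trans = "matrix",
                                      mu = "numeric",
                                      lambda = "numeric",
                                      consensus = "character"))

setValidity("ProfileHMM", function(object) {
  M <- nrow(object@match)
  if (M < 1) return("model-degenerate: no match states")
  if (ncol(object@match) != 20) return("match must have 20 columns")
  if (any(abs(rowSums(object@match) - 1) > 1e-9))
    return("match emissions must sum to 1")
  if (abs(sum(object@bg) - 1) > 1e-9) return("background must sum to 1")
  tr <- object@trans
  if (nrow(tr) != M || ncol(tr) != 7) return("trans must be M x 7")
  outM <- rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE])
  if (any(abs(outM[-M] - 1) > 1e-9))
    return("match outgoing transitions must sum to 1")
  if (!is.na(object@lambda) && object@lambda <= 0)
    return("calibrated lambda must be > 0")
  TRUE
})

#' SupportTree: a phylogeny carrying bootstrap supports
#'
#' Wraps an [ape::phylo] tree; supports live on internal edges,
#' expressed as percentages in \[0, 100\] and stored against the child
#' node of each internal edge (root has none).
#'
#' @slot tree A \code{phylo} object.
#' @slot support Numeric vector indexed by internal node number minus
#'   the tip count (NA where no support applies, e.g. the root).
#' @slot rooted Logical.
#' @export
setClass("SupportTree", representation(tree = "phylo",
                                       support = "numeric",
                                       rooted = "logical"))

setValidity("SupportTree", function(object) {
  phy <- object@tree
  if (anyDuplicated(phy$tip.label)) return("duplicate leaf ids")
  if (length(object@support) != phy$Nnode)
    return("support length must equal the number of internal nodes")
  s <- object@support[!is.na(object@support)]
  if (length(s) && (any(s < 0) || any(s > 100)))
    return("supports must lie in [0, 100]")
  TRUE
})

#' HitMatrix: model-by-sequence best E-values from a cross-search
#'
#' @slot evalue Numeric matrix, rows = query models, cols = target ids;
#'   NA marks pairs for which no alignment was produced.
#' @slot bits Matching matrix of forward bit scores.
#' @slot dbSize Per-query database size used for the E-values.
#' @export
setClass("HitMatrix", representation(evalue = "matrix",
                                     bits = "matrix",
                                     dbSize = "numeric"))

setValidity("HitMatrix", function(object) {
  if (!identical(dim(object@evalue), dim(object@bits)))
    return("evalue and bits must share dimensions")
  ev <- object@evalue[!is.na(object@evalue)]
  if (length(ev) && any(ev < 0)) return("E-values must be >= 0")
  if (length(object@dbSize) != nrow(object@evalue))
    return("one dbSize per query model required")
  TRUE
})
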