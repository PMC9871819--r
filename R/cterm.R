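#' @include phmm.R phylo.R
NULL

#' Extract the C-terminal tail anchored at the shared N-domain
#'
#' Locates the shared N-terminal domain with the Viterbi envelope of
#' the anchor model and returns everything downstream of the envelope
#' end.  Records without an anchor hit at \code{evalueMax} raise an
#' anchor-not-found condition; tails shorter than \code{minTail}
#' residues return \code{NULL} (too short to model).
#'
#' @param seq Amino-acid string.
#' @param ntermModel Calibrated anchor [ProfileHMM-class].
#' @param minTail Minimum usable tail length (default 20 residues).
#' @param evalueMax Anchor significance ceiling (default 1e-3,
#'   single-sequence database size).
#' @return Tail string, or NULL when the remaining tail is shorter
#'   than \code{minTail}.
#' @export
extractCTerm <- function(seq, ntermModel, minTail = 20,
                         evalueMax = 1e-3) {
  hit <- viterbiHit(ntermModel, seq)
  bits <- forwardBits(ntermModel, seq)
  if (hmmEvalue(ntermModel, bits, 1) > evalueMax)
    stop("anchor-not-found: no N-domain hit at E <= ", evalueMax)
  tail <- substring(seq, hit$env_end + 1L)      # env_end is 0-based excl
  if (nchar(tail) < minTail) return(NULL)
  tail
}

#' Extract tails for a whole collection
#'
#' @param records A [ProteinSet-class] or named character vector.
#' @inheritParams extractCTerm
#' @return \code{list(tails, skipped)}: named character vector of
#'   tails, and a data.frame of skipped ids with reasons
#'   (\code{anchor-not-found} / \code{tail-too-short}).
#' @export
extractCTermSet <- function(records, ntermModel, minTail = 20,
                            evalueMax = 1e-3) {
  seqs <- if (is(records, "ProteinSet"))
    setNames(as.character(sequences(records)), names(records)) else records
  tails <- character(0)
  skipped <- list()
  for (id in names(seqs)) {
    t <- tryCatch(extractCTerm(seqs[[id]], ntermModel, minTail,
                               evalueMax),
                  error = function(e) e)
    if (inherits(t, "error"))
      skipped[[id]] <- data.frame(seq_id = id,
                                  reason = "anchor-not-found")
    else if (is.null(t))
      skipped[[id]] <- data.frame(seq_id = id,
                                  reason = "tail-too-short")
    else tails[[id]] <- t
  }
  list(tails = tails,
       skipped = if (length(skipped)) do.call(rbind, skipped)
       else data.frame(seq_id = character(0), reason = character(0)))
}

#' Build a C-terminus group model
#'
#' Aligns the group's tails, applies soft gap trimming
#' (\code{gt = 0.1}), builds a profile HMM and calibrates it — the
#' standard recipe for a lineage-diagnostic tail model.
#'
#' @param tails Named character vector of >= 3 tail sequences.
#' @param gt Soft gap-trim threshold (default 0.1).
#' @param name Model name (typically the phylogenetic group).
#' @param seed Calibration seed.
#' @param nRandom Calibration null count.
#' @return A calibrated [ProfileHMM-class].
#' @export
buildGroupModel <- function(tails, gt = 0.1, name = "group", seed = 1,
                            nRandom = 1000) {
  if (length(tails) < 3)
    stop("group-too-small error: need >= 3 members, got ", length(tails))
  msa <- progressiveAlign(tails)
  msa <- trimGapThreshold(msa, gt)
  hmm <- buildProfileHMM(msa, occupancy = 0.5, pseudocount = 1,
                         name = name)
  calibrateHMM(hmm, nRandom = nRandom,
               lenMean = mean(nchar(tails)), seed = seed)
}

#' Thresholdless cross-search of tail models against a collection
#'
#' Every model is searched against every collection member's full
#' sequence; the best E-value per (model, target) is recorded with no
#' E-value threshold applied.  The database size per query is the
#' collection size.
#'
#' @param models List of calibrated [ProfileHMM-class] objects.
#' @param collection A [ProteinSet-class] or named character vector.
#' @return A [HitMatrix-class] (models x targets).
#' @export
crossSearch <- function(models, collection) {
  seqs <- if (is(collection, "ProteinSet"))
    setNames(as.character(sequences(collection)), names(collection))
  else collection
  nm <- unname(vapply(models, function(m) m@name, character(1)))
  ev <- matrix(NA_real_, length(models), length(seqs),
               dimnames = list(nm, names(seqs)))
  bits <- ev
  for (i in seq_along(models)) {
    if (is.na(models[[i]]@lambda))
      stop("state-error: model ", nm[i], " is not calibrated")
    tab <- searchHMM(models[[i]], seqs, evalueMax = NULL)
    ev[i, tab$target] <- tab$evalue
    bits[i, tab$target] <- tab$bits
  }
  new("HitMatrix", evalue = ev, bits = bits,
      dbSize = rep(length(seqs), length(models)))
}

#' @rdname HitMatrix-class
#' @export
setMethod("evalues", "HitMatrix", function(x) x@evalue)

#' @rdname HitMatrix-class
#' @export
setMethod("bitScores", "HitMatrix", function(x) x@bits)

#' @rdname HitMatrix-class
#' @export
setMethod("show", "HitMatrix", function(object) {
  cat("HitMatrix:", nrow(object@evalue), "models x",
      ncol(object@evalue), "targets\n")
})

#' Exact text round-trip for hit matrices
#' @param x A [HitMatrix-class].
#' @param path TSV path (long form: model, target, bits, evalue,
#'   db_size; full double precision).
#' @export
writeHitMatrix <- function(x, path) {
  long <- expand.grid(model = rownames(x@evalue),
                      target = colnames(x@evalue),
                      stringsAsFactors = FALSE)
  idx <- cbind(long$model, long$target)
  long$bits <- sprintf("%.17g", x@bits[idx])
  long$evalue <- sprintf("%.17g", x@evalue[idx])
  long$db_size <- x@dbSize[match(long$model, rownames(x@evalue))]
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' @rdname writeHitMatrix
#' @export
readHitMatrix <- function(path) {
  long <- readTsv(path)
  models <- unique(long$model); targets <- unique(long$target)
  ev <- matrix(NA_real_, length(models), length(targets),
               dimnames = list(models, targets))
  bits <- ev
  idx <- cbind(long$model, long$target)
  ev[idx] <- as.numeric(long$evalue)
  bits[idx] <- as.numeric(long$bits)
  db <- long$db_size[match(models, long$model)]
  new("HitMatrix", evalue = ev, bits = bits, dbSize = as.numeric(db))
}

#' Map cross-search hits onto tree leaves as heatmap bins
#'
#' Per leaf and query model, the E-value is binned on decade edges
#' bracketing the conventional strata (strong ~1e-10, weak ~1e-3,
#' marginal ~1e-2); bin 0 is the strongest, the last bin is blank (no
#' meaningful hit).  Emits an iTOL heatmap dataset.
#'
#' @param st A [SupportTree-class] whose leaves cover the matrix
#'   targets.
#' @param x A [HitMatrix-class].
#' @param bins Increasing E-value bin edges (default
#'   \code{c(1e-10, 1e-5, 1e-3, 1e-1)}; +Inf is implicit).
#' @param path Optional iTOL dataset file to write.
#' @return Integer bin matrix (models x leaves), invisibly when
#'   \code{path} is given.
#' @export
mapHitsToTree <- function(st, x, bins = c(1e-10, 1e-5, 1e-3, 1e-1),
                          path = NULL) {
  phy <- if (inherits(st, "phylo")) st else st@tree
  miss <- setdiff(colnames(x@evalue), phy$tip.label)
  if (length(miss))
    stop("missing-id error: targets absent from tree: ",
         paste(miss, collapse = ", "))
  blank <- length(bins)
  bin <- matrix(blank, nrow(x@evalue), length(phy$tip.label),
                dimnames = list(rownames(x@evalue), phy$tip.label))
  for (id in colnames(x@evalue)) {
    e <- x@evalue[, id]
    b <- ifelse(is.na(e), blank, rowSums(outer(e, bins, ">")))
    bin[, id] <- b
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con, sep = "\n")
    w("DATASET_HEATMAP")
    w("SEPARATOR TAB")
    w("DATASET_LABEL\tC-terminus cross-search")
    w("COLOR\t#1b9e77")
    w("FIELD_LABELS\t", paste(rownames(bin), collapse = "\t"))
    w("DATA")
    for (id in colnames(bin))
      w(id, "\t", paste(bin[, id], collapse = "\t"))
    return(invisible(bin))
  }
  bin
}

#' Provenance summary over family-by-domain strata
#'
#' For each query model and each (family label, taxonomic domain)
#' stratum of the collection, reports the median and minimum E-value
#' and the fraction of members hit at E <= 1e-3.  The verdict column
#' flags strata whose median E-value is at or below \code{flagAt}
#' (default 1e-2, the weakest conventionally reported signal
#' stratum): those are candidate source lineages of the query group's
#' tail.
#'
#' @param x A [HitMatrix-class].
#' @param groups Named character vector: target id -> family label.
#' @param taxDomain Named character vector: target id -> taxonomic
#'   domain.
#' @param flagAt Median E-value threshold for the verdict flag.
#' @return \code{data.frame(model, family, tax_domain, n,
#'   median_evalue, min_evalue, hit_frac, flagged)}.
#' @export
provenanceReport <- function(x, groups, taxDomain, flagAt = 1e-2) {
  ids <- colnames(x@evalue)
  fam <- groups[ids]; dom <- taxDomain[ids]
  strata <- unique(data.frame(family = fam, tax_domain = dom,
                              stringsAsFactors = FALSE))
  strata <- strata[order(strata$family, strata$tax_domain), ,
                   drop = FALSE]
  out <- list()
  for (m in rownames(x@evalue)) for (s in seq_len(nrow(strata))) {
    sel <- which(fam == strata$family[s] & dom == strata$tax_domain[s])
    e <- x@evalue[m, ids[sel]]
    e[is.na(e)] <- Inf
    med <- if (length(e)) median(e) else Inf
    out[[length(out) + 1L]] <- data.frame(
      model = m, family = strata$family[s],
      tax_domain = strata$tax_domain[s], n = length(sel),
      median_evalue = med,
      min_evalue = if (length(e)) min(e) else Inf,
      hit_frac = if (length(e)) mean(e <= 1e-3) else 0,
      flagged = is.finite(med) && med <= flagAt,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
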