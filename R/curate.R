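#' @include msa.R
NULL

#' Filter alignment rows by coverage
#'
#' Keeps rows whose non-gap character count divided by the full
#' alignment length is at least \code{minCov} (the boundary is
#' inclusive).  The denominator is the alignment length, not the
#' ungapped row length, matching the notion of alignment coverage.
#'
#' @param msa A [ProteinMSA-class].
#' @param minCov Fraction in (0, 1]; the classic homolog-collection
#'   setting is 0.6.
#' @return Character vector of kept row ids.
#' @export
coverageFilter <- function(msa, minCov = 0.6) {
  if (!is(msa, "ProteinMSA") || !length(msa@rows))
    stop("invalid-argument: empty alignment")
  if (minCov <= 0 || minCov > 1)
    stop("invalid-argument: minCov must be in (0, 1]")
  W <- msaWidth(msa)
  cov <- vapply(msa@rows, function(r)
    (W - lengths(regmatches(r, gregexpr("-", r, fixed = TRUE)))) / W,
    numeric(1))
  names(msa@rows)[cov >= minCov]
}

#' Redundancy-clustering identity cutoff for a taxonomic class
#'
#' Classes with up to 20 sequences cluster at 95\% identity; classes
#' with 250 or more at 55\%; in between the cutoff interpolates
#' linearly between those endpoints and is rounded to two decimals.
#' Monotonically non-increasing in \code{n}.
#'
#' @param n Number of sequences in the class (>= 0).
#' @return Identity fraction in (0, 1].
#' @examples
#' identityCutoffForClass(20)   # 0.95
#' identityCutoffForClass(250)  # 0.55
#' identityCutoffForClass(135)  # 0.75
#' @export
identityCutoffForClass <- function(n) {
  if (n < 0) stop("invalid-argument: n must be >= 0")
  if (n <= 20) return(0.95)
  if (n >= 250) return(0.55)
  round(0.95 + (n - 20) * (0.55 - 0.95) / (250 - 20), 2)
}

#' Pairwise global identity
#'
#' Identity of the Needleman-Wunsch global alignment of two sequences:
#' matches divided by the full alignment length (gap columns count in
#' the denominator).
#'
#' @param a,b Amino-acid strings.
#' @param matrix,gapOpen,gapExtend Passed to [pairwiseGlobal()].
#' @return Fraction in \[0, 1\].
#' @export
pairwiseIdentity <- function(a, b, matrix = "BLOSUM62",
                             gapOpen = -11, gapExtend = -1) {
  aln <- pairwiseGlobal(a, b, matrix, gapOpen, gapExtend)
  ca <- strsplit(aln$alignedA, "")[[1]]
  cb <- strsplit(aln$alignedB, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' Greedy CD-HIT-style identity clustering
#'
#' Sequences are sorted by length (descending, ties by id); each joins
#' the first existing cluster whose representative it matches at
#' \code{cutoff} identity or better, otherwise it founds a new cluster.
#' Representatives of different clusters are not guaranteed to be
#' mutually below the cutoff (greedy semantics).
#'
#' @param records A [ProteinSet-class] or named character vector
#'   (typically the members of one taxonomic class).
#' @param cutoff Identity fraction in (0, 1].
#' @return \code{list(representatives = ids, membership = data.frame
#'   (representative, member))}.
#' @export
clusterByIdentity <- function(records, cutoff) {
  if (cutoff <= 0 || cutoff > 1)
    stop("invalid-argument: cutoff must be in (0, 1]")
  seqs <- if (is(records, "ProteinSet"))
    setNames(as.character(sequences(records)), names(records)) else records
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  member <- character(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (r in reps) {
      if (pairwiseIdentity(seqs[[i]], seqs[[r]]) >= cutoff) {
        member[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, names(seqs)[i]); member[i] <- names(seqs)[i] }
  }
  list(representatives = reps,
       membership = data.frame(representative = member,
                               member = names(seqs),
                               stringsAsFactors = FALSE))
}

#' One random representative per taxonomic order
#'
#' @param records A [ProteinSet-class] with order labels.
#' @param seed Integer seed (fixed seed gives identical picks).
#' @param include Ids forced into the result regardless of the draw
#'   (the manually retained taxa); unknown ids are an error.
#' @return A [ProteinSet-class] subsample.
#' @export
onePerOrder <- function(records, seed = 1, include = character(0)) {
  meta <- recordMeta(records)
  if (any(is.na(meta$order)))
    stop("invalid-argument: records lack order labels")
  miss <- setdiff(include, names(records))
  if (length(miss))
    stop("missing-id error: ", paste(miss, collapse = ", "))
  picks <- withSeed(seed, {
    vapply(split(names(records), meta$order), function(ids)
      ids[sample.int(length(ids), 1L)], character(1))
  })
  records[sort(unique(c(unname(picks), include)))]
}

#' Gap-threshold alignment trimming (trimAl -gt style)
#'
#' Keeps columns whose non-gap fraction is at least \code{gt}
#' (inclusive boundary); provenance is composed so kept columns map
#' back to the input's original columns.  Common settings: 0.7 for
#' strict trimming, 0.2 inclusive, 0.1 soft.
#'
#' @param msa A [ProteinMSA-class].
#' @param gt Fraction in \[0, 1\]; \code{gt = 0} is the identity
#'   operation.
#' @return Trimmed [ProteinMSA-class].
#' @export
trimGapThreshold <- function(msa, gt) {
  if (gt < 0 || gt > 1) stop("invalid-argument: gt must be in [0, 1]")
  m <- msaMatrix(msa)
  frac <- colMeans(m != "-")
  keep <- which(frac >= gt)
  if (!length(keep)) stop("empty-alignment error: all columns removed")
  msaKeepColumns(msa, keep)
}

#' Entropy-based alignment trimming (BMGE style)
#'
#' Per column, the residue distribution is smoothed through a
#' similarity kernel derived from a scoring matrix
#' (\code{w(a | b) proportional to exp(S(a, b) / 2)}), so that similar
#' residues pool their mass, and the normalised Shannon entropy of the
#' smoothed distribution gives a score in \[0, 1\]: 0 for an invariant
#' column, close to 1 for a column uniform over the alphabet, and low
#' for columns varying only among similar residues.  Scores are
#' smoothed with a running window of 3 columns (block selection);
#' columns whose smoothed score exceeds \code{hMax}, or whose gap
#' fraction exceeds 0.2, are removed.  This trimmer is inspired by
#' entropy/block selection in BMGE, not a bit-compatible
#' reimplementation.
#'
#' @param msa A [ProteinMSA-class].
#' @param hMax Entropy ceiling in (0, 1]; 0.55 is the conventional
#'   setting for divergent protein alignments.
#' @param simMatrix Name of a shipped similarity matrix
#'   (default \code{"BLOSUM45"}, the lowest-identity BLOSUM available
#'   here, suited to divergent families).
#' @return Trimmed [ProteinMSA-class].
#' @export
trimEntropy <- function(msa, hMax = 0.55, simMatrix = "BLOSUM45") {
  if (hMax <= 0 || hMax > 1)
    stop("invalid-argument: hMax must be in (0, 1]")
  S <- scoringMatrix(simMatrix)
  kern <- exp(S / 2)                         # similarity kernel
  kern <- kern / rowSums(kern)               # w(a | b) rows sum to 1
  im <- msaIntMatrix(msa)
  score <- vapply(seq_len(ncol(im)), function(j) {
    col <- im[, j]; col <- col[col >= 0L]
    if (!length(col)) return(1)
    if (length(unique(col)) == 1L) return(0) # invariant column
    cnt <- tabulate(col + 1L, nbins = 20)
    f <- as.numeric((cnt / sum(cnt)) %*% kern)
    f <- f[f > 0]
    -sum(f * log(f)) / log(20)
  }, numeric(1))
  W <- length(score)
  sm <- vapply(seq_len(W), function(j)
    mean(score[max(1, j - 1):min(W, j + 1)]), numeric(1))
  gapFrac <- colMeans(msaMatrix(msa) == "-")
  keep <- which(sm <= hMax & gapFrac <= 0.2)
  if (!length(keep)) stop("empty-alignment error: all columns removed")
  out <- msaKeepColumns(msa, keep)
  attr(out, "trimScore") <- score
  out
}

#' Trim report
#' @param msa Original alignment.
#' @param trimmed Result of a trimming call on \code{msa}.
#' @return \code{data.frame(original_column, kept, score)} (score NA
#'   when the trimmer reports none).
#' @export
trimReport <- function(msa, trimmed) {
  sc <- attr(trimmed, "trimScore")
  orig <- provenance(msa)
  keptOrig <- provenance(trimmed)
  data.frame(original_column = orig,
             kept = orig %in% keptOrig,
             score = if (is.null(sc)) NA_real_ else sc)
}

#' Merge two alignments profile-to-profile
#'
#' The two inputs are aligned column-against-column (affine-gap global
#' profile alignment); rows of each input keep their mutual alignment
#' exactly, possibly interleaved with new all-gap columns.
#'
#' @param msaA,msaB [ProteinMSA-class] objects with disjoint row ids;
#'   an empty (NULL) \code{msaB} returns \code{msaA} unchanged.
#' @param matrix,gapOpen,gapExtend Alignment scoring parameters.
#' @return Merged [ProteinMSA-class] with fresh provenance.
#' @export
mergeAlignments <- function(msaA, msaB, matrix = "BLOSUM62",
                            gapOpen = -11, gapExtend = -1) {
  if (is.null(msaB) || !length(msaB@rows)) return(msaA)
  if (length(intersect(names(msaA@rows), names(msaB@rows))))
    stop("invalid-argument: overlapping row ids")
  S <- scoringMatrix(matrix)
  aln <- C_nw_profile(msaProfile(msaA), msaProfile(msaB), S,
                      gapOpen, gapExtend)
  mA <- msaMatrix(msaA); mB <- msaMatrix(msaB)
  W <- length(aln$pathA)
  out <- matrix("-", nrow(mA) + nrow(mB), W,
                dimnames = list(c(rownames(mA), rownames(mB)), NULL))
  ia <- aln$pathA > 0
  out[seq_len(nrow(mA)), ia] <- mA[, aln$pathA[ia], drop = FALSE]
  ib <- aln$pathB > 0
  out[nrow(mA) + seq_len(nrow(mB)), ib] <- mB[, aln$pathB[ib], drop = FALSE]
  ProteinMSA(setNames(apply(out, 1, paste, collapse = ""), rownames(out)))
}

#' Write cluster membership TSV
#' @param clustering Result of [clusterByIdentity()].
#' @param path Output TSV.
#' @export
writeClusterTable <- function(clustering, path)
  writeTsv(clustering$membership, path)
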