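#' @include curate.R
NULL

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch with affine gap costs and a deterministic
#' tie-break (diagonal over up over left).
#'
#' @param a,b Non-empty amino-acid strings.
#' @param matrix Scoring matrix name (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend Gap open / extension scores (community
#'   defaults -11 / -1).
#' @return \code{list(alignedA, alignedB, score)}; gaps as \code{-}.
#' @examples
#' pairwiseGlobal("MKVA", "MKA")$score
#' @export
pairwiseGlobal <- function(a, b, matrix = "BLOSUM62",
                           gapOpen = -11, gapExtend = -1) {
  if (!nzchar(a) || !nzchar(b))
    stop("invalid-argument: empty sequence")
  ea <- aaEncode(a, "a"); eb <- aaEncode(b, "b")
  onehot <- function(e) {
    p <- matrix(0, 20, length(e))
    ok <- e >= 0
    p[cbind(e[ok] + 1L, which(ok))] <- 1
    p
  }
  S <- scoringMatrix(matrix)
  aln <- C_nw_profile(onehot(ea), onehot(eb), S, gapOpen, gapExtend)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ga <- ifelse(aln$pathA > 0, ca[pmax(aln$pathA, 1)], "-")
  gb <- ifelse(aln$pathB > 0, cb[pmax(aln$pathB, 1)], "-")
  list(alignedA = paste(ga, collapse = ""),
       alignedB = paste(gb, collapse = ""),
       score = aln$score)
}

# k-mer (k = 3) cosine distance between ungapped sequences
kmerDistances <- function(seqs, k = 3) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(s))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- intersect(names(ci), names(cj))
    num <- sum(as.numeric(ci[shared]) * as.numeric(cj[shared]))
    den <- sqrt(sum(as.numeric(ci)^2)) * sqrt(sum(as.numeric(cj)^2))
    D[i, j] <- D[j, i] <- 1 - (if (den > 0) num / den else 0)
  }
  D
}

#' Progressive multiple alignment
#'
#' Builds a UPGMA guide tree from 3-mer cosine distances (ids break
#' ties so the result is independent of input order for distinct
#' sequences) and merges profiles up the tree with the affine-gap
#' profile aligner.  Once two residues are aligned within a profile
#' their relative alignment never changes ("once a gap, always a
#' gap").
#'
#' @param records A [ProteinSet-class] or named character vector of at
#'   least 2 sequences.
#' @param matrix,gapOpen,gapExtend Scoring parameters as in
#'   [pairwiseGlobal()].
#' @return A [ProteinMSA-class]; ungapping any row reproduces its
#'   input sequence.
#' @export
progressiveAlign <- function(records, matrix = "BLOSUM62",
                             gapOpen = -11, gapExtend = -1) {
  seqs <- if (is(records, "ProteinSet"))
    setNames(as.character(sequences(records)), names(records)) else records
  if (length(seqs) < 2)
    stop("invalid-argument: need at least 2 sequences")
  seqs <- seqs[order(names(seqs))]          # canonical input order
  if (length(seqs) == 2) {
    aln <- pairwiseGlobal(seqs[[1]], seqs[[2]], matrix, gapOpen, gapExtend)
    return(ProteinMSA(setNames(c(aln$alignedA, aln$alignedB), names(seqs))))
  }
  D <- kmerDistances(seqs)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  S <- scoringMatrix(matrix)
  merged <- vector("list", nrow(hc$merge))
  leaf <- function(i) ProteinMSA(seqs[hc$labels[i]])
  for (step in seq_len(nrow(hc$merge))) {
    m <- hc$merge[step, ]
    left <- if (m[1] < 0) leaf(-m[1]) else merged[[m[1]]]
    right <- if (m[2] < 0) leaf(-m[2]) else merged[[m[2]]]
    aln <- C_nw_profile(msaProfile(left), msaProfile(right), S,
                        gapOpen, gapExtend)
    mA <- msaMatrix(left); mB <- msaMatrix(right)
    W <- length(aln$pathA)
    out <- matrix("-", nrow(mA) + nrow(mB), W,
                  dimnames = list(c(rownames(mA), rownames(mB)), NULL))
    ia <- aln$pathA > 0
    out[seq_len(nrow(mA)), ia] <- mA[, aln$pathA[ia], drop = FALSE]
    ib <- aln$pathB > 0
    out[nrow(mA) + seq_len(nrow(mB)), ib] <- mB[, aln$pathB[ib],
                                                drop = FALSE]
    merged[[step]] <- ProteinMSA(setNames(apply(out, 1, paste,
                                                collapse = ""),
                                          rownames(out)))
  }
  final <- merged[[length(merged)]]
  msaKeepRows(final, names(seqs))           # stable row order by id
}

#' Align with an external aligner executable (adapter)
#'
#' Runs a user-supplied command template (receiving the input FASTA
#' path, writing aligned FASTA to stdout) and subjects its output to
#' the same invariants as the built-in aligner.  Lets users plug in
#' e.g. MAFFT without making it a dependency.
#'
#' @param records Sequences as in [progressiveAlign()].
#' @param command Command template containing \code{{input}}, e.g.
#'   \code{"mafft --auto {input}"}.
#' @return A [ProteinMSA-class].
#' @export
alignWithAdapter <- function(records, command) {
  seqs <- if (is(records, "ProteinSet"))
    setNames(as.character(sequences(records)), names(records)) else records
  tf <- tempfile(fileext = ".faa")
  on.exit(unlink(tf))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), tf, width = 60)
  out <- system(sub("{input}", tf, command, fixed = TRUE), intern = TRUE)
  of <- tempfile(fileext = ".afa")
  on.exit(unlink(of), add = TRUE)
  writeLines(out, of)
  msa <- readMsaFasta(of)
  for (id in names(seqs))
    if (!identical(toupper(ungapRow(msa, id)), toupper(seqs[[id]])))
      stop("data-integrity error: adapter output does not reproduce ", id)
  msa
}
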