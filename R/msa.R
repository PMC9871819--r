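#' @include AllGenerics.R
NULL

#' Construct a ProteinMSA
#'
#' @param rows Named character vector of equal-width gapped strings
#'   (gap character \code{-}).
#' @param provenance Optional integer vector mapping current columns to
#'   original column indices; defaults to \code{1:width}.
#' @return A [ProteinMSA-class].
#' @examples
#' msa <- ProteinMSA(c(a = "MK-V", b = "MKAV"))
#' msaWidth(msa)
#' @export
ProteinMSA <- function(rows, provenance = NULL) {
  if (is.null(provenance)) provenance <- seq_len(nchar(rows[1]))
  new("ProteinMSA", rows = rows, provenance = as.integer(provenance))
}

#' @rdname ProteinMSA-class
#' @export
setMethod("msaRows", "ProteinMSA", function(x) x@rows)

#' @rdname ProteinMSA-class
#' @export
setMethod("provenance", "ProteinMSA", function(x) x@provenance)

#' @rdname ProteinMSA-class
#' @export
setMethod("length", "ProteinMSA", function(x) length(x@rows))

#' @rdname ProteinMSA-class
#' @export
setMethod("names", "ProteinMSA", function(x) names(x@rows))

#' @rdname ProteinMSA-class
#' @export
setMethod("show", "ProteinMSA", function(object) {
  cat("ProteinMSA:", length(object@rows), "rows x",
      nchar(object@rows[1]), "columns\n")
})

#' Alignment width
#' @param x A ProteinMSA.
#' @return Integer number of columns.
#' @export
msaWidth <- function(x) nchar(x@rows[[1]])

#' Character matrix view of an alignment
#' @param x A ProteinMSA.
#' @return Character matrix, rows = sequences, columns = alignment
#'   columns, gap = \code{-}.
#' @export
msaMatrix <- function(x) {
  m <- do.call(rbind, strsplit(x@rows, "", fixed = TRUE))
  rownames(m) <- names(x@rows)
  m
}

# Integer matrix view: 0..19 residues, -1 = X, -2 = gap.
msaIntMatrix <- function(x) {
  m <- msaMatrix(x)
  idx <- match(m, AA_ORDER)
  out <- matrix(idx - 1L, nrow = nrow(m))
  out[m == "X"] <- -1L
  out[m == "-"] <- -2L
  if (anyNA(out)) stop("alphabet-error: invalid residue in alignment")
  rownames(out) <- rownames(m)
  out
}

#' Remove gaps from one alignment row
#' @param x A ProteinMSA.
#' @param id Row id.
#' @return Ungapped sequence string.
#' @export
ungapRow <- function(x, id) gsub("-", "", x@rows[[id]], fixed = TRUE)

# Subset alignment columns, composing provenance.
msaKeepColumns <- function(x, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep)) stop("empty-alignment error: all columns removed")
  m <- msaMatrix(x)[, keep, drop = FALSE]
  ProteinMSA(setNames(apply(m, 1, paste, collapse = ""), names(x@rows)),
             x@provenance[keep])
}

# Subset alignment rows.
msaKeepRows <- function(x, ids) {
  if (is.character(ids)) {
    miss <- setdiff(ids, names(x@rows))
    if (length(miss)) stop("missing-id error: ", paste(miss, collapse = ", "))
  }
  ProteinMSA(x@rows[ids], x@provenance)
}

#' Read / write aligned FASTA
#' @param path Aligned FASTA file (gaps as \code{-}).
#' @return \code{readMsaFasta}: a [ProteinMSA-class] with fresh
#'   provenance.
#' @export
readMsaFasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  ProteinMSA(setNames(as.character(ss), names(ss)))
}

#' @rdname readMsaFasta
#' @param x ProteinMSA to write (wrapped at 60 columns).
#' @export
writeMsaFasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x@rows), path,
                              width = 60)
  invisible(path)
}

# Column frequency profile (20 x W): counts of residues / nrow, gaps
# and X contribute no mass.
msaProfile <- function(x) {
  im <- msaIntMatrix(x)
  W <- ncol(im)
  prof <- matrix(0, 20, W)
  n <- nrow(im)
  for (j in seq_len(W)) {
    col <- im[, j]
    col <- col[col >= 0]
    if (length(col)) {
      tab <- tabulate(col + 1L, nbins = 20)
      prof[, j] <- tab / n
    }
  }
  prof
}
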