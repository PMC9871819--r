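#' @include msa.R
NULL

#' Pairwise corrected protein distances from an alignment
#'
#' Per pair of rows, \code{p} is the proportion of differing residues
#' over mutually ungapped columns, corrected with Kimura's (1983)
#' protein formula \code{d = -ln(1 - p - 0.2 p^2)}.  Saturated pairs
#' (\code{p >= 0.85}, where the correction is undefined) receive the
#' documented ceiling 5.0.
#'
#' @param msa A [ProteinMSA-class] with at least 2 rows.
#' @return Symmetric numeric matrix (expected substitutions/site),
#'   zero diagonal.
#' @export
proteinDistance <- function(msa) {
  if (length(msa@rows) < 2)
    stop("invalid-argument: need at least 2 rows")
  im <- msaIntMatrix(msa)
  im[im == -1L] <- -2L                     # X is not comparable
  pd <- C_pdist(im)
  ids <- rownames(im)
  if (any(pd$n[upper.tri(pd$n)] == 0)) {
    w <- which(pd$n == 0 & upper.tri(pd$n), arr.ind = TRUE)[1, ]
    stop("incomparable-pair error: ", ids[w[1]], " / ", ids[w[2]],
         " share no ungapped column")
  }
  p <- pd$p
  d <- p
  sat <- p >= 0.85
  d[sat] <- 5.0
  d[!sat] <- -log(1 - p[!sat] - 0.2 * p[!sat]^2)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Construct a SupportTree
#' @param tree An [ape::phylo].
#' @param support Numeric per-internal-node supports (NA allowed);
#'   defaults to all NA.
#' @param rooted Logical; defaults to [ape::is.rooted()].
#' @return A [SupportTree-class].
#' @export
SupportTree <- function(tree, support = NULL, rooted = ape::is.rooted(tree)) {
  if (is.null(support)) support <- rep(NA_real_, tree$Nnode)
  new("SupportTree", tree = tree, support = support, rooted = rooted)
}

#' @rdname SupportTree-class
#' @export
setMethod("asPhylo", "SupportTree", function(x) x@tree)

#' @rdname SupportTree-class
#' @export
setMethod("nodeSupport", "SupportTree", function(x) x@support)

#' @rdname SupportTree-class
#' @export
setMethod("show", "SupportTree", function(object) {
  s <- object@support[!is.na(object@support)]
  cat("SupportTree:", length(object@tree$tip.label), "leaves,",
      if (object@rooted) "rooted," else "unrooted,",
      if (length(s)) sprintf("supports %d-%d%%", round(min(s)),
                             round(max(s)))
      else "no supports", "\n")
})

# ---- neighbor joining -------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration.  Negative branch lengths are clamped to
#' zero with the deficit moved to the sibling edge; ties in the Q
#' criterion break deterministically on the smallest (i, j) index
#' pair, with taxa taken in lexicographic id order so the result never
#' depends on input row order.  Exact on additive matrices.
#'
#' @param D Symmetric distance matrix with >= 3 taxa (dimnames = ids).
#' @return An unrooted [SupportTree-class] (supports unset).
#' @export
neighborJoining <- function(D) {
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(n))
  if (n < 3) stop("invalid-argument: need at least 3 taxa")
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  lab <- rownames(D)
  fmt <- function(x) sprintf("%.10g", x)
  node <- lab                                # newick fragment per cluster
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(1L, 2L); bq <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- paste0("(", node[i], ":", fmt(li), ",", node[j], ":",
                     fmt(lj), ")")
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    node <- c(node[keep], merged)
    D <- D2
    n <- n - 1
  }
  # final three-point formulas
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- paste0("(", node[1], ":", fmt(l1), ",", node[2], ":", fmt(l2),
                ",", node[3], ":", fmt(l3), ");")
  phy <- ape::read.tree(text = nwk)
  SupportTree(phy, rooted = FALSE)
}

# ---- bipartitions and bootstrap ---------------------------------------

# Canonical string key per internal edge's bipartition: the sorted leaf
# set of the side not containing the lexicographically smallest leaf.
# Returns keys named by the internal node (edge child) number.
bipartitionKeys <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- min(phy$tip.label)
  nodes <- setdiff(unique(phy$edge[, 2]), seq_len(ntip))
  tipsBelow <- phangorn::Descendants(phy, nodes, "tips")
  keys <- vapply(seq_along(nodes), function(k) {
    set <- phy$tip.label[tipsBelow[[k]]]
    if (ref %in% set) set <- setdiff(phy$tip.label, set)
    if (length(set) < 2 || length(set) > ntip - 2) return(NA_character_)
    paste(sort(set), collapse = "\r")
  }, character(1))
  names(keys) <- nodes
  keys[!is.na(keys)]
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and attaches to each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#'
#' @param msa A [ProteinMSA-class].
#' @param nReps Number of bootstrap replicates (>= 1; 100 by default).
#' @param seed Integer seed (supports are reproducible under a fixed
#'   seed and invariant to leaf order).
#' @return An unrooted [SupportTree-class] with supports in \[0, 100\].
#' @export
bootstrapSupports <- function(msa, nReps = 100, seed = 1) {
  if (nReps < 1) stop("invalid-argument: nReps must be >= 1")
  tree <- neighborJoining(proteinDistance(msa))
  phy <- tree@tree
  keys <- bipartitionKeys(phy)
  count <- setNames(numeric(length(keys)), keys)
  m <- msaMatrix(msa)
  withSeed(seed, {
    for (rep in seq_len(nReps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      bm <- m[, cols, drop = FALSE]
      bmsa <- ProteinMSA(setNames(apply(bm, 1, paste, collapse = ""),
                                  rownames(m)))
      bt <- neighborJoining(proteinDistance(bmsa))
      bk <- bipartitionKeys(bt@tree)
      hit <- keys %in% bk
      count[hit] <- count[hit] + 1
    }
  })
  ntip <- length(phy$tip.label)
  support <- rep(NA_real_, phy$Nnode)
  idx <- as.integer(names(keys)) - ntip
  support[idx] <- 100 * count / nReps
  SupportTree(phy, support, rooted = FALSE)
}

# ---- rooting and collapsing -------------------------------------------

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path;
#' supports are carried across the rooting by bipartition matching
#' (bipartitions are rooting-invariant).
#'
#' @param st A [SupportTree-class] (or \code{phylo}) with >= 2 leaves
#'   and positive total path length.
#' @return A rooted [SupportTree-class].
#' @export
midpointRoot <- function(st) {
  if (inherits(st, "phylo")) st <- SupportTree(st)
  phy <- st@tree
  if (sum(phy$edge.length) <= 0)
    stop("degenerate-tree error: all branch lengths zero")
  ntip <- length(phy$tip.label)
  if (ntip == 2) {
    h <- sum(phy$edge.length) / 2
    out <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         phy$tip.label[1], h,
                                         phy$tip.label[2], h))
    return(SupportTree(out, rooted = TRUE))
  }
  supByKey <- st@support[as.integer(names(bipartitionKeys(phy))) - ntip]
  names(supByKey) <- bipartitionKeys(phy)
  rooted <- phangorn::midpoint(phy)
  rk <- bipartitionKeys(rooted)
  support <- rep(NA_real_, rooted$Nnode)
  hit <- rk %in% names(supByKey)
  support[as.integer(names(rk))[hit] - ntip] <- supByKey[rk[hit]]
  SupportTree(rooted, support, rooted = TRUE)
}

#' Collapse poorly supported edges into polytomies
#'
#' Contracts every internal edge whose support is below
#' \code{minSupport}; the contracted edge's length is discarded and
#' child edges are unchanged.  The conventional display threshold for
#' ultrafast-bootstrap-style supports is 85.
#'
#' @param st A [SupportTree-class] with supports.
#' @param minSupport Percentage in \[0, 100\]; 0 leaves the tree
#'   unchanged.
#' @return A [SupportTree-class] (possibly multifurcating).
#' @export
collapseLowSupport <- function(st, minSupport = 85) {
  phy <- st@tree
  sup <- st@support
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kill <- which(!is.na(sup) & sup < minSupport) + ntip
  kill <- setdiff(kill, root)
  if (!length(kill)) return(st)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  len <- setNames(phy$edge.length, as.character(phy$edge[, 2]))
  strFor <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    kids <- unlist(lapply(children[[as.character(v)]], kidStr))
    s <- if (!is.na(sup[v - ntip])) sprintf("%.6g", sup[v - ntip]) else ""
    paste0("(", paste(kids, collapse = ","), ")", s)
  }
  kidStr <- function(v) {
    if (v %in% kill) unlist(lapply(children[[as.character(v)]], kidStr))
    else paste0(strFor(v), ":", sprintf("%.10g", len[[as.character(v)]]))
  }
  out <- ape::read.tree(text = paste0(strFor(root), ";"))
  supportTreeFromPhylo(out, rooted = st@rooted)
}

# Build a SupportTree from a phylo whose node labels hold supports.
supportTreeFromPhylo <- function(phy, rooted = ape::is.rooted(phy)) {
  sup <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    v <- suppressWarnings(as.numeric(phy$node.label))
    sup[seq_along(v)] <- v
  }
  phy$node.label <- NULL
  SupportTree(phy, sup, rooted = rooted)
}

#' Newick round-trip for support trees
#'
#' Supports are written as internal node labels (IQ-TREE style),
#' branch lengths after colons; the reader accepts quoted and unquoted
#' labels.
#'
#' @param st A [SupportTree-class].
#' @param path File path (or, for the reader, a path to read).
#' @return \code{readSupportNewick}: a [SupportTree-class].
#' @export
writeSupportNewick <- function(st, path) {
  phy <- st@tree
  phy$node.label <- ifelse(is.na(st@support), "",
                           sprintf("%.6g", st@support))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname writeSupportNewick
#' @export
readSupportNewick <- function(path)
  supportTreeFromPhylo(ape::read.tree(path))

# ---- iTOL annotation export -------------------------------------------

.defaultPalette <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                     "#66a61e", "#e6ab02", "#a6761d", "#666666",
                     "#1f78b4", "#b2df8a", "#fb9a99", "#cab2d6")

#' Write an iTOL color-strip dataset for leaf classes
#'
#' @param st A [SupportTree-class] or \code{phylo}.
#' @param classes Named character vector: leaf id -> class label
#'   (every leaf must have one).
#' @param path Output text file.
#' @param palette Optional vector of colors recycled over classes; an
#'   empty/NULL palette applies the default palette.
#' @return The path, invisibly.
#' @export
writeItolColorStrip <- function(st, classes, path, palette = NULL) {
  phy <- if (inherits(st, "phylo")) st else st@tree
  miss <- setdiff(phy$tip.label, names(classes))
  if (length(miss))
    stop("missing-id error: no class for ", paste(miss, collapse = ", "))
  if (is.null(palette) || !length(palette)) palette <- .defaultPalette
  lev <- sort(unique(unname(classes[phy$tip.label])))
  cols <- setNames(rep_len(palette, length(lev)), lev)
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w("DATASET_COLORSTRIP")
  w("SEPARATOR TAB")
  w("DATASET_LABEL\tleaf classes")
  w("COLOR\t#000000")
  w("LEGEND_TITLE\tclasses")
  w("LEGEND_LABELS\t", paste(lev, collapse = "\t"))
  w("LEGEND_COLORS\t", paste(cols, collapse = "\t"))
  w("DATA")
  for (id in phy$tip.label)
    w(id, "\t", cols[[classes[[id]]]], "\t", classes[[id]])
  invisible(path)
}

#' Parse an iTOL color-strip dataset back to its leaf-class map
#' @param path File written by [writeItolColorStrip()].
#' @return Named character vector id -> class label.
#' @export
readItolColorStrip <- function(path) {
  ln <- readLines(path)
  start <- which(ln == "DATA")[1]
  rows <- strsplit(ln[(start + 1):length(ln)], "\t", fixed = TRUE)
  setNames(vapply(rows, `[`, character(1), 3),
           vapply(rows, `[`, character(1), 1))
}
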