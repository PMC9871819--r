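#' @include msa.R
NULL

# ---- model construction -----------------------------------------------

#' Build a profile HMM from a multiple alignment
#'
#' Columns whose non-gap fraction is at least \code{occupancy} become
#' match states.  Match emissions are pseudocount-smoothed observed
#' frequencies, \code{(counts + pseudocount * background) /
#' (n + pseudocount)}; transition probabilities are estimated from the
#' state path each row implies (match / delete on match columns, insert
#' elsewhere) with add-one (Laplace) smoothing over the outgoing
#' options of every state.
#'
#' @param msa A [ProteinMSA-class].
#' @param occupancy Minimum non-gap fraction for a match column, in
#'   (0, 1].
#' @param pseudocount Weight of the background pseudocount added to
#'   match emissions (0 disables smoothing).
#' @param name Model name.
#' @return A [ProfileHMM-class] (uncalibrated).
#' @examples
#' msa <- ProteinMSA(c(a = "MKV", b = "MKV", c = "MRV"))
#' hmm <- buildProfileHMM(msa, name = "toy")
#' hmm
#' @export
buildProfileHMM <- function(msa, occupancy = 0.5, pseudocount = 1,
                            name = "model") {
  stopifnot(is(msa, "ProteinMSA"))
  if (occupancy <= 0 || occupancy > 1)
    stop("invalid-argument: occupancy must be in (0, 1]")
  im <- msaIntMatrix(msa)
  n <- nrow(im)
  nongap <- colSums(im >= -1L) / n
  matchCols <- which(nongap >= occupancy)
  M <- length(matchCols)
  if (M == 0) stop("model-degenerate error: zero match columns")
  bg <- backgroundFrequencies()

  match <- matrix(0, M, 20, dimnames = list(NULL, AA_ORDER))
  for (k in seq_len(M)) {
    col <- im[, matchCols[k]]
    col <- col[col >= 0L]                       # drop gaps and X
    cnt <- tabulate(col + 1L, nbins = 20)
    match[k, ] <- (cnt + pseudocount * bg) / (length(col) + pseudocount)
    if (pseudocount == 0 && length(col) == 0)
      match[k, ] <- bg                          # fully ambiguous column
  }

  # implied state paths -> transition counts with Laplace smoothing
  cnt <- matrix(0, M, 7,
                dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  isMatch <- logical(ncol(im))
  isMatch[matchCols] <- TRUE
  posOf <- cumsum(isMatch)                      # model position per column
  for (r in seq_len(n)) {
    prev <- NULL                                # c(state, position)
    for (j in seq_len(ncol(im))) {
      resid <- im[r, j] >= -1L
      st <- if (isMatch[j]) {
        if (resid) c("M", posOf[j]) else c("D", posOf[j])
      } else if (resid) c("I", posOf[j]) else NULL
      if (is.null(st)) next
      if (st[1] == "I" && st[2] %in% c("0", as.character(M))) next
      if (!is.null(prev)) {
        key <- paste0(prev[1], st[1])
        k <- as.integer(prev[2])
        if (prev[1] == "I") k <- as.integer(prev[2])
        if (key %in% colnames(cnt) && k >= 1 && k <= M) {
          ok <- switch(key,
            MM = , MD = as.integer(st[2]) == k + 1L,
            MI = as.integer(st[2]) == k,
            IM = as.integer(st[2]) == k + 1L,
            II = as.integer(st[2]) == k,
            DM = , DD = as.integer(st[2]) == k + 1L)
          if (isTRUE(ok)) cnt[k, key] <- cnt[k, key] + 1
        }
      }
      prev <- st
    }
  }
  trans <- matrix(0, M, 7, dimnames = dimnames(cnt))
  for (k in seq_len(M)) {
    m3 <- cnt[k, c("MM", "MI", "MD")] + 1
    trans[k, c("MM", "MI", "MD")] <- m3 / sum(m3)
    i2 <- cnt[k, c("IM", "II")] + 1
    trans[k, c("IM", "II")] <- i2 / sum(i2)
    d2 <- cnt[k, c("DM", "DD")] + 1
    trans[k, c("DM", "DD")] <- d2 / sum(d2)
  }
  trans[M, c("MM", "MI", "MD")] <- c(1, 0, 0)   # only exit remains

  new("ProfileHMM", name = name, match = match, bg = bg, trans = trans,
      mu = NA_real_, lambda = NA_real_,
      consensus = paste(AA_ORDER[max.col(match, ties.method = "first")],
                        collapse = ""))
}

#' @rdname ProfileHMM-class
#' @param object A ProfileHMM.
#' @export
setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM '", object@name, "': ", nrow(object@match),
      " match states, ",
      if (is.na(object@lambda)) "uncalibrated"
      else sprintf("Gumbel(mu=%.3f, lambda=%.3f)", object@mu, object@lambda),
      "\n", sep = "")
})

#' Model length and consensus
#' @param hmm A [ProfileHMM-class].
#' @return \code{hmmLength}: number of match states;
#'   \code{hmmConsensus}: consensus string.
#' @export
hmmLength <- function(hmm) nrow(hmm@match)

#' @rdname hmmLength
#' @export
hmmConsensus <- function(hmm) hmm@consensus

# ---- scoring ----------------------------------------------------------

# Pack a model into the natural-log parameterisation the C++ kernels
# expect.  Local mode: uniform entry over match states; exit from match
# state k with probability 1/(M-k+1) (uniform over remaining end
# points), remaining outgoing mass rescaled.  Glocal mode: entry at
# match 1, exit at match M only.  Flank states emit background and are
# scored free, so their terms vanish from the log-odds.
hmmLogPack <- function(hmm, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  M <- nrow(hmm@match)
  lmat <- log(hmm@match) - rep(log(hmm@bg), each = M)
  tr <- hmm@trans
  if (mode == "local") {
    lentry <- rep(log(1 / M), M)
    ex <- 1 / (M - seq_len(M) + 1)
    ex[M] <- 1
    lexit <- log(ex)
    keep <- log(1 - ex)
    keep[M] <- -Inf
    lMM <- log(tr[, "MM"]) + keep
    lMI <- log(tr[, "MI"]) + keep
    lMD <- log(tr[, "MD"]) + keep
  } else {
    lentry <- c(0, rep(-Inf, M - 1))
    lexit <- c(rep(-Inf, M - 1), 0)
    lMM <- log(tr[, "MM"]); lMI <- log(tr[, "MI"]); lMD <- log(tr[, "MD"])
    lMM[M] <- lMI[M] <- lMD[M] <- -Inf
  }
  lIM <- log(tr[, "IM"]); lII <- log(tr[, "II"])
  lDM <- log(tr[, "DM"]); lDD <- log(tr[, "DD"])
  lIM[M] <- lII[M] <- lDM[M] <- lDD[M] <- -Inf
  list(lmat = lmat, lMM = lMM, lMI = lMI, lMD = lMD, lIM = lIM,
       lII = lII, lDM = lDM, lDD = lDD, lentry = lentry, lexit = lexit)
}

#' Forward bit score of a sequence under a profile HMM
#'
#' \code{log2} of the ratio between the full (path-summed) probability
#' of the sequence under the local-alignment model and its probability
#' under the background; always finite for non-empty sequences.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seq Amino-acid string (X allowed; scored neutrally).
#' @param mode \code{"local"} (Smith-Waterman-style entry/exit,
#'   default, matching hmmsearch semantics) or \code{"glocal"}
#'   (full-model alignment).
#' @return Bit score (numeric scalar).
#' @export
forwardBits <- function(hmm, seq, mode = "local") {
  if (!nzchar(seq)) stop("invalid-argument: empty sequence")
  C_forward_bits(hmmLogPack(hmm, mode), aaEncode(seq))
}

#' Best-path (Viterbi) hit with its envelope
#'
#' The envelope is the span of target residues emitted by match or
#' insert states on the single best path; ties prefer match over delete
#' over insert and the leftmost placement.
#'
#' @inheritParams forwardBits
#' @param target Optional target id recorded in the hit.
#' @return One-row \code{data.frame}: \code{target, model, bits,
#'   evalue, env_start, env_end} (0-based half-open) and
#'   \code{m_start, m_end} (1-based match states).  \code{evalue} is NA
#'   for uncalibrated models.
#' @export
viterbiHit <- function(hmm, seq, mode = "local", target = NA_character_) {
  if (!nzchar(seq)) stop("invalid-argument: empty sequence")
  v <- C_viterbi(hmmLogPack(hmm, mode), aaEncode(seq))
  ev <- if (is.na(hmm@lambda)) NA_real_ else hmmEvalue(hmm, v$bits, 1)
  data.frame(target = target, model = hmm@name, bits = v$bits,
             evalue = ev, env_start = v$env_start, env_end = v$env_end,
             m_start = v$m_start, m_end = v$m_end,
             stringsAsFactors = FALSE)
}

# ---- calibration ------------------------------------------------------

# Maximum-likelihood Gumbel fit (location mu, rate lambda = 1/scale).
# With `lambda` given, only the location is estimated (closed form).
gumbelFit <- function(x, lambda = NULL) {
  if (length(x) < 10 || stats::sd(x) < 1e-9)
    stop("calibration-error: degenerate score variance")
  if (!is.null(lambda)) {
    m <- max(-lambda * x)
    mu <- -(m + log(mean(exp(-lambda * x - m)))) / lambda
    return(list(mu = mu, lambda = lambda))
  }
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.57721566 * beta0
  nll <- function(p) {
    lam <- exp(p[2])
    z <- lam * (x - p[1])
    -sum(log(lam) - z - exp(-z))
  }
  fit <- stats::optim(c(mu0, -log(beta0)), nll, method = "BFGS")
  list(mu = fit$par[1], lambda = exp(fit$par[2]))
}

#' Calibrate a profile HMM for E-values
#'
#' Scores \code{nRandom} i.i.d. background sequences with the forward
#' algorithm and fits a Gumbel distribution to the scores by maximum
#' likelihood, with the scale fixed at \code{ln 2} per bit — the
#' asymptotic tail behavior of forward log-odds scores — and the
#' location free.  A free-scale fit matches the score bulk but badly
#' underestimates tail probabilities; the fixed-scale fit is mildly
#' conservative throughout the tail, which is the safe direction for
#' homolog collection.  E-values are then \code{dbSize * P(S >= s)}.
#'
#' @param hmm A [ProfileHMM-class].
#' @param nRandom Number of null sequences (>= 100; default 1000).
#' @param lenMean,lenSd Normal length distribution of the nulls,
#'   truncated below at 30; defaults: the model length and 0.2 times
#'   it.
#' @param seed Integer seed.
#' @return The model with Gumbel \code{mu}/\code{lambda} filled in.
#' @export
calibrateHMM <- function(hmm, nRandom = 1000, lenMean = NULL,
                         lenSd = NULL, seed = 1) {
  if (nRandom < 100) stop("invalid-argument: nRandom must be >= 100")
  lenMean <- lenMean %||% nrow(hmm@match)
  lenSd <- lenSd %||% (0.2 * lenMean)
  pack <- hmmLogPack(hmm, "local")
  scores <- withSeed(seed, {
    lens <- pmax(30L, as.integer(round(rnorm(nRandom, lenMean, lenSd))))
    vapply(lens, function(L) {
      C_forward_bits(pack, sample.int(20L, L, replace = TRUE,
                                      prob = hmm@bg) - 1L)
    }, numeric(1))
  })
  fit <- gumbelFit(scores, lambda = log(2))
  hmm@mu <- fit$mu
  hmm@lambda <- fit$lambda
  hmm
}

#' E-value of a bit score under a calibrated model
#' @param hmm Calibrated [ProfileHMM-class].
#' @param bits Bit score(s).
#' @param dbSize Number of sequences in the searched database.
#' @return E-value(s); linear in \code{dbSize}, monotonically
#'   decreasing in \code{bits}.
#' @export
hmmEvalue <- function(hmm, bits, dbSize) {
  if (is.na(hmm@lambda)) stop("state-error: model is not calibrated")
  z <- hmm@lambda * (bits - hmm@mu)
  ez <- exp(-z)
  # survival of the Gumbel; for tiny exp(-z) use the first-order form
  # so E-values stay strictly decreasing instead of underflowing to 0
  p <- ifelse(ez < 1e-12, ez, -expm1(-ez))
  dbSize * p
}

# ---- search -----------------------------------------------------------

#' Search a profile HMM against a sequence database
#'
#' One best hit per target (forward bit score for the E-value, Viterbi
#' for the envelope), sorted by ascending E-value.  The database size
#' for E-values is the number of sequences searched in this invocation.
#'
#' @param hmm Calibrated [ProfileHMM-class].
#' @param db A [ProteinSet-class] or named character vector.
#' @param evalueMax Report only hits with E-value at or below this
#'   threshold; \code{NULL} (no threshold) returns every target's best
#'   hit.
#' @param mode Alignment mode, see [forwardBits()].
#' @return \code{data.frame} with columns \code{target, model, bits,
#'   evalue, env_start, env_end, m_start, m_end}; envelopes 0-based
#'   half-open (see [writeHitTable()] for the 1-based file form).
#' @export
searchHMM <- function(hmm, db, evalueMax = NULL, mode = "local") {
  if (is.na(hmm@lambda)) stop("state-error: model is not calibrated")
  seqs <- if (is(db, "ProteinSet")) setNames(as.character(sequences(db)),
                                             names(db)) else db
  pack <- hmmLogPack(hmm, mode)
  n <- length(seqs)
  hits <- lapply(names(seqs), function(id) {
    enc <- aaEncode(seqs[[id]], id)
    bits <- C_forward_bits(pack, enc)
    v <- C_viterbi(pack, enc)
    data.frame(target = id, model = hmm@name, bits = bits,
               evalue = hmmEvalue(hmm, bits, n),
               env_start = v$env_start, env_end = v$env_end,
               m_start = v$m_start, m_end = v$m_end,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, hits)
  tab <- tab[order(tab$evalue, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(evalueMax)) tab <- tab[tab$evalue <= evalueMax, ,
                                      drop = FALSE]
  tab
}

#' Write / read a hit table
#'
#' File form uses 1-based inclusive envelope coordinates
#' (\code{env_start, env_end}); in-memory tables are 0-based half-open.
#'
#' @param hits Hit table from [searchHMM()].
#' @param path TSV path.
#' @export
writeHitTable <- function(hits, path) {
  out <- hits
  out$env_start <- out$env_start + 1L          # to 1-based inclusive
  writeTsv(out[, c("target", "model", "bits", "evalue",
                   "env_start", "env_end")], path)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(path) {
  tab <- readTsv(path)
  tab$env_start <- tab$env_start - 1L
  tab
}

# ---- plain-text model serialization -----------------------------------

#' Write / read the plain-text profile-HMM format
#'
#' A documented sectioned text format (\code{HEADER}, \code{BACKGROUND},
#' \code{MATCH k}, \code{TRANSITIONS k}) that round-trips models exactly
#' to 12 significant digits.
#'
#' @param hmm A [ProfileHMM-class].
#' @param path Output / input file.
#' @return \code{readHMMFile}: a [ProfileHMM-class].
#' @export
writeHMMFile <- function(hmm, path) {
  f <- function(x) paste(sprintf("%.12g", x), collapse = " ")
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  M <- nrow(hmm@match)
  w("FTSZPROV-HMM 1")
  w("NAME ", hmm@name)
  w("LENG ", M)
  w("CALIB ", f(c(hmm@mu, hmm@lambda)))
  w("BACKGROUND")
  w(f(hmm@bg))
  for (k in seq_len(M)) {
    w("MATCH ", k)
    w(f(hmm@match[k, ]))
    w("TRANSITIONS ", k)
    w(f(hmm@trans[k, ]))
  }
  w("END")
  invisible(path)
}

#' @rdname writeHMMFile
#' @export
readHMMFile <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "FTSZPROV-HMM"))
    stop("configuration-error: not a ftszprov HMM file")
  val <- function(tag) sub(paste0("^", tag, " "), "",
                           grep(paste0("^", tag, " "), ln, value = TRUE)[1])
  nums <- function(i) as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]])
  name <- val("NAME")
  M <- as.integer(val("LENG"))
  calib <- as.numeric(strsplit(val("CALIB"), "\\s+")[[1]])
  bg <- nums(which(ln == "BACKGROUND") + 1L)
  match <- matrix(0, M, 20, dimnames = list(NULL, AA_ORDER))
  trans <- matrix(0, M, 7,
                  dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  for (k in seq_len(M)) {
    match[k, ] <- nums(which(ln == paste("MATCH", k)) + 1L)
    trans[k, ] <- nums(which(ln == paste("TRANSITIONS", k)) + 1L)
  }
  # renormalise 12-digit rounding so validity holds exactly
  match <- match / rowSums(match)
  bg <- bg / sum(bg)
  new("ProfileHMM", name = name, match = match, bg = setNames(bg, AA_ORDER),
      trans = trans, mu = calib[1], lambda = calib[2],
      consensus = paste(AA_ORDER[max.col(match, ties.method = "first")],
                        collapse = ""))
}
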