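# Shared low-level helpers: alphabet handling, the fixed substitution
# model, seeded RNG scoping, and TSV conventions.

# PAML/Dayhoff residue order; all numeric emission/rate tables use it.
AA_ORDER <- c("A","R","N","D","C","Q","E","G","H","I",
              "L","K","M","F","P","S","T","W","Y","V")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode an amino-acid string as alphabet indices
#'
#' @param seq character scalar over the 20-letter alphabet plus \code{X}.
#' @param what label used in error messages.
#' @return Integer vector of 0-based indices; \code{X} becomes -1
#'   (wildcard: scored with odds ratio 1).
#' @keywords internal
aaEncode <- function(seq, what = "sequence") {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_ORDER)
  bad <- which(is.na(idx) & ch != "X")
  if (length(bad))
    stop("alphabet-error: invalid residue '", ch[bad[1]], "' at position ",
         bad[1], " of ", what)
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}

aaDecode <- function(idx) paste(AA_ORDER[idx], collapse = "")

# Dayhoff exchangeabilities and equilibrium frequencies (via phangorn's
# bundled model data), assembled into a rate matrix normalised to one
# expected substitution per site per unit time.
dayhoffModel <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    d <- utils::getFromNamespace(".Dayhoff", "phangorn")
    bf <- as.numeric(d$bf)
    nm <- toupper(names(d$bf))
    S <- matrix(0, 20, 20, dimnames = list(nm, nm))
    S[lower.tri(S)] <- d$Q
    S <- S + t(S)
    Q <- S * rep(bf, each = 20)      # q_ij = s_ij * pi_j
    diag(Q) <- -rowSums(Q)
    mu <- -sum(bf * diag(Q))         # expected rate
    Q <- Q / mu
    # reorder to AA_ORDER (phangorn already uses arndcqeghilkmfpstwyv)
    Q <- Q[AA_ORDER, AA_ORDER]
    bf <- setNames(bf[match(AA_ORDER, nm)], AA_ORDER)
    cache <<- list(Q = Q, bf = bf,
                   eig = eigenQ(Q, bf))
    cache
  }
})

# Symmetric eigendecomposition of a reversible rate matrix so that
# P(t) = D^-1/2 U exp(Lt) U' D^1/2 can be formed for any t cheaply.
eigenQ <- function(Q, bf) {
  d <- sqrt(bf)
  B <- Q * outer(d, 1 / d)           # symmetric similar matrix
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, d = d)
}

# Transition probability matrix after time t (expected subs/site).
pmatrix <- function(t, model = dayhoffModel()) {
  e <- model$eig
  P <- (e$U %*% (t(e$U) * exp(e$lambda * t)))
  P <- P * outer(1 / e$d, e$d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Amino-acid background frequencies
#'
#' Dayhoff equilibrium frequencies in the package's fixed residue order;
#' used as HMM insert/background emissions and the simulator's root
#' distribution.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
backgroundFrequencies <- function() dayhoffModel()$bf

# Evaluate expr with a locally seeded RNG, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a bounded child seed from a root seed and a stage label, so
# toggling one stage never shifts another stage's random stream.
# Polynomial rolling hash keeps distinct labels on distinct streams.
childSeed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483647)
}

writeTsv <- function(df, path) {
  # fixed 6-significant-digit float formatting, LF endings
  df[] <- lapply(df, function(x)
    if (is.numeric(x) && !is.integer(x)) signif(x, 6) else x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

readTsv <- function(path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)

# Retrieve a residue substitution scoring matrix by name from the set
# shipped with Biostrings, restricted and reordered to the 20-letter
# alphabet.
scoringMatrix <- function(name) {
  ok <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
          "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% ok)
    stop("configuration-error: unknown similarity matrix '", name,
         "' (available: ", paste(ok, collapse = ", "), ")")
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  m[AA_ORDER, AA_ORDER]
}
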