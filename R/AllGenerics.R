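#' @include AllClasses.R
NULL

#' @rdname ProteinSet-class
#' @param x,object A \code{ProteinSet}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ProteinSet-class
#' @export
setGeneric("recordMeta", function(x) standardGeneric("recordMeta"))

#' @rdname ProteinMSA-class
#' @param x,object A \code{ProteinMSA}.
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname ProteinMSA-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname SupportTree-class
#' @param x,object A \code{SupportTree}.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname SupportTree-class
#' @export
setGeneric("nodeSupport", function(x) standardGeneric("nodeSupport"))

#' @rdname HitMatrix-class
#' @param x,object A \code{HitMatrix}.
#' @export
setGeneric("evalues", function(x) standardGeneric("evalues"))

#' @rdname HitMatrix-class
#' @export
setGeneric("bitScores", function(x) standardGeneric("bitScores"))
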