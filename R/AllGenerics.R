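#' @rdname Pedigree-class
#' @param x,object a `Pedigree` (or other pedpurge object).
#' @export
setGeneric("pedIds", function(x) standardGeneric("pedIds"))

#' @rdname Pedigree-class
#' @export
setGeneric("pedSires", function(x) standardGeneric("pedSires"))

#' @rdname Pedigree-class
#' @export
setGeneric("pedDams", function(x) standardGeneric("pedDams"))

#' @rdname Pedigree-class
#' @export
setGeneric("birthDates", function(x) standardGeneric("birthDates"))

#' @rdname Pedigree-class
#' @export
setGeneric("pedSex", function(x) standardGeneric("pedSex"))

#' @rdname Pedigree-class
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname Pedigree-class
#' @export
setGeneric("isFounder", function(x) standardGeneric("isFounder"))

#' @rdname CoefficientSet-class
#' @export
setGeneric("coefficientTable", function(x) standardGeneric("coefficientTable"))
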