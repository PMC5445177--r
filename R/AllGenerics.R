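#' @rdname componentMode
#' @export
setGeneric("componentMode", function(object) standardGeneric("componentMode"))

#' @rdname summarizeFit
#' @export
setGeneric("summarizeFit", function(fit) standardGeneric("summarizeFit"))

#' @rdname accessors
#' @export
setGeneric("mixingRatio", function(object) standardGeneric("mixingRatio"))

#' @rdname accessors
#' @export
setGeneric("lowComponent", function(object) standardGeneric("lowComponent"))

#' @rdname accessors
#' @export
setGeneric("highComponent", function(object) standardGeneric("highComponent"))

#' @rdname volume-accessors
#' @export
setGeneric("volumeValues", function(object) standardGeneric("volumeValues"))

#' @rdname volume-accessors
#' @export
setGeneric("wmMask", function(object) standardGeneric("wmMask"))

#' @rdname volume-accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))

#' @rdname volume-accessors
#' @export
setGeneric("wmValues", function(object) standardGeneric("wmValues"))
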