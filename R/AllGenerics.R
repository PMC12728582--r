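#' @name rhizofun-generics
#' @title Accessor generics
#' @description Small accessor generics used across the package's classes.
#' @param x an object.
#' @return The accessed component; see the class documentation pages.
#' @keywords internal
NULL

#' @rdname rhizofun-generics
#' @export
setGeneric("kingdom", function(x) standardGeneric("kingdom"))

#' @rdname rhizofun-generics
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname rhizofun-generics
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname rhizofun-generics
#' @export
setGeneric("functionNames", function(x) standardGeneric("functionNames"))

#' @rdname rhizofun-generics
#' @export
setGeneric("fmValues", function(x) standardGeneric("fmValues"))

#' @rdname rhizofun-generics
#' @export
setGeneric("ami", function(x) standardGeneric("ami"))

#' @rdname rhizofun-generics
#' @export
setGeneric("groupAMI", function(x) standardGeneric("groupAMI"))

#' @rdname rhizofun-generics
#' @export
setGeneric("pmi", function(x) standardGeneric("pmi"))

#' @rdname rhizofun-generics
#' @export
setGeneric("stdFunctions", function(x) standardGeneric("stdFunctions"))

#' @rdname rhizofun-generics
#' @export
setGeneric("pmiEigenvalues", function(x) standardGeneric("pmiEigenvalues"))

#' @rdname rhizofun-generics
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname rhizofun-generics
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname rhizofun-generics
#' @export
setGeneric("buildParams", function(x) standardGeneric("buildParams"))

#' @rdname rhizofun-generics
#' @export
setGeneric("complexityScores", function(x) standardGeneric("complexityScores"))

#' @rdname rhizofun-generics
#' @export
setGeneric("fisherC", function(x) standardGeneric("fisherC"))

#' @rdname rhizofun-generics
#' @export
setGeneric("pathCoefficients", function(x) standardGeneric("pathCoefficients"))

#' @rdname rhizofun-generics
#' @export
setGeneric("pathEffects", function(x) standardGeneric("pathEffects"))
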