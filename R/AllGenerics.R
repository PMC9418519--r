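#' @name frustule3d-generics
#' @title Accessor generics
#' @param x an object
#' @param object an object
NULL

#' @rdname frustule3d-generics
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname frustule3d-generics
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname frustule3d-generics
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname frustule3d-generics
#' @export
setGeneric("semantics", function(x) standardGeneric("semantics"))

#' @rdname frustule3d-generics
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' @rdname frustule3d-generics
#' @export
setGeneric("layerBoundaries", function(x) standardGeneric("layerBoundaries"))

#' @rdname frustule3d-generics
#' @export
setGeneric("layerTable", function(x) standardGeneric("layerTable"))
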