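#' @rdname ProteinMSA-class
#' @param x,object An object.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname ProteinMSA-class
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname ProteinMSA-class
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname ProteinMSA-class
#' @export
setGeneric("seqDescriptions", function(x) standardGeneric("seqDescriptions"))

#' @rdname UpgmaTree-class
#' @param x An object.
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))

#' @rdname UpgmaTree-class
#' @export
setGeneric("asHclust", function(x) standardGeneric("asHclust"))

#' @rdname PartitionSet-class
#' @param x A `PartitionSet`.
#' @param k Number of subgroups (level), in 1..N.
#' @export
setGeneric("partitionAt", function(x, k) standardGeneric("partitionAt"))

#' @rdname EntropyProfile-class
#' @param x An object.
#' @export
setGeneric("hGlobal", function(x) standardGeneric("hGlobal"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("hAverage", function(x) standardGeneric("hAverage"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("hLevel", function(x) standardGeneric("hLevel"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("conservation", function(x) standardGeneric("conservation"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("gapFraction", function(x) standardGeneric("gapFraction"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("nDistinct", function(x) standardGeneric("nDistinct"))

#' @rdname EntropyProfile-class
#' @export
setGeneric("lowSupport", function(x) standardGeneric("lowSupport"))

#' @rdname PropertyTable-class
#' @param x An object.
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @rdname PropertyProfile-class
#' @param x An object.
#' @export
setGeneric("sdMatrix", function(x) standardGeneric("sdMatrix"))
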