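# Accessor generics. Slots are never accessed with @ by user code.

#' @rdname Bicluster-class
#' @param x,object a package object.
#' @export
setGeneric("geneIndices", function(x) standardGeneric("geneIndices"))

#' @rdname Bicluster-class
#' @export
setGeneric("conditionIndices",
           function(x) standardGeneric("conditionIndices"))

#' @rdname Bicluster-class
#' @export
setGeneric("residueScore", function(x) standardGeneric("residueScore"))

#' @rdname Bicluster-class
#' @export
setGeneric("varianceScore", function(x) standardGeneric("varianceScore"))

#' @rdname Bicluster-class
#' @export
setGeneric("biclusterVolume", function(x) standardGeneric("biclusterVolume"))

#' @rdname Bicluster-class
#' @export
setGeneric("biclusterScore", function(x) standardGeneric("biclusterScore"))

#' @rdname BiclusterRun-class
#' @export
setGeneric("bestBicluster", function(x) standardGeneric("bestBicluster"))

#' @rdname BiclusterRun-class
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname BiclusterRun-class
#' @export
setGeneric("eliteBiclusters", function(x) standardGeneric("eliteBiclusters"))

#' @rdname BiclusterRun-class
#' @export
setGeneric("evaluationCount", function(x) standardGeneric("evaluationCount"))

#' @rdname PlantedDataset-class
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname PlantedDataset-class
#' @export
setGeneric("truthBlocks", function(x) standardGeneric("truthBlocks"))

#' @rdname PlantedDataset-class
#' @export
setGeneric("presetName", function(x) standardGeneric("presetName"))
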