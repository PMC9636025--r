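#' @import methods
#' @importFrom stats rbinom rgeom rnorm rpois runif setNames quantile sd cor
#'   pchisq qnorm
#' @importFrom utils head read.delim write.table
#' @importClassesFrom Biostrings DNAStringSet XStringSet
NULL

#' Accessors for package classes
#'
#' \code{pixels} and \code{umPerPixel} access the raster and physical scale
#' of a [LabelMask-class]; \code{maskLabels} lists the round labels present;
#' \code{cells} and \code{bounds} access a [TissuePhantom-class];
#' \code{geneInfo}, \code{transcriptSeqs} and \code{expressionMeans} access a
#' [TranscriptomeModel-class]; \code{umiCounts} and \code{barcodeTotals}
#' access a [UMICountMatrix-class].
#'
#' @param x an object of the documented class.
#' @return the slot contents (see Details of each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("umPerPixel", function(x) standardGeneric("umPerPixel"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname accessors
#' @export
setGeneric("bounds", function(x) standardGeneric("bounds"))
#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname accessors
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))
#' @rdname accessors
#' @export
setGeneric("expressionMeans", function(x) standardGeneric("expressionMeans"))
#' @rdname accessors
#' @export
setGeneric("umiCounts", function(x) standardGeneric("umiCounts"))
#' @rdname accessors
#' @export
setGeneric("barcodeTotals", function(x) standardGeneric("barcodeTotals"))

#' @rdname accessors
#' @export
setMethod("pixels", "LabelMask", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("umPerPixel", "LabelMask", function(x) x@umPerPixel)
#' @rdname accessors
#' @export
setMethod("maskLabels", "LabelMask",
    function(x) sort(unique(x@pixels[x@pixels > 0L])))
#' @rdname accessors
#' @export
setMethod("cells", "TissuePhantom", function(x) x@cells)
#' @rdname accessors
#' @export
setMethod("bounds", "TissuePhantom", function(x) x@bounds)
#' @rdname accessors
#' @export
setMethod("geneInfo", "TranscriptomeModel", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("transcriptSeqs", "TranscriptomeModel", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("expressionMeans", "TranscriptomeModel", function(x) x@expression)
#' @rdname accessors
#' @export
setMethod("umiCounts", "UMICountMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("barcodeTotals", "UMICountMatrix", function(x) colSums(x@counts))

setMethod("show", "LabelMask", function(object) {
    px <- object@pixels
    labs <- maskLabels(object)
    cat("LabelMask:", nrow(px), "x", ncol(px), "px at",
        object@umPerPixel, "um/px\n")
    cat("  labels:", if (length(labs)) paste(labs, collapse = ", ")
        else "(none)", "\n")
    cat("  labelled area:", sum(px > 0L) * object@umPerPixel^2, "um^2\n")
})

setMethod("show", "ScatterModel", function(object) {
    cat("ScatterModel: sigma =", object@sigmaUm, "um, threshold =",
        object@crosslinkThreshold, ", carryover =", object@carryoverRate, "\n")
})

setMethod("show", "ReadLayout", function(object) {
    cat("ReadLayout: [barcode ", object@barcodeLen, "][UMI ", object@umiLen,
        "][junction ", nchar(object@junctionSeq), "-",
        nchar(object@junctionSeq) + 1L, "][cDNA <= ", object@cdnaMapLen,
        "]\n", sep = "")
})

setMethod("show", "TissuePhantom", function(object) {
    cat("TissuePhantom:", nrow(object@cells), "cells in",
        object@bounds[1L], "x", object@bounds[2L], "um\n")
    if (nrow(object@cells))
        print(table(region = object@cells$region,
                    species = object@cells$species))
})

setMethod("show", "TranscriptomeModel", function(object) {
    cat("TranscriptomeModel:", nrow(object@genes), "genes (",
        paste(unique(object@genes$species), collapse = " + "), "),",
        nrow(object@expression), "cell types\n")
})

setMethod("show", "SWParams", function(object) {
    cat("SWParams: match", object@match, "/ mismatch", object@mismatch,
        "/ gap", object@gapOpen, "+", object@gapExtend,
        "; accept >=", object@acceptThreshold, "\n")
})

setMethod("show", "UMICountMatrix", function(object) {
    cat("UMICountMatrix:", nrow(object@counts), "genes x",
        ncol(object@counts), "barcodes;", sum(object@counts),
        "molecules\n")
    print(colSums(object@counts))
})
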