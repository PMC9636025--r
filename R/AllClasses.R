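#' LabelMask: an integer-labelled photomask raster
#'
#' A 2-D raster in which pixel value 0 means unlabelled and a positive
#' integer \code{k} means the pixel belongs to the region of interest (ROI)
#' illuminated in barcoding round \code{k}. The physical scale is carried as
#' microns per pixel, with the physical origin at the raster corner and a
#' half-open pixel convention: pixel \code{[i, j]} covers
#' \code{[(j-1), j) x [(i-1), i)} in pixel units (row = y, column = x).
#'
#' @slot pixels integer matrix of non-negative labels.
#' @slot umPerPixel positive numeric, microns per pixel.
#'
#' @seealso [polygonToMask()], [erodeMask()], [scatterDose()]
#' @export
setClass("LabelMask",
    representation(pixels = "matrix", umPerPixel = "numeric"),
    validity = function(object) {
        px <- object@pixels
        if (!is.numeric(px)) return("'pixels' must be a numeric/integer matrix")
        if (any(px < 0) || any(px != floor(px)))
            return("'pixels' must contain non-negative integer labels")
        if (length(object@umPerPixel) != 1L || !is.finite(object@umPerPixel) ||
            object@umPerPixel <= 0)
            return("'umPerPixel' must be a single positive number")
        TRUE
    })

#' ScatterModel: out-of-ROI light scatter and wash noise parameters
#'
#' Mechanistic stand-in for out-of-ROI barcoding: the binary round mask is
#' blurred with a Gaussian of physical scale \code{sigmaUm}; a molecule
#' crosslinks where the blurred dose reaches \code{crosslinkThreshold}, and
#' an uncrosslinked barcode survives the stringent washes with probability
#' \code{carryoverRate}.
#'
#' @slot sigmaUm Gaussian blur scale in microns (>= 0).
#' @slot crosslinkThreshold dose level in (0, 1] above which crosslinking
#'   occurs.
#' @slot carryoverRate probability in [0, 1) that an uncrosslinked barcode
#'   survives the washes.
#' @export
setClass("ScatterModel",
    representation(sigmaUm = "numeric", crosslinkThreshold = "numeric",
                   carryoverRate = "numeric"),
    prototype(sigmaUm = 0, crosslinkThreshold = 0.5, carryoverRate = 0),
    validity = function(object) {
        if (object@sigmaUm < 0) return("'sigmaUm' must be >= 0")
        if (object@crosslinkThreshold <= 0 || object@crosslinkThreshold > 1)
            return("'crosslinkThreshold' must be in (0, 1]")
        if (object@carryoverRate < 0 || object@carryoverRate >= 1)
            return("'carryoverRate' must be in [0, 1)")
        TRUE
    })

#' ReadLayout: declarative structure of a barcoded Read 1
#'
#' Read 1 of a light-barcoded library is
#' \code{[barcode][UMI][junction remnant][cDNA]}. The junction remnant is
#' the shared priming ("P") domain copied across the crosslink junction; it
#' is typically 7 nt and becomes 8 nt when the strand-displacing polymerase
#' A-tails, so the extra base is an A on the read strand.
#'
#' @slot barcodeLen barcode length in nt (default 12).
#' @slot umiLen UMI length in nt (default 8; 4^8 = 65,536 possible UMIs).
#' @slot junctionSeq the 7-nt junction domain as read on Read 1.
#' @slot junctionExtendProb probability the remnant carries the A-tail base
#'   (8 nt total).
#' @slot junctionExtensionBase the single extension base ("A").
#' @slot cdnaMapLen maximum mappable cDNA length in nt (default 40).
#' @slot atailMin,atailMax uniform bounds on the Read 2 leading T-run length.
#' @export
setClass("ReadLayout",
    representation(barcodeLen = "integer", umiLen = "integer",
                   junctionSeq = "character", junctionExtendProb = "numeric",
                   junctionExtensionBase = "character", cdnaMapLen = "integer",
                   atailMin = "integer", atailMax = "integer"),
    prototype(barcodeLen = 12L, umiLen = 8L, junctionSeq = "TCAGGTC",
              junctionExtendProb = 0.5, junctionExtensionBase = "A",
              cdnaMapLen = 40L, atailMin = 5L, atailMax = 15L),
    validity = function(object) {
        if (object@barcodeLen < 1L) return("'barcodeLen' must be positive")
        if (object@umiLen < 1L) return("'umiLen' must be positive")
        if (nchar(object@junctionSeq) < 1L)
            return("'junctionSeq' must be non-empty")
        if (object@junctionExtendProb < 0 || object@junctionExtendProb > 1)
            return("'junctionExtendProb' must be in [0, 1]")
        if (nchar(object@junctionExtensionBase) != 1L)
            return("'junctionExtensionBase' must be a single base")
        if (object@cdnaMapLen < 1L) return("'cdnaMapLen' must be positive")
        if (object@atailMin < 0L || object@atailMax < object@atailMin)
            return("invalid A-tail length bounds")
        TRUE
    })

#' TissuePhantom: synthetic cells with positions and labels
#'
#' A field of non-overlapping circular cells, each carrying a species tag, a
#' cell-type tag and the region it was seeded in. Coordinates are microns
#' with the origin at the field corner.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{radius_um}, \code{species}, \code{cell_type},
#'   \code{region}.
#' @slot bounds numeric length-2 field size (width, height) in microns.
#' @export
setClass("TissuePhantom",
    representation(cells = "data.frame", bounds = "numeric"),
    validity = function(object) {
        cl <- object@cells
        need <- c("cell_id", "x_um", "y_um", "radius_um", "species",
                  "cell_type", "region")
        if (!all(need %in% names(cl)))
            return(paste("'cells' must have columns:",
                         paste(need, collapse = ", ")))
        if (anyDuplicated(cl$cell_id)) return("'cell_id' must be unique")
        if (nrow(cl) && any(cl$radius_um <= 0)) return("radii must be > 0")
        if (length(object@bounds) != 2L || any(object@bounds <= 0))
            return("'bounds' must be two positive numbers")
        if (nrow(cl) && (any(cl$x_um < 0 | cl$x_um > object@bounds[1L]) ||
                         any(cl$y_um < 0 | cl$y_um > object@bounds[2L])))
            return("cell centroids must lie within bounds")
        TRUE
    })

#' TranscriptomeModel: a (possibly merged two-species) synthetic transcriptome
#'
#' Gene sequences plus per-(cell type, gene) mean expression, emulating a
#' merged multi-species reference in which every gene id is unique.
#'
#' @slot sequences [Biostrings::DNAStringSet] named by gene id.
#' @slot genes data.frame with columns \code{gene_id}, \code{species},
#'   \code{length_nt}, \code{biotype}.
#' @slot expression numeric matrix of mean transcripts per cell,
#'   cell types x genes.
#' @export
setClass("TranscriptomeModel",
    representation(sequences = "DNAStringSet", genes = "data.frame",
                   expression = "matrix"),
    validity = function(object) {
        g <- object@genes
        need <- c("gene_id", "species", "length_nt", "biotype")
        if (!all(need %in% names(g)))
            return(paste("'genes' must have columns:",
                         paste(need, collapse = ", ")))
        if (anyDuplicated(g$gene_id))
            return("gene ids must be unique across species")
        if (!identical(names(object@sequences), g$gene_id))
            return("'sequences' names must equal genes$gene_id in order")
        if (!identical(unname(Biostrings::width(object@sequences)),
                       as.integer(g$length_nt)))
            return("'length_nt' must equal sequence lengths")
        if (!identical(colnames(object@expression), g$gene_id))
            return("'expression' columns must equal gene ids")
        if (any(object@expression < 0)) return("expression must be >= 0")
        TRUE
    })

#' SWParams: local-alignment scoring used for rescue
#'
#' Affine-gap Smith-Waterman scoring. A gap of length L costs
#' \code{gapOpen + (L - 1) * gapExtend} (striped-SW convention). Reads are
#' rescued when the best local score against the rescue sequence reaches
#' \code{acceptThreshold}.
#'
#' @slot match positive match score (default 2).
#' @slot mismatch negative mismatch score (default -3).
#' @slot gapOpen positive cost of the first gapped base (default 5).
#' @slot gapExtend positive cost of each further gapped base (default 2).
#' @slot acceptThreshold minimum score for rescue (default 40).
#' @export
setClass("SWParams",
    representation(match = "numeric", mismatch = "numeric", gapOpen = "numeric",
                   gapExtend = "numeric", acceptThreshold = "numeric"),
    prototype(match = 2, mismatch = -3, gapOpen = 5, gapExtend = 2,
              acceptThreshold = 40),
    validity = function(object) {
        if (object@match <= 0) return("'match' must be positive")
        if (object@mismatch >= 0) return("'mismatch' must be negative")
        if (object@gapOpen < 0 || object@gapExtend < 0)
            return("gap penalties must be non-negative")
        if (object@acceptThreshold <= 0)
            return("'acceptThreshold' must be positive")
        TRUE
    })

#' UMICountMatrix: deduplicated molecule counts per gene and barcode
#'
#' @slot counts integer matrix, genes x barcodes, of deduplicated molecule
#'   counts.
#' @export
setClass("UMICountMatrix",
    representation(counts = "matrix"),
    validity = function(object) {
        cn <- object@counts
        if (any(cn < 0) || any(cn != floor(cn)))
            return("counts must be non-negative integers")
        if (is.null(rownames(cn)) || is.null(colnames(cn)))
            return("counts must have gene rownames and barcode colnames")
        TRUE
    })

# ---- constructors ----------------------------------------------------------

#' Create a LabelMask
#'
#' @param pixels integer matrix of non-negative labels (0 = unlabelled).
#' @param umPerPixel microns per pixel (> 0).
#' @return a [LabelMask-class] object.
#' @examples
#' m <- LabelMask(matrix(0L, 10, 10), umPerPixel = 1)
#' @export
LabelMask <- function(pixels, umPerPixel = 1) {
    storage.mode(pixels) <- "integer"
    new("LabelMask", pixels = pixels, umPerPixel = as.numeric(umPerPixel))
}

#' Create a ScatterModel
#'
#' @param sigmaUm Gaussian blur scale in microns.
#' @param crosslinkThreshold dose threshold in (0, 1].
#' @param carryoverRate wash carryover probability in [0, 1).
#' @return a [ScatterModel-class] object.
#' @export
ScatterModel <- function(sigmaUm = 0, crosslinkThreshold = 0.5,
                         carryoverRate = 0) {
    new("ScatterModel", sigmaUm = sigmaUm,
        crosslinkThreshold = crosslinkThreshold, carryoverRate = carryoverRate)
}

#' Create a ReadLayout
#'
#' @param barcodeLen,umiLen,cdnaMapLen segment lengths in nt.
#' @param junctionSeq 7-nt junction domain as read on Read 1.
#' @param junctionExtendProb probability of the 8-nt (A-tailed) remnant.
#' @param junctionExtensionBase the A-tail base.
#' @param atailMin,atailMax Read 2 leading T-run length bounds.
#' @return a [ReadLayout-class] object.
#' @examples
#' ReadLayout()  # default 12 + 8 + 7/8 + up to 40 nt
#' @export
ReadLayout <- function(barcodeLen = 12L, umiLen = 8L, junctionSeq = "TCAGGTC",
                       junctionExtendProb = 0.5, junctionExtensionBase = "A",
                       cdnaMapLen = 40L, atailMin = 5L, atailMax = 15L) {
    new("ReadLayout", barcodeLen = as.integer(barcodeLen),
        umiLen = as.integer(umiLen), junctionSeq = junctionSeq,
        junctionExtendProb = junctionExtendProb,
        junctionExtensionBase = junctionExtensionBase,
        cdnaMapLen = as.integer(cdnaMapLen), atailMin = as.integer(atailMin),
        atailMax = as.integer(atailMax))
}

#' Create SWParams
#'
#' @param match,mismatch,gapOpen,gapExtend,acceptThreshold scoring values;
#'   see [SWParams-class].
#' @return an [SWParams-class] object.
#' @export
SWParams <- function(match = 2, mismatch = -3, gapOpen = 5, gapExtend = 2,
                     acceptThreshold = 40) {
    new("SWParams", match = match, mismatch = mismatch, gapOpen = gapOpen,
        gapExtend = gapExtend, acceptThreshold = acceptThreshold)
}

#' Create a UMICountMatrix
#'
#' @param counts integer matrix with gene rownames and barcode colnames.
#' @return a [UMICountMatrix-class] object.
#' @export
UMICountMatrix <- function(counts) {
    storage.mode(counts) <- "integer"
    new("UMICountMatrix", counts = counts)
}
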