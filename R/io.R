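# Plain-text interchange: FASTQ, mask TSV + sidecar scale, count exports.

#' Write reads as FASTQ
#'
#' Four-line records with constant Phred+33 dummy qualities ("I").
#'
#' @param reads named character vector of sequences.
#' @param path output path (".gz" accepted).
#' @return invisibly, the path.
#' @export
writeFastq <- function(reads, path) {
    x <- Biostrings::DNAStringSet(unname(reads))
    names(x) <- names(reads)
    Biostrings::writeXStringSet(
        x, path, format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(reads))),
        compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Read FASTQ into a named character vector
#'
#' @param path FASTQ path (gz accepted).
#' @return named character vector of sequences.
#' @export
readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    setNames(as.character(x), names(x))
}

#' Write / read a LabelMask as a plain TSV raster
#'
#' The physical scale rides in a `# um_per_pixel:` comment on the first
#' line, so a mask round-trips through a single text file.
#'
#' @param mask a [LabelMask-class].
#' @param path TSV path.
#' @return invisibly the path / the [LabelMask-class].
#' @export
writeMaskTSV <- function(mask, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# um_per_pixel: ", umPerPixel(mask)), con)
    write.table(pixels(mask), con, sep = "\t", row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeMaskTSV
#' @export
readMaskTSV <- function(path) {
    first <- readLines(path, n = 1L)
    if (!grepl("^# um_per_pixel:", first))
        stop("missing '# um_per_pixel:' header line")
    upp <- as.numeric(sub("^# um_per_pixel:\\s*", "", first))
    px <- as.matrix(read.delim(path, header = FALSE, comment.char = "#"))
    dimnames(px) <- NULL
    LabelMask(px, upp)
}

#' Export a UMICountMatrix
#'
#' \code{exportCountsTSV} writes a genes x barcodes TSV;
#' \code{exportCountsMTX} writes MatrixMarket plus row/column name files.
#'
#' @param x a [UMICountMatrix-class].
#' @param path output path (for MTX, the \code{.mtx} path; names go to
#'   \code{<path>.genes.txt} / \code{<path>.barcodes.txt}).
#' @return invisibly, the path.
#' @export
exportCountsTSV <- function(x, path) {
    write.table(data.frame(gene_id = rownames(umiCounts(x)),
                           umiCounts(x), check.names = FALSE),
                path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname exportCountsTSV
#' @export
exportCountsMTX <- function(x, path) {
    m <- Matrix::Matrix(umiCounts(x), sparse = TRUE)
    Matrix::writeMM(m, path)
    writeLines(rownames(umiCounts(x)), paste0(path, ".genes.txt"))
    writeLines(colnames(umiCounts(x)), paste0(path, ".barcodes.txt"))
    invisible(path)
}

#' Write / read a barcode whitelist TSV
#'
#' @param whitelist data.frame from [barcodeWhitelist()].
#' @param path TSV path.
#' @return invisibly the path / the whitelist data.frame.
#' @export
writeWhitelistTSV <- function(whitelist, path) {
    write.table(whitelist, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeWhitelistTSV
#' @export
readWhitelistTSV <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}
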