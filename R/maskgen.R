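#' Rasterize ROI polygons into a photomask
#'
#' Converts hand-drawn ROI polygons (micron coordinates) into an integer
#' label raster by the pixel-center rule: a pixel receives label \code{k}
#' iff its center lies inside polygon \code{k} (even-odd crossing rule).
#' Later polygons overwrite earlier ones on overlap, mirroring iterative
#' barcoding rounds where a cDNA crosslinks only once.
#'
#' @param polygons list of closed polygons; each a 2-column matrix or
#'   data.frame of (x_um, y_um) vertices (the closing edge is implicit).
#' @param labels integer vector of distinct positive labels, one per polygon.
#' @param umPerPixel microns per pixel of the output raster.
#' @param widthUm,heightUm physical raster size in microns.
#' @return a [LabelMask-class]. Row i / column j of the raster covers the
#'   half-open pixel \code{[(j-1), j) x [(i-1), i)} in pixel units, origin at
#'   the raster corner.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' m <- polygonToMask(list(sq), labels = 1L, umPerPixel = 1,
#'                    widthUm = 20, heightUm = 20)
#' sum(pixels(m) == 1L)  # 100 px = 100 um^2
#' @export
polygonToMask <- function(polygons, labels, umPerPixel, widthUm, heightUm) {
    if (length(polygons) != length(labels))
        stop("'polygons' and 'labels' must have equal length")
    if (any(labels <= 0) || anyDuplicated(labels))
        stop("'labels' must be distinct positive integers")
    nc <- as.integer(round(widthUm / umPerPixel))
    nr <- as.integer(round(heightUm / umPerPixel))
    if (nc < 1L || nr < 1L) stop("raster would be empty")
    cx <- (seq_len(nc) - 0.5) * umPerPixel
    cy <- (seq_len(nr) - 0.5) * umPerPixel
    px <- rep(cx, each = nr)          # column-major over (row=y, col=x)
    py <- rep(cy, times = nc)
    out <- matrix(0L, nr, nc)
    for (p in seq_along(polygons)) {
        v <- as.matrix(polygons[[p]])
        if (nrow(v) < 3L)
            stop("polygon ", p, " is degenerate (<3 vertices)")
        inside <- rep(FALSE, length(px))
        nv <- nrow(v)
        jprev <- nv
        for (i in seq_len(nv)) {
            x1 <- v[jprev, 1L]; y1 <- v[jprev, 2L]
            x2 <- v[i, 1L];     y2 <- v[i, 2L]
            crosses <- (y1 > py) != (y2 > py)
            if (any(crosses)) {
                xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
                hit <- px[crosses] < xint
                idx <- which(crosses)[hit]
                inside[idx] <- !inside[idx]
            }
            jprev <- i
        }
        out[inside] <- as.integer(labels[p])
    }
    LabelMask(out, umPerPixel)
}

#' Morphologically erode every labelled region of a mask
#'
#' Each label region is eroded by a Euclidean disk of radius
#' \code{distanceUm}: a pixel keeps its label iff every pixel within that
#' distance (including outside the raster, treated as background) carries
#' the same label. Drawing photomasks 1-3 um inside the intended boundary
#' compensates for out-of-ROI light scatter; regions may vanish entirely.
#'
#' @param mask a [LabelMask-class].
#' @param distanceUm erosion distance in microns (>= 0; 0 is the identity).
#' @return the eroded [LabelMask-class].
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' m <- polygonToMask(list(sq), 1L, 1, 20, 20)
#' sum(pixels(erodeMask(m, 1)) == 1L)  # 64 px: 8 x 8
#' @export
erodeMask <- function(mask, distanceUm) {
    stopifnot(is(mask, "LabelMask"))
    if (distanceUm < 0) stop("'distanceUm' must be >= 0")
    if (distanceUm == 0) return(mask)
    r <- distanceUm / umPerPixel(mask)
    ri <- as.integer(floor(r + 1e-9))
    off <- expand.grid(di = -ri:ri, dj = -ri:ri)
    off <- off[off$di^2 + off$dj^2 <= r^2 + 1e-9, , drop = FALSE]
    px <- pixels(mask)
    nr <- nrow(px); nc <- ncol(px)
    out <- matrix(0L, nr, nc)
    for (k in maskLabels(mask)) {
        ind <- px == k
        # pad so out-of-raster neighbours read as background
        pad <- matrix(FALSE, nr + 2L * ri, nc + 2L * ri)
        pad[ri + seq_len(nr), ri + seq_len(nc)] <- ind
        keep <- matrix(TRUE, nr, nc)
        for (o in seq_len(nrow(off))) {
            di <- off$di[o]; dj <- off$dj[o]
            keep <- keep & pad[ri + di + seq_len(nr), ri + dj + seq_len(nc)]
        }
        out[keep] <- k
    }
    LabelMask(out, umPerPixel(mask))
}

#' Error-diffusion dithering of a grayscale image
#'
#' Converts an intensity raster in [0, 1] into a binary photomask with
#' Floyd-Steinberg error diffusion (7/16 ahead, 3/16, 5/16, 1/16 into the
#' next row) on a serpentine (boustrophedon) scan, so the output is
#' bit-reproducible. Summed intensity is conserved up to the residual
#' carried off the final row.
#'
#' @param gray numeric matrix with values in [0, 1].
#' @return integer matrix in {0, 1} of the same dimensions.
#' @examples
#' d <- ditherToBinary(matrix(0.5, 8, 8))
#' mean(d)  # 0.5 within 1/64
#' @export
ditherToBinary <- function(gray) {
    if (!is.matrix(gray) || !is.numeric(gray))
        stop("'gray' must be a numeric matrix")
    if (any(gray < 0 | gray > 1)) stop("intensities must lie in [0, 1]")
    img <- gray
    nr <- nrow(img); nc <- ncol(img)
    out <- matrix(0L, nr, nc)
    for (i in seq_len(nr)) {
        ltr <- i %% 2L == 1L
        cols <- if (ltr) seq_len(nc) else rev(seq_len(nc))
        step <- if (ltr) 1L else -1L
        for (j in cols) {
            old <- img[i, j]
            new <- if (old >= 0.5) 1L else 0L
            out[i, j] <- new
            err <- old - new
            jf <- j + step
            if (jf >= 1L && jf <= nc) img[i, jf] <- img[i, jf] + err * 7 / 16
            if (i < nr) {
                jb <- j - step
                if (jb >= 1L && jb <= nc)
                    img[i + 1L, jb] <- img[i + 1L, jb] + err * 3 / 16
                img[i + 1L, j] <- img[i + 1L, j] + err * 5 / 16
                if (jf >= 1L && jf <= nc)
                    img[i + 1L, jf] <- img[i + 1L, jf] + err * 1 / 16
            }
        }
    }
    out
}

#' Gaussian light-scatter dose field for one barcoding round
#'
#' Convolves the binary mask of one round with a unit-mass discrete Gaussian
#' of physical scale \code{sigmaUm}, modelling light scatter around the
#' illuminated ROI. Over a large uniform region the dose approaches 1;
#' with \code{sigmaUm = 0} the dose equals the binary mask. Crosslinking is
#' then modelled downstream as a hard threshold on this dose.
#'
#' @param mask a [LabelMask-class].
#' @param roundId the round label whose ROI is illuminated. Absent labels
#'   give an all-zero dose.
#' @param model a [ScatterModel-class] supplying \code{sigmaUm}.
#' @return numeric matrix of doses in [0, 1], same dimensions as the mask.
#' @export
scatterDose <- function(mask, roundId, model = ScatterModel()) {
    stopifnot(is(mask, "LabelMask"), is(model, "ScatterModel"))
    bin <- (pixels(mask) == roundId) * 1
    sig <- model@sigmaUm / umPerPixel(mask)
    if (sig == 0) return(bin)
    R <- as.integer(ceiling(4 * sig))
    w <- exp(-((-R:R)^2) / (2 * sig^2))
    w <- w / sum(w)
    convolveAxis <- function(m, along) {
        nr <- nrow(m); nc <- ncol(m)
        acc <- matrix(0, nr, nc)
        if (along == "rows") {  # shift columns
            pad <- matrix(0, nr, nc + 2L * R)
            pad[, R + seq_len(nc)] <- m
            for (k in -R:R)
                acc <- acc + w[k + R + 1L] * pad[, R + k + seq_len(nc)]
        } else {
            pad <- matrix(0, nr + 2L * R, nc)
            pad[R + seq_len(nr), ] <- m
            for (k in -R:R)
                acc <- acc + w[k + R + 1L] * pad[R + k + seq_len(nr), ]
        }
        acc
    }
    convolveAxis(convolveAxis(bin, "rows"), "cols")
}

#' Physical area of one labelled region
#'
#' @param mask a [LabelMask-class].
#' @param label the round label.
#' @return area in square microns.
#' @export
maskArea <- function(mask, label) {
    sum(pixels(mask) == label) * umPerPixel(mask)^2
}
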