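# Independent reference implementations used to cross-check the package.

# quadratic affine-gap local alignment DP (gap of length L costs
# open + (L - 1) * ext)
swOracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
    a <- strsplit(a, "")[[1L]]
    b <- strsplit(b, "")[[1L]]
    n <- length(a); m <- length(b)
    H <- matrix(0, n + 1L, m + 1L)
    E <- matrix(-Inf, n + 1L, m + 1L)
    Fm <- matrix(-Inf, n + 1L, m + 1L)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open, E[i + 1L, j] - ext)
            Fm[i + 1L, j + 1L] <- max(H[i, j + 1L] - open, Fm[i, j + 1L] - ext)
            sc <- if (a[i] == b[j]) match else mismatch
            H[i + 1L, j + 1L] <- max(0, H[i, j] + sc,
                                     E[i + 1L, j + 1L], Fm[i + 1L, j + 1L])
            best <- max(best, H[i + 1L, j + 1L])
        }
    }
    best
}

# brute-force directional UMI collapse: explicit adjacency matrix +
# recursive depth-first absorption from count-sorted roots
dedupOracle <- function(umis) {
    tab <- table(umis)
    cnt <- as.integer(tab)
    u <- names(tab)
    n <- length(u)
    if (n == 0L) return(0L)
    ham <- function(x, y) sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
    D <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) ham(u[i], u[j])))
    ord <- order(-cnt, u)
    visited <- logical(n)
    nclust <- 0L
    absorb <- function(i) {
        for (j in seq_len(n)) {
            if (!visited[j] && D[i, j] == 1L && cnt[i] >= 2L * cnt[j] - 1L) {
                visited[j] <<- TRUE
                absorb(j)
            }
        }
    }
    for (i in ord) {
        if (visited[i]) next
        visited[i] <- TRUE
        nclust <- nclust + 1L
        absorb(i)
    }
    nclust
}

# brute-force even-odd point-in-polygon for a single point
pipOracle <- function(px, py, poly) {
    n <- nrow(poly)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
        xi <- poly[i, 1L]; yi <- poly[i, 2L]
        xj <- poly[j, 1L]; yj <- poly[j, 2L]
        if ((yi > py) != (yj > py)) {
            xcross <- xi + (py - yi) * (xj - xi) / (yj - yi)
            if (px < xcross) inside <- !inside
        }
        j <- i
    }
    inside
}

# brute-force disk erosion: pixel kept iff every pixel within radius r
# (Euclidean, in px) carries the same label; outside the raster = background
erodeOracle <- function(px, r) {
    nr <- nrow(px); nc <- ncol(px)
    out <- matrix(0L, nr, nc)
    ri <- floor(r + 1e-9)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        k <- px[i, j]
        if (k == 0L) next
        keep <- TRUE
        for (di in -ri:ri) for (dj in -ri:ri) {
            if (di^2 + dj^2 > r^2 + 1e-9) next
            ii <- i + di; jj <- j + dj
            if (ii < 1L || ii > nr || jj < 1L || jj > nc || px[ii, jj] != k) {
                keep <- FALSE; break
            }
        }
        if (keep) out[i, j] <- k
    }
    out
}
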