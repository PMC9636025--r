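# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# n random DNA strings of the given width, as a character vector
randomDNA <- function(n, width) {
    if (n == 0L) return(character(0))
    m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# vectorized per-position mismatch count between equal-width string vectors
mismatchCount <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (!length(a)) return(integer(0))
    wa <- nchar(a)
    if (any(wa != nchar(b)))
        stop("mismatchCount requires pairwise equal widths")
    out <- integer(length(a))
    for (w in unique(wa)) {
        idx <- which(wa == w)
        ma <- matrix(utf8ToInt(paste(a[idx], collapse = "")), nrow = w)
        mb <- matrix(utf8ToInt(paste(b[idx], collapse = "")), nrow = w)
        out[idx] <- colSums(ma != mb)
    }
    out
}

# reverse complement for plain character vectors
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# i.i.d. substitution errors at rate `rate` applied to a character vector
injectSubstitutions <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    total <- sum(nchar(seqs))
    nerr <- rbinom(1L, total, rate)
    if (nerr == 0L) return(seqs)
    chars <- strsplit(paste(seqs, collapse = ""), "")[[1L]]
    pos <- sample.int(total, nerr)
    # substitute with a uniformly chosen different base
    repl <- vapply(chars[pos],
                   function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    chars[pos] <- repl
    ends <- cumsum(nchar(seqs))
    starts <- c(1L, head(ends, -1L) + 1L)
    joined <- paste(chars, collapse = "")
    substring(joined, starts, ends)
}

# exact binomial-style normal-approximation CI bounds used in recovery tests
binomCI <- function(p, n, level = 0.99) {
    z <- qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    c(lower = p - half, upper = p + half)
}
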