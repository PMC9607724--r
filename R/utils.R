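# Internal sequence utilities shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Vector of random DNA strings with the given lengths (length 0 -> "").
random_dna <- function(lengths) {
  total <- sum(lengths)
  if (total == 0) return(rep("", length(lengths)))
  bases <- sample(DNA_BASES, total, replace = TRUE)
  idx <- rep.int(seq_along(lengths), lengths)
  out <- rep("", length(lengths))
  filled <- vapply(split(bases, idx), paste, character(1), collapse = "")
  out[as.integer(names(filled))] <- filled
  out
}

# Geometric draw (number of failures, mean = mu) truncated at cap.
# mu may be a vector (recycled against n).
rgeom_capped <- function(n, mu, cap) {
  mu <- rep_len(mu, n)
  x <- integer(n)
  pos <- mu > 0
  if (any(pos)) x[pos] <- rgeom(sum(pos), prob = 1 / (1 + mu[pos]))
  pmin(x, cap)
}

# Translate nucleotide strings (length multiple of 3) to amino acids.
translate_nt <- function(nt) {
  if (length(nt) == 0) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     if.fuzzy.codon = "X"))
}

# Positional amino-acid identity between equal-length strings, in percent.
# Vectorized over pairs; errors if any pair has unequal lengths.
positional_identity <- function(a, b) {
  la <- nchar(a)
  if (any(la != nchar(b))) {
    rc_abort("positional identity requires equal-length sequences",
             "length_mismatch")
  }
  n <- length(a)
  out <- numeric(n)
  for (len in unique(la)) {
    sel <- which(la == len)
    if (len == 0) { out[sel] <- 100; next }
    ma <- matrix(unlist(strsplit(a[sel], "", fixed = TRUE)),
                 ncol = len, byrow = TRUE)
    mb <- matrix(unlist(strsplit(b[sel], "", fixed = TRUE)),
                 ncol = len, byrow = TRUE)
    out[sel] <- 100 * rowSums(ma == mb) / len
  }
  out
}

# Number of mismatching characters between equal-length strings (vectorized).
hamming_nt <- function(a, b) {
  la <- nchar(a)
  stopifnot(all(la == nchar(b)))
  round((1 - positional_identity(a, b) / 100) * la)
}

# All unordered index pairs i<j within a vector of group labels, restricted to
# groups of size >= 2. Returns a two-column integer matrix.
pairs_within_groups <- function(labels) {
  idx <- split(seq_along(labels), labels)
  idx <- idx[lengths(idx) >= 2L]
  if (length(idx) == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  }
  out <- lapply(idx, function(v) {
    cm <- utils::combn(v, 2L)
    matrix(c(cm[1, ], cm[2, ]), ncol = 2)
  })
  out <- do.call(rbind, out)
  colnames(out) <- c("i", "j")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
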