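#' @include AllClasses.R
NULL

# Canonical amino-acid alphabet used throughout (emission column order).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average amino-acid composition of well-curated protein databases
# (Swiss-Prot-like frequencies, renormalized). Used as the default
# residue background for sequence simulation and null-model sampling.
AA_COMPOSITION <- c(
  A = 0.0826, C = 0.0136, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0394, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292)
AA_COMPOSITION <- AA_COMPOSITION / sum(AA_COMPOSITION)

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

HYDROPHOBIC_AA <- c("A", "F", "I", "L", "M", "V")
POLAR_AA <- setdiff(AA20, HYDROPHOBIC_AA)

# Digitize an amino-acid string into 0-based codes over AA20; X (and any
# residue outside the canonical 20) becomes code 20 and scores as background.
digitizeAA <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], AA20) - 1L
  codes[is.na(codes)] <- 20L
  codes
}

# Map non-canonical residues (B, Z, U, O and anything else outside the
# canonical 20 + X) to X, with a logged warning.
canonicalizeAA <- function(seqs) {
  chars <- unique(unlist(strsplit(as.character(seqs), "")))
  bad <- setdiff(chars, c(AA20, "X"))
  if (length(bad)) {
    warning("non-canonical residues mapped to X: ",
            paste(sort(bad), collapse = ", "), call. = FALSE)
    out <- as.character(seqs)
    for (b in bad) out <- gsub(b, "X", out, fixed = TRUE)
    nm <- names(seqs)
    seqs <- Biostrings::AAStringSet(out)
    names(seqs) <- nm
  }
  seqs
}

# Sample a random amino-acid sequence from a residue composition.
randomAASeq <- function(n, composition = AA_COMPOSITION) {
  paste(sample(AA20, n, replace = TRUE, prob = composition[AA20]),
        collapse = "")
}

# Method-of-moments Gumbel fit: location mu, scale beta.
fitGumbelMoments <- function(x) {
  beta <- stats::sd(x) * sqrt(6) / pi
  mu <- mean(x) - 0.5772156649015329 * beta
  c(mu = mu, beta = beta)
}

# Tail-weighted Gumbel fit (peaks over threshold): the scale is the mean
# exceedance over the upper-tail threshold and the location is set so the
# fitted upper-tail mass at the threshold matches its empirical value.
# Far more accurate than a moments fit where E-values live (the extreme
# tail), at the price of ignoring the bulk.
fitGumbelTail <- function(x, tailFrac = 0.3) {
  tau <- stats::quantile(x, 1 - tailFrac, names = FALSE)
  exceed <- x[x > tau] - tau
  if (length(exceed) < 5 || mean(exceed) <= 0) return(fitGumbelMoments(x))
  beta <- mean(exceed)
  mu <- tau - beta * (-log(-log(1 - tailFrac)))
  c(mu = mu, beta = beta)
}

# Upper-tail probability of a Gumbel(mu, beta), floored away from zero so
# downstream E-values stay strictly positive.
gumbelUpperTail <- function(x, mu, beta) {
  z <- (x - mu) / beta
  p <- -expm1(-exp(-z))
  pmax(p, 1e-320)
}

# All overlapping k-mers of a sequence (character vector).
seqKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
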