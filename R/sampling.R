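#' Low-discrepancy sequences on the unit hypercube
#'
#' `hammersley_nodes()` returns the first `n` points of a Hammersley set in
#' `d` dimensions: the first coordinate is the equispaced sequence
#' `(i - 1/2) / n` and the remaining `d - 1` coordinates are radical-inverse
#' (van der Corput) sequences in the first `d - 1` prime bases, evaluated at
#' indices `1..n`. The half-integer offset on the first coordinate and the
#' use of indices starting at one keep every node strictly inside the open
#' hypercube, where inverse CDFs are finite.
#'
#' `halton_nodes()` drops the equispaced coordinate and uses radical
#' inverses in the first `d` prime bases; unlike the Hammersley set it is
#' extensible in `n`. An optional Cranley-Patterson rotation (a random shift
#' modulo one, drawn from R's RNG) decorrelates the higher-base coordinates
#' and makes independent randomised replicates possible while preserving
#' low discrepancy.
#'
#' @param n Number of points.
#' @param d Dimension.
#' @return An `n` x `d` matrix with entries in the open interval (0, 1).
#' @examples
#' hammersley_nodes(4, 2)
#' @export
hammersley_nodes <- function(n, d) {
  stopifnot(n >= 1, d >= 1)
  out <- matrix(0, n, d)
  out[, 1] <- (seq_len(n) - 0.5) / n
  if (d > 1) {
    bases <- prime_bases(d - 1)
    for (j in seq_len(d - 1)) {
      out[, j + 1] <- radical_inverse(seq_len(n), bases[j])
    }
  }
  out
}

#' @rdname hammersley_nodes
#' @param shift Logical; apply a random shift modulo one (uses the current
#'   RNG state, so wrap in [withr::with_seed()] or set a seed for
#'   reproducibility).
#' @param start Index of the first sequence element (larger values skip the
#'   initial, most structured part of the sequence).
#' @export
halton_nodes <- function(n, d, shift = FALSE, start = 1L) {
  stopifnot(n >= 1, d >= 1, start >= 1)
  bases <- prime_bases(d)
  out <- matrix(0, n, d)
  idx <- seq.int(start, length.out = n)
  for (j in seq_len(d)) {
    out[, j] <- radical_inverse(idx, bases[j])
  }
  if (shift) {
    s <- stats::runif(d)
    out <- sweep(out, 2, s, "+") %% 1
    # keep nodes off the boundary after the shift
    eps <- 1e-12
    out[out < eps] <- eps
    out[out > 1 - eps] <- 1 - eps
  }
  out
}

#' Radical inverse (van der Corput) sequence
#'
#' Reflects the base-`b` digits of each index about the radix point:
#' index `i = sum(a_k b^k)` maps to `sum(a_k b^(-k-1))`.
#'
#' @param i Vector of non-negative integer indices.
#' @param base Integer base (a prime for use in Halton/Hammersley sets).
#' @return Numeric vector in `[0, 1)`.
#' @export
radical_inverse <- function(i, base) {
  i <- as.double(i)
  out <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

# First k primes (enough for any realistic parameter dimension).
prime_bases <- function(k) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113,
              127, 131, 137, 139, 149, 151, 157, 163, 167, 173)
  if (k > length(primes)) stop("dimension too large: at most ",
                               length(primes) + 1, " supported", call. = FALSE)
  primes[seq_len(k)]
}

#' Draw parameter samples through the joint distribution
#'
#' Maps a Hammersley set through the (inverse) Rosenblatt transformation of
#' the joint, yielding a deterministic low-discrepancy sample of the
#' parameters.
#'
#' @inheritParams rosenblatt_inverse
#' @param n Number of samples.
#' @export
sample_joint <- function(joint, n) {
  rosenblatt_inverse(joint, hammersley_nodes(n, joint$d))
}
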