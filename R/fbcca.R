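#' FBCCA parameter set
#'
#' Collects everything the target-identification stage needs: the candidate
#' stimulation frequencies, the number of reference harmonics H, the
#' sub-band bank, and the sub-band weighting constants. The presets follow
#' the two standard stimulation sets: low (6.67, 7.50, 8.57 Hz; H = 4;
#' sub-bands 2-60 / 12-60 / 20-60 Hz; weights n^-1.25 + 0.25) and high
#' (36, 40, 45 Hz; H = 1; single band 35-60 Hz, weight fixed to 1 so the
#' combined score is the raw correlation and margins are scale-comparable
#' across sets).
#'
#' @param set `"low"` or `"high"` preset, or `NULL` to specify everything.
#' @param frequencies Candidate frequencies in Hz (distinct, positive).
#' @param harmonics Number of sinusoidal components per reference (H >= 1).
#' @param subbands A [subband_bank()].
#' @param weight_a,weight_b Sub-band weight constants: `w(n) = n^-a + b`.
#' @param combine_squared Fuse squared correlations instead of raw ones.
#' @param fs Sampling rate in Hz.
#' @return An object of class `fbcca_params`.
#' @export
fbcca_params <- function(set = c("low", "high"), frequencies = NULL,
                         harmonics = NULL, subbands = NULL,
                         weight_a = 1.25, weight_b = 0.25,
                         combine_squared = FALSE, fs = 600) {
  if (!is.null(set)) {
    set <- match.arg(set)
    if (is.null(frequencies)) {
      frequencies <- if (set == "low") c(6.67, 7.50, 8.57) else c(36, 40, 45)
    }
    if (is.null(harmonics)) harmonics <- if (set == "low") 4L else 1L
    if (is.null(subbands)) subbands <- standard_subband_bank(set, fs = fs)
  }
  if (is.null(frequencies) || is.null(harmonics) || is.null(subbands)) {
    stop("frequencies, harmonics and subbands are required when no preset is used",
         call. = FALSE)
  }
  if (any(frequencies <= 0) || anyDuplicated(frequencies)) {
    stop("frequencies must be distinct and positive", call. = FALSE)
  }
  if (harmonics < 1) stop("harmonics must be >= 1", call. = FALSE)
  if (harmonics * max(frequencies) >= fs / 2) {
    stop("highest reference harmonic exceeds Nyquist", call. = FALSE)
  }
  structure(list(set = if (is.null(set)) "custom" else set,
                 frequencies = as.numeric(frequencies),
                 harmonics = as.integer(harmonics), subbands = subbands,
                 weight_a = weight_a, weight_b = weight_b,
                 combine_squared = isTRUE(combine_squared), fs = fs),
            class = "fbcca_params")
}

#' Sine-cosine reference matrix for a candidate frequency
#'
#' Builds the 2H x N matrix whose row pairs are
#' `sin(2*pi*h*f*n/fs)`, `cos(2*pi*h*f*n/fs)` for h = 1..H and
#' n = 0..N-1. The time index restarts at 0 for every buffer snapshot;
#' canonical correlation with a sine/cosine pair is phase-invariant, so
#' alignment with stimulus onset is immaterial.
#'
#' @param f_k Candidate frequency in Hz.
#' @param H Number of harmonics (fundamental counted as h = 1).
#' @param fs Sampling rate in Hz.
#' @param n_samples Number of columns N.
#' @return A numeric 2H x N matrix.
#' @export
build_reference <- function(f_k, H, fs, n_samples) {
  if (H * f_k >= fs / 2) {
    stop("reference harmonic exceeds Nyquist; reduce H", call. = FALSE)
  }
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  t <- (seq_len(n_samples) - 1) / fs
  Y <- matrix(0, nrow = 2L * H, ncol = n_samples)
  for (h in seq_len(H)) {
    w <- 2 * pi * h * f_k
    Y[2 * h - 1, ] <- sin(w * t)
    Y[2 * h, ] <- cos(w * t)
  }
  Y
}

#' First canonical correlation between two multichannel signals
#'
#' Computes the largest canonical correlation between the row spaces of `X`
#' (channels x N) and `Y` (2H x N) by the numerically stable orthogonal
#' route: row-mean-center, thin QR of each transposed matrix with
#' rank-revealing tolerance, then the largest singular value of Q_x' Q_y.
#' Rank truncation (relative tolerance `tol`) guards near-degenerate buffers
#' from producing spurious correlations of 1.
#'
#' @param X Numeric matrix, variables in rows, samples in columns.
#' @param Y Numeric matrix, same number of columns as `X`.
#' @param tol Relative rank tolerance for the QR decompositions.
#' @return The first canonical correlation, clipped to `[0, 1]`.
#' @export
canonical_correlation <- function(X, Y, tol = 1e-7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- ncol(X)
  if (ncol(Y) != n) stop("X and Y must have the same number of samples", call. = FALSE)
  if (n <= max(nrow(X), nrow(Y))) {
    stop("need more samples than variables in either set", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  if (any(rowSums(Xc^2) == 0)) {
    stop("degenerate input: zero-variance channel in X", call. = FALSE)
  }
  Qx <- qr_basis(t(Xc), tol)
  Qy <- qr_basis(t(Yc), tol)
  if (ncol(Qx) == 0L || ncol(Qy) == 0L) {
    stop("degenerate input: rank-zero matrix", call. = FALSE)
  }
  rho <- svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d[1]
  min(max(rho, 0), 1)
}

qr_basis <- function(M, tol) {
  dec <- qr(M, tol = tol)
  qr.Q(dec)[, seq_len(dec$rank), drop = FALSE]
}

#' Sub-band fusion weight
#'
#' Decaying weight `w(n) = n^-a + b` for 1-based sub-band number `n`,
#' emphasising lower sub-bands, which retain the more reliable SSVEP
#' content. With defaults a = 1.25, b = 0.25: w(1) = 1.25,
#' w(2) ~ 0.6705, w(3) ~ 0.5027.
#'
#' @param n 1-based sub-band number.
#' @param a Decay exponent.
#' @param b Offset.
#' @return The weight.
#' @export
subband_weight <- function(n, a = 1.25, b = 0.25) {
  if (any(n < 1)) stop("sub-band number must be >= 1", call. = FALSE)
  n^(-a) + b
}

# Reference-basis cache: the orthonormal basis of a reference matrix depends
# only on (f, H, fs, N), and the streaming engine re-scores overlapping
# buffer lengths constantly, so memoization removes most of the QR cost.
.ref_cache <- new.env(parent = emptyenv())

reference_basis <- function(f_k, H, fs, n_samples, tol = 1e-7) {
  key <- paste(format(f_k, digits = 12), H, fs, n_samples, sep = "|")
  hit <- .ref_cache[[key]]
  if (!is.null(hit)) return(hit)
  Y <- build_reference(f_k, H, fs, n_samples)
  Q <- qr_basis(t(Y - rowMeans(Y)), tol)
  if (length(.ref_cache) > 512L) rm(list = ls(.ref_cache), envir = .ref_cache)
  .ref_cache[[key]] <- Q
  Q
}

#' FBCCA scores for a buffer snapshot
#'
#' Runs the full filter-bank canonical correlation analysis: the buffer is
#' decomposed into sub-bands, each sub-band is correlated with each
#' candidate frequency's sine-cosine reference, and per-frequency scores are
#' fused as the weighted sum of (optionally squared) first canonical
#' correlations. When the bank has a single sub-band the weight is fixed to
#' 1 and the procedure reduces to standard CCA on the band-passed buffer.
#'
#' @param buffer An [eeg_segment()] or channels x N matrix.
#' @param params An [fbcca_params()].
#' @return An object of class `fbcca_scores`: fields `rho`
#'   (frequency x sub-band matrix), `combined`, `winner`, `runner_up`,
#'   `margin`, `frequencies`.
#' @export
fbcca_scores <- function(buffer, params) {
  seg <- if (inherits(buffer, "eeg_segment")) buffer
         else eeg_segment(buffer, fs = params$fs)
  if (seg$fs != params$fs) stop("buffer fs does not match params fs", call. = FALSE)
  bank <- params$subbands
  n_sb <- length(bank$specs)
  n_f <- length(params$frequencies)
  n <- ncol(seg$samples)
  w <- if (n_sb == 1L) 1 else subband_weight(seq_len(n_sb), params$weight_a, params$weight_b)
  rho <- matrix(NA_real_, nrow = n_f, ncol = n_sb,
                dimnames = list(format(params$frequencies), NULL))
  for (sb in seq_len(n_sb)) {
    Xf <- apply_subband(seg, sb, bank)$samples
    Xc <- Xf - rowMeans(Xf)
    if (any(rowSums(Xc^2) == 0)) {
      stop("degenerate input: zero-variance channel in buffer", call. = FALSE)
    }
    Qx <- qr_basis(t(Xc), 1e-7)
    for (k in seq_len(n_f)) {
      Qy <- reference_basis(params$frequencies[k], params$harmonics, params$fs, n)
      r <- svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d[1]
      rho[k, sb] <- min(max(r, 0), 1)
    }
  }
  base <- if (params$combine_squared) rho^2 else rho
  combined <- as.numeric(base %*% w)
  ord <- order(combined, decreasing = TRUE)
  structure(list(rho = rho, combined = combined,
                 winner = ord[1], runner_up = if (n_f > 1) ord[2] else NA_integer_,
                 margin = if (n_f > 1) combined[ord[1]] - combined[ord[2]] else Inf,
                 frequencies = params$frequencies, weights = w),
            class = "fbcca_scores")
}

#' @export
print.fbcca_scores <- function(x, ...) {
  cat("<fbcca_scores>\n")
  print(round(cbind(x$rho, combined = x$combined), 4))
  cat(sprintf("winner: %g Hz (margin %.4f)\n",
              x$frequencies[x$winner], x$margin))
  invisible(x)
}

#' Margin-threshold target selection
#'
#' Accepts the top-scoring frequency only when its combined score exceeds
#' the runner-up's by at least `threshold`. Exact ties in the combined
#' scores are broken toward the lower frequency-list index, making replays
#' deterministic.
#'
#' @param scores An [fbcca_scores()].
#' @param threshold Non-negative margin threshold (score units).
#' @return `NULL` when no decision fires; otherwise a list with `index`,
#'   `frequency` and `margin`.
#' @export
select_target <- function(scores, threshold = 0.30) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  combined <- scores$combined
  win <- which.max(combined)           # ties resolve to the lower index
  margin <- if (length(combined) > 1) {
    combined[win] - max(combined[-win])
  } else {
    Inf
  }
  if (margin >= threshold) {
    list(index = win, frequency = scores$frequencies[win], margin = margin)
  } else {
    NULL
  }
}
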