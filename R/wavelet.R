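# The 36-criterion wavelet profile: a single-level 2D discrete wavelet
# transform of each patient's selected-feature signal under each of 31
# filter banks, summarized by matrix criteria, cA-vs-detail regressions,
# and whole-signal energy/waveform length.

#' The 31 wavelet filter banks
#'
#' Eleven biorthogonal spline banks, Daubechies db2-db9, symlets sym2-sym8
#' and coiflets coif1-coif5.
#'
#' @return Character vector of 31 filter bank identifiers.
#' @export
#' @examples
#' filter_banks()
filter_banks <- function() names(.wavelet_filters)

get_filter <- function(bank) {
  f <- .wavelet_filters[[bank]]
  if (is.null(f)) {
    abort(sprintf("unknown filter bank '%s'; valid banks: %s", bank,
                  paste(filter_banks(), collapse = ", ")))
  }
  f
}

# Single-level 1D DWT of x with one filter. Symmetric mode reflects
# filt_len-1 samples at each edge (output length floor((N+L-1)/2));
# periodization mode wraps circularly with even-shift polyphase rows
# (output length N/2), which makes the transform orthogonal for the
# orthonormal families.
dwt1 <- function(x, f, mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  L <- length(f)
  N <- length(x)
  if (mode == "symmetric") {
    p <- L - 1
    # half-sample symmetric extension (period 2N), valid for any p
    i <- (1 - p):(N + p)
    ti <- ((i - 1) %% (2 * N) + 2 * N) %% (2 * N)
    ext <- x[ifelse(ti < N, ti + 1, 2 * N - ti)]
    Nv <- N + L - 1
    val <- numeric(Nv)
    fr <- rev(f)
    for (m in seq_len(L)) val <- val + fr[m] * ext[m:(m + Nv - 1)]
    val[seq(2, by = 2, length.out = floor((N + L - 1) / 2))]
  } else {
    if (N %% 2 == 1) {
      x <- c(x, x[N])
      N <- N + 1
    }
    half <- N / 2
    out <- numeric(half)
    for (k in seq_len(half)) {
      idx <- ((2 * (k - 1) + seq_len(L) - 1) %% N) + 1
      out[k] <- sum(f * x[idx])
    }
    out
  }
}

#' Reshape a selected-feature row into the 2D signal matrix
#'
#' The m selected values (assembled sequence-major) are laid out row-major
#' into a matrix with 4 rows -- one per MRI sequence -- and
#' `max(2, ceiling(m / 4))` columns, right-padded with zeros; the number of
#' zero pads is recorded in the `"n_pad"` attribute.
#'
#' @param v Numeric vector of selected feature values, length >= 4.
#' @return A 4 x k numeric matrix with attribute `n_pad`.
#' @export
#' @examples
#' reshape_signal(1:10)   # 4 x 3, 2 zero pads
reshape_signal <- function(v) {
  m <- length(v)
  if (m < 4) abort("need at least 4 selected values (one per sequence).")
  k <- max(2L, as.integer(ceiling(m / 4)))
  out <- matrix(0, 4, k)
  out <- matrix(c(v, numeric(4 * k - m)), nrow = 4, ncol = k, byrow = TRUE)
  attr(out, "n_pad") <- 4L * k - m
  out
}

#' Single-level 2D discrete wavelet transform
#'
#' Separable single-level transform: the low/high-pass pair is applied down
#' the rows and along the columns, yielding the approximation `cA` (low-low)
#' and the horizontal/vertical/diagonal details `cH` (high-low), `cV`
#' (low-high), `cD` (high-high), all of equal shape.
#'
#' @param M Numeric matrix, at least 2 x 2.
#' @param bank A filter bank id from [filter_banks()].
#' @param mode Boundary handling: `"symmetric"` (default) or
#'   `"periodization"` (orthogonal on even sizes; used for energy checks).
#' @return List of class `coefficient_quad` with matrices `cA`, `cH`, `cV`,
#'   `cD`.
#' @export
#' @examples
#' q <- dwt2_single_level(matrix(1:16, 4, 4), "db2")
#' dim(q$cA)
dwt2_single_level <- function(M, bank, mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  f <- get_filter(bank)
  if (!is.matrix(M) || nrow(M) < 2 || ncol(M) < 2) {
    abort("`M` must be a matrix of at least 2 x 2.")
  }
  rows_pass <- function(M, filt) apply(M, 2, dwt1, f = filt, mode = mode)
  cols_pass <- function(M, filt) t(apply(M, 1, dwt1, f = filt, mode = mode))
  lo_r <- rows_pass(M, f$dec_lo)
  hi_r <- rows_pass(M, f$dec_hi)
  if (is.null(dim(lo_r))) lo_r <- matrix(lo_r, nrow = 1)
  if (is.null(dim(hi_r))) hi_r <- matrix(hi_r, nrow = 1)
  structure(list(cA = cols_pass(lo_r, f$dec_lo),
                 cH = cols_pass(hi_r, f$dec_lo),
                 cV = cols_pass(lo_r, f$dec_hi),
                 cD = cols_pass(hi_r, f$dec_hi),
                 bank = bank, mode = mode),
            class = "coefficient_quad")
}

#' The seven matrix criteria
#'
#' Maximum, minimum, average, median, standard deviation, Shannon entropy
#' and signal energy of a coefficient matrix. Energy is the sum of squared
#' entries; entropy is computed on the normalized squared-coefficient
#' distribution `p_i = x_i^2 / sum(x^2)` in bits, with an all-zero matrix
#' assigned entropy 0.
#'
#' @param M Non-empty numeric matrix (or vector).
#' @return Named numeric vector of length 7.
#' @export
#' @examples
#' matrix_criteria(matrix(c(1, -1, 1, -1), 2))
matrix_criteria <- function(M) {
  x <- as.vector(M)
  if (!length(x)) abort("empty matrix.")
  en <- sum(x^2)
  ent <- if (en > 0) shannon_entropy(x^2 / en) else 0
  c(max = max(x), min = min(x), mean = mean(x), median = median(x),
    sd = if (length(x) > 1) sd(x) else 0, entropy = ent, energy = en)
}

#' Slope and standard error between cA and one detail matrix
#'
#' Ordinary least squares of the flattened detail coefficients on the
#' flattened approximation coefficients (with intercept); returns the slope
#' and the slope's standard error. A zero-variance cA is a degenerate fit:
#' slope 0, SE 0, flagged.
#'
#' @param ca,detail Equal-shape numeric matrices with at least 3 cells.
#' @return Named numeric vector `slope`, `se`, with attribute `degenerate`.
#' @export
pair_regression <- function(ca, detail) {
  x <- as.vector(ca)
  y <- as.vector(detail)
  if (length(x) != length(y)) abort("cA and detail must have equal shape.")
  n <- length(x)
  if (n < 3) abort("need at least 3 cells.")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    out <- c(slope = 0, se = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - (mean(y) + slope * (x - mean(x)))
  rss <- sum(res^2)
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  out <- c(slope = slope, se = se)
  attr(out, "degenerate") <- FALSE
  out
}

#' Whole-signal energy and waveform length
#'
#' Energy is the sum of squares of the original (unpadded) selected-feature
#' signal; the wavelength criterion is implemented as waveform length, the
#' sum of absolute successive differences.
#'
#' @param v Numeric vector, length >= 2.
#' @return Named numeric vector `energy`, `wavelength`.
#' @export
#' @examples
#' whole_signal_criteria(c(0, 1, 0, 1))
whole_signal_criteria <- function(v) {
  if (length(v) < 2) abort("need at least 2 values.")
  c(energy = sum(v^2), wavelength = sum(abs(diff(v))))
}

#' Canonical names of the 36 wavelet-profile criteria
#'
#' @return Character vector of length 36: 7 criteria for each of cA, cH,
#'   cV, cD; slope and standard error for each (cA, detail) pair; and the
#'   whole-signal energy and wavelength.
#' @export
wavelet_profile_names <- function() {
  mats <- c("cA", "cH", "cV", "cD")
  crit <- c("max", "min", "mean", "median", "sd", "entropy", "energy")
  c(as.vector(t(outer(mats, crit, paste, sep = "_"))),
    as.vector(t(outer(c("slope", "se"), c("cH", "cV", "cD"), paste, sep = "_"))),
    "signal_energy", "signal_wavelength")
}

#' Build the 36-criterion profile of one sample under one filter bank
#'
#' @param v The patient's selected-feature row (sequence-major), length >= 4.
#' @param bank A filter bank id from [filter_banks()].
#' @return Named numeric vector of length 36 (28 matrix criteria + 6
#'   regression values + 2 whole-signal values).
#' @export
build_profile <- function(v, bank) {
  q <- dwt2_single_level(reshape_signal(v), bank)
  mats <- list(cA = q$cA, cH = q$cH, cV = q$cV, cD = q$cD)
  block28 <- unlist(lapply(mats, matrix_criteria))
  reg <- unlist(lapply(c("cH", "cV", "cD"), function(d) {
    r <- pair_regression(q$cA, mats[[d]])
    c(r[["slope"]], r[["se"]])
  }))
  out <- c(block28, reg[c(1, 3, 5, 2, 4, 6)], whole_signal_criteria(v))
  setNames(out, wavelet_profile_names())
}

#' Build profile tables for every filter bank
#'
#' @param tbl An assembled selected-feature table (`patient_id`, `label`,
#'   selected columns, as from [assemble_rows()]).
#' @param banks Filter bank ids (default all 31).
#' @return Named list of tibbles, one per bank; each has `patient_id`,
#'   `label` and the 36 criterion columns.
#' @export
build_all_profiles <- function(tbl, banks = filter_banks()) {
  bad <- setdiff(banks, filter_banks())
  if (length(bad)) {
    abort(sprintf("unknown filter bank(s): %s; valid banks: %s",
                  paste(bad, collapse = ", "),
                  paste(filter_banks(), collapse = ", ")))
  }
  feats <- feature_columns(tbl)
  X <- as.matrix(tbl[, feats])
  out <- lapply(banks, function(b) {
    prof <- t(apply(X, 1, build_profile, bank = b))
    dplyr::bind_cols(
      tbl[, intersect(c("patient_id", "label"), names(tbl)), drop = FALSE],
      tibble::as_tibble(as.data.frame(prof))
    )
  })
  names(out) <- banks
  out
}
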