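# Internal helpers shared across modules.

# The four MRI sequences, in the canonical (sequence-major) assembly order.
#' Canonical MRI sequence names
#'
#' The four conventional MRI sequences the pipeline expects, in the order
#' used for row assembly and signal reshaping: T1-weighted, T2-weighted,
#' contrast-enhanced T1, and FLAIR.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' mri_sequences()
mri_sequences <- function() c("T1W", "T2W", "T1C", "FLAIR")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Deterministic sub-seed derivation: keeps derived seeds positive and < 2^31.
derive_seed <- function(seed, label) {
  offs <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + offs) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# log2 with the 0 * log(0) = 0 convention used by every entropy in the package
xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

shannon_entropy <- function(p) {
  -sum(xlog2(p))
}

# Feature columns of a feature table (everything except identifiers/labels)
feature_columns <- function(tbl) {
  setdiff(names(tbl), c("patient_id", "label"))
}
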