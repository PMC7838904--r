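#' @keywords internal
"_PACKAGE"

## Closed vocabulary of biological group labels.  "control" only appears
## after merge_control_groups() has pooled the non-malignant groups.
GROUP_LEVELS <- c(
  "normal", "BPH", "NAD", "HGPIN",
  "primary_tumor", "metastatic_primary_tumor", "metastasis",
  "control"
)

CONTROL_LIKE_GROUPS <- c("normal", "BPH", "NAD")
TUMOR_BEARING_GROUPS <- c("primary_tumor", "metastatic_primary_tumor", "metastasis")

cx_log <- function(..., verbose = getOption("crossexpr.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[crossexpr] ", ...)
  invisible(NULL)
}

cx_stop <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) cx_stop(msg)
  invisible(TRUE)
}

#' Inverse of the trigamma function
#'
#' Newton solver for `trigamma(x) = y`, needed when estimating the prior
#' degrees of freedom of the variance hyperprior by matching moments of
#' log sample variances.
#'
#' @param y positive numeric vector.
#' @return x with `trigamma(x) = y` elementwise.
#' @keywords internal
trigamma_inverse <- function(y) {
  out <- y
  omit <- is.na(y)
  big <- !omit & y > 1e7
  out[big] <- 1 / sqrt(y[big])
  small <- !omit & y < 1e-6
  out[small] <- 1 / y[small]
  todo <- !(omit | big | small)
  if (any(todo)) {
    x <- 0.5 + 1 / y[todo]
    for (i in seq_len(50)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[todo] <- x
  }
  out
}

## Deterministic sub-seed derivation: all generator randomness flows from
## one user seed through sub-seeds drawn up front, so each sub-stream can
## be replayed independently.  Sub-seeds stay below 2^31 - 1.
derive_subseeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
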