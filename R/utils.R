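# Internal helpers: seeded RNG scoping, seed derivation, assertions.

LABEL_FALL <- "Fall"
LABEL_NOTFALL <- "NotFall"
LABEL_LEVELS <- c(LABEL_FALL, LABEL_NOTFALL)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a child seed from a master seed
#'
#' All randomness in multi-part simulations flows from one master seed via
#' this splitting scheme, so each part is independently reproducible.
#' Kept below 2^31 - 1.
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  invisible(x)
}

assert_labels <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), LABEL_LEVELS)
  if (length(bad) > 0) {
    stopf("labels must be one of \"%s\"; found: %s",
          paste(LABEL_LEVELS, collapse = "\", \""),
          paste(utils::head(bad, 3), collapse = ", "))
  }
  invisible(labels)
}

# Right-aligned rolling mean of width k, computed with one cumulative sum so
# detector and tests share identical floating-point arithmetic.
rolling_mean <- function(x, k) {
  n <- length(x)
  if (n < k) return(numeric(0))
  cs <- cumsum(x)
  (cs[k:n] - c(0, cs[seq_len(n - k)])) / k
}
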