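# Internal helpers shared across modules.

#' @useDynLib ggee, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qnorm sd var lm.fit coef pnorm setNames
#' @importFrom utils read.table write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(msg, class = "ggee_invalid_argument") {
  stop(errorCondition(msg, class = c(class, "ggee_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("ggee_degenerate_input", "ggee_error")))
}

#' Derive reproducible child seeds from one master seed
#'
#' Draws `n` integer seeds from the RNG stream seeded by `master`, so that
#' every replicate of a study can be regenerated in isolation from its own
#' seed while the whole study is reproducible from the master seed alone.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1)`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(expr)
}

# Column-standardize a matrix using (optionally) statistics from `train` rows.
# Zero-variance columns keep their centered values and are reported.
standardize_cols <- function(x, train = NULL) {
  x <- as.matrix(x)
  idx <- train %||% seq_len(nrow(x))
  mu <- colMeans(x[idx, , drop = FALSE])
  sg <- apply(x[idx, , drop = FALSE], 2, sd)
  zero <- !is.finite(sg) | sg <= 0
  sg[zero] <- 1
  out <- sweep(sweep(x, 2, mu, "-"), 2, sg, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sg
  attr(out, "zero_variance") <- which(zero)
  out
}
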