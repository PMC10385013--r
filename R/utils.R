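#' @keywords internal
"_PACKAGE"

# Interaction label schema, fixed order used everywhere (confusion-matrix rows,
# classifier output units). Negative first, then the four positive DDI types.
DDI_CLASSES <- c("negative", "mechanism", "effect", "advice", "int")
DDI_POSITIVE_CLASSES <- c("mechanism", "effect", "advice", "int")
ENTITY_TYPES <- c("drug", "brand", "group", "drug_n")

PAD_TOKEN <- "<PAD>"

#' Run code with a temporary RNG seed
#'
#' Sets the RNG to a known state, evaluates `expr`, and restores the previous
#' global RNG state so library calls never disturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Numerically stable softmax
#'
#' @param x numeric vector, or matrix (softmax taken row-wise).
#' @return object of the same shape with non-negative entries summing to 1.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

# Glorot (Xavier) uniform initialization for a fan_in x fan_out matrix.
glorot_matrix <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Column-wise max of a matrix, returning max values and the row index of each
# maximum (ties broken by the first row). Used by pooling layers.
col_max_with_index <- function(m) {
  idx <- max.col(t(m), ties.method = "first")
  list(values = m[cbind(idx, seq_len(ncol(m)))], index = idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
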