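#' Value map
#'
#' Linear mapping from a memory readout to a scalar value: each memory node
#' carries a (possibly zero) value weight and the value of a memory state
#' is the inner product `V = v . m`. Scenario statements like "the value of
#' A is 0.4" are realised by spreading 0.4 over the nodes of A's pattern so
#' that the settled attractor reads out exactly 0.4.
#'
#' @param v Numeric vector of per-node values, length = memory size.
#' @return A numeric vector of class `value_map`.
#' @export
value_map <- function(v) {
  v <- as.numeric(v)
  if (length(v) == 0L || !all(is.finite(v))) {
    stop("value map must be a nonempty finite numeric vector", call. = FALSE)
  }
  structure(v, class = "value_map")
}

#' Evaluate a memory readout
#'
#' @param m Memory readout vector.
#' @param vm A [value_map()] (or plain numeric vector) of the same length.
#' @return Scalar value `V = v %*% m`.
#' @export
evaluate_value <- function(m, vm) {
  if (length(m) != length(vm)) {
    stop("dimension mismatch: readout has length ", length(m),
         ", value map has length ", length(vm), call. = FALSE)
  }
  sum(as.numeric(vm) * as.numeric(m))
}

# spread a scalar value uniformly over the nodes of a binary pattern
pattern_value <- function(pattern, value) {
  as.numeric(pattern) * value / sum(pattern)
}
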