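# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Euclidean length of each row of a matrix
.row_norms <- function(m) sqrt(rowSums(m * m))

# deterministic stop with a consistent error class so callers/tests can match
.gcut_stop <- function(msg, class) {
  stop(structure(class = c(class, "gcut_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# polyline arc length for a k x 3 coordinate matrix
.polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(.row_norms(coords[-1L, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE]))
}
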