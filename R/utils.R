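# Internal helpers shared across modules.

# Module colour sequence used for size-ranked module names (grey is reserved
# for unassigned genes). Beyond the named colours, modules fall back to
# "module<N>".
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue", "paleturquoise"
)

module_color_names <- function(n) {
  if (n <= length(.module_colors)) {
    .module_colors[seq_len(n)]
  } else {
    c(.module_colors, paste0("module", seq.int(length(.module_colors) + 1L, n)))
  }
}

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.check_fraction <- function(x, name, lo = 0, hi = 1, open = TRUE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (open) x > lo & x < hi else x >= lo & x <= hi)
  if (!all(ok)) {
    stop(sprintf("'%s' must lie in %s%g, %g%s", name,
                 if (open) "(" else "[", lo, hi, if (open) ")" else "]"),
         call. = FALSE)
  }
  x
}

.check_square_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  invisible(m)
}

# Column-standardize a vector to zero mean, unit (sample) variance.
.standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector", call. = FALSE)
  (x - mean(x)) / s
}
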