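`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoid area under a sampled curve
#'
#' @param x ordered abscissae (e.g. sparsity degrees).
#' @param y curve values, same length as `x`.
#' @return The trapezoid-rule integral of `y` over `x`; 0 (with a warning)
#'   for a single-point grid.
#' @examples
#' auc_trapezoid(c(0.5, 0.9), c(1, 1))  # 0.4
#' @export
auc_trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) {
    warning("single-point grid: AUC is 0 by convention")
    return(0)
  }
  if (is.unsorted(x, strictly = TRUE)) stop("`x` must be strictly increasing")
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Deterministic child seed from a parent seed and a text tag, so that any
# per-group / per-statistic resampling stream can be reproduced in
# isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483647
  as.integer((seed %% 2147483647 + h) %% 2147483647)
}

# Scan a result record for fields JSON cannot represent, naming the path.
assert_serializable <- function(x, path = "results") {
  if (is.function(x) || is.environment(x) || typeof(x) == "externalptr")
    stop("field `", path, "` is not serializable to JSON")
  if (is.list(x)) {
    nms <- names(x) %||% seq_along(x)
    for (i in seq_along(x))
      assert_serializable(x[[i]], paste(path, nms[i], sep = "$"))
  }
  invisible(TRUE)
}
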