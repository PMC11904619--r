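#' @keywords internal
#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom ggplot2 autoplot
#' @importFrom generics tidy glance
#' @importFrom stats setNames
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministically derive a 31-bit sub-seed from a master seed and labels.
# Keeps derived seeds below 2^31 so they remain valid R integers.
derive_seed <- function(master, ...) {
  parts <- c(master, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.numeric(x)
  })))
  h <- 0
  for (p in parts) h <- (h * 31 + (as.numeric(p) %% 1000003)) %% 2147483587
  as.integer(h + 1)
}

rms <- function(x) sqrt(mean(x^2))
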