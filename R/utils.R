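#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rlnorm runif rbinom sd quantile coef fitted
#'   anova as.formula lm na.omit pnorm setNames var
NULL

# Derive a reproducible 31-bit sub-seed from a base seed and stream labels.
# Plain integer hashing keeps every derived seed strictly below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) {
      h <- (h * 31 + ch) %% 2147483629
    }
  }
  as.integer(h)
}

# Run code under a temporary RNG state keyed by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
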