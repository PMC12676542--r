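#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm runif rbeta sd pt qnorm p.adjust t.test
#'   dgamma convolve anova lm optimize setNames
#' @importFrom utils combn head read.csv write.csv
NULL

# Derive a child seed from a root seed and a stage/index pair.
# Counter-based split: keeps every stage's stream independent of the
# others while staying inside the 32-bit integer range R requires.
derive_seed <- function(root_seed, stage, index = 0L) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(paste0(stage, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(root_seed) * 7919 + h) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

# Unit-normalize columns/rows safely; zero vectors stay zero.
l2_normalize <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}
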