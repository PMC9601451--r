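#' @keywords internal
"_PACKAGE"

# Modification-type vocabulary used throughout the package.
MOD_TYPES <- c("m6A", "m6Am", "m1A", "2'-O-Me", "m5C", "m5U", "m7G",
               "A-to-I", "pseudouridine")

CONFIDENCE_LEVELS <- c("high", "medium", "low")
EFFECT_LEVELS <- c("gain", "loss")
GENE_TYPES <- c("protein_coding", "noncoding")
REGION_LEVELS <- c("exonic", "3'UTR", "5'UTR", "intronic", "other")

#' Round half away from zero
#'
#' Printed-table rounding convention (base `round()` is round-half-even).
#' Used for every percentage the summaries report.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. A NULL seed leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == floor(x) && x >= 0

assert_prob <- function(x, name, open_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (x > 0 || (!open_lower && x == 0)) && x <= 1
  if (!ok) stopf("`%s` must be a probability in %s0, 1], got %s",
                 name, if (open_lower) "(" else "[", format(x))
  invisible(x)
}
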