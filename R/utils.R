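#' @keywords internal
"_PACKAGE"

## The four use-status classes, in canonical order.
STATUS_CLASSES <- c("C", "D", "S", "U")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding used in the result tables: 0.885 rounds to 0.89 rather
#' than to the IEEE banker's value. Internal computations keep full precision.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Coerce a label vector to a factor over the four status classes,
## erroring on anything outside {C, D, S, U}.
as_status <- function(x, arg = "labels") {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% STATUS_CLASSES)
  if (any(bad)) {
    stop(sprintf("%s contains values outside {C, D, S, U}: %s",
                 arg, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  factor(x, levels = STATUS_CLASSES)
}

## Path to a packaged default data file.
sup_extdata <- function(...) {
  system.file("extdata", ..., package = "supstatus", mustWork = TRUE)
}

## Run an expression with a locally seeded RNG, restoring the caller's
## RNG state afterwards so package functions do not disturb user code.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a reproducible sub-seed from a base seed and a character tag,
## kept within the 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
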