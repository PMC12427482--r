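#' Round half away from zero
#'
#' Commercial rounding: 0.5 rounds to 1, -0.5 to -1 (base R's `round()` rounds
#' half to even). Used for integer percentages in demographic tables.
#'
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Analyzable area of a circular TMA core
#'
#' Area of a disc of the given diameter, in mm^2. A standard 1.0 mm tissue
#' microarray core has an analyzable area of 0.785 mm^2.
#'
#' @param diameter_um core diameter in micrometres (default 1000)
#' @param digits decimal places to round to (default 3, matching how core
#'   areas are conventionally reported); `NULL` for no rounding
#' @return area in mm^2
#' @export
core_area_mm2 <- function(diameter_um = 1000, digits = 3) {
  a <- pi * (diameter_um / 2000)^2
  if (is.null(digits)) a else round(a, digits)
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
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

stop_osimc <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
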