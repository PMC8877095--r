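#' @keywords internal
"_PACKAGE"

## internal helpers shared across modules

stop_bowl <- function(..., class = "bowlrecon_error") {
  stop(errorCondition(paste0(...), class = c(class, "bowlrecon_error")))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_bowl(what, " must be finite numeric", class = "bowlrecon_validation_error")
  }
  invisible(x)
}

check_positive <- function(x, what) {
  check_finite(x, what)
  if (any(x <= 0)) {
    stop_bowl(what, " must be > 0", class = "bowlrecon_validation_error")
  }
  invisible(x)
}

## coerce a 2-column point representation (matrix, data.frame or length-2
## vector) to an n x 2 numeric matrix
as_points <- function(p, what = "points") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop_bowl(what, " must have 2 coordinates")
    p <- matrix(p, ncol = 2L)
  }
  p <- p[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  check_finite(p, what)
  unname(p)
}

## round half away from zero at `digits` decimals (printed-table convention;
## base round() rounds half to even)
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## cumulative trapezoid integral of y over x (same length as x, starts at 0)
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
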