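#' Geometric mean
#'
#' @param x Numeric vector of strictly positive values.
#' @param na.rm Drop `NA` values before averaging.
#' @return The geometric mean, `exp(mean(log(x)))`.
#' @examples
#' geomean(c(1, 4)) # 2
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ids are case-sensitive, whitespace-trimmed strings
trim_id <- function(x) trimws(as.character(x))

stop_mirnorm <- function(..., class) {
  stop(structure(
    class = c(class, "mirnorm_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
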