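#' Round half away from zero
#'
#' Percentages in reports are rounded to a fixed number of decimals with ties
#' going away from zero (so 87.195 -> 87.20), unlike [base::round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(87.195, 2.5, -2.5), 2)
round_half_up <- function(x, digits = 2) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

#' Null-coalescing operator
#' @param a,b `a` unless it is `NULL`, then `b`.
#' @return `a` or `b`.
#' @export
#' @name op-null-default
`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## row-bind a list of data.frames that may be empty
rbind_df <- function(lst) {
  lst <- lst[vapply(lst, function(d) !is.null(d) && nrow(d) > 0, logical(1))]
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
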