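#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in
#' fragment-analysis summary tables conventionally round half away from
#' zero (e.g. 2.85 -> 2.9, 45.83 -> 46). All percentages reported by this
#' package go through this rule.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.85), 0)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Modal value with smallest-value tie-break
#'
#' @param x vector (sizes in bp or ordinal scores); NAs dropped.
#' @return the most frequent value; on ties the smallest such value.
#' @keywords internal
mode_min <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  vals <- suppressWarnings(as.numeric(names(tab)))
  if (anyNA(vals)) vals <- names(tab)  # non-numeric labels
  winners <- vals[tab == max(tab)]
  min(winners)
}

# semicolon-joined integer lists are the on-disk form for minor peak sets
join_sizes <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

split_sizes <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) integer(0)
    else as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
  })
}

# derive a stream-specific 32-bit seed from a user seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
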