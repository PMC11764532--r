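#  internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' @noRd
.complement <- function(x) {
  out <- unname(.COMPLEMENT[x])
  out[is.na(x)] <- NA_character_
  out
}

#' @noRd
.is_ambiguous_pair <- function(a, b) {
  # A/T and C/G pairs cannot be strand-checked against another panel
  !is.na(a) & !is.na(b) & .complement(a) == b
}

#' @noRd
.stopf <- function(fmt, ..., class = "wolfdogpop_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' @noRd
.assert <- function(cond, fmt, ..., class = "wolfdogpop_error") {
  if (!isTRUE(cond)) .stopf(fmt, ..., class = class)
}

# running sum over windows of width w (length(x) - w + 1 values)
#' @noRd
.window_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}
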