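#' @importFrom rlang abort warn %||% .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_wider pivot_longer
#' @importFrom purrr map map_dbl map_lgl imap list_rbind
NULL

# deterministic child seed: adding synapses/conditions never perturbs the
# draws of earlier ones, and distinct (salt, i) pairs get distinct streams
child_seed <- function(seed, i, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 9973 * salt + i
  as.integer((s * 69069 + 1) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# bilinear interpolation of matrix `img` at fractional (row, col) positions;
# callers guarantee 1 <= r, c <= dim (checked upstream as a boundary error)
interp_bilinear <- function(img, r, c) {
  r0 <- pmin(pmax(floor(r), 1L), nrow(img) - 1L)
  c0 <- pmin(pmax(floor(c), 1L), ncol(img) - 1L)
  fr <- r - r0
  fc <- c - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}
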