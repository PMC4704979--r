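#' @importFrom rlang abort %||% .data
#' @importFrom stats pbinom sd runif
#' @importFrom tibble as_tibble tibble
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"

#' @export
tibble::as_tibble

abort_wm <- function(message, class) {
  rlang::abort(message, class = c(class, "wm_error"))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in clinical
#' reports conventionally round half up (93.75 -> 94, 83.5 -> 84). Used by
#' every percent summary in the package.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(83.5, 93.75, 81.25))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# tolerance used whenever a percentage is compared against a threshold,
# so that counts that mathematically reach the threshold are never lost
# to floating-point representation
.pct_eps <- 1e-9

exercise_types <- function() c("vs_wm", "op_nb", "d_nb")

check_exercise_type <- function(x) {
  if (!(is.character(x) && length(x) == 1 && x %in% exercise_types())) {
    abort_wm(
      paste0("unknown exercise type: ", paste(x, collapse = ", "),
             " (expected one of vs_wm, op_nb, d_nb)"),
      "wm_domain_error"
    )
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!(is.numeric(x) && length(x) == 1 && is.finite(x) && x == trunc(x) && x >= min)) {
    abort_wm(sprintf("`%s` must be a single integer >= %d", name, min),
             "wm_domain_error")
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0)) {
    abort_wm(sprintf("`%s` must be a single positive number", name),
             "wm_config_error")
  }
  as.numeric(x)
}

# deterministic derived seed, kept inside 32-bit integer range
derive_seed <- function(seed, k = 1L) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(k)) %% 2147483647)
}

fast_row <- function(fields, class) {
  tibble::new_tibble(fields, nrow = 1L, class = class)
}
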