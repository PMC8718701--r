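#' Derive a child seed from a master seed
#'
#' Deterministic integer map used to fan one master seed out into
#' independent streams (fold shuffles, per-configuration network
#' initialisation, dropout masks) so that an entire benchmark run is
#' reproducible end to end from a single `--seed`. Kept strictly below
#' `2^31` so the result is always a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param stream Integer stream index (>= 0).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  as.integer((abs(master) * 7919 + stream * 104729) %% 2147483629)
}

# round-half-up with a floor of 1; base round() is round-half-even
round_half_up <- function(x, floor_at = 1L) {
  pmax(floor_at, as.integer(floor(x + 0.5)))
}

# full one-hot incidence of a factor-like vector against a fixed level set
incidence_matrix <- function(values, levels) {
  m <- matrix(0, nrow = length(values), ncol = length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(values), match(values, levels))] <- 1
  m
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
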