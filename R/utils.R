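#' @keywords internal
"_PACKAGE"

# Shared internal helpers: argument checking, rolling statistics, rounding.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  ok_lower <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_lower || x > upper) {
    stop_invalid("`%s` = %g is outside the allowed range", name, x)
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Rounding convention used when echoing statistics at a fixed number of
#' decimal places (base `round()` rounds half to even, which disagrees with
#' the convention common in sport-science reporting).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.525, 2) # 2.53
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Centered moving maximum over an odd window width, O(n) block algorithm
# (forward/backward running maxima over blocks of the window width).
# Edges are treated as if padded with -Inf, so edge windows are truncated.
moving_max <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  np <- n + 2L * h
  nb <- ceiling(np / width)
  pad_total <- nb * width - np
  xp <- c(rep(-Inf, h), x, rep(-Inf, h + pad_total))
  m <- matrix(xp, nrow = width)
  left <- as.vector(apply(m, 2L, cummax))
  right <- as.vector(apply(m[width:1L, , drop = FALSE], 2L, cummax)[width:1L, , drop = FALSE])
  # padded window for sample i is [i, i + width - 1]
  idx <- seq_len(n)
  pmax(right[idx], left[idx + width - 1L])
}

# Centered moving median via stats::runmed (odd width enforced).
moving_median <- function(x, width) {
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L || length(x) < width) return(rep(stats::median(x), length(x)))
  as.numeric(stats::runmed(x, width, endrule = "median"))
}

# Derive a per-unit substream seed from a base seed; keeps results for unit i
# independent of how many other units exist. Stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 2654435761 + index * 40503) %% 2147483647)
}

# Lognormal meanlog/sdlog from a target arithmetic mean and SD (mean > 0).
lognormal_pars <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
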