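#' Standard error of the mean
#'
#' @param x numeric vector.
#' @return `sd(x)/sqrt(n)`, or `NA_real_` when fewer than two values are
#'   available (a single replicate carries no spread information).
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Centered moving average with truncated ends
#'
#' Smooths a numeric vector with a centered window of odd length. Near the
#' termini the window shrinks to whatever indices exist, so no values outside
#' the vector are invented and a constant input is reproduced exactly.
#'
#' @param x numeric vector.
#' @param window odd positive integer window length (default 5).
#' @return numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Stable 32-bit string hash (FNV-1a folded into [1, 2^31 - 2]); used to derive
# independent per-run seeds from a campaign master seed.
hash32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 2)) + 1L
}

#' Derive a reproducible child seed
#'
#' Combines a master seed with a character identifier so that every run of a
#' campaign gets an independent but fully reproducible random stream.
#'
#' @param master integer master seed.
#' @param id character identifier (e.g. a run id).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, id) {
  stopifnot(length(master) == 1L, length(id) == 1L)
  h <- as.numeric(hash32(paste0(id, ":", as.integer(master))))
  as.integer((h + as.numeric(master)) %% (2^31 - 2)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
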