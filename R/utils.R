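# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a global seed
#'
#' A single global seed fans out to per-stage seeds via a fixed hash of the
#' stage name, so that each pipeline stage is reproducible in isolation.
#' The result is always a positive integer below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 99991L
  as.integer((abs(seed) %% 21473L) * 99991L + h + 1L)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# minor-allele frequency from an effect-allele frequency
maf_of <- function(eaf) pmin(eaf, 1 - eaf)

BASES <- c("A", "C", "G", "T")

is_single_base <- function(x) x %in% BASES

# A/T and C/G allele pairs cannot be disambiguated across strands
is_palindromic_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

log_count <- function(what, n) {
  if (n > 0) message(sprintf("%s: %d", what, n))
  invisible(n)
}
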