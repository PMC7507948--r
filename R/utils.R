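# Internal helpers: classed conditions, unit constants, seeded substreams.

#' @keywords internal
pf_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "portoflow_error", "error", "condition")))
}

pf_check_positive <- function(..., .what = NULL) {
  args <- list(...)
  nms <- if (is.null(.what)) names(args) else .what
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      pf_stop(sprintf("'%s' must be strictly positive and finite", nms[i]),
              "pf_parameter_error")
    }
  }
  invisible(TRUE)
}

# 1 mmHg = 133.322 Pa (fixed conversion)
.PA_PER_MMHG <- 133.322

#' Convert pascal to millimetres of mercury
#'
#' Bridges the solver's SI gauge pressures to the clinical mmHg scale
#' (1 mmHg = 133.322 Pa).
#'
#' @param p pressure in Pa.
#' @return pressure in mmHg.
#' @examples
#' pa_to_mmhg(133.322)  # 1
#' @export
pa_to_mmhg <- function(p) p / .PA_PER_MMHG

#' Convert millimetres of mercury to pascal
#' @param p pressure in mmHg.
#' @return pressure in Pa.
#' @export
mmhg_to_pa <- function(p) p * .PA_PER_MMHG

# Deterministic per-unit substream seed derived from a base seed.  Keeps the
# draws of animal i invariant to the presence of animals j > i and stays
# below 2^31 - 1.
pf_substream <- function(seed, index) {
  x <- (as.double(seed) %% 2147483647) * 48271 + 69621 * as.double(index)
  as.integer(x %% 2147483647)
}

# Normal(mean, sd) truncated below at `lower` (default 0.2 * mean), by
# rejection; at the coefficients of variation used here the rejection rate
# is negligible so the expectation bias is immaterial.
pf_rnorm_trunc <- function(n, mean, sd, lower = 0.2 * mean) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); lower <- rep_len(lower, n)
  x <- stats::rnorm(n, mean, sd)
  x[sd == 0] <- mean[sd == 0]
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower[bad]]
    guard <- guard + 1L
    if (guard > 10000L) pf_stop("truncated-normal rejection failed to converge",
                                "pf_parameter_error")
  }
  x
}

# Small rolling hash for provenance stamps (not cryptographic).
pf_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- as.integer(charToRaw(s))
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2147483647
  sprintf("%010d", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
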