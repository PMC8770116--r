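#' @keywords internal
"_PACKAGE"

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("salivamigr_domain_error", "error")))
}

stop_unsupported_material <- function(material) {
  stop(errorCondition(
    sprintf("unsupported material '%s': no coefficient set loaded", material),
    class = c("salivamigr_unsupported_material", "salivamigr_domain_error", "error")
  ))
}

#' Validate a CAS registry number checksum
#'
#' CAS numbers have the form NNNNNN-NN-R where the final digit R is a
#' checksum: the digits (excluding R), read right to left, are multiplied by
#' 1, 2, 3, ... and summed; R is that sum modulo 10.
#'
#' @param cas Character vector of CAS registry numbers.
#' @return Logical vector; `NA` for missing/empty input.
#' @examples
#' cas_is_valid("117-81-7") # DEHP, TRUE
#' @export
cas_is_valid <- function(cas) {
  vapply(cas, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA)
    if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    n <- length(digits)
    check <- digits[n]
    body <- rev(digits[-n])
    sum(body * seq_along(body)) %% 10 == check
  }, logical(1), USE.NAMES = FALSE)
}

# Build a checksum-valid CAS-like identifier from an integer body.
# Used by the synthetic generator; these are synthetic identifiers, not
# registered CAS numbers.
make_synthetic_cas <- function(body) {
  body <- as.integer(body)
  s <- sprintf("%06d", body)
  digits <- as.integer(strsplit(s, "")[[1]])
  rdig <- rev(digits)
  check <- sum(rdig * seq_along(rdig)) %% 10
  sprintf("%s-%s-%d", substr(s, 1, 4), substr(s, 5, 6), check)
}

# Attach a structured warning string to an object without signalling.
add_warning <- function(x, msg) {
  attr(x, "warnings") <- c(attr(x, "warnings"), msg)
  x
}

#' Warnings attached to a result object
#'
#' Applicability-domain and clamping diagnostics are attached to result
#' objects as a character vector rather than signalled, so screening runs
#' over many rows are not interrupted.
#'
#' @param x A result returned by [estimate_dp()], [estimate_kms()] or
#'   [migrated_fraction()].
#' @return Character vector of warning messages (zero-length if none).
#' @export
result_warnings <- function(x) {
  w <- attr(x, "warnings")
  if (is.null(w)) character(0) else w
}
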