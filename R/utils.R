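#' Unit helpers
#'
#' All internal computation uses SI units: concentrations in molar (M),
#' times in seconds (s), rates in s^-1 or M^-1 s^-1. These helpers convert
#' the bench-side idiom (micromolar, nanomolar, minutes, milliseconds) to SI
#' at the interface.
#'
#' @param x numeric vector.
#' @return numeric vector in SI units (M or s).
#' @examples
#' uM(2)        # 2e-6 M
#' minutes(62)  # 3720 s
#' @export
uM <- function(x) x * 1e-6

#' @rdname uM
#' @export
nM <- function(x) x * 1e-9

#' @rdname uM
#' @export
minutes <- function(x) x * 60

#' @rdname uM
#' @export
ms <- function(x) x * 1e-3

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All synthetic-data generators go through this,
# which makes them pure functions of (truth, noise spec).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_if_not_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single finite nonnegative number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_times <- function(times, require_zero_start = FALSE) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop("'times' must be a numeric vector without missing values",
         call. = FALSE)
  }
  if (any(times < 0)) stop("'times' must be nonnegative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (require_zero_start && times[1L] != 0) {
    stop("'times' must start at 0", call. = FALSE)
  }
  invisible(times)
}
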