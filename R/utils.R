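# Internal helpers shared across modules.

#' Evaluate code with a private, restorable RNG state
#'
#' Seeds the RNG, runs `code`, then restores whatever `.Random.seed` the
#' caller had, so simulation functions are pure in (params, seed) and never
#' perturb the user's random stream.
#'
#' @noRd
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Scalar checks used by constructors; abort with the argument name.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_date <- function(x, name) {
  if (inherits(x, "Date") && length(x) == 1 && !is.na(x)) return(invisible(x))
  if (is.character(x) && length(x) == 1) {
    d <- suppressWarnings(as.Date(x))
    if (!is.na(d)) return(invisible(d))
  }
  abort(sprintf("`%s` must be a single Date (or ISO 'YYYY-MM-DD' string).",
                name))
}

as_scalar_date <- function(x, name) {
  check_date(x, name)
  as.Date(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
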