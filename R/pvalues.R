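#' Validate a set of p-values
#'
#' Checks a numeric vector of per-test p-values and returns it unchanged
#' (apart from dropping names). All downstream functions accept any numeric
#' vector and call this validator themselves; it exists so that malformed
#' input fails early with a clear message. Input order is preserved: all
#' sorting inside the package is internal and never reorders caller data.
#'
#' @param p Numeric vector of p-values, each in \[0, 1\].
#' @return The validated numeric vector of p-values.
#' @examples
#' as_pvalues(c(0.01, 0.2, 0.95))
#' @export
as_pvalues <- function(p) {
  if (is.null(p) || length(p) == 0L) {
    stop("p-value set is empty: at least one p-value is required", call. = FALSE)
  }
  if (!is.numeric(p)) {
    stop("p-values must be numeric", call. = FALSE)
  }
  p <- as.numeric(p)
  if (anyNA(p)) {
    stop("p-values contain NA", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  unname(p)
}

#' Read p-values from a plain-text file
#'
#' Reads one p-value per line. Blank lines and lines starting with `#` are
#' skipped, matching the input format of the classic SGoF+ command-line
#' software.
#'
#' @param path Path to a text file with one p-value per line.
#' @return Numeric vector of validated p-values, in file order.
#' @export
read_pvalues <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("no p-values found in '", path, "'", call. = FALSE)
  }
  p <- suppressWarnings(as.numeric(lines))
  if (anyNA(p)) {
    stop("non-numeric line(s) in '", path, "'", call. = FALSE)
  }
  as_pvalues(p)
}

# Run code with a private RNG state: seeds deterministically, then restores
# whatever .Random.seed the caller had (or removes it if there was none).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  as.numeric(alpha)
}
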