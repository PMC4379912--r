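#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported ages and percentages
#' follow the half-up convention of published tables instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (half away from zero).
#' @export
#' @examples
#' round_half_up(c(0.855, 2.5, -2.5), c(2, 0, 0))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a relative epsilon so values stored just under .5 (e.g. 43.945
  # represented as 43.94499...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9 * pmax(1, abs(x))) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MT_LENGTH <- 16569L
CONTROL_REGION <- c(16024L, 576L) # circular interval 16024..16569 + 1..576

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

transition_partner <- function(base) {
  unname(c(A = "G", G = "A", C = "T", T = "C")[base])
}

is_transition <- function(ref, derived) {
  (ref %in% PURINES & derived %in% PURINES) |
    (ref %in% PYRIMIDINES & derived %in% PYRIMIDINES)
}

dna_complement <- function(base) {
  unname(c(A = "T", T = "A", C = "G", G = "C", "-" = "-")[base])
}

## ---- circular 1-based inclusive intervals ---------------------------------

#' Normalise covered intervals
#'
#' Covered ranges are 1-based inclusive and may wrap the circular genome
#' (e.g. 16024-407 means 16024..16569 plus 1..407).
#'
#' @param covered two-column matrix (start, end), or a numeric vector of
#'   length 2, or a list of such vectors.
#' @return integer matrix with columns `start`, `end`.
#' @keywords internal
as_intervals <- function(covered) {
  if (is.null(covered)) covered <- c(1L, MT_LENGTH)
  if (is.list(covered)) covered <- do.call(rbind, covered)
  if (is.vector(covered)) covered <- matrix(covered, ncol = 2, byrow = TRUE)
  m <- matrix(as.integer(covered), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (any(m < 1L | m > MT_LENGTH)) stop("interval bounds outside [1, 16569]")
  m
}

#' Expand covered intervals to positions / test membership
#'
#' @param covered covered interval(s): two-column matrix or `c(start, end)`;
#'   circular wrap allowed.
#' @return `covered_positions`: sorted integer vector of covered positions.
#' @export
#' @examples
#' length(covered_positions(c(16024, 407))) # 953
covered_positions <- function(covered) {
  m <- as_intervals(covered)
  sort(unique(unlist(lapply(seq_len(nrow(m)), function(i) {
    interval_positions(m[i, ])
  }))))
}

#' @rdname covered_positions
#' @param pos integer vector of positions.
#' @return `position_in_covered`: logical vector, one entry per `pos`.
#' @export
position_in_covered <- function(pos, covered) {
  m <- as_intervals(covered)
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(m))) {
    s <- m[i, 1]; e <- m[i, 2]
    out <- out | if (s <= e) pos >= s & pos <= e else pos >= s | pos <= e
  }
  out
}

interval_positions <- function(iv) {
  if (iv[1] <= iv[2]) iv[1]:iv[2] else c(iv[1]:MT_LENGTH, 1:iv[2])
}

in_control_region <- function(pos) {
  pos >= CONTROL_REGION[1] | pos <= CONTROL_REGION[2]
}

#' Parse a flat key-value configuration file
#'
#' Reads a minimal flat YAML dialect: one `key: value` pair per line,
#' `#` comments and blank lines ignored. Values are returned as character.
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  stats::setNames(lapply(kv, function(x) trimws(x[3])),
                  vapply(kv, function(x) x[2], ""))
}
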