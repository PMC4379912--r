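## Moran's I correlograms over geographic distance classes.

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees; vectors
#'   recycle.
#' @return distance in kilometres (mean Earth radius 6,371 km).
#' @export
#' @examples
#' great_circle_distance(0, 0, 0, 90) # quarter circumference ~ 10,007.5
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("invalid coordinates")
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

pairwise_km <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- great_circle_distance(lat[i], lon[i], lat[j], lon[j])
  }
  d
}

#' Distance class boundaries for a correlogram
#'
#' Default: `k` equal-width classes over `(0, max pairwise distance]`;
#' `"equal_count"` instead places boundaries at pair-count quantiles.
#'
#' @param lat,lon coordinates of the populations (>= 2 points).
#' @param k number of classes (>= 1).
#' @param method `"equal_width"` or `"equal_count"`.
#' @return numeric vector of class boundaries of length `k + 1` (first
#'   element 0; classes are `(b[i], b[i+1]]`).
#' @export
make_distance_classes <- function(lat, lon, k = 5,
                                  method = c("equal_width", "equal_count")) {
  method <- match.arg(method)
  if (length(lat) < 2) stop("need >= 2 points")
  d <- pairwise_km(lat, lon)
  dv <- d[upper.tri(d)]
  if (max(dv) == 0) stop("all points identical")
  if (method == "equal_width") {
    b <- seq(0, max(dv), length.out = k + 1)
  } else {
    b <- c(0, stats::quantile(dv, probs = seq_len(k) / k, names = FALSE))
    b[k + 1] <- max(dv)
  }
  b
}

morans_i_class <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(w)
  (n / s0) * as.numeric(z %*% w %*% z) / sum(z^2)
}

#' Moran's I correlogram
#'
#' For each distance class `c`, binary weights `w_ij = 1` iff the
#' great-circle distance between populations i and j falls in `c`, and
#' `I_c = (n / sum w) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2`. Significance per class by random permutation of the values over
#' locations, two-sided around the null expectation `-1/(n-1)` with the
#' add-one rule `(b + 1) / (m + 1)`.
#'
#' @param values per-population values (e.g. a haplogroup frequency); must
#'   not be constant.
#' @param lat,lon population coordinates.
#' @param classes class boundaries from [make_distance_classes()], or an
#'   integer number of equal-width classes.
#' @param permutations permutation count (default 999).
#' @param seed RNG seed (required when `permutations > 0`).
#' @return object of class `correlogram`: data.frame `table` with columns
#'   `lower`, `upper`, `n_pairs`, `I`, `expected`, `p`; plus `permutations`,
#'   `seed`.
#' @export
morans_i_correlogram <- function(values, lat, lon, classes = 5,
                                 permutations = 999, seed = NULL) {
  n <- length(values)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(values) == 0) stop("constant values: Moran's I undefined")
  if (length(classes) == 1) classes <- make_distance_classes(lat, lon, classes)
  if (permutations > 0) {
    if (is.null(seed)) stop("seed required for permutation test")
    set.seed(seed)
  }
  d <- pairwise_km(lat, lon)
  e_i <- -1 / (n - 1)
  k <- length(classes) - 1
  perms <- if (permutations > 0)
    replicate(permutations, sample(values)) else NULL
  rows <- lapply(seq_len(k), function(ci) {
    w <- (d > classes[ci] & d <= classes[ci + 1]) * 1
    diag(w) <- 0
    npairs <- sum(w) / 2
    if (npairs == 0)
      return(data.frame(lower = classes[ci], upper = classes[ci + 1],
                        n_pairs = 0, I = NA_real_, expected = e_i,
                        p = NA_real_))
    iobs <- morans_i_class(values, w)
    p <- NA_real_
    if (permutations > 0) {
      istar <- apply(perms, 2, morans_i_class, w = w)
      p <- (sum(abs(istar - e_i) >= abs(iobs - e_i) - 1e-12) + 1) /
        (permutations + 1)
    }
    data.frame(lower = classes[ci], upper = classes[ci + 1],
               n_pairs = npairs, I = iobs, expected = e_i, p = p)
  })
  structure(list(table = do.call(rbind, rows), permutations = permutations,
                 seed = seed), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("Moran's I correlogram (", x$permutations, " permutations):\n", sep = "")
  print(transform(x$table, I = round(I, 4), p = round(p, 4)), row.names = FALSE)
  invisible(x)
}

#' Write a correlogram as TSV
#'
#' @param cg a `correlogram`.
#' @param path output path.
#' @export
write_correlogram <- function(cg, path) {
  utils::write.table(cg$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
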