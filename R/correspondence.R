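#' Labeled sensitivity vector
#'
#' Nonnegative sensitivities (units of 1/noise-sd), one per texture
#' statistic, used in the degree-of-correspondence comparison. Typically a
#' 3-vector over the statistics shared between studies (e.g. `beta_h`,
#' `theta`, `alpha`).
#'
#' @param values Nonnegative numeric values, not all zero.
#' @param labels Distinct statistic names, one per value.
#' @return Named numeric vector of class `sensitivity_vector`.
#' @export
sensitivity_vector <- function(values, labels = names(values)) {
  force(labels)
  values <- as.numeric(values)
  if (is.null(labels)) stop("sensitivity values must be labeled", call. = FALSE)
  stopifnot(length(labels) == length(values))
  if (anyDuplicated(labels)) stop("labels must be distinct", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("sensitivities must be finite and nonnegative", call. = FALSE)
  }
  if (all(values == 0)) stop("sensitivity vector must be nonzero", call. = FALSE)
  structure(stats::setNames(values, labels), class = "sensitivity_vector")
}

as_sensitivity <- function(v) {
  if (inherits(v, "sensitivity_vector")) v else sensitivity_vector(v)
}

#' Degree of correspondence between two sensitivity vectors
#'
#' The cosine of the angle between two nonnegative sensitivity vectors:
#' `c(u, v) = (u . v) / (||u|| ||v||)`. Because both vectors lie in the
#' positive orthant, `c` is confined to `[0, 1]`, with 1 indicating a
#' perfect match up to a scaling factor. Scale-invariant and symmetric.
#'
#' @param u,v [sensitivity_vector()]s with matching labels.
#' @return Cosine similarity in `[0, 1]`.
#' @examples
#' u <- sensitivity_vector(c(beta_h = 3, theta = 4, alpha = 0))
#' v <- sensitivity_vector(c(beta_h = 4, theta = 3, alpha = 0))
#' degree_of_correspondence(u, v)  # 24/25
#' @export
degree_of_correspondence <- function(u, v) {
  u <- as_sensitivity(u); v <- as_sensitivity(v)
  if (!identical(names(u), names(v))) {
    if (setequal(names(u), names(v))) {
      v <- sensitivity_vector(unclass(v)[names(u)])
    } else {
      stop(sprintf("label mismatch: {%s} vs {%s}",
                   paste(names(u), collapse = ","),
                   paste(names(v), collapse = ",")), call. = FALSE)
    }
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  # rounding can push parallel vectors infinitesimally past 1
  min(max(sum(u * v) / (nu * nv), 0), 1)
}

#' Scale a sensitivity vector to unit Euclidean norm
#'
#' @param v A [sensitivity_vector()].
#' @return The vector scaled to norm 1; direction (and any cosine with
#'   other vectors) unchanged.
#' @export
unit_normalize <- function(v) {
  v <- as_sensitivity(v)
  sensitivity_vector(unclass(v) / sqrt(sum(v^2)))
}

#' Sample the positive-orthant null distribution of cosines
#'
#' The null hypothesis for the degree of correspondence is that the two
#' sensitivity vectors are unrelated directions in the positive orthant of
#' 3-D space. Each null draw takes two random unit vectors with spherical
#' angles `theta1, theta2, phi1, phi2` i.i.d. uniform on `[0, pi/2]` and
#' returns their cosine
#' `c_null = cos(theta1) cos(theta2) + cos(phi1 - phi2) sin(theta1) sin(theta2)`.
#'
#' @param n Number of samples.
#' @param seed Optional seed.
#' @return Numeric vector of `n` cosines, all in `[0, 1]`.
#' @export
sample_null_cosines <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    t1 <- stats::runif(n, 0, pi / 2)
    t2 <- stats::runif(n, 0, pi / 2)
    f1 <- stats::runif(n, 0, pi / 2)
    f2 <- stats::runif(n, 0, pi / 2)
    cos(t1) * cos(t2) + cos(f1 - f2) * sin(t1) * sin(t2)
  })
}

#' Monte Carlo p-value for an observed degree of correspondence
#'
#' Fraction of null cosine samples strictly greater than the observed
#' value. The default `n = 1e7` matches the resolution used for the
#' reported tail probabilities; samples are drawn in blocks to bound
#' memory.
#'
#' @param c_obs Observed cosine in `[0, 1]`.
#' @param n Number of null samples.
#' @param seed Optional seed.
#' @param block Samples per block.
#' @return p-value in `[0, 1]`.
#' @export
monte_carlo_pvalue <- function(c_obs, n = 1e7, seed = NULL, block = 1e6) {
  stopifnot(is.numeric(c_obs), length(c_obs) == 1L,
            c_obs >= 0, c_obs <= 1, n >= 1)
  with_seed(seed, {
    exceed <- 0
    left <- n
    while (left > 0) {
      m <- min(block, left)
      exceed <- exceed + sum(sample_null_cosines(m) > c_obs)
      left <- left - m
    }
    exceed / n
  })
}

#' Degree-of-correspondence test
#'
#' Computes the cosine between two sensitivity vectors and its Monte Carlo
#' p-value under the positive-orthant null.
#'
#' @inheritParams degree_of_correspondence
#' @param n Number of null samples.
#' @param seed Optional seed.
#' @return Object of class `correspondence_result`: list with `c`,
#'   `p_value`, `n_null_samples`, `seed`.
#' @export
correspondence_test <- function(u, v, n = 1e7, seed = NULL) {
  c_obs <- degree_of_correspondence(u, v)
  structure(
    list(c = c_obs,
         p_value = monte_carlo_pvalue(c_obs, n = n, seed = seed),
         n_null_samples = n,
         seed = seed),
    class = "correspondence_result"
  )
}

#' @export
print.correspondence_result <- function(x, ...) {
  cat(sprintf(
    "degree of correspondence: c = %.4f (p = %.4g, %g Monte Carlo null samples)\n",
    x$c, x$p_value, x$n_null_samples))
  invisible(x)
}

#' Read a sensitivity vector from CSV or JSON
#'
#' CSV format: columns `label,value`. JSON format: an object mapping
#' labels to values.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A [sensitivity_vector()].
#' @export
read_sensitivity <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    return(sensitivity_vector(unlist(obj)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "value") %in% names(df))) {
    stop(sprintf("'%s': expected columns label,value", path), call. = FALSE)
  }
  sensitivity_vector(df$value, df$label)
}
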