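#' Texture specification
#'
#' Bundles the parameters of a maximum-entropy binary texture: the glider
#' kind whose statistic is controlled, the signed intensity of that
#' statistic, the image size, and an RNG seed for reproducibility.
#'
#' Intensity is the target expectation of the glider's spin product
#' (white = +1, black = -1) over all placements: 0 is white noise and
#' +/-1 forces the parity of every placement. Textures default to the
#' 39x22-pixel landscape format used for full-field rodent stimuli.
#'
#' @param glider One of [GLIDER_KINDS].
#' @param intensity Signed statistic level in `[-1, 1]`.
#' @param height,width Texture dimensions in pixels (rows, columns).
#' @param seed Optional integer seed; identical specs generate identical
#'   textures.
#' @return An object of class `texture_spec`.
#' @seealso [generate_texture()]
#' @export
texture_spec <- function(glider, intensity, height = 22L, width = 39L,
                         seed = NULL) {
  glider <- match_glider(glider)
  stopifnot(is.numeric(intensity), length(intensity) == 1L)
  if (!is.finite(intensity) || abs(intensity) > 1) {
    stop("intensity must lie in [-1, 1]", call. = FALSE)
  }
  height <- as.integer(height)
  width <- as.integer(width)
  min_dim <- if (glider == "gamma") 1L else 2L
  if (height < min_dim || width < min_dim) {
    stop(sprintf("texture must be at least %dx%d for glider '%s'",
                 min_dim, min_dim, glider), call. = FALSE)
  }
  structure(
    list(glider = glider, intensity = intensity,
         height = height, width = width, seed = seed),
    class = "texture_spec"
  )
}

#' @export
print.texture_spec <- function(x, ...) {
  cat(sprintf("texture spec: %s at intensity %+.3f, %d x %d (h x w)%s\n",
              x$glider, x$intensity, x$height, x$width,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Construct a texture object from a pixel matrix
#'
#' @param pixels Matrix of 0 (black) and 1 (white) values.
#' @return An object of class `texture`: the integer pixel matrix, with the
#'   generating spec (if any) attached as an attribute.
#' @export
as_texture <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!all(pixels %in% c(0, 1))) {
    stop("texture pixels must be exactly 0 (black) or 1 (white)", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("texture", "matrix"))
}

#' Spin view of a texture
#'
#' Maps pixels to spins: white (1) -> +1, black (0) -> -1. Glider
#' statistics are defined on this view.
#'
#' @param tex A `texture` object or 0/1 matrix.
#' @return Integer matrix of -1/+1 values.
#' @export
spins <- function(tex) {
  z <- 2L * unclass(as_texture(tex)) - 1L
  z
}

#' @export
print.texture <- function(x, ...) {
  cat(sprintf("binary texture, %d x %d (h x w)\n", nrow(x), ncol(x)))
  spec <- attr(x, "spec")
  if (!is.null(spec)) print(spec)
  invisible(x)
}

# draw n spins, +1 with probability p_plus
rspin <- function(n, p_plus) {
  ifelse(stats::runif(n) < p_plus, 1L, -1L)
}

#' Generate a maximum-entropy glider texture
#'
#' Samples a binary texture from the maximum-entropy ensemble whose
#' expected glider statistic equals the requested intensity, leaving all
#' other structure as random as possible.
#'
#' The constructions are glider-specific:
#' \describe{
#'   \item{gamma}{i.i.d. pixels, white with probability `(1+intensity)/2`.}
#'   \item{beta_*}{independent 1-D Markov chains along the glider axis
#'     (rows, columns, or diagonals): each chain starts from a fair coin
#'     and each successive spin repeats its predecessor with probability
#'     `(1+intensity)/2`.}
#'   \item{theta_*}{first row and column seeded with fair coins; the
#'     remaining cells are filled in raster order so that each new glider
#'     placement's parity is +1 with probability `(1+intensity)/2`.
#'     Non-canonical orientations are produced by generating the canonical
#'     (omitted top-left corner) ensemble and applying the deterministic
#'     flip that maps it to the requested orientation; flips preserve the
#'     maximum-entropy property.}
#'   \item{alpha}{first row and column fair; each remaining spin is the
#'     product of its three upper-left 2x2 neighbors times an independent
#'     sign that is +1 with probability `(1+intensity)/2`.}
#' }
#'
#' @param spec A [texture_spec()].
#' @return A `texture` object with the spec attached.
#' @examples
#' tex <- generate_texture(texture_spec("alpha", 1, seed = 1))
#' measure_statistic(tex, "alpha")  # exactly 1: parity forced
#' @export
generate_texture <- function(spec) {
  if (!inherits(spec, "texture_spec")) {
    stop("spec must be a texture_spec object", call. = FALSE)
  }
  h <- spec$height; w <- spec$width
  g <- spec$intensity
  p <- (1 + g) / 2
  z <- with_seed(spec$seed, switch(
    spec$glider,
    gamma = matrix(rspin(h * w, p), h, w, byrow = TRUE),
    beta_h = gen_beta_chains(h, w, p, axis = "h"),
    beta_v = gen_beta_chains(h, w, p, axis = "v"),
    beta_dmain = gen_beta_chains(h, w, p, axis = "dmain"),
    beta_danti = gen_beta_chains(h, w, p, axis = "danti"),
    theta_tl = gen_theta_canonical(h, w, p),
    theta_tr = gen_theta_canonical(h, w, p)[, w:1, drop = FALSE],
    theta_bl = gen_theta_canonical(h, w, p)[h:1, , drop = FALSE],
    theta_br = gen_theta_canonical(h, w, p)[h:1, w:1, drop = FALSE],
    alpha = gen_alpha(h, w, p)
  ))
  tex <- as_texture((z + 1L) %/% 2L)
  attr(tex, "spec") <- spec
  tex
}

# Markov chains of "repeat previous spin with probability p" along the
# rows (h), columns (v), or diagonals (dmain: down-right, danti: down-left).
# Diagonal chains are expressed as a row recurrence: each cell copies its
# diagonal predecessor times a +/-1 step, with fresh fair seeds where a
# diagonal enters the lattice.
gen_beta_chains <- function(h, w, p, axis) {
  if (axis == "v") {
    return(t(gen_beta_chains(w, h, p, axis = "h")))
  }
  z <- matrix(0L, h, w)
  if (axis == "h") {
    z[, 1L] <- rspin(h, 0.5)
    if (w > 1L) {
      steps <- matrix(rspin(h * (w - 1L), p), h, w - 1L, byrow = TRUE)
      for (j in 2:w) z[, j] <- z[, j - 1L] * steps[, j - 1L]
    }
    return(z)
  }
  z[1L, ] <- rspin(w, 0.5)
  for (i in 2:h) {
    if (axis == "dmain") {
      z[i, 1L] <- rspin(1L, 0.5)
      if (w > 1L) z[i, 2:w] <- z[i - 1L, 1:(w - 1L)] * rspin(w - 1L, p)
    } else { # danti
      if (w > 1L) z[i, 1:(w - 1L)] <- z[i - 1L, 2:w] * rspin(w - 1L, p)
      z[i, w] <- rspin(1L, 0.5)
    }
  }
  z
}

# Canonical three-point ensemble: omitted corner top-left, so each new cell
# z[i,j] closes the L {(i-1,j),(i,j-1),(i,j)} with parity sign r.
# Row recurrence: z[i,j] = z[i,1] * cumprod(z[i-1,j'] * r[j']) over j' = 2..j.
gen_theta_canonical <- function(h, w, p) {
  z <- matrix(0L, h, w)
  z[1L, ] <- rspin(w, 0.5)
  z[2:h, 1L] <- rspin(h - 1L, 0.5)
  for (i in 2:h) {
    u <- z[i - 1L, 2:w] * rspin(w - 1L, p)
    z[i, 2:w] <- z[i, 1L] * cumprod(u)
  }
  z
}

# Four-point ensemble: z[i,j] = z[i-1,j] z[i,j-1] z[i-1,j-1] r, filled in
# raster order via the same cumulative-product row recurrence.
gen_alpha <- function(h, w, p) {
  z <- matrix(0L, h, w)
  z[1L, ] <- rspin(w, 0.5)
  z[2:h, 1L] <- rspin(h - 1L, 0.5)
  for (i in 2:h) {
    u <- z[i - 1L, 2:w] * z[i - 1L, 1:(w - 1L)] * rspin(w - 1L, p)
    z[i, 2:w] <- z[i, 1L] * cumprod(u)
  }
  z
}

#' Measure the empirical glider statistic of a texture
#'
#' Averages the product of spin values (+1 white, -1 black) at the glider's
#' cells over every fully-in-bounds placement of the glider.
#'
#' @param tex A `texture` object or 0/1 matrix.
#' @param kind One of [GLIDER_KINDS].
#' @return A value in `[-1, 1]`.
#' @examples
#' checker <- as_texture(outer(1:4, 1:4, function(i, j) (i + j) %% 2))
#' measure_statistic(checker, "beta_h")  # -1: adjacent spins always differ
#' measure_statistic(checker, "alpha")   # +1: 2x2 parity is even
#' @export
measure_statistic <- function(tex, kind) {
  z <- spins(tex)
  off <- glider_offsets(kind)
  ext_r <- max(off[, "row"]); ext_c <- max(off[, "col"])
  nr <- nrow(z) - ext_r; nc <- ncol(z) - ext_c
  if (nr < 1L || nc < 1L) {
    stop("texture is smaller than the glider bounding box", call. = FALSE)
  }
  prod <- matrix(1L, nr, nc)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, "row"]; dc <- off[k, "col"]
    prod <- prod * z[(1L + dr):(nr + dr), (1L + dc):(nc + dc), drop = FALSE]
  }
  mean(prod)
}

#' Full statistic profile of a texture
#'
#' @param tex A `texture` object or 0/1 matrix, at least 2x2.
#' @return Named numeric vector: [measure_statistic()] for all ten glider
#'   kinds.
#' @export
statistic_profile <- function(tex) {
  vapply(GLIDER_KINDS, function(k) measure_statistic(tex, k), numeric(1))
}
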