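#' Glider kinds
#'
#' The ten local pixel templates ("gliders") that define the multipoint
#' texture statistics. Each glider is a set of 1--4 cells inside a 2x2
#' bounding box; the statistic of a texture is the average, over all
#' fully-in-bounds placements of the glider, of the product of the spin
#' values (+1 = white, -1 = black) at the glider cells.
#'
#' Naming follows the field's convention by glider order:
#' \describe{
#'   \item{`gamma`}{one-point (luminance): a single cell.}
#'   \item{`beta_h`, `beta_v`, `beta_dmain`, `beta_danti`}{two-point pairs:
#'     horizontal, vertical, main-diagonal and anti-diagonal neighbors.}
#'   \item{`theta_tl`, `theta_tr`, `theta_bl`, `theta_br`}{three-point
#'     L-shaped gliders, named after the omitted corner of the 2x2 box
#'     (top-left, top-right, bottom-left, bottom-right).}
#'   \item{`alpha`}{four-point: the full 2x2 block.}
#' }
#'
#' @format A character vector of the ten glider names.
#' @seealso [glider_offsets()], [measure_statistic()]
#' @export
GLIDER_KINDS <- c(
  "gamma",
  "beta_h", "beta_v", "beta_dmain", "beta_danti",
  "theta_tl", "theta_tr", "theta_bl", "theta_br",
  "alpha"
)

# canonical cell sets, 0-based (row, col) offsets within the 2x2 box
.glider_offset_table <- list(
  gamma      = rbind(c(0L, 0L)),
  beta_h     = rbind(c(0L, 0L), c(0L, 1L)),
  beta_v     = rbind(c(0L, 0L), c(1L, 0L)),
  beta_dmain = rbind(c(0L, 0L), c(1L, 1L)),
  beta_danti = rbind(c(0L, 1L), c(1L, 0L)),
  theta_tl   = rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L)),
  theta_tr   = rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L)),
  theta_bl   = rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L)),
  theta_br   = rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L)),
  alpha      = rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
)

#' Cell offsets of a glider
#'
#' Returns the canonical cell offsets of a glider kind as a two-column
#' integer matrix of 0-based `(row, col)` positions within the 2x2
#' bounding box. Rows increase downward; the origin is the top-left cell.
#'
#' @param kind One of [GLIDER_KINDS].
#' @return Integer matrix with columns `row` and `col`, one row per cell.
#' @examples
#' glider_offsets("beta_h")   # horizontal pair
#' glider_offsets("alpha")    # full 2x2 block
#' @export
glider_offsets <- function(kind) {
  kind <- match_glider(kind)
  off <- .glider_offset_table[[kind]]
  dimnames(off) <- list(NULL, c("row", "col"))
  off
}

#' Number of cells in a glider
#'
#' @param kind One of [GLIDER_KINDS].
#' @return Integer in 1..4 (the order of the corresponding statistic).
#' @export
glider_order <- function(kind) {
  nrow(glider_offsets(kind))
}

match_glider <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L) {
    stop("glider kind must be a single string", call. = FALSE)
  }
  kind <- tolower(kind)
  if (!kind %in% GLIDER_KINDS) {
    stop(sprintf(
      "unknown glider kind '%s'; valid kinds: %s",
      kind, paste(GLIDER_KINDS, collapse = ", ")
    ), call. = FALSE)
  }
  kind
}
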