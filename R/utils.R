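# Internal helpers shared across modules.

#' @importFrom stats median quantile rnorm runif sd kmeans pnorm uniroot approx
#' @importFrom utils head tail
NULL

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         lo = NULL, hi = NULL, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (integer && x != round(x)) abort_field(field, "must be an integer")
  if (positive && x <= 0) abort_field(field, "must be > 0")
  if (nonneg && x < 0) abort_field(field, "must be >= 0")
  if (!is.null(lo) && x < lo) abort_field(field, sprintf("must be >= %s", lo))
  if (!is.null(hi) && x > hi) abort_field(field, sprintf("must be <= %s", hi))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# EBImage stores images as (x, y); the package convention is matrix[y, x].
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

# Linear indices of pixels inside an ellipse (centre in px, semi-axes in px,
# orientation in degrees from +x, y down). Clipped to the raster.
ellipse_pixels <- function(cx, cy, a, b, theta_deg, nrow_px, ncol_px) {
  th <- theta_deg * pi / 180
  ext <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  eyt <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  x0 <- max(1L, floor(cx - ext)); x1 <- min(ncol_px, ceiling(cx + ext))
  y0 <- max(1L, floor(cy - eyt)); y1 <- min(nrow_px, ceiling(cy + eyt))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  row_idx <- rep(ys, times = length(xs))
  col_idx <- rep(xs, each = length(ys))
  (col_idx[inside] - 1L) * nrow_px + row_idx[inside]
}

# Fold an undirected axis-angle difference into [0, 90] degrees.
fold_angle <- function(deg) {
  d <- deg %% 180
  ifelse(d > 90, 180 - d, d)
}

# Quantize a [0,1] float raster to the 16-bit grid so TIFF round-trips are
# lossless.
quantize16 <- function(m) round(pmin(pmax(m, 0), 1) * 65535) / 65535

largest_component <- function(mask) {
  lbl <- from_ebi(EBImage::bwlabel(as_ebi(mask)))
  if (max(lbl) == 0L) return(mask & FALSE)
  tab <- tabulate(lbl[lbl > 0L])
  lbl == which.max(tab)
}
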