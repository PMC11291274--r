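# Shift a matrix by (dr, dc) pixels, padding with NA. Positive dr moves
# values down (southward source offset -dr).
.shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  r_dst <- max(1, 1 + dr):min(nr, nr + dr)
  c_dst <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(r_dst) < 1 || length(c_dst) < 1) return(out)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

#' Circular focal mean
#'
#' Replaces each pixel by the mean of valid pixels whose centers lie within
#' `radius_px` pixels (Euclidean distance in pixel units) of its center, the
#' focal pixel included. The default radius of 1.5 selects the 8-connected
#' 3x3 neighbourhood plus center. With `fill_only = TRUE` valid pixels pass
#' through unchanged and only nodata pixels receive the neighbourhood mean,
#' which is the gap-filling mode used when interpolating isolated holes in
#' the depth-to-groundwater layer. Pixels with no valid neighbour stay
#' nodata.
#'
#' @param grid a [raster_grid()].
#' @param radius_px neighbourhood radius in pixels (>= 1).
#' @param fill_only logical; only fill nodata pixels, never overwrite valid
#'   ones.
#' @return A `raster_grid` of the same geometry.
#' @export
focal_mean <- function(grid, radius_px = 1.5, fill_only = FALSE) {
  if (!is.numeric(radius_px) || length(radius_px) != 1 || !is.finite(radius_px) ||
      radius_px < 1)
    stop("invalid parameter: radius_px must be a single number >= 1")
  v <- rg_values(grid)
  r <- floor(radius_px)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2, , drop = FALSE]
  s <- matrix(0, nrow(v), ncol(v))
  n <- matrix(0, nrow(v), ncol(v))
  for (i in seq_len(nrow(offs))) {
    sh <- .shift_matrix(v, offs$dr[i], offs$dc[i])
    ok <- !is.na(sh)
    s[ok] <- s[ok] + sh[ok]
    n <- n + ok
  }
  out <- ifelse(n > 0, s / n, NA_real_)
  if (fill_only) {
    keep <- !is.na(v)
    out[keep] <- v[keep]
  }
  rg_like(grid, out)
}

# Mean over an odd square window of side 2*half+1, clipped at grid edges,
# counting only valid (non-NA) pixels. Summed-area tables make this O(n)
# regardless of window size, which is what keeps the multi-kilometre
# temperature-anomaly windows tractable.
.box_mean <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m; z[is.na(z)] <- 0
  cnt <- matrix(as.numeric(!is.na(m)), nr, nc)
  pad_cum <- function(x) {
    s <- matrix(0, nr + 1, nc + 1)
    s[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
    s
  }
  S <- pad_cum(z); C <- pad_cum(cnt)
  r <- seq_len(nr); cc <- seq_len(nc)
  r1 <- pmax(r - half, 1); r2 <- pmin(r + half, nr)
  c1 <- pmax(cc - half, 1); c2 <- pmin(cc + half, nc)
  R1 <- matrix(r1, nr, nc); R2 <- matrix(r2, nr, nc)
  C1 <- matrix(c1, nr, nc, byrow = TRUE); C2 <- matrix(c2, nr, nc, byrow = TRUE)
  win_sum <- function(Scum) {
    Scum[cbind(c(R2 + 1), c(C2 + 1))] - Scum[cbind(c(R1), c(C2 + 1))] -
      Scum[cbind(c(R2 + 1), c(C1))] + Scum[cbind(c(R1), c(C1))]
  }
  tot <- matrix(win_sum(S), nr, nc)
  num <- matrix(win_sum(C), nr, nc)
  ifelse(num > 0, tot / num, NA_real_)
}

# Repeated 5x5 box smoothing of a random field; standardized output.
# Used by the scene generator to build spatially coherent fields.
.smooth_field <- function(nr, nc, passes = 3, half = 2) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) f <- .box_mean(f, half)
  (f - mean(f)) / stats::sd(f)
}
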