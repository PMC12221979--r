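as_volume <- function(x) {
  v <- if (inherits(x, "voxel_grid")) x$values else x
  if (length(dim(v)) != 3L) stop("expected a 3-D volume")
  v
}

# Sliding-window sums over all (D-w+1)^3 fully interior windows, via a
# zero-padded 3-D cumulative-sum (integral volume) table.
box_sums <- function(a, w) {
  d <- dim(a)
  cs <- apply(a, c(2L, 3L), cumsum)
  cs <- aperm(apply(cs, c(1L, 3L), cumsum), c(2L, 1L, 3L))
  cs <- aperm(apply(cs, c(1L, 2L), cumsum), c(2L, 3L, 1L))
  S <- array(0, d + 1L)
  S[-1L, -1L, -1L] <- cs
  lo <- seq_len(d[1L] - w + 1L)
  hi <- lo + w
  S[hi, hi, hi] - S[lo, hi, hi] - S[hi, lo, hi] - S[hi, hi, lo] +
    S[lo, lo, hi] + S[lo, hi, lo] + S[hi, lo, lo] - S[lo, lo, lo]
}

#' Structural similarity index for 3-D volumes
#'
#' Mean local SSIM over a sliding cubic window (uniform weights, interior
#' windows only), with the standard stabilization constants
#' `C1 = (0.01 range)^2` and `C2 = (0.03 range)^2`. Symmetric in its
#' arguments; 1 for identical volumes; can be negative for structurally
#' anti-correlated volumes; constant equal inputs give 1 (the constants
#' prevent 0/0).
#'
#' @param a,b [voxel_grid()]s or 3-D arrays of the same side.
#' @param window cubic window side, default 7.
#' @param data_range value range of the data, default 1.
#' @return SSIM score in \[-1, 1\].
#' @export
ssim3d <- function(a, b, window = 7L, data_range = 1) {
  va <- as_volume(a); vb <- as_volume(b)
  if (!all(dim(va) == dim(vb))) stop("ssim3d: shape mismatch")
  if (dim(va)[1L] < window) stop("ssim3d: volume smaller than window")
  n <- window^3
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_a <- box_sums(va, window) / n
  mu_b <- box_sums(vb, window) / n
  var_a <- box_sums(va * va, window) / n - mu_a^2
  var_b <- box_sums(vb * vb, window) / n - mu_b^2
  cov_ab <- box_sums(va * vb, window) / n - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2)
  mean(num / den)
}

#' Normalized cross-correlation of two volumes
#'
#' Pearson correlation of the flattened, mean-centred volumes, in
#' \[-1, 1\]. Constant inputs have no defined correlation and raise an
#' error.
#'
#' @param a,b [voxel_grid()]s or 3-D arrays of the same side.
#' @return NCC score.
#' @export
ncc <- function(a, b) {
  va <- as.numeric(as_volume(a)); vb <- as.numeric(as_volume(b))
  if (length(va) != length(vb)) stop("ncc: shape mismatch")
  if (sd(va) == 0 || sd(vb) == 0)
    stop("ncc: undefined correlation for a constant volume")
  cor(va, vb)
}
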