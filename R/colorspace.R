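# sRGB <-> CIELAB conversions, D65 / 2 degree observer, exact and invertible.
#
# All functions are matrix-vectorized: colors are n x 3 matrices. The forward
# transform is the IEC 61966-2-1 piecewise sRGB transfer function followed by
# the sRGB-to-XYZ matrix and the CIELAB functions (including the linear branch
# of f below (6/29)^3). The inverse matrix is computed with solve() from the
# same forward matrix, so round trips are exact to floating-point precision.

# D65 reference white on the Y = 100 scale
.white_d65 <- c(X = 95.047, Y = 100.0, Z = 108.883)

# sRGB (linear) -> XYZ, D65, Y scaled to 100. Derived at full precision from
# the sRGB primary chromaticities with columns scaled so that RGB (1,1,1)
# maps exactly to the reference white: neutral colors are then exactly
# achromatic (a* = b* = 0). Agrees with the published 7-digit matrix to ~1e-5.
.srgb_to_xyz_mat <- local({
  xy <- rbind(r = c(0.64, 0.33), g = c(0.30, 0.60), b = c(0.15, 0.06))
  P <- apply(xy, 1, function(p) c(p[1], p[2], 1 - p[1] - p[2]) / p[2])
  P %*% diag(drop(solve(P, .white_d65)))
})

.xyz_to_srgb_mat <- solve(.srgb_to_xyz_mat)

.lab_delta <- 6 / 29 # CIELAB f() linear-branch threshold is .lab_delta^3

.as_color_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop(what, " must be a length-3 vector or an n x 3 matrix", call. = FALSE)
    }
    x <- matrix(x, nrow = 1L)
  }
  x <- unname(as.matrix(x))
  if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  x
}

#' Convert sRGB colors to CIELAB
#'
#' Applies the standard sRGB inverse transfer function (linear below 0.04045,
#' exponent 2.4 above), the sRGB-to-XYZ matrix, and the CIELAB functions with
#' the D65 reference white (Xn = 95.047, Yn = 100, Zn = 108.883).
#'
#' @param rgb A length-3 vector or n x 3 matrix of gamma-encoded sRGB
#'   components in `[0, 1]`.
#' @return An n x 3 matrix with columns `L`, `a`, `b`.
#' @examples
#' srgb_to_lab(c(1, 0, 0)) # the sRGB red primary, L* ~ 53.24
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- .as_color_matrix(rgb, "rgb")
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz_mat)
  t3 <- sweep(xyz, 2, .white_d65, "/")
  d <- .lab_delta
  f <- ifelse(t3 > d^3, sign(t3) * abs(t3)^(1 / 3), t3 / (3 * d^2) + 4 / 29)
  lab <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  lab
}

#' Convert CIELAB colors to sRGB
#'
#' Exact inverse of [srgb_to_lab()] on its range. Out-of-gamut Lab input
#' yields components outside `[0, 1]`; nothing is clamped here, which is what
#' makes the function usable as an analytic gamut-membership test.
#'
#' @param lab A length-3 vector or n x 3 matrix of CIELAB coordinates.
#' @return An n x 3 matrix with columns `r`, `g`, `b` (possibly outside
#'   `[0, 1]` for undisplayable input).
#' @export
lab_to_srgb <- function(lab) {
  lab <- .as_color_matrix(lab, "lab")
  d <- .lab_delta
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  f <- cbind(fx, fy, fz)
  t3 <- ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
  xyz <- sweep(t3, 2, .white_d65, "*")
  lin <- xyz %*% t(.xyz_to_srgb_mat)
  rgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * sign(lin) * abs(lin)^(1 / 2.4) - 0.055)
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

# validation-free Lab -> sRGB kernel for the optimizer's hot path; identical
# arithmetic to lab_to_srgb() but indexed assignment instead of ifelse()
.lab2rgb_raw <- function(lab) {
  d <- .lab_delta
  fy <- (lab[, 1] + 16) / 116
  f <- cbind(fy + lab[, 2] / 500, fy, fy - lab[, 3] / 200)
  t3 <- f * f * f
  low <- f <= d
  t3[low] <- 3 * d^2 * (f[low] - 4 / 29)
  xyz <- t3 * rep(.white_d65, each = nrow(t3))
  lin <- xyz %*% t(.xyz_to_srgb_mat)
  rgb <- 1.055 * sign(lin) * abs(lin)^(1 / 2.4) - 0.055
  low <- lin <= 0.0031308
  rgb[low] <- 12.92 * lin[low]
  rgb
}

# round half away from zero, so hex output is bit-identical across platforms
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Format CIELAB colors as sRGB hex strings
#'
#' @param lab A length-3 vector or n x 3 matrix of CIELAB coordinates.
#' @param clamp If `TRUE`, out-of-gamut colors are clamped channel-wise to
#'   `[0, 1]` in sRGB before formatting. If `FALSE`, out-of-gamut input is an
#'   error naming the offending Lab triple(s).
#' @return A character vector of `"#RRGGBB"` strings (uppercase).
#' @export
lab_to_hex <- function(lab, clamp = TRUE) {
  rgb <- lab_to_srgb(lab)
  out <- rgb < -1e-9 | rgb > 1 + 1e-9
  if (any(out)) {
    if (!clamp) {
      lab <- .as_color_matrix(lab, "lab")
      i <- which(rowSums(out) > 0)[1]
      stop(sprintf(
        "Lab color (%.4g, %.4g, %.4g) is outside the sRGB gamut and clamp = FALSE",
        lab[i, 1], lab[i, 2], lab[i, 3]
      ), call. = FALSE)
    }
    rgb <- pmin(pmax(rgb, 0), 1)
  } else {
    rgb <- pmin(pmax(rgb, 0), 1) # wash out the +-1e-9 tolerance
  }
  chan <- matrix(.round_half_away(255 * rgb), ncol = 3)
  toupper(sprintf("#%02x%02x%02x", chan[, 1], chan[, 2], chan[, 3]))
}
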