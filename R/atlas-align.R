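#' Fit a 2D section-to-atlas transform from landmark pairs
#'
#' Least-squares estimation of a planar transform `T` such that
#' `T(moving) ~ fixed`, from corresponding landmark coordinates in um. The
#' `"similarity"` model (rotation + isotropic scale + translation, closed
#' form via SVD / Umeyama) is the default, matching manual contour-based
#' alignment; `"affine"` adds shear and anisotropic scale.
#'
#' @param fixed_points,moving_points n x 2 matrices (or data.frames) of
#'   `(x, y)` coordinates in um; `n >= 2` for similarity, `n >= 3`
#'   non-collinear for affine.
#' @param model `"similarity"` (default) or `"affine"`.
#' @return A `transform2d`: list with `model`, `A` (2 x 2 matrix), `t`
#'   (length-2 translation), `rms_residual_um`, `n_pairs`. Apply with
#'   [apply_transform()].
#' @export
fit_transform <- function(fixed_points, moving_points,
                          model = c("similarity", "affine")) {
  model <- match.arg(model)
  F <- as.matrix(fixed_points)[, 1:2, drop = FALSE]
  M <- as.matrix(moving_points)[, 1:2, drop = FALSE]
  storage.mode(F) <- "double"; storage.mode(M) <- "double"
  n <- nrow(F)
  if (nrow(M) != n) stopf("fixed and moving point counts differ")
  min_n <- if (model == "similarity") 2L else 3L
  if (n < min_n) stopf("'%s' model needs >= %d landmark pairs", model, min_n)

  if (model == "similarity") {
    mu_f <- colMeans(F); mu_m <- colMeans(M)
    Fc <- sweep(F, 2, mu_f); Mc <- sweep(M, 2, mu_m)
    var_m <- sum(Mc^2) / n
    if (var_m < 1e-12) stopf("degenerate landmark geometry: moving points coincide")
    S <- crossprod(Fc, Mc) / n            # covariance fixed~moving
    sv <- svd(S)
    d_sign <- sign(det(sv$u %*% t(sv$v)))
    D <- diag(c(1, d_sign))
    R <- sv$u %*% D %*% t(sv$v)
    s <- sum(diag(D) * sv$d) / var_m
    A <- s * R
    t <- mu_f - A %*% mu_m
  } else {
    X <- cbind(M, 1)
    if (qr(X)$rank < 3L) stopf("degenerate landmark geometry: collinear points")
    beta <- qr.solve(X, F)                # 3 x 2
    A <- t(beta[1:2, , drop = FALSE])
    t <- as.numeric(beta[3, ])
  }
  tr <- structure(list(model = model, A = A, t = as.numeric(t)),
                  class = "transform2d")
  res <- apply_transform(tr, M) - F
  tr$rms_residual_um <- sqrt(mean(res^2))   # per-coordinate RMS
  tr$n_pairs <- n
  tr
}

#' Apply / invert a 2D transform
#'
#' @param transform a `transform2d`.
#' @param points n x 2 matrix of `(x, y)` um coordinates.
#' @return `apply_transform()`: n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  P <- as.matrix(points)[, 1:2, drop = FALSE]
  sweep(P %*% t(transform$A), 2, transform$t, "+")
}

#' @rdname apply_transform
#' @return `invert_transform()`: the inverse `transform2d`.
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  structure(list(model = transform$model, A = Ai,
                 t = as.numeric(-Ai %*% transform$t)),
            class = "transform2d")
}

#' Identity transform
#' @return A `transform2d` with `A = I`, `t = 0`.
#' @export
identity_transform <- function() {
  structure(list(model = "similarity", A = diag(2), t = c(0, 0)),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d> %s: t = (%.3g, %.3g) um\n", x$model,
              x$t[1], x$t[2]))
  print(x$A)
  invisible(x)
}

#' Grid-displacement registration quality metric
#'
#' Samples a regular grid of reference points across the atlas bounds
#' (anchored at the bounds origin, default spacing 350 um — typically 50-70
#' points on a section-sized field) and reports the displacement
#' `|T(p) - p|` of each point under the fitted transform, plus its mean and
#' sample SD. Under a pure translation `t` every displacement equals `|t|`
#' exactly.
#'
#' @param transform a `transform2d`.
#' @param atlas_bounds_um `(xmin, xmax, ymin, ymax)` in um.
#' @param grid_spacing_um grid spacing (default 350 um).
#' @return A `registration_qc`: `n_points`, `grid_spacing_um`,
#'   `grid_points_um`, `displacements_um`, `mean_um`, `sd_um`.
#' @export
displacement_qc <- function(transform, atlas_bounds_um,
                            grid_spacing_um = 350) {
  b <- as.numeric(atlas_bounds_um)
  if (length(b) != 4L || b[2] < b[1] || b[4] < b[3]) {
    stopf("'atlas_bounds_um' must be (xmin, xmax, ymin, ymax)")
  }
  xs <- seq(b[1], b[2], by = grid_spacing_um)
  ys <- seq(b[3], b[4], by = grid_spacing_um)
  P <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  disp <- sqrt(rowSums((apply_transform(transform, P) - P)^2))
  structure(list(n_points = nrow(P), grid_spacing_um = grid_spacing_um,
                 grid_points_um = P, displacements_um = disp,
                 mean_um = mean(disp),
                 sd_um = if (length(disp) > 1L) sd(disp) else 0),
            class = "registration_qc")
}

#' @export
print.registration_qc <- function(x, ...) {
  cat(sprintf(
    "<registration_qc> %d points at %g um spacing: displacement %.3g +/- %.3g um\n",
    x$n_points, x$grid_spacing_um, x$mean_um, x$sd_um))
  invisible(x)
}

#' Assign atlas region ids to points
#'
#' Maps section coordinates into atlas space with `transform`, then looks up
#' the region label at the nearest atlas pixel. Points that land outside the
#' label image get the background id 0.
#'
#' @param points_um n x 2 matrix of section `(x, y)` coordinates in um.
#' @param map a [region_map()].
#' @param transform a `transform2d` mapping section into atlas coordinates
#'   (default: identity).
#' @return integer vector of region ids.
#' @export
assign_regions <- function(points_um, map, transform = identity_transform()) {
  P <- as.matrix(points_um)[, 1:2, drop = FALSE]
  if (!nrow(P)) return(integer())
  Q <- apply_transform(transform, P)
  px <- map$pixel_size_um
  j <- floor(Q[, 1] / px[1]) + 1
  i <- floor(Q[, 2] / px[2]) + 1
  out <- integer(nrow(P))
  ok <- i >= 1 & i <= nrow(map$labels) & j >= 1 & j <= ncol(map$labels)
  out[ok] <- map$labels[cbind(i[ok], j[ok])]
  out
}
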