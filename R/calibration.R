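# Projective floor-plane calibration: pixel coordinates -> floor cm.

#' Fit a projective transform from four point correspondences
#'
#' Solves the direct linear transform for the 3x3 homography mapping four
#' image (pixel) points to four floor (cm) points, correcting the perspective
#' distortion of a bird's-eye camera. Exactly four correspondences determine
#' the eight degrees of freedom.
#'
#' @param image_points 4x2 matrix of pixel coordinates.
#' @param floor_points 4x2 matrix of floor coordinates (cm).
#' @return an object of class `calibration_map`: list with `matrix` (3x3,
#'   normalized so `matrix[3, 3] == 1`), `image_points`, `floor_points`.
#' @export
fit_projective_transform <- function(image_points, floor_points) {
  image_points <- as.matrix(image_points)
  floor_points <- as.matrix(floor_points)
  stopifnot(nrow(image_points) == 4, ncol(image_points) == 2,
            nrow(floor_points) == 4, ncol(floor_points) == 2)
  if (.any_three_collinear(image_points) || .any_three_collinear(floor_points)) {
    stop("degenerate quadrilateral: three of the four points are collinear")
  }
  # DLT rows: x' = (h1.p)/(h3.p), y' = (h2.p)/(h3.p), h33 fixed to 1.
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (k in 1:4) {
    x <- image_points[k, 1]; y <- image_points[k, 2]
    u <- floor_points[k, 1]; v <- floor_points[k, 2]
    A[2 * k - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * k, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * k - 1] <- u
    b[2 * k] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("calibration failed: correspondence system is singular")
  })
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-12) stop("calibration failed: transform is not invertible")
  map <- structure(list(matrix = H, image_points = image_points,
                        floor_points = floor_points),
                   class = "calibration_map")
  # self-check against the defining correspondences
  err <- max(abs(apply_calibration(image_points, map) - floor_points))
  if (err > 1e-6) stop("calibration failed: residual ", format(err), " cm")
  map
}

.any_three_collinear <- function(p) {
  for (drop in 1:4) {
    q <- p[-drop, , drop = FALSE]
    area2 <- abs((q[2, 1] - q[1, 1]) * (q[3, 2] - q[1, 2]) -
                 (q[3, 1] - q[1, 1]) * (q[2, 2] - q[1, 2]))
    scale <- max(abs(q)) + 1
    if (area2 <= 1e-9 * scale^2) return(TRUE)
  }
  FALSE
}

#' Apply a calibration map to points
#'
#' @param points n x 2 matrix of pixel coordinates.
#' @param map a `calibration_map` (or any 3x3 matrix).
#' @param inverse map floor coordinates back to pixels instead.
#' @return n x 2 matrix of mapped coordinates after perspective division.
#' @export
apply_calibration <- function(points, map, inverse = FALSE) {
  H <- if (inherits(map, "calibration_map")) map$matrix else map
  if (inverse) H <- solve(H)
  points <- matrix(as.numeric(points), ncol = 2)
  ph <- cbind(points, 1) %*% t(H)
  ph[, 1:2, drop = FALSE] / ph[, 3]
}

#' Calibrate a raw digitized session from pixels to floor coordinates
#'
#' @param raw a `raw_digitization` whose series are in pixel coordinates.
#' @param map a `calibration_map`.
#' @return the `raw_digitization` with all series mapped to floor cm.
#' @export
calibrate_session <- function(raw, map) {
  stopifnot(inherits(raw, "raw_digitization"))
  raw$series <- lapply(raw$series, function(s) {
    ok <- !is.na(s$x) & !is.na(s$y)
    if (any(ok)) {
      m <- apply_calibration(cbind(s$x[ok], s$y[ok]), map)
      s$x[ok] <- m[, 1]
      s$y[ok] <- m[, 2]
    }
    s
  })
  raw
}

#' Read a calibration point file (JSON or YAML-like) and fit the transform
#'
#' The file must contain `image_points` and `floor_points`, each 4x2.
#'
#' @param path JSON file with the two point sets.
#' @return a `calibration_map`.
#' @export
read_calibration <- function(path) {
  spec <- jsonlite::fromJSON(path)
  fit_projective_transform(spec$image_points, spec$floor_points)
}
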