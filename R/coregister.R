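# Coregistration of the two serial-section coordinate frames. Serial
# 3-micron sections are related by a near-similarity transform, so the
# default model is scaled-rotation + translation estimated by closed-form
# Procrustes on landmark pairs, with an optional landmark-free ICP
# refinement on dense (e.g. PCK+ centroid) clouds.

#' Construct a 2-D affine/similarity transform
#'
#' @param A 2x2 linear part (must be invertible).
#' @param b Length-2 translation (micrometres).
#' @param kind One of `"identity"`, `"similarity"`, `"affine"`.
#' @param rmse_um Root-mean-square fit residual, if the transform was
#'   estimated from data.
#' @return Object of class `transform2d`.
#' @export
transform2d <- function(A = diag(2), b = c(0, 0), kind = "affine",
                        rmse_um = NA_real_) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < .Machine$double.eps) {
    stop("transform linear part is singular")
  }
  if (kind == "similarity") {
    s2 <- sum(A[, 1]^2)
    ortho <- max(abs(crossprod(A) - s2 * diag(2)))
    if (ortho > 1e-8 * max(1, s2)) {
      stop("similarity transform requires a scaled-orthogonal linear part")
    }
  }
  structure(list(A = A, b = as.numeric(b), kind = kind,
                 rmse_um = rmse_um),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d %s> det=%.6g rmse=%.4g um\n",
              x$kind, det(x$A), x$rmse_um))
  invisible(x)
}

#' Apply a 2-D transform to points
#'
#' @param points Two-column matrix or data frame with `x_um`/`y_um`.
#' @param t A `transform2d`.
#' @return Matrix of transformed coordinates (or the input data frame with
#'   coordinates replaced, if a data frame was supplied).
#' @export
apply_transform <- function(points, t) {
  stopifnot(inherits(t, "transform2d"))
  xy <- as_xy_matrix(points)
  out <- xy %*% t(t$A)
  out[, 1] <- out[, 1] + t$b[1]
  out[, 2] <- out[, 2] + t$b[2]
  if (is.data.frame(points) && all(c("x_um", "y_um") %in% names(points))) {
    points$x_um <- out[, 1]
    points$y_um <- out[, 2]
    return(points)
  }
  colnames(out) <- c("x_um", "y_um")
  out
}

#' Invert a 2-D transform
#' @param t A `transform2d`.
#' @return The inverse `transform2d`.
#' @export
invert_transform <- function(t) {
  Ai <- solve(t$A)
  transform2d(Ai, -as.numeric(Ai %*% t$b), kind = t$kind)
}

#' Compose transforms (`t2` after `t1`)
#' @param t2,t1 `transform2d` objects.
#' @return `transform2d` equal to applying `t1` then `t2`.
#' @export
compose_transform <- function(t2, t1) {
  kind <- if (t2$kind == "similarity" && t1$kind == "similarity")
    "similarity" else "affine"
  transform2d(t2$A %*% t1$A, as.numeric(t2$A %*% t1$b) + t2$b, kind = kind)
}

#' Estimate a least-squares transform from paired landmarks
#'
#' Similarity transforms use the closed-form orthogonal-Procrustes-with-
#' scale (Umeyama) solution; affine transforms are ordinary least squares.
#'
#' @param moving,fixed Paired point matrices (row i of `moving` corresponds
#'   to row i of `fixed`); at least 2 pairs for a similarity, 3 non-collinear
#'   pairs for an affine transform.
#' @param kind `"similarity"` (default) or `"affine"`.
#' @return A `transform2d` mapping `moving` onto `fixed`, with `rmse_um`.
#' @export
estimate_transform <- function(moving, fixed,
                               kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  M <- as_xy_matrix(moving)
  F <- as_xy_matrix(fixed)
  if (nrow(M) != nrow(F)) stop("moving and fixed must be paired")
  n <- nrow(M)
  if (kind == "similarity" && n < 2) {
    stop("similarity estimation needs at least 2 point pairs")
  }
  if (kind == "affine" && n < 3) {
    stop("affine estimation needs at least 3 point pairs")
  }
  mu_m <- colMeans(M)
  mu_f <- colMeans(F)
  X <- sweep(M, 2, mu_m)
  Y <- sweep(F, 2, mu_f)
  if (kind == "similarity") {
    S <- crossprod(Y, X) / n
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    D <- diag(c(1, d))
    R <- sv$u %*% D %*% t(sv$v)
    var_m <- sum(X^2) / n
    if (var_m == 0) stop("degenerate (coincident) moving landmarks")
    s <- sum(sv$d * c(1, d)) / var_m
    A <- s * R
  } else {
    Z <- cbind(1, M)
    if (qr(Z)$rank < 3) stop("collinear landmarks: affine fit is rank deficient")
    B <- qr.solve(Z, F)
    A <- t(B[2:3, , drop = FALSE])
    mu_f <- as.numeric(B[1, ]) + as.numeric(A %*% mu_m)  # so b below is B[1, ]
  }
  b <- mu_f - as.numeric(A %*% mu_m)
  res <- F - (M %*% t(A) + matrix(b, n, 2, byrow = TRUE))
  rmse <- sqrt(mean(rowSums(res^2)))
  transform2d(A, b, kind = kind, rmse_um = rmse)
}

# Brute-force nearest-neighbour indices of query points in ref, chunked to
# bound memory.
nn_index <- function(query, ref, chunk = 512L) {
  q <- as_xy_matrix(query)
  r <- as_xy_matrix(ref)
  nq <- nrow(q)
  out <- integer(nq)
  r2 <- rowSums(r^2)
  i <- 1L
  while (i <= nq) {
    j <- min(nq, i + chunk - 1L)
    Q <- q[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), r2, "+") - 2 * Q %*% t(r)
    out[i:j] <- max.col(-d2, ties.method = "first")
    i <- j + 1L
  }
  out
}

#' Iterative closest point refinement of a transform
#'
#' Alternates nearest-neighbour matching of the transformed moving cloud to
#' the fixed cloud with a closed-form similarity re-fit. The matched-pair
#' RMSE is non-increasing across iterations; the loop stops when the
#' improvement drops below `tol` or after `max_iter` iterations. With a
#' grossly wrong initialisation on sparse clouds ICP can converge to a
#' wrong local optimum; the returned `rmse_um` reports that honestly.
#'
#' @param moving,fixed Point clouds (not paired).
#' @param init Initial `transform2d` (default identity).
#' @param max_iter,tol Convergence controls.
#' @return A `transform2d` with the final matched-pair `rmse_um` and an
#'   `iterations` attribute.
#' @export
refine_icp <- function(moving, fixed, init = transform2d(kind = "similarity"),
                       max_iter = 50L, tol = 1e-6) {
  M <- as_xy_matrix(moving)
  F <- as_xy_matrix(fixed)
  if (nrow(M) == 0 || nrow(F) == 0) stop("ICP requires nonempty point clouds")
  cur <- init
  prev_rmse <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    Mt <- apply_transform(M, cur)
    idx <- nn_index(Mt, F)
    rmse <- sqrt(mean(rowSums((F[idx, , drop = FALSE] - Mt)^2)))
    if (rmse < tol) {
      cur$rmse_um <- rmse
      break
    }
    cand <- estimate_transform(M, F[idx, , drop = FALSE], kind = "similarity")
    if (rmse > prev_rmse + 1e-12) {
      break  # never accept a step that worsens the matched-pair rmse
    }
    cur <- transform2d(cand$A, cand$b, kind = "similarity", rmse_um = cand$rmse_um)
    if (prev_rmse - cand$rmse_um < tol || it >= max_iter) {
      break
    }
    prev_rmse <- cand$rmse_um
  }
  attr(cur, "iterations") <- it
  cur
}
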