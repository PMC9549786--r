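# Pairwise Euclidean distances between two point sets (n x 3, m x 3).
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Minimum heavy-atom distance from each residue (grouped by key) to a point set.
min_dist_per_residue <- function(atom_df, pts) {
  if (nrow(atom_df) == 0 || nrow(pts) == 0)
    return(setNames(numeric(0), character(0)))
  d <- cross_dist(as.matrix(atom_df[, c("x", "y", "z")]), pts)
  dm <- apply(d, 1, min)
  tapply(dm, factor(atom_df$key, levels = unique(atom_df$key)), min)
}

#' Rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (det = +1).
#' @param translation length-3 numeric vector (Angstrom).
#' @return object of class `rigid_transform`; apply with [apply_transform()].
#' @export
new_rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rotation (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param xyz n x 3 matrix of coordinates.
#' @return transformed n x 3 matrix: `xyz %*% t(R) + translation` per row.
#' @export
apply_transform <- function(t, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(t$rotation), 2, t$translation, "+")
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  new_rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimising the RMSD of `mov`
#' onto `ref`, via SVD of the covariance matrix with determinant correction
#' so that reflections are never returned.
#'
#' @param ref,mov n x 3 coordinate matrices, n >= 3, matched row-by-row.
#' @return list with `transform` (a `rigid_transform`) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(ref, mov) {
  ref <- matrix(as.numeric(ref), ncol = 3)
  mov <- matrix(as.numeric(mov), ncol = 3)
  n <- nrow(ref)
  if (n < 3 || nrow(mov) != n)
    stop("degenerate-superposition error: need >= 3 matched points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  P <- sweep(mov, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)                       # 3x3 covariance
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) stop("degenerate-superposition error: collinear points")
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- as.numeric(cr - R %*% cm)
  tf <- new_rigid_transform(R, tr)
  moved <- apply_transform(tf, mov)
  list(transform = tf, rmsd = sqrt(mean(rowSums((moved - ref)^2))))
}

# RMSD of mov onto ref after Kabsch superposition; Inf when degenerate.
superpose_rmsd <- function(ref, mov) {
  out <- tryCatch(kabsch_superpose(ref, mov), error = function(e) NULL)
  if (is.null(out)) Inf else out$rmsd
}
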