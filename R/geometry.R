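# 0-3D periodic geometry: unit cells, translated images, and enumeration of
# interatomic displacement vectors within a cutoff sphere.

#' Construct a unit cell with 0-3 periodic directions
#'
#' Lattice vectors are rows of a 3x3 matrix in bohr. Rows flagged
#' non-periodic take no part in image enumeration (their translation integers
#' are fixed at 0); their stored vectors are zeroed.
#'
#' @param vectors 3x3 numeric matrix; row i is lattice vector i (bohr). May be
#'   `NULL` for a fully non-periodic system.
#' @param periodic Logical length-3 vector of periodic flags.
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(diag(10, 3), periodic = c(TRUE, TRUE, TRUE))
#' unit_cell()  # isolated (molecular) system
#' @export
unit_cell <- function(vectors = NULL, periodic = c(FALSE, FALSE, FALSE)) {
  if (is.null(vectors)) vectors <- matrix(0, 3, 3)
  vectors <- as.matrix(vectors)
  stopifnot(identical(dim(vectors), c(3L, 3L)), length(periodic) == 3)
  periodic <- as.logical(periodic)
  vectors[!periodic, ] <- 0
  if (any(periodic)) {
    sub <- vectors[periodic, , drop = FALSE]
    if (qr(sub)$rank < nrow(sub)) {
      stop("invalid-cell: periodic lattice vectors must be linearly independent",
           call. = FALSE)
    }
  }
  structure(list(vectors = vectors, periodic = periodic), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  n <- sum(x$periodic)
  cat(sprintf("<unit_cell: %dD periodic>\n", n))
  if (n > 0) print(x$vectors[x$periodic, , drop = FALSE])
  invisible(x)
}

#' Nuclear position of a translated image
#'
#' \deqn{\vec R_b = \vec R_B + L_1 \vec v^{(1)} + L_2 \vec v^{(2)} +
#'   L_3 \vec v^{(3)}}
#'
#' @param position Length-3 numeric, nuclear position (bohr).
#' @param cell A [unit_cell()].
#' @param translations Integer triple (L1, L2, L3); must be zero along
#'   non-periodic directions.
#' @return Length-3 numeric position of the image (bohr).
#' @export
image_position <- function(position, cell, translations) {
  stopifnot(length(position) == 3, length(translations) == 3)
  if (any(translations[!cell$periodic] != 0)) {
    stop("invalid-translation: nonzero translation along a non-periodic direction",
         call. = FALSE)
  }
  as.numeric(position + drop(translations %*% cell$vectors))
}

# Internal: per-direction translation ranges guaranteeing coverage of a
# cutoff sphere around any point of the reference cell. Uses the
# perpendicular width of the cell along each reciprocal direction.
.translation_ranges <- function(cell, cutoff) {
  nmax <- integer(3)
  if (any(cell$periodic)) {
    v <- cell$vectors
    idx <- which(cell$periodic)
    sub <- v[idx, , drop = FALSE]
    if (abs(det_or_gram(sub)) < 1e-12) {
      stop("invalid-cell: degenerate (zero-volume) periodic cell", call. = FALSE)
    }
    g <- sub %*% t(sub)
    ginv <- solve(g)
    for (k in seq_along(idx)) {
      # perpendicular width along lattice direction k = 1/sqrt((G^-1)_kk)
      width <- 1 / sqrt(ginv[k, k])
      nmax[idx[k]] <- ceiling(cutoff / width) + 1L
    }
  }
  nmax
}

# Internal: |det| for a full-rank square submatrix or Gram determinant for
# 1-2 row matrices.
det_or_gram <- function(m) {
  if (nrow(m) == 3) return(det(m))
  sqrt(det(m %*% t(m)))
}

#' Enumerate displacement vectors between two sites within a cutoff
#'
#' Lists every periodic image `b` of site B with \eqn{0 < d_{Ab} <}
#' `cutoff`, where \eqn{d_{Ab} = \lVert \vec R_b - \vec R_A \rVert}. The
#' self-pair (identical positions, zero translation) is excluded.
#'
#' @param a,b Length-3 numeric positions (bohr).
#' @param cell A [unit_cell()].
#' @param cutoff Distance cutoff in bohr (> 0).
#' @return A tibble with columns `l1,l2,l3` (translation integers),
#'   `dx,dy,dz` (components of \eqn{\vec R_b - \vec R_A}, bohr) and `d`
#'   (distance, bohr).
#' @examples
#' cellobj <- unit_cell()
#' pair_displacements(c(0, 0, 0), c(0, 0, 3), cellobj, cutoff = 50)
#' @export
pair_displacements <- function(a, b, cell = unit_cell(), cutoff) {
  stopifnot(cutoff > 0, length(a) == 3, length(b) == 3)
  nmax <- .translation_ranges(cell, cutoff)
  grid <- expand.grid(l1 = -nmax[1]:nmax[1], l2 = -nmax[2]:nmax[2],
                      l3 = -nmax[3]:nmax[3])
  shift <- as.matrix(grid) %*% cell$vectors
  dx <- b[1] - a[1] + shift[, 1]
  dy <- b[2] - a[2] + shift[, 2]
  dz <- b[3] - a[3] + shift[, 3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- d < cutoff & d > 1e-12
  tibble::tibble(l1 = grid$l1[keep], l2 = grid$l2[keep], l3 = grid$l3[keep],
                 dx = dx[keep], dy = dy[keep], dz = dz[keep], d = d[keep])
}

# Internal: displacement lists for all ordered pairs (i, j) with i <= j,
# stored as a list of lists of matrices cbind(dx, dy, dz, d). For i == j the
# list holds image displacements only (empty for non-periodic systems).
.system_displacements <- function(positions, cell, cutoff) {
  n <- nrow(positions)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- vector("list", n)
    for (j in i:n) {
      dd <- pair_displacements(positions[i, ], positions[j, ], cell, cutoff)
      out[[i]][[j]] <- cbind(dx = dd$dx, dy = dd$dy, dz = dd$dz, d = dd$d)
    }
  }
  out
}
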