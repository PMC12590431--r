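# 3-D Delaunay tetrahedralisation (incremental Bowyer-Watson) and alpha
# shapes. Written for the modest point counts of the near-optimal region
# search (hundreds to a few thousand points).

# circumcentre and squared circumradius of tetra v (4 x 3); list(c, r2)
.circumsphere <- function(v) {
  A <- 2 * (v[2:4, , drop = FALSE] -
              matrix(v[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
  ctr <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(ctr)) return(list(c = c(NA, NA, NA), r2 = Inf))
  list(c = ctr, r2 = sum((v[1, ] - ctr)^2))
}

.tet_volume <- function(v) {
  abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
}

#' Delaunay tetrahedralisation of a 3-D point cloud
#'
#' Incremental Bowyer-Watson construction. Points must not be all
#' coplanar or collinear.
#'
#' @param points numeric matrix, n x 3, n >= 4.
#' @return list with `tets` (m x 4 matrix of point indices), `circum_r`
#'   (circumradius per tetrahedron) and `volumes`.
#' @export
delaunay_3d <- function(points) {
  P <- .as_matrix(points)
  stopifnot(ncol(P) == 3)
  n <- nrow(P)
  if (n < 4) stop("degenerate input: need at least 4 points")
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  scale_len <- max(sv)
  if (sv[3] < 1e-10 * max(scale_len, 1))
    stop("degenerate input: points are (near-)coplanar or collinear")

  ctr <- colMeans(P)
  d <- max(sqrt(rowSums(sweep(P, 2, ctr)^2)))
  big <- 50 * max(d, 1e-12)
  super <- rbind(ctr + c(3 * big, 0, -big), ctr + c(-3 * big / 2,
                 3 * big * sqrt(3) / 2, -big),
                 ctr + c(-3 * big / 2, -3 * big * sqrt(3) / 2, -big),
                 ctr + c(0, 0, 3 * big))
  V <- rbind(P, super)
  tets <- matrix(n + 1:4, nrow = 1)
  cs <- .circumsphere(super)
  cents <- matrix(cs$c, nrow = 1)
  r2s <- cs$r2

  eps <- 1e-12 * max(d^2, 1)
  for (ip in seq_len(n)) {
    p <- V[ip, ]
    d2 <- (cents[, 1] - p[1])^2 + (cents[, 2] - p[2])^2 +
      (cents[, 3] - p[3])^2
    bad <- which(d2 < r2s - eps)
    if (length(bad) == 0L) {
      # numerical safety: force the containing tetra to be split
      bad <- which(d2 < r2s + eps)
      if (length(bad) == 0L) bad <- which.min(d2 - r2s)
    }
    faces <- do.call(rbind, lapply(bad, function(t) {
      tt <- tets[t, ]
      rbind(sort(tt[-1]), sort(tt[-2]), sort(tt[-3]), sort(tt[-4]))
    }))
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    cnt <- table(key)
    boundary <- faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
    keep <- setdiff(seq_len(nrow(tets)), bad)
    tets <- tets[keep, , drop = FALSE]
    cents <- cents[keep, , drop = FALSE]
    r2s <- r2s[keep]
    for (f in seq_len(nrow(boundary))) {
      newt <- c(boundary[f, ], ip)
      cs <- .circumsphere(V[newt, , drop = FALSE])
      if (!is.finite(cs$r2)) next              # skip flat slivers
      tets <- rbind(tets, newt)
      cents <- rbind(cents, cs$c)
      r2s <- c(r2s, cs$r2)
    }
  }
  real <- rowSums(tets <= n) == 4L
  tets <- tets[real, , drop = FALSE]
  r2s <- r2s[real]
  rownames(tets) <- NULL
  vols <- vapply(seq_len(nrow(tets)), function(i)
    .tet_volume(P[tets[i, ], , drop = FALSE]), numeric(1))
  list(tets = tets, circum_r = sqrt(r2s), volumes = vols)
}

# connected components of points through shared tetrahedra (union-find)
.one_component <- function(tets, n) {
  if (nrow(tets) == 0L) return(FALSE)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (t in seq_len(nrow(tets))) {
    r0 <- find(tets[t, 1])
    for (j in 2:4) parent[find(tets[t, j])] <- r0
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

#' 3-D alpha shape of a point cloud
#'
#' Keeps the Delaunay tetrahedra whose circumradius does not exceed
#' `alpha`; the shape is their union, its boundary the triangles belonging
#' to exactly one kept tetrahedron, and its volume the sum of kept
#' tetrahedron volumes. `alpha = Inf` recovers the convex hull.
#' `alpha = "auto"` picks the smallest circumradius (binary search over
#' the observed circumradii) at which every input point belongs to one
#' connected component of the shape.
#'
#' @param points numeric matrix, n x 3 (n >= 4, not all coplanar).
#' @param alpha radius parameter, `Inf`, or `"auto"`.
#' @return object of class `alpha_shape`: `facets` (boundary triangles as
#'   index triples), `tets` (kept tetrahedra), `volume`, `alpha`,
#'   `points`.
#' @export
alpha_shape_3d <- function(points, alpha = "auto") {
  P <- .as_matrix(points)
  dl <- delaunay_3d(P)
  pick_alpha <- identical(alpha, "auto")
  if (pick_alpha) {
    radii <- sort(unique(dl$circum_r))
    connected_at <- function(a) {
      kt <- dl$tets[dl$circum_r <= a, , drop = FALSE]
      all(seq_len(nrow(P)) %in% kt) && .one_component(kt, nrow(P))
    }
    # connectivity is monotone in alpha, so binary search works
    if (!connected_at(radii[length(radii)])) {
      alpha <- Inf
    } else {
      lo <- 1L
      hi <- length(radii)
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (connected_at(radii[mid])) hi <- mid else lo <- mid + 1L
      }
      alpha <- radii[hi]
    }
  }
  keep <- dl$circum_r <= alpha
  tets <- dl$tets[keep, , drop = FALSE]
  volume <- sum(dl$volumes[keep])
  facets <- matrix(integer(0), ncol = 3)
  if (nrow(tets) > 0L) {
    faces <- do.call(rbind, lapply(seq_len(nrow(tets)), function(t) {
      tt <- tets[t, ]
      rbind(sort(tt[-1]), sort(tt[-2]), sort(tt[-3]), sort(tt[-4]))
    }))
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    cnt <- table(key)
    facets <- faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  }
  structure(list(facets = facets, tets = tets, volume = volume,
                 alpha = alpha, points = P), class = "alpha_shape")
}

#' Test membership of points in an alpha shape
#'
#' A point is inside (or on) the shape if it lies in at least one kept
#' tetrahedron (barycentric test with tolerance).
#'
#' @param shape an [alpha_shape_3d()] result.
#' @param points numeric matrix, m x 3.
#' @param tol barycentric tolerance.
#' @return logical vector of length m.
#' @export
in_alpha_shape <- function(shape, points, tol = 1e-9) {
  Q <- .as_matrix(points)
  P <- shape$points
  vapply(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    for (t in seq_len(nrow(shape$tets))) {
      v <- P[shape$tets[t, ], , drop = FALSE]
      A <- t(v[2:4, , drop = FALSE]) - v[1, ]
      bc <- tryCatch(solve(A, q - v[1, ]), error = function(e) NULL)
      if (is.null(bc)) next
      if (all(bc >= -tol) && sum(bc) <= 1 + tol) return(TRUE)
    }
    FALSE
  }, logical(1))
}
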