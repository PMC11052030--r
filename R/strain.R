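#' Per-particle deformation gradient from two configurations
#'
#' Least-squares local affine map of each particle's neighbourhood: with
#' distance vectors d0 (reference) and d (current) to the neighbours, J_i
#' solves sum |d0 J - d|^2 -> min, i.e. J_i = (sum d0^T d0)^-1 (sum d0^T d).
#' Exact whenever the local motion is affine.
#'
#' @param ref,cur n x d matrices (d = 2 or 3) with aligned particle
#'   indexing.
#' @param neighbors optional list of neighbour index vectors per particle;
#'   built from \code{cutoff} in the reference configuration when NULL.
#' @param cutoff neighbour radius; default 1.5 x the mean nearest-neighbour
#'   spacing of the reference cloud.
#' @return list of class \code{strain_field_raw}: \code{J} (n x d x d
#'   array), logical \code{ok} (FALSE where the neighbourhood was rank
#'   deficient or too small), \code{neighbors}, \code{cutoff}.
#' @export
deformation_gradient <- function(ref, cur, neighbors = NULL, cutoff = NULL) {
  ref <- as.matrix(ref); cur <- as.matrix(cur)
  stopifnot(all(dim(ref) == dim(cur)))
  n <- nrow(ref); dd <- ncol(ref)
  stopifnot(dd %in% c(2L, 3L))
  if (is.null(neighbors)) {
    if (is.null(cutoff)) cutoff <- 1.5 * .mean_nn_spacing(ref)
    neighbors <- .radius_neighbors(ref, cutoff)
  }
  J <- array(NA_real_, c(n, dd, dd))
  ok <- logical(n)
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (length(nb) < dd) next
    D0 <- sweep(ref[nb, , drop = FALSE], 2, ref[i, ])
    D1 <- sweep(cur[nb, , drop = FALSE], 2, cur[i, ])
    M <- crossprod(D0)                      # sum d0^T d0
    if (abs(det(M)) < 1e-12 * (mean(diag(M)) + 1e-300)^dd) next
    # normal-equation solution, transposed into the column convention
    # (d = J d0), so a global map x -> A x is recovered as J = A
    J[i, , ] <- t(solve(M, crossprod(D0, D1)))
    ok[i] <- TRUE
  }
  structure(list(J = J, ok = ok, neighbors = neighbors, cutoff = cutoff),
            class = "strain_field_raw")
}

.mean_nn_spacing <- function(x) {
  n <- nrow(x)
  take <- if (n > 400) sample(n, 400) else seq_len(n)
  mean(vapply(take, function(i) {
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    sqrt(min(d2[d2 > 0]))
  }, numeric(1)))
}

.radius_neighbors <- function(x, cutoff) {
  n <- nrow(x)
  lapply(seq_len(n), function(i) {
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    setdiff(which(d2 <= cutoff^2), i)
  })
}

#' Rotation, stretch and strain from a deformation gradient
#'
#' Right polar decomposition J = R U (R orthogonal with det +1, U symmetric
#' positive definite) via the singular value decomposition; the strain is
#' E = U - I, whose diagonal elements are tension-to-original-length
#' ratios along the axes.
#'
#' @param J a d x d deformation gradient with positive determinant.
#' @return list with \code{R}, \code{U}, \code{E}.
#' @export
strain_from_gradient <- function(J) {
  J <- as.matrix(J)
  if (!all(is.finite(J))) stop("non-finite deformation gradient")
  if (det(J) <= 0) stop("det(J) <= 0: inverted neighbourhood")
  sv <- svd(J)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {  # guard; cannot occur when det(J) > 0 with positive svs
    sv$v[, ncol(sv$v)] <- -sv$v[, ncol(sv$v)]
    R <- sv$u %*% t(sv$v)
  }
  U <- sv$v %*% diag(sv$d, length(sv$d)) %*% t(sv$v)
  list(R = R, U = U, E = U - diag(nrow(J)))
}

#' Finite-strain field between two point clouds
#'
#' Combines \code{\link{deformation_gradient}} and
#' \code{\link{strain_from_gradient}} over all particles and extracts the
#' scalar strain along the requested axis (the corresponding diagonal
#' element of E = U - I).
#'
#' @inheritParams deformation_gradient
#' @param axis analysis axis: 1/2/3 or "x"/"y"/"z" (default "y", the
#'   penetration direction of the microinjection assay).
#' @return object of class \code{strain_field}: data frame with the scalar
#'   \code{strain} (NA where the neighbourhood was unusable) plus the full
#'   \code{J}, rotation/stretch arrays and \code{ok} flags as attributes.
#' @export
strain_field <- function(ref, cur, axis = "y", neighbors = NULL,
                         cutoff = NULL) {
  ax <- if (is.character(axis)) match(axis, c("x", "y", "z")) else as.integer(axis)
  dg <- deformation_gradient(ref, cur, neighbors, cutoff)
  n <- nrow(ref); dd <- ncol(as.matrix(ref))
  stopifnot(ax >= 1, ax <= dd)
  strain <- rep(NA_real_, n)
  E <- array(NA_real_, c(n, dd, dd))
  R <- array(NA_real_, c(n, dd, dd))
  for (i in which(dg$ok)) {
    J <- dg$J[i, , ]
    if (det(J) <= 0) { dg$ok[i] <- FALSE; next }
    s <- strain_from_gradient(J)
    E[i, , ] <- s$E
    R[i, , ] <- s$R
    strain[i] <- s$E[ax, ax]
  }
  structure(data.frame(strain = strain),
            class = c("strain_field", "data.frame"),
            J = dg$J, E = E, R = R, ok = dg$ok, axis = ax,
            cutoff = dg$cutoff)
}

#' Project a slab of a 3-D cloud onto a plane
#'
#' Keeps the points within \code{thickness/2} of the plane and projects
#' them orthogonally onto it, returning 2-D in-plane coordinates.  Used to
#' compare the simulated 3-D strain with 2-D image-derived strain near the
#' cell centre.
#'
#' @param cloud n x 3 matrix.
#' @param point a point on the plane; \code{normal} the plane normal.
#' @param thickness slab thickness.
#' @return n_kept x 2 matrix of in-plane coordinates; attributes
#'   \code{kept} (row indices) and \code{basis} (3 x 2 in-plane basis).
#' @export
cross_section_projection <- function(cloud, point, normal, thickness) {
  cloud <- as.matrix(cloud)
  u <- normal / sqrt(sum(normal^2))
  s <- as.numeric(sweep(cloud, 2, point) %*% u)
  keep <- which(abs(s) <= thickness / 2)
  if (length(keep) == 0) stop("empty slab: no points within the cross-section")
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  B <- cbind(e1, e2)
  proj <- sweep(cloud[keep, , drop = FALSE], 2, point) %*% B
  structure(proj, kept = keep, basis = B)
}

#' Normalised strain histogram
#'
#' @param strain vector of scalar strains (NAs dropped).
#' @param edges bin edges; default width 0.05 over [-1, 1].
#' @param label source label (e.g. "simulation" / "experiment").
#' @return object of class \code{strain_histogram}: list with \code{edges},
#'   \code{mass} (sums to 1), \code{label}.
#' @export
strain_histogram <- function(strain, edges = seq(-1, 1, by = 0.05),
                             label = "simulation") {
  s <- strain[is.finite(strain)]
  s <- pmin(pmax(s, edges[1]), edges[length(edges)] - 1e-12)
  cnt <- tabulate(findInterval(s, edges), nbins = length(edges) - 1)
  m <- cnt / sum(cnt)
  structure(list(edges = edges, mass = m, label = label),
            class = "strain_histogram")
}

#' Histogram comparison metrics
#'
#' Jaccard similarity sum(min)/sum(max) (intersection over union of the
#' two mass vectors), Bhattacharyya distance -ln sum sqrt(p q), and
#' Jensen-Shannon divergence with natural logarithm (range [0, ln 2]).
#' Both histograms must share the same bin grid; no silent re-binning.
#'
#' @param P0,P1 \code{strain_histogram} objects on identical edges.
#' @return list with \code{jaccard}, \code{bhattacharyya}, \code{js}.
#' @export
compare_histograms <- function(P0, P1) {
  if (!isTRUE(all.equal(P0$edges, P1$edges)))
    stop("histograms use different bin edges; re-bin explicitly first")
  p <- P0$mass; q <- P1$mass
  jac <- sum(pmin(p, q)) / sum(pmax(p, q))
  bc <- sum(sqrt(p * q))
  bhat <- -log(bc)
  m <- (p + q) / 2
  kl <- function(a, b) {
    sel <- a > 0
    sum(a[sel] * log(a[sel] / b[sel]))
  }
  js <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  list(jaccard = jac, bhattacharyya = bhat, js = js)
}

#' Strain analysis of a microinjection result
#'
#' Computes the per-particle finite-strain field of the cytoskeleton (or
#' all mobile cell particles) between the checkpointed post-aspiration
#' reference and the state at rupture, the central cross-section 2-D
#' strain, and the strain histogram along the penetration axis.
#'
#' @param result a \code{microinjection_result}.
#' @param component \code{"actin"} (default) or \code{"all"}.
#' @param thickness cross-section slab thickness; default 1.5.
#' @param edges histogram bin edges.
#' @return list with \code{field} (3-D \code{strain_field}),
#'   \code{section} (2-D strain data frame), \code{histogram},
#'   \code{high_strain_fraction} (|strain| > 0.2) and
#'   \code{mean_abs_strain}.
#' @export
analyze_injection_strain <- function(result, component = "actin",
                                     thickness = 1.5,
                                     edges = seq(-1, 1, by = 0.05)) {
  idx <- if (component == "actin" && length(result$idx$actin) > 0)
    result$idx$actin else
      sort(c(result$idx$membrane, result$idx$actin, result$idx$acp))
  ref <- result$reference[idx, , drop = FALSE]
  cur <- result$final[idx, , drop = FALSE]
  fld <- strain_field(ref, cur, axis = "y")
  ctr <- colMeans(ref)
  p_ref <- cross_section_projection(ref, ctr, normal = c(0, 0, 1), thickness)
  kept <- attr(p_ref, "kept")
  p_cur <- sweep(cur[kept, , drop = FALSE], 2, ctr) %*% attr(p_ref, "basis")
  sec <- strain_field(p_ref, p_cur, axis = 2)  # in-plane y is column 2
  hs <- strain_histogram(fld$strain, edges)
  st <- fld$strain[is.finite(fld$strain)]
  list(field = fld, section = sec, histogram = hs,
       high_strain_fraction = mean(abs(st) > 0.2),
       mean_abs_strain = mean(abs(st)))
}
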