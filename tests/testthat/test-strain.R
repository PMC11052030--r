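# Finite-strain fields from point clouds and histogram comparison metrics.

rot3 <- function(ax, th) {
  u <- ax / sqrt(sum(ax^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

test_that("deformation gradient is exact for affine motions", {
  set.seed(6)
  ref <- matrix(runif(600, 0, 5), 200, 3)
  # identity and pure translation
  for (cur in list(ref, sweep(ref, 2, c(1, -2, 0.5), "+"))) {
    dg <- deformation_gradient(ref, cur)
    for (i in which(dg$ok))
      expect_equal(dg$J[i, , ], diag(3), tolerance = 1e-10)
  }
  # generic affine map recovered exactly at every particle
  A <- rbind(c(1.1, 0.05, 0), c(0.02, 0.9, 0.03), c(0, 0.01, 1.2))
  dgA <- deformation_gradient(ref, ref %*% t(A), cutoff = 1.4)
  expect_gt(mean(dgA$ok), 0.9)
  for (i in which(dgA$ok))
    expect_equal(dgA$J[i, , ], A, tolerance = 1e-9)
  # rank-deficient neighbourhood flagged, not errored
  line <- cbind(seq_len(10) * 0.1, 0, 0)
  dgl <- deformation_gradient(line, line, cutoff = 0.25)
  expect_true(all(!dgl$ok))
})

test_that("polar decomposition separates rotation from stretch", {
  # pure rotations carry no strain
  for (th in c(0.3, 1.2, 2.5)) {
    s <- strain_from_gradient(rot3(c(1, 2, 3), th))
    expect_equal(s$E, matrix(0, 3, 3), tolerance = 1e-10)
    expect_equal(det(s$R), 1, tolerance = 1e-10)
  }
  # pure stretch passes through
  s2 <- strain_from_gradient(diag(c(1.2, 0.9, 1.0)))
  expect_equal(s2$E, diag(c(0.2, -0.1, 0)), tolerance = 1e-12)
  # random J with det > 0: R orthogonal, U = R^T J symmetric, J = R U
  set.seed(3)
  for (k in 1:20) {
    J <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(J) <= 0) next
    s <- strain_from_gradient(J)
    expect_equal(crossprod(s$R), diag(3), tolerance = 1e-10)
    expect_equal(s$U, t(s$U), tolerance = 1e-10)
    expect_equal(s$R %*% s$U, J, tolerance = 1e-10)
  }
  expect_error(strain_from_gradient(diag(c(-1, 1, 1))), "det")
})

test_that("strain fields are frame-indifferent and recover known maps", {
  set.seed(9)
  ref <- matrix(runif(450, 0, 4), 150, 3)
  A <- diag(c(1.0, 1.1, 1.0))           # 10% stretch along y
  cur <- ref %*% t(A)
  fld <- strain_field(ref, cur, axis = "y")
  expect_equal(mean(fld$strain, na.rm = TRUE), 0.1, tolerance = 1e-9)
  # pre-rotating the current configuration leaves E unchanged
  R <- rot3(c(0, 0, 1), 0.7)
  fldR <- strain_field(ref, cur %*% t(R), axis = "y")
  expect_equal(fldR$strain, fld$strain, tolerance = 1e-9)
  # noise convergence: mean strain approaches truth as noise -> 0
  errs <- vapply(c(1e-2, 1e-3, 0), function(sn) {
    curn <- cur + matrix(rnorm(length(cur), sd = sn), nrow(cur))
    abs(mean(strain_field(ref, curn, axis = "y")$strain, na.rm = TRUE) - 0.1)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("cross-sections project consistently with the 3-D strain", {
  set.seed(10)
  ref <- matrix(runif(900, 0, 6), 300, 3)
  A <- diag(c(1.05, 1.15, 0.95))
  cur <- ref %*% t(A)
  ctr <- colMeans(ref)
  pr <- cross_section_projection(ref, ctr, normal = c(0, 0, 1),
                                 thickness = 2)
  kept <- attr(pr, "kept")
  expect_true(length(kept) > 30)
  pc <- sweep(cur[kept, , drop = FALSE], 2, ctr) %*% attr(pr, "basis")
  fld2 <- strain_field(pr, pc, axis = 2)
  expect_equal(mean(fld2$strain, na.rm = TRUE), 0.15, tolerance = 1e-9)
  # slab thicker than the cloud keeps every point
  pr_all <- cross_section_projection(ref, ctr, c(0, 0, 1), thickness = 100)
  expect_equal(length(attr(pr_all, "kept")), nrow(ref))
  # points on the plane are unchanged by projection (in-plane coordinates)
  onplane <- cbind(ref[1:5, 1:2], ctr[3])
  pr_on <- cross_section_projection(onplane, ctr, c(0, 0, 1), 1)
  back <- sweep(pr_on %*% t(attr(pr_on, "basis")), 2, ctr, "+")
  expect_equal(back, onplane, tolerance = 1e-12)
  expect_error(cross_section_projection(ref, ctr + c(0, 0, 100),
                                        c(0, 0, 1), 0.1), "empty")
})

test_that("histogram metrics behave at identity, disjointness and by hand", {
  set.seed(2)
  x <- rnorm(500, sd = 0.2)
  P <- strain_histogram(x)
  expect_equal(sum(P$mass), 1)
  idm <- compare_histograms(P, P)
  expect_equal(idm$jaccard, 1)
  expect_equal(idm$bhattacharyya, 0, tolerance = 1e-12)
  expect_equal(idm$js, 0, tolerance = 1e-12)
  # disjoint supports: jaccard 0, js = ln 2
  Q1 <- strain_histogram(runif(400, -0.9, -0.5))
  Q2 <- strain_histogram(runif(400, 0.5, 0.9))
  dm <- compare_histograms(Q1, Q2)
  expect_equal(dm$jaccard, 0)
  expect_equal(dm$js, log(2), tolerance = 1e-12)
  expect_true(is.infinite(dm$bhattacharyya) || dm$bhattacharyya > 10)
  # hand evaluation: p = (.5, .5), q = (.9, .1)
  e2 <- c(0, 0.5, 1)
  Ph <- structure(list(edges = e2, mass = c(0.5, 0.5), label = "p"),
                  class = "strain_histogram")
  Qh <- structure(list(edges = e2, mass = c(0.9, 0.1), label = "q"),
                  class = "strain_histogram")
  hm <- compare_histograms(Ph, Qh)
  expect_equal(hm$bhattacharyya, -log(sqrt(0.45) + sqrt(0.05)),
               tolerance = 1e-12)
  # symmetry of all three metrics
  hm2 <- compare_histograms(Qh, Ph)
  expect_equal(unlist(hm), unlist(hm2), tolerance = 1e-12)
  # mismatched bins are a hard error
  Qb <- strain_histogram(x, edges = seq(-1, 1, by = 0.1))
  expect_error(compare_histograms(P, Qb), "bin edges")
})
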