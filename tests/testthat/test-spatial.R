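test_that("Neumann Laplacian: constants, quadratics and conservation", {
  dx <- 0.075
  f <- matrix(5, 12, 10)
  expect_equal(laplacian_neumann(f, dx), matrix(0, 12, 10))

  # exact for quadratics on interior cells
  a <- 1.7
  x <- (seq_len(20) - 0.5) * dx
  f <- outer(x, rep(1, 15)) ; f <- a * f^2
  L <- laplacian_neumann(f, dx)
  expect_equal(L[2:19, 2:14], matrix(2 * a, 18, 13), tolerance = 1e-9)

  # discrete divergence theorem: total flux zero for any field
  set.seed(42)
  f <- matrix(rnorm(12 * 10), 12, 10)
  expect_equal(sum(laplacian_neumann(f, dx)), 0, tolerance = 1e-12)

  expect_error(laplacian_neumann(matrix(0, 2, 2), dx), "3 x 3")
  expect_error(laplacian_neumann(matrix(0, 5, 5), -1), "dx")
})

test_that("spectral, direct and Jacobi solvers agree on small grids", {
  set.seed(7)
  for (dims in list(c(12, 12), c(16, 9), c(20, 20))) {
    nu <- matrix(runif(dims[1] * dims[2], 0, 50), dims[1], dims[2])
    sp <- solve_presynaptic_rate(nu, 0.385, 0.075, method = "spectral")
    di <- solve_presynaptic_rate(nu, 0.385, 0.075, method = "direct")
    ja <- solve_presynaptic_rate(nu, 0.385, 0.075, method = "jacobi",
                                 tol = 1e-10)
    expect_lt(max(abs(sp - di)) / max(abs(di)), 1e-8)
    expect_lt(max(abs(ja - di)) / max(abs(di)), 1e-6)
  }
})

test_that("screened-Poisson solution obeys the constant solution and limits", {
  nu <- matrix(10, 15, 15)
  phi <- solve_presynaptic_rate(nu, 0.385, 0.075)
  expect_equal(phi, nu, tolerance = 1e-10)

  # screening limit: lambda -> 0 gives phi -> nu pointwise
  set.seed(1)
  nu <- matrix(runif(100, 0, 30), 10, 10)
  phi <- solve_presynaptic_rate(nu, 1e-4, 0.075)
  expect_equal(phi, nu, tolerance = 1e-4)

  # discrete maximum principle
  phi <- solve_presynaptic_rate(nu, 0.385, 0.075)
  expect_true(all(phi >= min(nu) - 1e-9 & phi <= max(nu) + 1e-9))

  expect_error(solve_presynaptic_rate(-nu, 0.385, 0.075), "non-negative")
  expect_error(solve_presynaptic_rate(nu, 0, 0.075), "lambda")
})

test_that("point source decays with the connectivity length lambda", {
  # long 1D strip: the Green's function decays as exp(-r / lambda)
  lam <- 0.385; dx <- 0.075
  nx <- 160; ny <- 3
  nu <- matrix(0, nx, ny)
  nu[1, ] <- 100
  phi <- solve_presynaptic_rate(nu, lam, dx, method = "direct")
  r <- (seq_len(nx) - 1) * dx
  sel <- r > 2 * lam & r < 6 * lam   # away from source and far boundary
  fit <- lm(log(phi[sel, 2]) ~ r[sel])
  lam_fit <- -1 / coef(fit)[2]
  expect_lt(abs(lam_fit - lam) / lam, 0.05)
})

test_that("Jacobi reports non-convergence with the residual", {
  nu <- matrix(1, 10, 10)
  nu[5, 5] <- 100
  expect_error(
    solve_presynaptic_rate(nu, 0.385, 0.075, method = "jacobi",
                           tol = 1e-12, max_iter = 3),
    "residual")
})

test_that("lesion masks rasterise deterministically", {
  dom <- build_domain()
  expect_error(make_lesion_mask(dom, "partial_segment", x0 = 1, y0 = 1,
                                x1 = 1, y1 = 1), "degenerate")
  none <- make_lesion_mask(dom, "none")
  expect_equal(sum(none$cells), 0)
  expect_identical(none$kind, "none")

  seg <- make_lesion_mask(dom, "partial_segment", x0 = 2, y0 = 3, x1 = 4,
                          y1 = 3)
  # brute-force rasterisation: cells whose column range the segment spans
  expect_equal(sum(seg$cells), round(2 / dom$dx), tolerance = 1)
  expect_true(all(which(seg$cells, arr.ind = TRUE)[, 2] == 40))

  line <- make_lesion_mask(dom, "complete_line", x = 3)
  expect_equal(sum(line$cells), dom$ny)

  # a full-height cut splits the domain into two phi-components
  nu <- matrix(0, dom$nx, dom$ny)
  nu[10, 40] <- 50   # source well left of the cut
  phi <- solve_presynaptic_rate(nu, 0.385, dom$dx, lesion = line,
                                method = "direct")
  right <- phi[(ceiling(3 / dom$dx) + 1):dom$nx, ]
  expect_true(all(right == 0))
  expect_gt(max(phi[1:20, ]), 0)
})

test_that("lesion Dirichlet rows keep phi zero on masked cells", {
  dom <- tiny_domain()
  seg <- make_lesion_mask(dom, "partial_segment", x0 = 0.5, y0 = 0.2,
                          x1 = 0.5, y1 = 0.7)
  nu <- matrix(20, dom$nx, dom$ny)
  phi <- solve_presynaptic_rate(nu, 0.385, dom$dx, lesion = seg,
                                method = "direct")
  expect_true(all(phi[seg$cells] == 0))
  expect_true(all(phi[!seg$cells] > 0))
})

test_that("blocked-diffusion lesions zero the crossing fluxes symmetrically", {
  dom <- tiny_domain()
  line <- make_lesion_mask(dom, "complete_line", x = 0.6,
                           blocks_diffusion = TRUE)
  f <- matrix(0, dom$nx, dom$ny)
  f[1:4, ] <- 10
  L <- laplacian_neumann(f, dom$dx, lesion = line)
  # conservation still holds (blocked edges drop symmetrically)
  expect_equal(sum(L), 0, tolerance = 1e-12)
  # no flux reaches the far side of the cut
  cut <- ceiling(0.6 / dom$dx)
  expect_true(all(L[(cut + 1):dom$nx, ] == 0))
})
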