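#' Discrete Laplacian with zero-flux boundaries
#'
#' Five-point central-difference Laplacian on a regular cell-centred grid
#' with Neumann (mirror ghost-cell) boundary conditions: the flux across
#' every outer boundary is zero, so the operator conserves the total of the
#' field exactly. If a lesion mask with `blocks_diffusion = TRUE` is given,
#' inter-cell fluxes across edges touching lesion cells are zeroed as well
#' (an impermeable cut).
#'
#' @param field Numeric matrix (rows = x, columns = y).
#' @param dx Grid spacing (mm).
#' @param lesion Optional [make_lesion_mask()] object.
#' @return Matrix of the same shape, in field units per mm^2.
#' @export
laplacian_neumann <- function(field, dx, lesion = NULL) {
  nx <- nrow(field); ny <- ncol(field)
  if (is.null(nx) || nx < 3 || ny < 3) abort("grid must be at least 3 x 3")
  if (!is.numeric(dx) || dx <= 0) abort("`dx` must be positive (mm)")
  block <- !is.null(lesion) && lesion$kind != "none" && isTRUE(lesion$blocks_diffusion)

  # edge fluxes (difference across each interior edge), zeroed where blocked
  fx <- field[-1, , drop = FALSE] - field[-nx, , drop = FALSE]
  fy <- field[, -1, drop = FALSE] - field[, -ny, drop = FALSE]
  if (block) {
    if (!is.null(lesion$cut_after)) {
      fx[lesion$cut_after, ] <- 0
    } else {
      cells <- lesion$cells
      fx[cells[-nx, , drop = FALSE] | cells[-1, , drop = FALSE]] <- 0
      fy[cells[, -ny, drop = FALSE] | cells[, -1, drop = FALSE]] <- 0
    }
  }
  out <- matrix(0, nx, ny)
  out[-nx, ] <- out[-nx, ] + fx
  out[-1, ]  <- out[-1, ]  - fx
  out[, -ny] <- out[, -ny] + fy
  out[, -1]  <- out[, -1]  - fy
  out / dx^2
}

# DCT-II eigenbasis of the 1D Neumann Laplacian: columns v_k(i) =
# cos(pi k (i + 1/2) / n) (orthonormalised), eigenvalues mu_k =
# 2 cos(pi k / n) - 2 (in units of 1/dx^2 once divided by dx^2).
dct_basis <- function(n) {
  i <- seq_len(n) - 0.5
  k <- seq_len(n) - 1
  V <- outer(i, k, function(i, k) cos(pi * k * i / n))
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  list(V = V, mu = 2 * cos(pi * k / n) - 2)
}

# Sparse matrix of the screened-Poisson operator I - (lambda/dx)^2 * Lap
# with Neumann outer boundaries and Dirichlet identity rows on lesion cells.
# Cell (i, j) maps to row (j - 1) * nx + i (column-major).
screened_matrix <- function(nx, ny, lambda_conn, dx, lesion = NULL) {
  alpha <- (lambda_conn / dx)^2
  has <- !is.null(lesion) && lesion$kind != "none"
  les <- if (has) lesion$cells else matrix(FALSE, nx, ny)
  cut <- if (has) lesion$cut_after else NULL
  idx <- function(i, j) (j - 1L) * nx + i
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      r <- idx(i, j)
      if (les[i, j]) {
        ii <- c(ii, r); jj <- c(jj, r); vv <- c(vv, 1)
        next
      }
      nbr <- rbind(
        if (i > 1  && !(!is.null(cut) && i - 1L == cut)) c(i - 1L, j),
        if (i < nx && !(!is.null(cut) && i == cut))      c(i + 1L, j),
        if (j > 1)  c(i, j - 1L),
        if (j < ny) c(i, j + 1L)
      )
      # severed edges are flux-free (Neumann): absent from the diagonal;
      # dead (Dirichlet) neighbours keep their diagonal weight
      diag_val <- 1 + alpha * nrow(nbr)
      ii <- c(ii, r); jj <- c(jj, r); vv <- c(vv, diag_val)
      for (q in seq_len(nrow(nbr))) {
        if (!les[nbr[q, 1], nbr[q, 2]]) {
          ii <- c(ii, r); jj <- c(jj, idx(nbr[q, 1], nbr[q, 2])); vv <- c(vv, -alpha)
        }
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nx * ny, nx * ny))
}

#' Presynaptic firing rate from the somatic rate
#'
#' Solves the screened-Poisson (elliptic) connectivity equation
#' `lambda^2 (d2/dx2 + d2/dy2) phi = phi - nu` with zero-flux boundaries.
#' Its Green's function is the exponentially decaying connectivity kernel
#' `exp(-r / lambda)`, so `phi` is the somatic rate `nu` smoothed over the
#' axo-dendritic connectivity footprint. On lesion cells `phi = 0` is
#' enforced (Dirichlet rows), and lesion edges carry no coupling flux.
#'
#' Three solution paths are provided: `"spectral"` (exact solve in the
#' DCT-II eigenbasis of the Neumann Laplacian; unlesioned domains only),
#' `"direct"` (sparse LU of the full system; any domain), and `"jacobi"`
#' (the classical point-Jacobi iteration, kept as a reference path).
#'
#' @param nu Somatic firing-rate matrix (Hz), all entries non-negative.
#' @param lambda_conn Connectivity length (mm).
#' @param dx Grid spacing (mm).
#' @param lesion Optional [make_lesion_mask()] object.
#' @param method `"spectral"`, `"direct"` or `"jacobi"`.
#' @param tol Relative-residual tolerance (Jacobi path).
#' @param max_iter Iteration budget (Jacobi path).
#' @return Matrix `phi` (Hz), same shape as `nu`. Away from lesions the
#'   discrete maximum principle holds: `min(nu) <= phi <= max(nu)`.
#' @export
solve_presynaptic_rate <- function(nu, lambda_conn, dx, lesion = NULL,
                                   method = c("spectral", "direct", "jacobi"),
                                   tol = 1e-8, max_iter = 200000) {
  method <- match.arg(method)
  if (any(nu < 0)) abort("`nu` must be non-negative everywhere")
  if (lambda_conn <= 0) abort("`lambda_conn` must be positive (mm)")
  nx <- nrow(nu); ny <- ncol(nu)
  has_lesion <- !is.null(lesion) && lesion$kind != "none"
  alpha <- (lambda_conn / dx)^2

  if (method == "spectral") {
    if (has_lesion) {
      abort("spectral solve requires an unlesioned domain; use method = \"direct\"")
    }
    bx <- dct_basis(nx); by <- dct_basis(ny)
    denom <- 1 - alpha * outer(bx$mu, by$mu, "+")
    return(bx$V %*% ((crossprod(bx$V, nu) %*% by$V) / denom) %*% t(by$V))
  }

  if (method == "direct") {
    A <- screened_matrix(nx, ny, lambda_conn, dx, lesion)
    b <- as.vector(nu)
    if (has_lesion) b[as.vector(lesion$cells)] <- 0
    return(matrix(as.numeric(Matrix::solve(A, b)), nx, ny))
  }

  # Jacobi reference path
  les <- if (has_lesion) lesion$cells else matrix(FALSE, nx, ny)
  phi <- matrix(0, nx, ny)
  rhs <- nu; rhs[les] <- 0
  # number of in-grid neighbours per cell (lesion neighbours count in the
  # diagonal but contribute value 0)
  m <- matrix(4, nx, ny)
  m[1, ] <- m[1, ] - 1; m[nx, ] <- m[nx, ] - 1
  m[, 1] <- m[, 1] - 1; m[, ny] <- m[, ny] - 1
  diagv <- 1 + alpha * m
  bnorm <- sqrt(sum(rhs^2))
  if (bnorm == 0) return(phi)
  nbr_sum <- function(p) {
    p[les] <- 0
    s <- matrix(0, nx, ny)
    s[-nx, ] <- s[-nx, ] + p[-1, ]
    s[-1, ]  <- s[-1, ]  + p[-nx, ]
    s[, -ny] <- s[, -ny] + p[, -1]
    s[, -1]  <- s[, -1]  + p[, -ny]
    s
  }
  for (it in seq_len(max_iter)) {
    phi_new <- (rhs + alpha * nbr_sum(phi)) / diagv
    phi_new[les] <- 0
    phi <- phi_new
    if (it %% 50 == 0 || it == max_iter) {
      resid <- sqrt(sum((diagv * phi - alpha * nbr_sum(phi) - rhs)^2)) / bnorm
      if (resid <= tol) return(phi)
    }
  }
  abort(sprintf(
    "Jacobi iteration did not reach tol = %g within %d iterations (residual %g)",
    tol, max_iter, resid))
}

#' Lesion mask for the simulation domain
#'
#' Rasterises a lesion of the synaptic connectivity onto the grid. On
#' lesion cells the presynaptic rate is pinned to zero (`phi = 0`), which
#' interrupts the axo-dendritic spread; potassium diffusion still crosses
#' the lesion unless `blocks_diffusion = TRUE`.
#'
#' @param domain A [build_domain()] object (grid geometry).
#' @param kind `"none"`, `"partial_segment"` (a straight segment given by
#'   its endpoints), or `"complete_line"` (a vertical cut spanning the full
#'   domain height at `x`).
#' @param x0,y0,x1,y1 Segment endpoints (mm), for `"partial_segment"`.
#' @param x Position (mm) of the vertical cut, for `"complete_line"`.
#' @param blocks_diffusion Should the lesion also block potassium
#'   diffusion (an impermeable cut)? Default `FALSE`: lesions interrupt
#'   synaptic connectivity only.
#' @param style How a `"complete_line"` cut is realised. `"cells"`: the
#'   rasterised cell column is deadened (`phi = 0` Dirichlet rows), as for
#'   partial segments. `"edges"`: a blade cut -- the synaptic coupling
#'   (and, with `blocks_diffusion`, the potassium flux) across the
#'   interface between two columns is severed while the cells on both
#'   sides stay alive; no tissue is removed.
#' @return An object of class `lesion_mask` with elements `kind`, `cells`
#'   (logical matrix), `style`, `cut_after` (for edge cuts: coupling is
#'   severed between columns `cut_after` and `cut_after + 1`) and
#'   `blocks_diffusion`.
#' @export
make_lesion_mask <- function(domain, kind = c("none", "partial_segment",
                                              "complete_line"),
                             x0 = NULL, y0 = NULL, x1 = NULL, y1 = NULL,
                             x = NULL, blocks_diffusion = FALSE,
                             style = c("cells", "edges")) {
  kind <- match.arg(kind)
  style <- match.arg(style)
  if (style == "edges" && kind != "complete_line") {
    abort("edge-style cuts are only defined for complete_line lesions")
  }
  nx <- domain$nx; ny <- domain$ny; dx <- domain$dx
  cells <- matrix(FALSE, nx, ny)
  if (kind == "partial_segment") {
    if (is.null(x0) || is.null(y0) || is.null(x1) || is.null(y1)) {
      abort("partial_segment needs endpoints x0, y0, x1, y1 (mm)")
    }
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    if (len == 0) abort("degenerate (zero-length) lesion segment")
    lims <- c(0, nx * dx, 0, ny * dx)
    if (min(x0, x1) < lims[1] || max(x0, x1) > lims[2] ||
        min(y0, y1) < lims[3] || max(y0, y1) > lims[4]) {
      abort("lesion segment endpoints must lie inside the domain")
    }
    s <- seq(0, 1, length.out = max(2L, ceiling(len / (dx / 4)) + 1L))
    ci <- pmin(nx, pmax(1L, ceiling((x0 + s * (x1 - x0)) / dx)))
    cj <- pmin(ny, pmax(1L, ceiling((y0 + s * (y1 - y0)) / dx)))
    cells[cbind(ci, cj)] <- TRUE
  } else if (kind == "complete_line") {
    if (is.null(x)) abort("complete_line needs the cut position `x` (mm)")
    if (style == "cells") {
      ci <- pmin(nx, pmax(1L, ceiling(x / dx)))
      cells[ci, ] <- TRUE
    } else {
      cut_after <- pmin(nx - 1L, pmax(1L, as.integer(round(x / dx))))
      return(structure(list(kind = kind, cells = cells, style = style,
                            cut_after = cut_after,
                            blocks_diffusion = isTRUE(blocks_diffusion)),
                       class = "lesion_mask"))
    }
  }
  structure(list(kind = kind, cells = cells, style = style,
                 cut_after = NULL,
                 blocks_diffusion = isTRUE(blocks_diffusion)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> kind = %s, %d cells, blocks_diffusion = %s\n",
              x$kind, sum(x$cells), x$blocks_diffusion))
  invisible(x)
}
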