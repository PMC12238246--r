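#' Intercellular stress from traction by two-dimensional force balance
#'
#' Monolayer stress microscopy: the in-plane stress tensor sigma of the cell
#' sheet (thickness h) balances the substrate traction t through
#' `h * d sigma_ij / d x_j = t_i`. The balance is solved over the image
#' frame as a plane-stress finite-element problem for a homogeneous,
#' isotropic, elastically compatible sheet with stress-free boundaries;
#' rigid-body motions are removed by Lagrange constraints. The equilibrium
#' content of the recovered stress is independent of the fictitious sheet
#' modulus (unity is used); the fictitious Poisson ratio redistributes
#' stress only weakly and defaults to zero, for which the one-dimensional
#' force balance is reproduced exactly.
#'
#' @param traction a net-force-free traction `vector_field` (Pa).
#' @param gel a [gel_spec()]; the monolayer height enters as 1/h.
#' @param sheet_poisson Poisson ratio of the fictitious elastic sheet
#'   (default 0).
#' @return object of class `stress_field`: `avg_normal_pa` (matrix of the
#'   average normal stress `(sigma_xx + sigma_yy)/2` at element centers, in
#'   Pa), tensor components `sxx_pa`, `syy_pa`, `sxy_pa`, `spacing_um`, and
#'   `summary` with `mean_abs_pa` and `mean_signed_pa`.
#' @export
monolayer_stress <- function(traction, gel, sheet_poisson = 0) {
  stopifnot(inherits(traction, "vector_field"), inherits(gel, "gel_spec"))
  tx <- traction$vx; ty <- traction$vy
  n <- nrow(tx)
  if (ncol(tx) != n) stop("traction grid must be square")
  scale <- mean(sqrt(tx^2 + ty^2))
  if (scale > 0 &&
      sqrt(sum(tx)^2 + sum(ty)^2) / (scale * n^2) > 1e-6)
    stop("unbalanced traction field: remove the net (DC) component first")
  d_m <- traction$spacing_um * 1e-6
  h_m <- gel$height_um * 1e-6

  Ke <- q4_stiffness(d_m, sheet_poisson)
  nn <- n * n
  node <- function(r, c) (c - 1L) * n + r
  er <- rep(seq_len(n - 1L), times = n - 1L)
  ec <- rep(seq_len(n - 1L), each = n - 1L)
  conn <- cbind(node(er, ec), node(er, ec + 1L),
                node(er + 1L, ec + 1L), node(er + 1L, ec))
  dofs <- cbind(conn[, 1], conn[, 1] + nn, conn[, 2], conn[, 2] + nn,
                conn[, 3], conn[, 3] + nn, conn[, 4], conn[, 4] + nn)
  ne <- nrow(conn)
  ii <- rep(t(dofs), times = rep(8L, 8L * ne))
  jj <- as.vector(t(dofs[, rep(seq_len(8L), times = 8L)]))
  xx <- rep(as.vector(Ke), times = ne)
  # assemble; duplicated (i,j) triplets are summed
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2 * nn, 2 * nn))

  # tributary-area load lumping (half cells on edges, quarter at corners);
  # re-balance to numerical zero
  w1 <- rep(1, n); w1[c(1L, n)] <- 0.5
  W <- outer(w1, w1)
  fx <- -as.vector(tx * W) * d_m^2
  fy <- -as.vector(ty * W) * d_m^2
  fx <- fx - mean(fx); fy <- fy - mean(fy)
  Fv <- c(fx, fy)

  xs <- rep((seq_len(n) - 0.5) * d_m, times = n)  # y (row) coordinate
  ys <- xs
  xn <- rep((seq_len(n) - 0.5) * d_m, each = n)   # x (col) coordinate
  C <- cbind(c(rep(1, nn), rep(0, nn)),
             c(rep(0, nn), rep(1, nn)),
             c(-(ys - mean(ys)), (xn - mean(xn))))
  KKT <- rbind(cbind(K, Matrix::Matrix(C, sparse = TRUE)),
               cbind(Matrix::t(Matrix::Matrix(C, sparse = TRUE)),
                     Matrix::Matrix(0, 3, 3, sparse = TRUE)))
  sol <- Matrix::solve(KKT, c(Fv, 0, 0, 0))
  u <- as.numeric(sol[seq_len(2 * nn)])

  # element-center stresses via the bilinear strain-displacement matrix
  D <- pstress_D(sheet_poisson)
  Bc <- q4_center_B(d_m)
  ue <- matrix(u[t(dofs)], nrow = 8L)
  eps <- Bc %*% ue
  sig <- D %*% eps                       # thickness-integrated stress, N/m
  m <- n - 1L
  sxx <- matrix(sig[1, ], m, m) / h_m
  syy <- matrix(sig[2, ], m, m) / h_m
  sxy <- matrix(sig[3, ], m, m) / h_m
  avg <- (sxx + syy) / 2
  structure(list(avg_normal_pa = avg, sxx_pa = sxx, syy_pa = syy,
                 sxy_pa = sxy, spacing_um = traction$spacing_um,
                 summary = list(mean_abs_pa = mean(abs(avg)),
                                mean_signed_pa = mean(avg))),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("<stress_field> %d x %d, mean |sigma| = %.4g Pa, mean signed = %.4g Pa\n",
              nrow(x$avg_normal_pa), ncol(x$avg_normal_pa),
              x$summary$mean_abs_pa, x$summary$mean_signed_pa))
  invisible(x)
}

pstress_D <- function(nu) {
  matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3) / (1 - nu^2)
}

# 8x8 stiffness of a square bilinear quad (side a, unit modulus/thickness).
q4_stiffness <- function(a, nu) {
  D <- pstress_D(nu)
  gp <- c(-1, 1) / sqrt(3)
  xi_n <- c(-1, 1, 1, -1); eta_n <- c(-1, -1, 1, 1)
  Ke <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    dNdx <- xi_n * (1 + eta * eta_n) / 4 * (2 / a)
    dNdy <- eta_n * (1 + xi * xi_n) / 4 * (2 / a)
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    Ke <- Ke + t(B) %*% D %*% B * (a / 2)^2
  }
  Ke
}

q4_center_B <- function(a) {
  xi_n <- c(-1, 1, 1, -1); eta_n <- c(-1, -1, 1, 1)
  dNdx <- xi_n / 4 * (2 / a)
  dNdy <- eta_n / 4 * (2 / a)
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNdx
  B[2, seq(2, 8, 2)] <- dNdy
  B[3, seq(1, 8, 2)] <- dNdy
  B[3, seq(2, 8, 2)] <- dNdx
  B
}
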