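test_that("backward differences and their adjoint are exact adjoints", {
  set.seed(3)
  m <- matrix(rnorm(8 * 11), 8, 11)
  u <- list(x = matrix(rnorm(8 * 11), 8, 11),
            y = matrix(rnorm(8 * 11), 8, 11))
  d <- patchtv:::diff_back(m)
  lhs <- sum(d$x * u$x) + sum(d$y * u$y)
  rhs <- sum(m * patchtv:::diff_back_adjoint(u))
  expect_equal(lhs, rhs, tolerance = 1e-13)
})

test_that("tv_value matches a brute-force double loop", {
  set.seed(5)
  m <- matrix(rnorm(49), 7, 7)
  brute <- function(m, periodic) {
    ny <- nrow(m); nx <- ncol(m)
    s <- 0
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      dy <- if (i > 1) m[i, j] - m[i - 1, j]
            else if (periodic) m[1, j] - m[ny, j] else 0
      dx <- if (j > 1) m[i, j] - m[i, j - 1]
            else if (periodic) m[i, 1] - m[i, nx] else 0
      s <- s + sqrt(dx^2 + dy^2)
    }
    s
  }
  expect_equal(tv_value(m, "zero"), brute(m, FALSE), tolerance = 1e-12)
  expect_equal(tv_value(m, "periodic"), brute(m, TRUE), tolerance = 1e-12)
  expect_equal(tv_value(matrix(2, 5, 5)), 0)
})

test_that("shrink_step matches a numeric 2D minimizer on 200 random tuples", {
  set.seed(42)
  worst <- 0
  for (t in 1:200) {
    a1 <- rnorm(2, sd = 2)
    a2 <- rnorm(2, sd = 2)
    alpha <- runif(1, 0.05, 3)
    sigma <- runif(1, 0.05, 3)
    s <- sigma / alpha
    f <- function(u) sqrt(sum(u^2)) + sum((u - a1)^2) + s * sum((u - a2)^2)
    cl <- shrink_step(list(x = a1[1], y = a1[2]),
                      list(x = a2[1], y = a2[2]), alpha, sigma)
    ucl <- c(cl$x, cl$y)
    best <- ucl
    for (st in list(c(0, 0), a1, a2, ucl + rnorm(2, sd = 0.1))) {
      o <- optim(st, f, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
      o <- optim(o$par, f, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
      if (f(o$par) < f(best)) best <- o$par
    }
    worst <- max(worst, sqrt(sum((ucl - best)^2)))
    # closed form is never beaten by the numeric minimizer
    expect_lte(f(ucl), f(best) + 1e-10)
  }
  expect_lte(worst, 1e-6)
})

test_that("shrink_step zeroes the dead zone and handles v = 0", {
  z <- list(x = matrix(0, 2, 2), y = matrix(0, 2, 2))
  small <- list(x = matrix(0.1, 2, 2), y = matrix(0.1, 2, 2))
  u <- shrink_step(small, z, alpha = 1, sigma_n = 1)  # |v| < 1
  expect_equal(u$x, matrix(0, 2, 2))
  u0 <- shrink_step(z, z, alpha = 1, sigma_n = 1)
  expect_equal(u0$y, matrix(0, 2, 2))
})

test_that("laplacian_symbol diagonalises D'D under the DFT", {
  set.seed(8)
  m <- matrix(rnorm(6 * 9), 6, 9)
  sym <- patchtv:::laplacian_symbol(6, 9)
  dtd <- patchtv:::diff_back_adjoint(patchtv:::diff_back(m))
  via_fft <- Re(fft(sym * fft(m), inverse = TRUE)) / (6 * 9)
  expect_equal(via_fft, dtd, tolerance = 1e-10)
})

test_that("stacked operator gradient and residual match a dense oracle", {
  set.seed(13)
  n <- 16
  M <- Matrix::Matrix(matrix(rnorm(24 * n), 24, n), sparse = TRUE)
  Hd <- matrix(runif(n * n), n, n)
  Hd <- Hd / rowSums(Hd)
  H <- methods::as(Hd, "CsparseMatrix")
  g <- rnorm(24)
  beta <- 0.7
  K <- stacked_operator(M, g, H, beta)
  a <- rnorm(n)
  Kd <- rbind(as.matrix(M), sqrt(beta) * (diag(n) - Hd))
  gt <- c(g, rep(0, n))
  expect_equal(patchtv:::stacked_resid2(K, a), sum((Kd %*% a - gt)^2),
               tolerance = 1e-12)
  expect_equal(patchtv:::stacked_grad(K, a),
               as.vector(t(Kd) %*% (Kd %*% a - gt)), tolerance = 1e-12)
  expect_equal(patchtv:::stacked_norm2(K, a), sum((Kd %*% a)^2),
               tolerance = 1e-12)
  expect_error(stacked_operator(M, g, NULL, beta), "requires H")
  expect_error(stacked_operator(M, g[-1], H, beta))
})

test_that("image_update solves its quadratic system to 1e-10", {
  set.seed(21)
  ny <- 8; nx <- 8
  M <- Matrix::Matrix(matrix(rnorm(40 * ny * nx, sd = 0.2), 40, ny * nx),
                      sparse = TRUE)
  g <- rnorm(40)
  K <- stacked_operator(M, g)
  A_n <- matrix(rnorm(ny * nx), ny, nx)
  u <- list(x = matrix(rnorm(ny * nx), ny, nx),
            y = matrix(rnorm(ny * nx), ny, nx))
  alpha <- 0.6; sigma <- 0.9
  A1 <- image_update(A_n, u, alpha, sigma, K)
  # residual of (alpha D'D + sigma I) A1 = alpha D'u + sigma A_n - grad
  lhs <- alpha * patchtv:::diff_back_adjoint(patchtv:::diff_back(A1)) +
    sigma * A1
  grad <- matrix(patchtv:::stacked_grad(K, as.vector(A_n)), ny, nx)
  rhs <- alpha * patchtv:::diff_back_adjoint(u) + sigma * A_n - grad
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  # alpha = 0 reduces to a plain gradient step
  A0 <- image_update(A_n, u, 0, sigma, K)
  expect_equal(A0, A_n - grad / sigma, tolerance = 1e-10)
})

test_that("bb_step_update matches its formulas", {
  set.seed(31)
  ny <- 5; nx <- 6
  M <- Matrix::Matrix(matrix(rnorm(20 * ny * nx), 20, ny * nx), sparse = TRUE)
  K <- stacked_operator(M, rnorm(20))
  rnd <- function() matrix(rnorm(ny * nx), ny, nx)
  A_n <- rnd(); A_next <- rnd()
  u_n <- list(x = rnd(), y = rnd())
  u_next <- list(x = rnd(), y = rnd())
  b_n <- list(x = rnd(), y = rnd())
  out <- bb_step_update(A_n, A_next, u_n, u_next, b_n, 0.7, K)
  dn <- patchtv:::diff_back(A_next)
  expect_equal(out$b$x, b_n$x - (u_next$x - dn$x), tolerance = 1e-12)
  expect_equal(out$b$y, b_n$y - (u_next$y - dn$y), tolerance = 1e-12)
  dA <- as.vector(A_next - A_n)
  num <- sum(as.vector(M %*% dA)^2)
  den <- sum((u_next$x - u_n$x)^2) + sum((u_next$y - u_n$y)^2) + sum(dA^2)
  expect_equal(out$sigma, num / den, tolerance = 1e-12)
  # unchanged iterates keep sigma
  same <- bb_step_update(A_n, A_n, u_n, u_n, b_n, 0.7, K)
  expect_equal(same$sigma, 0.7)
})

test_that("stopping_check implements the relative-change rule", {
  u <- list(x = matrix(1, 2, 2), y = matrix(0, 2, 2))
  almost <- list(x = matrix(1 + 1e-6, 2, 2), y = matrix(0, 2, 2))
  far <- list(x = matrix(2, 2, 2), y = matrix(0, 2, 2))
  z <- list(x = matrix(0, 2, 2), y = matrix(0, 2, 2))
  expect_true(stopping_check(u, almost, 1e-4))
  expect_false(stopping_check(u, far, 1e-4))
  expect_true(stopping_check(z, z, 1e-4))   # 0/0: converged
  expect_false(stopping_check(z, u, 1e-4))  # zero now, nonzero before
  expect_error(stopping_check(u, u, 0))
})
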