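dummy_spectrum_set <- function(n_sub = 20, seed = 1) {
  set.seed(seed)
  amp <- array(abs(rnorm(n_sub * 19 * 2 * 31, 3)),
               dim = c(n_sub, 19, 2, 31),
               dimnames = list(sprintf("S%02d", 1:n_sub), eeg_labels(),
                               c("Go", "NoGo"), 0:30))
  structure(list(amplitude = amp, freqs = 0:30,
                 subjects = sprintf("S%02d", 1:n_sub),
                 channel_names = eeg_labels(),
                 n_trials = matrix(60L, n_sub, 2)),
            class = "plk_spectrum_set")
}

dummy_erp_set <- function(n_sub = 20, seed = 2) {
  set.seed(seed)
  tms <- ((-25):153) / 256 * 1000
  dat <- array(rnorm(n_sub * 19 * 2 * 179),
               dim = c(n_sub, 19, 2, 179),
               dimnames = list(sprintf("S%02d", 1:n_sub), eeg_labels(),
                               c("Go", "NoGo"), NULL))
  structure(list(data = dat, times_ms = tms,
                 subjects = sprintf("S%02d", 1:n_sub),
                 channel_names = eeg_labels()), class = "plk_erp_set")
}

test_that("PCA inputs have the canonical shapes and ratios", {
  fin <- assemble_fpca_input(dummy_spectrum_set())
  expect_equal(dim(fin$X), c(760, 31))
  expect_equal(round(nrow(fin$X) / ncol(fin$X), 1), 24.5)
  small <- assemble_fpca_input(dummy_spectrum_set(n_sub = 2))
  expect_equal(nrow(small$X), 76)
  tin <- assemble_tpca_input(dummy_erp_set(), "Go")
  expect_equal(dim(tin$X), c(380, 179))
  expect_equal(round(nrow(tin$X) / ncol(tin$X), 1), 2.1)
  expect_equal(length(tin$variable_axis), 179)
  expect_equal(diff(tin$variable_axis)[1], 1000 / 256)   # 3.9 ms grid
})

test_that("covariance PCA matches closed forms and reconstructs exactly", {
  # diag(4, 1) covariance: first loading (2, 0) up to sign, 80% variance;
  # built with exact sample moments (centred, orthogonalised, rescaled)
  set.seed(33)
  a <- rnorm(400); a <- a - mean(a)
  b <- rnorm(400); b <- b - mean(b); b <- b - a * sum(a * b) / sum(a * a)
  X <- cbind(2 * a / stats::sd(a), b / stats::sd(b))
  cp <- covariance_pca(X)
  expect_equal(abs(cp$pattern[, 1]), c(2, 0), tolerance = 1e-9)
  expect_equal(cp$eigenvalues[1] / sum(cp$eigenvalues), 0.8, tolerance = 1e-9)
  # random matrix: full reconstruction and trace bookkeeping
  Y <- matrix(rnorm(300), 50, 6)
  cpy <- covariance_pca(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_lt(max(abs(cpy$scores %*% t(cpy$pattern) - Yc)), 1e-8)
  expect_lt(abs(sum(cpy$eigenvalues) - sum(diag(stats::cov(Y)))) /
            sum(cpy$eigenvalues), 1e-8)
  expect_equal(apply(cpy$scores, 2, stats::sd), rep(1, 6), tolerance = 1e-9)
  # duplicated variable: rank deficiency detected and dropped
  Z <- cbind(Y, Y[, 1])
  expect_message(cpz <- covariance_pca(Z), "rank-deficient")
  expect_equal(length(cpz$eigenvalues), 6)
})

test_that("varimax matches a brute-force rotation-angle grid", {
  set.seed(34)
  A0 <- cbind(c(rep(2, 5), rep(0, 5)), c(rep(0, 5), rep(1.5, 5)))
  A0 <- A0 + matrix(rnorm(20, sd = 0.05), 10, 2)
  th0 <- 0.6
  A <- A0 %*% matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2)
  vm <- varimax_rotate(A, kaiser = FALSE)
  grid <- seq(0, pi / 2, length.out = 200001)
  crit <- vapply(grid, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    varimax_criterion(A %*% R)
  }, 0)
  expect_lt(abs(varimax_criterion(vm$loadings) - max(crit)), 1e-6)
  # simple structure recovered (columns match A0 up to sign/order)
  m <- abs(stats::cor(vm$loadings, A0))
  expect_true(all(apply(m, 1, max) > 0.999))
  # already-simple loadings: rotation ~ identity
  simple <- cbind(c(rep(2, 5), rep(0, 5)), c(rep(0, 5), rep(1.5, 5)))
  vm0 <- varimax_rotate(simple, kaiser = FALSE)
  expect_lt(max(abs(abs(vm0$rotmat) - diag(2))), 1e-4)
  # orthogonality invariant: per-variable communality preserved
  expect_equal(rowSums(vm$loadings^2), rowSums(A^2), tolerance = 1e-10)
})

test_that("promax behaves like varimax on orthogonal truth", {
  set.seed(35)
  L <- matrix(0, 30, 2)
  L[1:15, 1] <- rnorm(15, 2, 0.2); L[16:30, 2] <- rnorm(15, 2, 0.2)
  S <- matrix(rnorm(2000), 1000, 2)
  X <- S %*% t(L) + matrix(rnorm(30000, sd = 0.2), 1000, 30)
  cp <- covariance_pca(X)
  pm <- suppressWarnings(promax_rotate(cp$pattern[, 1:2]))
  expect_lt(max(abs(pm$phi[upper.tri(pm$phi)])), 0.05)
  agree <- abs(stats::cor(pm$pattern, pm$varimax$loadings))
  expect_true(all(apply(agree, 1, max) > 0.99))
  # kappa = 1: target equals loadings, transformation ~ identity
  vm <- suppressWarnings(varimax_rotate(cp$pattern[, 1:2]))
  pm1 <- suppressWarnings(promax_rotate(cp$pattern[, 1:2], kappa = 1))
  expect_lt(max(abs(abs(crossprod(vm$rotmat, pm1$trans)) - diag(2))), 1e-6)
})

test_that("promax recovers a planted oblique factor correlation", {
  set.seed(36)
  phi_true <- matrix(c(1, 0.5, 0.5, 1), 2)
  Lc <- chol(phi_true)
  S <- matrix(rnorm(760 * 2), 760, 2) %*% Lc     # correlated factors
  L <- matrix(0, 31, 2)
  L[3:9, 1] <- 3 * exp(-0.5 * ((3:9 - 6) / 1.5)^2)
  L[18:28, 2] <- 3 * exp(-0.5 * ((18:28 - 23) / 2)^2)
  X <- S %*% t(L) + matrix(rnorm(760 * 31, sd = 0.3), 760, 31)
  cp <- select_and_scale(rotate_components(covariance_pca(X), "promax"))
  sel <- which(cp$selected)
  j1 <- sel[which.min(abs(cp$peak_variable[sel] - 6))]
  j2 <- sel[which.min(abs(cp$peak_variable[sel] - 23))]
  expect_lt(abs(abs(cp$phi[j1, j2]) - 0.5), 0.15)
})

test_that("selection, scaling, ordering and sign are deterministic", {
  set.seed(37)
  ss <- dummy_spectrum_set(n_sub = 10, seed = 40)
  # add structure so selection is non-trivial
  alpha <- 4 * exp(-0.5 * ((0:30 - 9) / 1.5)^2)
  for (s in 1:10) {
    ss$amplitude[s, , , ] <- ss$amplitude[s, , , ] +
      rep(exp(rnorm(1, 0, 0.4)) * rep(alpha, each = 19 * 2), 1)
  }
  inp <- assemble_fpca_input(ss)
  cp <- select_and_scale(rotate_components(covariance_pca(inp), "promax"))
  expect_true(all(diff(cp$peak_variable) >= 0))   # ordered by peak
  expect_true(all(cp$pct_variance[cp$selected] >= 1.5))
  expect_true(all(cp$pct_variance[!cp$selected] < 1.5))
  expect_lt(sum(cp$pct_variance[cp$selected]), 100 + 1e-9)
  # spectra are positive, so every selected peak loading is positive
  expect_true(all(cp$pattern[cbind(cp$peak_index, seq_along(cp$names))]
                  [cp$selected] > 0))
  # permuting case order leaves the signed solution unchanged
  perm <- sample(nrow(inp$X))
  inp2 <- inp; inp2$X <- inp$X[perm, ]; inp2$case_meta <- inp$case_meta[perm, ]
  cp2 <- select_and_scale(rotate_components(covariance_pca(inp2), "promax"))
  expect_equal(cp2$pattern[, cp2$selected], cp$pattern[, cp$selected],
               tolerance = 1e-6)
  # inclusive threshold boundary
  fake <- cp; fake$pct_variance <- c(1.5, rep(1, length(cp$names) - 1))
  fake$selected <- fake$pct_variance >= 1.5
  expect_true(fake$selected[1])
})

test_that("peak amplitudes recover planted per-subject strengths", {
  set.seed(38)
  n_sub <- 20
  strength <- exp(rnorm(n_sub, 0, 0.5))
  alpha <- 5 * exp(-0.5 * ((0:30 - 9) / 1.5)^2)
  topo <- topography_gaussian("Pz", 90, fixture_montage)
  amp <- array(0, dim = c(n_sub, 19, 2, 31),
               dimnames = list(sprintf("S%02d", 1:n_sub), eeg_labels(),
                               c("Go", "NoGo"), 0:30))
  for (s in 1:n_sub) for (co in 1:2) {
    amp[s, , co, ] <- outer(topo, alpha) * strength[s] +
      abs(matrix(rnorm(19 * 31, 0.3, 0.05), 19))
  }
  ss <- structure(list(amplitude = amp, freqs = 0:30,
                       subjects = sprintf("S%02d", 1:n_sub),
                       channel_names = eeg_labels(),
                       n_trials = matrix(60L, n_sub, 2)),
                  class = "plk_spectrum_set")
  cp <- select_and_scale(rotate_components(
    covariance_pca(assemble_fpca_input(ss)), "promax"))
  j <- which(cp$selected & cp$peak_variable == 9)
  expect_length(j, 1)
  meas <- peak_amplitudes(cp, "pooled", components = j)
  expect_equal(nrow(meas), n_sub)                 # one value per subject
  expect_gt(stats::cor(meas[[2]], strength, method = "spearman"), 0.9)
  expect_gt(stats::cor(meas[[2]], strength), 0.99)
  # recovered topography tracks the planted one
  topo_hat <- component_topography(cp, j)
  expect_gt(stats::cor(topo_hat[eeg_labels()], topo[eeg_labels()]), 0.95)
  # all-equal cases -> zero between-subject variance
  amp0 <- amp; for (s in 1:n_sub) amp0[s, , , ] <- amp[1, , , ]
  ss0 <- ss; ss0$amplitude <- amp0
  cp0 <- suppressMessages(select_and_scale(rotate_components(
    covariance_pca(assemble_fpca_input(ss0)), "promax")))
  m0 <- peak_amplitudes(cp0, "pooled", components = which(cp0$selected)[1])
  expect_lt(stats::sd(m0[[2]]), 1e-8)
})

test_that("structure = pattern x phi and variance bookkeeping hold", {
  set.seed(39)
  X <- matrix(rnorm(380 * 20), 380, 20) %*% diag(seq(3, 0.5, length.out = 20))
  cp <- rotate_components(covariance_pca(X), "promax")
  expect_lt(max(abs(cp$structure - cp$pattern %*% cp$phi)), 1e-8)
  vm <- rotate_components(covariance_pca(X), "varimax")
  expect_equal(sum(vm$pattern^2), sum(covariance_pca(X)$pattern^2),
               tolerance = 1e-8)                  # varimax keeps total variance
  expect_equal(vm$phi, diag(20))
})
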