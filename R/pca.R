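#' Assemble the frequency-PCA input matrix
#'
#' Stacks prestimulus spectra over subject x channel x condition into a
#' case x frequency matrix: 20 subjects x 19 channels x 2 conditions give
#' 760 cases x 31 variables (DC-30 Hz), a case-to-variable ratio of 24.5.
#'
#' @param ss `plk_spectrum_set`.
#' @return list of class `plk_pca_input`: `X` (cases x variables,
#'   microvolts), `case_meta` (subject/channel/condition per case),
#'   `variable_axis` (frequencies, Hz), `axis_unit`.
#' @export
assemble_fpca_input <- function(ss) {
  stopifnot(inherits(ss, "plk_spectrum_set"))
  d <- dim(ss$amplitude)
  n_case <- d[1] * d[2] * d[3]
  X <- matrix(0, n_case, d[4])
  meta <- data.frame(subject = character(n_case), channel = character(n_case),
                     condition = character(n_case), stringsAsFactors = FALSE)
  r <- 0L
  for (s in seq_len(d[1])) for (ch in seq_len(d[2])) for (co in seq_len(d[3])) {
    r <- r + 1L
    X[r, ] <- ss$amplitude[s, ch, co, ]
    meta[r, ] <- c(ss$subjects[s], ss$channel_names[ch],
                   dimnames(ss$amplitude)[[3]][co])
  }
  structure(list(X = X, case_meta = meta, variable_axis = ss$freqs,
                 axis_unit = "Hz"), class = "plk_pca_input")
}

#' Assemble the temporal-PCA input matrix for one condition
#'
#' Stacks condition-mean ERPs (-100..600 ms at 256 Hz, 179 samples) over
#' subject x channel: 20 subjects x 19 channels give 380 cases x 179
#' variables, a case-to-variable ratio of 2.1.
#'
#' @param es `plk_erp_set` from [erp_set()].
#' @param condition "Go" or "NoGo".
#' @return `plk_pca_input` (variable axis = latency, ms).
#' @export
assemble_tpca_input <- function(es, condition = c("Go", "NoGo")) {
  condition <- match.arg(condition)
  d <- dim(es$data)                      # subject x channel x cond x sample
  co <- match(condition, dimnames(es$data)[[3]])
  n_case <- d[1] * d[2]
  X <- matrix(0, n_case, d[4])
  meta <- data.frame(subject = character(n_case), channel = character(n_case),
                     condition = condition, stringsAsFactors = FALSE)
  r <- 0L
  for (s in seq_len(d[1])) for (ch in seq_len(d[2])) {
    r <- r + 1L
    X[r, ] <- es$data[s, ch, co, ]
    meta$subject[r] <- es$subjects[s]
    meta$channel[r] <- es$channel_names[ch]
  }
  structure(list(X = X, case_meta = meta, variable_axis = es$times_ms,
                 axis_unit = "ms"), class = "plk_pca_input")
}

#' Covariance-matrix PCA
#'
#' Eigendecomposition of the variable covariance matrix over cases
#' (variables centred, never standardised; n-1 denominator).  Unrotated
#' loadings are eigenvector x sqrt(eigenvalue), so they carry microvolt
#' units per standardised-score SD and `scores %*% t(loadings)`
#' reconstructs the centred data when all components are retained.
#' Components with (numerically) non-positive eigenvalues are dropped with
#' a message.
#'
#' @param input `plk_pca_input` (or plain case x variable matrix).
#' @return object of class `plk_components` holding unrotated loadings
#'   (`pattern`), standardised `scores`, `eigenvalues`, `total_variance`,
#'   `grand_mean`, and the input metadata.
#' @export
covariance_pca <- function(input) {
  if (is.matrix(input)) {
    input <- structure(list(X = input, case_meta = NULL,
                            variable_axis = seq_len(ncol(input)),
                            axis_unit = "index"), class = "plk_pca_input")
  }
  X <- input$X
  if (anyNA(X)) stop_invalid("PCA input contains missing values")
  n <- nrow(X)
  gm <- colMeans(X)
  Xc <- sweep(X, 2, gm)
  C <- crossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  tol <- max(e$values) * 1e-12
  keep <- which(e$values > tol)
  if (length(keep) < ncol(X)) {
    message(sprintf("rank-deficient covariance: retaining %d of %d components",
                    length(keep), ncol(X)))
  }
  lam <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  A <- V %*% diag(sqrt(lam), length(lam))
  Fs <- Xc %*% V %*% diag(1 / sqrt(lam), length(lam))
  structure(list(pattern = A, structure = A, scores = Fs,
                 phi = diag(length(lam)), eigenvalues = lam,
                 total_variance = sum(diag(C)), grand_mean = gm,
                 variable_axis = input$variable_axis,
                 axis_unit = input$axis_unit, case_meta = input$case_meta,
                 rotation = "none"),
            class = "plk_components")
}

#' Raw Varimax simple-structure criterion
#'
#' Sum over components of the variance of the squared loadings; the
#' quantity maximised by Varimax rotation.
#' @param L loading matrix (variables x components).
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(L) {
  sum(colMeans(L^4) - colMeans(L^2)^2)
}

#' Varimax rotation (orthogonal) with optional Kaiser normalisation
#'
#' Maximises the Varimax criterion by the simultaneous SVD update; with
#' `kaiser = TRUE` the loading rows are scaled to unit communality before
#' rotation and restored afterwards.  The criterion is non-decreasing per
#' sweep; convergence when the relative gain falls below `eps` (warning
#' and best-so-far after `max_iter` sweeps).
#'
#' @param A loading matrix (variables x components).
#' @param kaiser apply Kaiser normalisation (default TRUE).
#' @param eps relative convergence tolerance (default 1e-10).
#' @param max_iter sweep cap (default 1000).
#' @return list: `rotmat` (orthogonal k x k), `loadings` (= A %*% rotmat),
#'   `iterations`.
#' @export
varimax_rotate <- function(A, kaiser = TRUE, eps = 1e-10, max_iter = 1000) {
  k <- ncol(A)
  if (k < 2) return(list(rotmat = diag(k), loadings = A, iterations = 0L))
  h <- sqrt(rowSums(A^2)); h[h < 1e-12] <- 1
  An <- if (kaiser) A / h else A
  R <- diag(k); d <- 0
  it <- 0L
  repeat {
    it <- it + 1L
    L <- An %*% R
    B <- crossprod(An, L^3 - L %*% diag(colMeans(L^2), k))
    s <- La.svd(B)
    R <- s$u %*% s$vt
    d_old <- d; d <- sum(s$d)
    if (it >= max_iter) {
      warning("varimax did not converge; returning best rotation found")
      break
    }
    if (d_old != 0 && d < d_old * (1 + eps)) break
  }
  list(rotmat = R, loadings = A %*% R, iterations = it)
}

#' Promax rotation (oblique)
#'
#' Varimax first, then an oblique least-squares transformation towards the
#' sign-preserved `|loading|^kappa` target, with columns normalised so the
#' factor correlation matrix has unit diagonal.
#'
#' @param A loading matrix (variables x components).
#' @param kappa target power (default 3).
#' @param kaiser Kaiser normalisation for the Varimax step.
#' @return list: `trans` (total transformation, pattern = A %*% trans),
#'   `pattern`, `phi` (factor correlations), `varimax` (inner result).
#' @export
promax_rotate <- function(A, kappa = 3, kaiser = TRUE) {
  vm <- varimax_rotate(A, kaiser = kaiser)
  # target and least-squares fit in row-normalised (Kaiser) space, the
  # ERP-PCA convention: microvolt-scale loadings would otherwise dominate
  # the powered target and drive the transformation towards singularity
  h <- sqrt(rowSums(A^2)); h[h < 1e-12] <- 1
  L <- (if (kaiser) A / h else A) %*% vm$rotmat
  Q <- sign(L) * abs(L)^kappa
  G <- crossprod(L)
  if (rcond(G) < 1e-12) {
    stop_invalid("promax transformation singular for components: %s",
                 paste(which(colSums(abs(L)) < 1e-10), collapse = ", "))
  }
  U <- solve(G, crossprod(L, Q))
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), ncol(U))
  Tm <- vm$rotmat %*% U
  phi <- solve(crossprod(U))
  phi <- (phi + t(phi)) / 2
  list(trans = Tm, pattern = A %*% Tm, phi = phi, varimax = vm)
}

#' Rotate a PCA solution
#'
#' Applies Varimax (orthogonal) or Promax (oblique) rotation to the full
#' unrotated solution, propagating loadings, scores, and factor
#' correlations consistently: for a transformation T, pattern = A T,
#' scores = F (T')^{-1}, Phi = (T'T)^{-1}, structure = pattern Phi, so
#' scores %*% t(pattern) still reconstructs the centred data.
#'
#' @param comp `plk_components` from [covariance_pca()].
#' @param rotation "varimax" or "promax".
#' @param kappa Promax power (default 3).
#' @param kaiser Kaiser normalisation (default TRUE).
#' @return rotated `plk_components`.
#' @export
rotate_components <- function(comp, rotation = c("varimax", "promax"),
                              kappa = 3, kaiser = TRUE) {
  rotation <- match.arg(rotation)
  A <- comp$pattern
  if (rotation == "varimax") {
    vm <- varimax_rotate(A, kaiser = kaiser)
    comp$pattern <- vm$loadings
    comp$phi <- diag(ncol(A))
    comp$structure <- comp$pattern
    comp$scores <- comp$scores %*% vm$rotmat
  } else {
    pm <- promax_rotate(A, kappa = kappa, kaiser = kaiser)
    comp$pattern <- pm$pattern
    comp$phi <- pm$phi
    comp$structure <- pm$pattern %*% pm$phi
    comp$scores <- comp$scores %*% t(solve(pm$trans))
  }
  comp$rotation <- rotation
  comp
}

#' Select components by percent variance and finalise scaling
#'
#' Computes each rotated component's percent variance (sum of squared
#' microvolt-scaled loadings over the total data variance; for oblique
#' solutions the pattern-matrix sum of squares, which need not total
#' 100%), the peak variable (argmax |scaled loading|), a deterministic
#' sign (the scaled loading at the peak takes the sign of the grand-mean
#' data value there; positive when that mean is zero), selection at the
#' inclusive threshold, and ascending peak-variable ordering.
#'
#' @param comp rotated `plk_components`.
#' @param threshold percent-variance selection threshold (default 1.5,
#'   inclusive).
#' @return `plk_components` with `pct_variance`, `peak_variable`,
#'   `peak_index`, `selected`, components reordered.
#' @export
select_and_scale <- function(comp, threshold = 1.5) {
  P <- comp$pattern
  k <- ncol(P)
  pct <- colSums(P^2) / comp$total_variance * 100
  peak_idx <- apply(abs(P), 2, which.max)
  gm_sign <- sign(comp$grand_mean[peak_idx])
  gm_sign[gm_sign == 0] <- 1
  flip <- sign(P[cbind(peak_idx, seq_len(k))]) * gm_sign < 0
  if (any(flip)) {
    D <- diag(ifelse(flip, -1, 1), k)
    comp$pattern <- P <- P %*% D
    comp$scores <- comp$scores %*% D
    comp$phi <- D %*% comp$phi %*% D
    comp$structure <- comp$pattern %*% comp$phi
  }
  ord <- order(comp$variable_axis[peak_idx], -pct)
  comp$pattern <- comp$pattern[, ord, drop = FALSE]
  comp$structure <- comp$structure[, ord, drop = FALSE]
  comp$scores <- comp$scores[, ord, drop = FALSE]
  comp$phi <- comp$phi[ord, ord, drop = FALSE]
  comp$pct_variance <- pct[ord]
  comp$peak_index <- peak_idx[ord]
  comp$peak_variable <- comp$variable_axis[peak_idx[ord]]
  comp$selected <- comp$pct_variance >= threshold
  comp$names <- component_names(comp)
  comp
}

# Band/latency tags: delta 1-3 Hz, theta 4-7, alpha 8-12, beta 13-30.
component_names <- function(comp) {
  if (comp$axis_unit == "Hz") {
    band <- vapply(comp$peak_variable, function(f) {
      if (f < 1) "dc" else if (f <= 3) "delta" else if (f <= 7) "theta"
      else if (f <= 12) "alpha" else "beta"
    }, "")
    sprintf("%s_%dHz", band, round(comp$peak_variable))
  } else {
    sprintf("t%03dms", round(comp$peak_variable))
  }
}

#' Global mean peak amplitudes per subject
#'
#' For every case, a component's amplitude in microvolts is its
#' standardised score times the scaled loading at the component's peak
#' variable.  Within subject these are averaged over the scalp channels
#' (the "global mean"); `mode = "pooled"` additionally averages the Go and
#' NoGo cases (the frequency-PCA convention), `mode = "per_condition"`
#' keeps them separate (the temporal-PCA convention applies it to a
#' single-condition input).
#'
#' @param comp selected `plk_components` (with case_meta).
#' @param mode "pooled" or "per_condition".
#' @param prefix measure-name prefix (e.g. "EEG").
#' @param domain domain tag for the measure table.
#' @param components which components to extract (default the selected).
#' @return `plk_measures`, one column per component.
#' @export
peak_amplitudes <- function(comp, mode = c("pooled", "per_condition"),
                            prefix = "EEG", domain = "EEG",
                            components = which(comp$selected)) {
  mode <- match.arg(mode)
  if (is.null(comp$case_meta)) stop_invalid("components carry no case metadata")
  meta <- comp$case_meta
  subjects <- unique(meta$subject)
  cols <- list(); doms <- character()
  for (j in components) {
    amp_case <- comp$scores[, j] * comp$pattern[comp$peak_index[j], j]
    if (mode == "pooled") {
      v <- vapply(subjects, function(s) mean(amp_case[meta$subject == s]), 0)
      nm <- paste(prefix, comp$names[j], sep = "_")
      cols[[nm]] <- v; doms[nm] <- domain
    } else {
      for (co in unique(meta$condition)) {
        sel <- meta$condition == co
        v <- vapply(subjects, function(s) {
          mean(amp_case[sel & meta$subject == s])
        }, 0)
        nm <- paste(prefix, co, comp$names[j], sep = "_")
        cols[[nm]] <- v; doms[nm] <- domain
      }
    }
  }
  do.call(measure_table,
          c(list(subjects = subjects), cols, list(domains = doms)))
}

#' Mean per-channel component amplitude (topography)
#'
#' Averages each case-level component amplitude within channel, giving the
#' component's scalp topography in microvolts (used to compare recovered
#' components against planted topographies).
#'
#' @param comp selected `plk_components`.
#' @param component component index.
#' @return named numeric vector, one value per channel.
#' @export
component_topography <- function(comp, component) {
  meta <- comp$case_meta
  amp_case <- comp$scores[, component] *
    comp$pattern[comp$peak_index[component], component]
  chans <- unique(meta$channel)
  stats::setNames(vapply(chans, function(ch) {
    mean(amp_case[meta$channel == ch])
  }, 0), chans)
}
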