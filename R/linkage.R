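#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).  Returns NA
#' (with attribute `flag = "zero_rank_variance"`) when either vector has
#' no rank variance.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return Spearman rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop_invalid("x and y must have equal length >= 4")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(NA_real_, flag = "zero_rank_variance"))
  }
  stats::cor(rx, ry)
}

#' Two-tailed p value for a Spearman correlation (t approximation)
#'
#' t = rho sqrt((n-2)/(1-rho^2)) referred to Student's t with n-2 degrees
#' of freedom, doubled tail.  |rho| = 1 gives p = 0 by convention.
#'
#' @param rho Spearman correlation.
#' @param n sample size.
#' @return two-tailed p value.
#' @export
spearman_p <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Confidence interval for a Spearman correlation (Fisher z)
#'
#' Fisher z-transform with the Bonett-Wright standard error
#' sqrt((1 + rho^2/2)/(n - 3)), back-transformed by tanh.  The default
#' because it reproduces the printed anchor intervals; the classical
#' Fieller-style variant (SE sqrt(1.06/(n-3))) is available via `method`.
#'
#' @param rho Spearman correlation.
#' @param n sample size (> 3).
#' @param level confidence level (default 0.95).
#' @param method "bonett-wright" (default) or "fieller".
#' @return numeric c(ci_low, ci_high).
#' @export
spearman_ci <- function(rho, n, level = 0.95,
                        method = c("bonett-wright", "fieller")) {
  method <- match.arg(method)
  if (n <= 3) stop_invalid("CI undefined for n <= 3")
  if (is.na(rho)) return(c(NA_real_, NA_real_))
  z <- atanh(rho)
  se <- switch(method,
               "bonett-wright" = sqrt((1 + rho^2 / 2) / (n - 3)),
               "fieller" = sqrt(1.06 / (n - 3)))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - zc * se, z + zc * se))
}

band_for_p <- function(p) {
  if (is.na(p)) NA_character_
  else if (p <= 0.05) "significant"
  else if (p <= 0.10) "near"
  else "null"
}

#' Build the cross-domain Spearman link table
#'
#' Computes every pairwise Spearman correlation between measures of
#' different domains (EEG x ERP, EEG x behaviour, ERP x behaviour; Go and
#' NoGo ERP measures count as one ERP domain for pair enumeration, so
#' Go-ERP x NoGo-behaviour crossings are included but ERP x ERP pairs are
#' not), with two-tailed p, 95% CI, and significance banding (significant
#' p <= 0.05; near 0.05 < p <= 0.10).  No multiple-testing correction is
#' applied to the banding; a Benjamini-Hochberg column is appended as
#' supplementary output.
#'
#' @param measures `plk_measures` with domain tags.
#' @param level CI level.
#' @param ci_method CI variant, see [spearman_ci()].
#' @return data.frame of class `plk_links`: x_domain, x_name, y_domain,
#'   y_name, n, rho, p, ci_low, ci_high, band, p_bh.
#' @export
build_link_table <- function(measures, level = 0.95,
                             ci_method = "bonett-wright") {
  if (nrow(measures) < 4) stop_invalid("need at least 4 subjects")
  doms <- attr(measures, "domains")
  major <- function(d) if (startsWith(d, "ERP")) "ERP" else d
  nms <- names(doms)
  rows <- list()
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      if (major(doms[[i]]) == major(doms[[j]])) next
      x <- measures[[nms[i]]]; y <- measures[[nms[j]]]
      ok <- stats::complete.cases(x, y)
      rho <- spearman_rho(x[ok], y[ok])
      p <- spearman_p(rho, sum(ok))
      ci <- if (sum(ok) > 3) spearman_ci(rho, sum(ok), level, ci_method)
            else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        x_domain = doms[[i]], x_name = nms[i],
        y_domain = doms[[j]], y_name = nms[j],
        n = sum(ok), rho = as.numeric(rho), p = p,
        ci_low = ci[1], ci_high = ci[2],
        band = if (is.na(rho)) "undefined" else band_for_p(p),
        flag = attr(rho, "flag") %||% "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("plk_links", "data.frame")
  out
}
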