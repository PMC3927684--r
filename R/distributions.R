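#' Frequency distribution of a count table
#'
#' n(f): the number of k-mer types having each copy number f. Conservation
#' identities: `sum(f * n(f)) = total_tokens`, `sum(n(f)) = n_types`.
#'
#' @param table A `kmer_count_table`.
#' @return A `freq_dist` data.frame with columns `f`, `n_f`, ascending in
#'   f, carrying `k` and `total_tokens` attributes.
#' @export
frequency_distribution <- function(table) {
  check_table(table)
  tab <- table(table$count)
  fd <- data.frame(f = as.numeric(names(tab)), n_f = as.numeric(tab))
  fd <- fd[order(fd$f), , drop = FALSE]
  rownames(fd) <- NULL
  structure(fd, k = table$k, total_tokens = table$total_tokens,
            class = c("freq_dist", "data.frame"))
}

#' Rank-frequency (Zipf) distribution of a count table
#'
#' Frequencies sorted descending; the highest f gets rank 1. Ties get
#' distinct consecutive ranks, broken by the lexicographically smallest
#' canonical k-mer, so `max(r)` equals the number of types.
#'
#' @param table A `kmer_count_table`.
#' @return A `rank_freq` data.frame with columns `r`, `f`, `kmer`.
#' @export
rank_frequency <- function(table) {
  check_table(table)
  o <- order(-table$count, table$kmer, method = "radix")
  structure(data.frame(r = seq_along(o), f = table$count[o],
                       kmer = table$kmer[o], stringsAsFactors = FALSE),
            k = table$k, class = c("rank_freq", "data.frame"))
}

new_fit <- function(model, fit, coefficients, fit_range, n_points) {
  res <- stats::residuals(fit)
  y <- stats::fitted(fit) + res
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  structure(list(model = model,
                 coefficients = coefficients,
                 fit_range = fit_range,
                 n_points = n_points,
                 residual_sum_sq = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("loglog_fit [%s]: %s | n = %d, RSS = %.4g, R^2 = %.4f\n",
              x$model,
              paste(sprintf("%s = %.6g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$n_points, x$residual_sum_sq, x$r_squared))
  invisible(x)
}

#' Power-law fit in log-log scale
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`, i.e. the model
#' `log10 y = a + b log10 x`, restricted to `x_range`.
#'
#' @param x,y Positive numeric vectors (same length).
#' @param x_range Optional inclusive `c(lo, hi)` bounds on x.
#' @return A `loglog_fit` with coefficients `a` (intercept) and `b`
#'   (exponent), the fit range, n, RSS and R-squared.
#' @examples
#' fit_powerlaw(c(10, 100), c(100, 1))  # a = 4, b = -2
#' @export
fit_powerlaw <- function(x, y, x_range = NULL) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(x_range)) keep <- keep & x >= x_range[1] & x <= x_range[2]
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 in-range points for a power-law fit")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive x and y")
  fit <- stats::lm(log10(y) ~ log10(x))
  new_fit("powerlaw", fit,
          c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2])),
          range(x), length(x))
}

#' Piecewise power-law fit of a mappability curve
#'
#' The decay of p_ns with k is not a single power law: it is steeper at
#' short k and flattens past ~200 bp. Each requested k segment is fitted
#' independently; the default segments (20-80 and 200-1000) deliberately
#' leave the 80-200 transition unfitted.
#'
#' @param curve Data.frame with columns `k` and `p_ns` (e.g. from
#'   [mappability_curve()]; any second column name is accepted via `y`).
#' @param segments List of inclusive k ranges `c(lo, hi)`.
#' @param y Name of the response column, default `"p_ns"`.
#' @return Named list of `loglog_fit`, one per segment.
#' @export
fit_piecewise <- function(curve,
                          segments = list(c(20, 80), c(200, 1000)),
                          y = "p_ns") {
  stopifnot(is.data.frame(curve), "k" %in% names(curve), y %in% names(curve))
  fits <- lapply(segments, function(seg) {
    n_in <- sum(curve$k >= seg[1] & curve$k <= seg[2] & !is.na(curve[[y]]))
    if (n_in < 2)
      stop(sprintf("segment k = %g-%g contains %d usable point(s); need >= 2",
                   seg[1], seg[2], n_in))
    fit_powerlaw(curve$k, curve[[y]], x_range = seg)
  })
  names(fits) <- vapply(segments, function(s) paste0("k", s[1], "-", s[2]), "")
  fits
}

#' Extrapolate a power-law fit
#'
#' @param fit A `loglog_fit` with model `"powerlaw"`.
#' @param x Positive value(s) to predict at.
#' @return `10^a * x^b`.
#' @examples
#' # the published long-read segment predicts ~0.2% non-singletons at 10 kb
#' f <- list(model = "powerlaw", coefficients = c(a = -0.4371, b = -0.5495))
#' class(f) <- "loglog_fit"
#' extrapolate_powerlaw(f, 10000)
#' @export
extrapolate_powerlaw <- function(fit, x) {
  stopifnot(inherits(fit, "loglog_fit"), fit$model == "powerlaw")
  if (any(x <= 0)) stop("x must be positive")
  10^fit$coefficients[["a"]] * x^fit$coefficients[["b"]]
}

#' Solve a decaying power law for y = 1
#'
#' The k at which an extrapolated decreasing power law (e.g. max f vs k)
#' reaches 1: `x = 10^(-a/b)`.
#'
#' @param fit A `loglog_fit` with negative slope `b`.
#' @return The crossing point x.
#' @export
solve_unit_frequency <- function(fit) {
  stopifnot(inherits(fit, "loglog_fit"))
  a <- fit$coefficients[["a"]]; b <- fit$coefficients[["b"]]
  if (b >= 0) stop("slope b must be negative (no y = 1 crossing)")
  10^(-a / b)
}

#' Log-log slope of a frequency distribution
#'
#' OLS of `log10 n(f)` on `log10 f` over occupied frequencies within
#' `f_range` (no zero bins, no smoothing). The slope steepens with k: the
#' FD tail shortens as k-mers outgrow typical repeat-element lengths, so
#' it is not a universal exponent.
#'
#' @param fd A `freq_dist` (or data.frame with columns `f`, `n_f`).
#' @param f_range Inclusive frequency bounds, e.g. `c(3, 200)`.
#' @return A `loglog_fit`.
#' @export
fit_fd_slope <- function(fd, f_range) {
  stopifnot(is.data.frame(fd), all(c("f", "n_f") %in% names(fd)))
  fit_powerlaw(fd$f, fd$n_f, x_range = f_range)
}

rfd_design <- function(rfd, model) {
  r <- rfd$r; f <- rfd$f
  max_r <- max(r); max_f <- max(f)
  switch(model,
    weibull = list(y = log(f),
                   X = cbind(x1 = log(log((max_r + 1) / r)))),
    quadlog = list(y = log(f),
                   X = cbind(x1 = log(r), x2 = log(r)^2)),
    reverse_beta = list(y = log(r),
                        X = cbind(x1 = log(f), x2 = log(max_f + 1 - f))))
}

#' Fit a rank-frequency distribution
#'
#' Three regression models for concave Zipf curves, all linear after
#' transformation (natural logs):
#' \describe{
#'   \item{weibull}{`log f ~ log(log((max(r)+1)/r))`}
#'   \item{quadlog}{`log f ~ log r + (log r)^2` (quadratic logarithmic)}
#'   \item{reverse_beta}{`log r ~ log f + log(max(f)+1-f)`, the Beta rank
#'     function with the roles of f and r reversed, suited to "Z"-shaped
#'     log-log RFDs}
#' }
#'
#' @param rfd A `rank_freq` (or data.frame with columns `r`, `f`).
#' @param model One of `"weibull"`, `"quadlog"`, `"reverse_beta"`.
#' @return A `loglog_fit` with coefficients `c0` (intercept), `c1`, and
#'   `c2` for the three-coefficient models.
#' @export
fit_rfd <- function(rfd, model = c("weibull", "quadlog", "reverse_beta")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(rfd), all(c("r", "f") %in% names(rfd)))
  d <- rfd_design(rfd, model)
  p <- ncol(d$X) + 1
  if (nrow(rfd) < p)
    stop(sprintf("model '%s' needs >= %d rank-frequency pairs", model, p))
  fit <- stats::lm(d$y ~ d$X)
  co <- stats::coef(fit)
  names(co) <- paste0("c", seq_along(co) - 1)
  out <- new_fit(model, fit, co, range(rfd$r), nrow(rfd))
  out$max_r <- max(rfd$r)
  out$max_f <- max(rfd$f)
  out
}

# predicted log f at the observed ranks; reverse_beta is inverted by
# monotone bisection on f since it regresses log r, not log f
predict_log_f <- function(fit, rfd) {
  r <- rfd$r
  co <- fit$coefficients
  if (fit$model == "weibull") {
    x <- log(log((fit$max_r + 1) / r))
    return(co[["c0"]] + co[["c1"]] * x)
  }
  if (fit$model == "quadlog") {
    return(co[["c0"]] + co[["c1"]] * log(r) + co[["c2"]] * log(r)^2)
  }
  g <- function(f) co[["c0"]] + co[["c1"]] * log(f) +
    co[["c2"]] * log(fit$max_f + 1 - f)
  lo <- 1e-9; hi <- fit$max_f + 1 - 1e-9
  glo <- g(lo); ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo == ghi) return(rep(NA_real_, length(r)))
  decreasing <- glo > ghi   # g should be monotone in f for inversion
  probe <- g(seq(lo, hi, length.out = 65))
  if (any(diff(probe) > 0) && any(diff(probe) < 0)) return(rep(NA_real_, length(r)))
  vapply(log(r), function(target) {
    if ((target - glo) * (target - ghi) > 0) return(NA_real_)
    a <- lo; b <- hi
    for (i in 1:80) {
      mid <- (a + b) / 2
      gm <- g(mid)
      if ((gm > target) == decreasing) a <- mid else b <- mid
    }
    log((a + b) / 2)
  }, numeric(1))
}

#' Compare the three rank-frequency fits
#'
#' Fits all three models and puts them on a common footing: each model's
#' RSS in its own response space, plus the root-mean-square error of
#' predicted vs observed `log f` at the observed ranks (the reverse-Beta
#' prediction is inverted numerically by bisection; inversion failure is
#' reported as NA, not an error). The RMS column is this package's
#' construction for cross-model ranking, not a published statistic.
#'
#' @param rfd A `rank_freq`.
#' @return Data.frame with columns `model`, `rss_own_space`, `rms_log_f`,
#'   plus a `fits` attribute holding the three `loglog_fit` objects.
#' @export
compare_rfd_fits <- function(rfd) {
  models <- c("weibull", "quadlog", "reverse_beta")
  fits <- lapply(models, function(m) fit_rfd(rfd, m))
  names(fits) <- models
  rms <- vapply(fits, function(ft) {
    pred <- predict_log_f(ft, rfd)
    if (all(is.na(pred))) return(NA_real_)
    sqrt(mean((pred - log(rfd$f))^2, na.rm = TRUE))
  }, numeric(1))
  structure(data.frame(model = models,
                       rss_own_space = vapply(fits, `[[`, 0, "residual_sum_sq"),
                       rms_log_f = rms, row.names = NULL),
            fits = fits)
}

#' Serialize a fit (or list of fits) to JSON
#'
#' @param fits A `loglog_fit` or a (possibly named) list of them.
#' @param path Output path.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "loglog_fit")) fits <- list(fits)
  payload <- lapply(fits, function(ft) {
    list(model = ft$model, coefficients = as.list(ft$coefficients),
         fit_range = ft$fit_range, n_points = ft$n_points,
         residual_sum_sq = ft$residual_sum_sq, r_squared = ft$r_squared)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
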