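test_that("frequency distribution is an exact histogram with conservation", {
  t2 <- count_kmers("ACGT", 2)                 # {AC:2, CG:1}
  fd <- frequency_distribution(t2)
  expect_equal(fd$f, c(1, 2))
  expect_equal(fd$n_f, c(1, 1))

  t5 <- count_kmers(strrep("A", 6), 2)         # {AA:5}
  fd5 <- frequency_distribution(t5)
  expect_equal(fd5$f, 5)
  expect_equal(fd5$n_f, 1)

  tab <- count_kmers(fix_small()$pset, 31)
  fdx <- frequency_distribution(tab)
  expect_equal(sum(fdx$f * fdx$n_f), tab$total_tokens)
  expect_equal(sum(fdx$n_f), tab$n_types)
})

test_that("rank-frequency ranks descending with deterministic tie-break", {
  tab <- count_kmers(c("AAA", "ACGT"), 2)      # AA:2, AC:2, CG:1
  rfd <- rank_frequency(tab)
  expect_equal(rfd$r, 1:3)
  expect_equal(rfd$f, c(2, 2, 1))
  expect_equal(rfd$kmer[1], "AA")              # tie at f=2 broken lexically

  # FD/RFD duality: |{r : f_r >= f}| = sum_{f' >= f} n(f')
  set.seed(5)
  for (i in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE, prob = c(5, 1, 1, 3)),
               collapse = "")
    tb <- count_kmers(s, 3)
    fd <- frequency_distribution(tb)
    rf <- rank_frequency(tb)
    for (f in fd$f) {
      expect_equal(sum(rf$f >= f), sum(fd$n_f[fd$f >= f]))
    }
  }
})

test_that("power-law fit recovers exact models and is affine-equivariant", {
  two <- fit_powerlaw(c(10, 100), c(100, 1))
  expect_equal(two$coefficients[["a"]], 4)
  expect_equal(two$coefficients[["b"]], -2)

  x <- seq(2, 500, length.out = 10)
  y <- 0.5 * x^(-1.3)
  ft <- fit_powerlaw(x, y)
  expect_equal(ft$coefficients[["a"]], log10(0.5), tolerance = 1e-12)
  expect_equal(ft$coefficients[["b"]], -1.3, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1)

  # scaling y by c shifts the intercept by log10(c), slope unchanged
  ft2 <- fit_powerlaw(x, 7 * y)
  expect_equal(ft2$coefficients[["a"]] - ft$coefficients[["a"]], log10(7),
               tolerance = 1e-12)
  expect_equal(ft2$coefficients[["b"]], ft$coefficients[["b"]],
               tolerance = 1e-12)

  expect_error(fit_powerlaw(1:10, (1:10)^-1, x_range = c(100, 200)),
               "at least 2")
  expect_error(fit_powerlaw(c(1, 2), c(-1, 2)), "positive")
})

test_that("piecewise fitting works per segment and leaves the gap unfitted", {
  k <- default_k_grid()
  p <- ifelse(k <= 100, 10^1.58366 * k^-1.5478, 10^-0.4371 * k^-0.5495)
  curve <- data.frame(k = k, p_ns = p)
  fits <- fit_piecewise(curve)
  expect_named(fits, c("k20-80", "k200-1000"))
  expect_equal(fits[["k20-80"]]$coefficients[["a"]], 1.58366, tolerance = 1e-10)
  expect_equal(fits[["k20-80"]]$coefficients[["b"]], -1.5478, tolerance = 1e-10)
  expect_equal(fits[["k200-1000"]]$coefficients[["b"]], -0.5495,
               tolerance = 1e-10)

  single <- fit_piecewise(curve, list(c(20, 80)))[[1]]
  direct <- fit_powerlaw(curve$k, curve$p_ns, c(20, 80))
  expect_equal(single$coefficients, direct$coefficients)
  expect_error(fit_piecewise(curve, list(c(1001, 2000))), "k = 1001-2000")
})

test_that("extrapolation and the unit-frequency crossing follow closed forms", {
  id <- structure(list(model = "powerlaw", coefficients = c(a = 0, b = 0)),
                  class = "loglog_fit")
  expect_equal(extrapolate_powerlaw(id, 123), 1)
  expect_error(extrapolate_powerlaw(id, -1), "positive")

  # the published long-read segment: ~0.2% non-singletons at 10 kb reads
  lr <- structure(list(model = "powerlaw",
                       coefficients = c(a = -0.4371, b = -0.5495)),
                  class = "loglog_fit")
  expect_equal(round(100 * extrapolate_powerlaw(lr, 10000), 1), 0.2)

  f1 <- structure(list(model = "powerlaw", coefficients = c(a = 2, b = -1)),
                  class = "loglog_fit")
  expect_equal(solve_unit_frequency(f1), 100)
  f2 <- structure(list(model = "powerlaw", coefficients = c(a = 4, b = -2)),
                  class = "loglog_fit")
  expect_equal(solve_unit_frequency(f2), 100)
  # max-f decay with the printed coefficients crosses f = 1 near k ~ 2700
  f3 <- structure(list(model = "powerlaw",
                       coefficients = c(a = 8.99, b = -2.62)),
                  class = "loglog_fit")
  expect_equal(solve_unit_frequency(f3), 10^(8.99 / 2.62))
  expect_true(abs(solve_unit_frequency(f3) - 2700) < 100)
  bad <- structure(list(model = "powerlaw", coefficients = c(a = 1, b = 0.5)),
                   class = "loglog_fit")
  expect_error(solve_unit_frequency(bad), "negative")
})

test_that("FD slope fit recovers an exact power-law tail", {
  f <- 2:100
  fd <- data.frame(f = f, n_f = 1000 * f^(-2.5))
  ft <- fit_fd_slope(fd, c(2, 100))
  expect_equal(ft$coefficients[["b"]], -2.5, tolerance = 1e-12)
  expect_error(fit_fd_slope(fd[1, ], c(2, 2)), "at least 2")
})

test_that("all three RFD regressions recover generating coefficients", {
  n <- 100
  r <- 1:n
  fw <- exp(3 + 0.8 * log(log((n + 1) / r)))
  wb <- fit_rfd(data.frame(r = r, f = fw), "weibull")
  expect_equal(unname(wb$coefficients), c(3, 0.8), tolerance = 1e-9)

  r2 <- 1:1000
  fq <- exp(5 - 0.6 * log(r2) - 0.1 * log(r2)^2)
  ql <- fit_rfd(data.frame(r = r2, f = fq), "quadlog")
  expect_equal(unname(ql$coefficients), c(5, -0.6, -0.1), tolerance = 1e-9)

  # reverse Beta: construct an admissible descending f sequence and ranks
  # exactly on the model, then check recovery
  f3 <- seq(100, 1, length.out = 60)
  r3 <- exp(2 - 1.2 * log(f3) + 0.5 * log(max(f3) + 1 - f3))
  rb <- fit_rfd(data.frame(r = r3, f = f3), "reverse_beta")
  expect_equal(unname(rb$coefficients), c(2, -1.2, 0.5), tolerance = 1e-6)

  expect_error(fit_rfd(data.frame(r = 1:2, f = c(3, 1)), "quadlog"), ">= 3")
})

test_that("model comparison picks the generating model", {
  r <- 1:300
  f_ql <- exp(6 - 0.5 * log(r) - 0.15 * log(r)^2)
  cmp_ql <- compare_rfd_fits(data.frame(r = r, f = f_ql))
  expect_equal(cmp_ql$model[which.min(cmp_ql$rms_log_f)], "quadlog")

  f_wb <- exp(2 + 0.9 * log(log((max(r) + 1) / r)))
  cmp_wb <- compare_rfd_fits(data.frame(r = r, f = f_wb))
  expect_equal(cmp_wb$model[which.min(cmp_wb$rms_log_f)], "weibull")

  # on a real concave k-mer RFD all three fits exist with finite numbers
  tab <- count_kmers(fix_small()$pset, 31)
  cmp <- compare_rfd_fits(rank_frequency(tab))
  expect_true(all(is.finite(cmp$rss_own_space)))
  fits <- attr(cmp, "fits")
  expect_true(all(vapply(fits, function(ft)
    all(is.finite(ft$coefficients)), TRUE)))
})

test_that("FD tail slope steepens as k grows toward element length", {
  # on the many-family power-law fixture (element lengths 100-1000 bp) the
  # tail regression slope over f = 2-30 becomes more negative with k, up
  # to the k where the occupied tail still supports a fit: the exponent is
  # not a universal parameter
  ps <- fix_fd()$pset
  slopes <- vapply(c(30, 80, 150, 300), function(k) {
    fd <- frequency_distribution(count_kmers(ps, k))
    fit_fd_slope(fd, c(2, 30))$coefficients[["b"]]
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("fit JSON serialization carries model, coefficients and range", {
  ft <- fit_powerlaw(c(10, 20, 40), c(100, 25, 6.25))
  path <- withr::local_tempfile(fileext = ".json")
  write_fits_json(list(seg = ft), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$seg$model, "powerlaw")
  expect_equal(back$seg$coefficients$b, ft$coefficients[["b"]])
  expect_equal(back$seg$n_points, 3)
})
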