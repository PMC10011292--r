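make_rep_data <- function(n_plots, reps, s2pl, s2e, seed = 1) {
  set.seed(seed)
  p <- rnorm(n_plots, sd = sqrt(s2pl))
  tibble::tibble(
    plot_id = rep(sprintf("P%03d", seq_len(n_plots)), each = reps),
    value = rep(p, each = reps) + rnorm(n_plots * reps, sd = sqrt(s2e)),
    trait = "T1", year = 2020L, timepoint = "TP4")
}

test_that("technical repeatability hits its limits and recovers a known truth", {
  d <- make_rep_data(40, 2, 1, 1)
  d$value <- rep(rnorm(40), each = 2)           # identical replicates
  expect_equal(technical_repeatability(d)$repeatability, 1, tolerance = 1e-6)

  d2 <- make_rep_data(60, 3, 0, 1, seed = 2)    # plots all alike, reps noisy
  d2$value <- rnorm(180)
  expect_lt(technical_repeatability(d2)$repeatability, 0.1)

  r <- technical_repeatability(make_rep_data(200, 3, 4, 1, seed = 3))
  expect_equal(r$repeatability, 0.8, tolerance = 0.05)

  d3 <- make_rep_data(10, 1, 1, 1, seed = 4)    # no replicated plots
  expect_error(technical_repeatability(d3), "technical replicates")
})

test_that("within-year partition recovers simulated components and nulls", {
  d <- line_tp_data(nl = 300, s2g = 2, s2gtp = 1, s2e = 1, seed = 31)
  vc <- within_year_partition(d)
  expect_equal(vc$sigma2_g, 2, tolerance = 0.3)
  expect_equal(vc$sigma2_gTP, 1, tolerance = 0.25)
  expect_equal(vc$sigma2_e, 1, tolerance = 0.15)

  # no interaction simulated: interaction estimate collapses
  d0 <- line_tp_data(nl = 200, s2g = 2, s2gtp = 0, s2e = 1, seed = 32)
  vc0 <- within_year_partition(d0)
  expect_lt(vc0$sigma2_gTP, 0.05 * vc0$sigma2_g + 0.05)

  # duplicated timepoint data: TP2 content identical to TP1
  d1 <- line_tp_data(nl = 100, s2gtp = 1, seed = 33)
  half <- d1[d1$timepoint == "TP4", ]
  dup <- half; dup$timepoint <- "TP6"
  vcd <- within_year_partition(dplyr::bind_rows(half, dup))
  expect_lt(vcd$sigma2_gTP, 0.05)

  expect_error(within_year_partition(half), "2 timepoints")
})

test_that("check-based plot error is plain arithmetic with flags", {
  set.seed(41)
  vals <- rnorm(30)
  vals <- (vals - mean(vals)) / stats::sd(vals) * sqrt(1.5)  # variance 1.5
  out <- check_plot_error(vals, assay_error = 0.5, reps = 1)
  expect_equal(out$sigma2_pltE, 1.0, tolerance = 1e-10)
  expect_false(out$negative)

  # noiseless checks: estimate is minus the scaled assay error, flagged
  out2 <- suppressWarnings(check_plot_error(rep(3, 12), assay_error = 0.6,
                                            reps = 2))
  expect_equal(out2$sigma2_pltE, -0.3)
  expect_true(out2$negative)

  expect_error(check_plot_error(rnorm(4), 0.1), "fewer than 5")
})

test_that("plot-error simulation recovers the generating variance", {
  ests <- vapply(1:20, function(s) {
    set.seed(100 + s)
    plt <- rnorm(30, sd = sqrt(0.8))
    d <- tibble::tibble(
      plot_id = rep(sprintf("C%02d", 1:30), each = 3),
      value = rep(plt, each = 3) + rnorm(90, sd = sqrt(0.6)))
    suppressWarnings(check_plot_error(d, assay_error = 0.6)$sigma2_pltE)
  }, 1)
  expect_equal(mean(ests), 0.8, tolerance = 0.2 * 0.8)
})

test_that("after-ripening change variance and ratios follow the decomposition", {
  vc <- tibble::tibble(trait = "FAN", year = 2020, sigma2_g = 2,
                       sigma2_gTP = 1.5, sigma2_e = 1)
  out <- delta_gtp(vc, 0.5)
  expect_equal(out$sigma2_dgTP, 1.0)
  expect_equal(out$ratio1, 0.5 / 1.5)
  expect_equal(out$ratio2, 0.5)
  expect_false(out$negative)

  expect_equal(delta_gtp(vc, 0)$sigma2_dgTP, vc$sigma2_gTP)

  # plot error exceeding the interaction variance: negative, flagged, kept
  out2 <- suppressWarnings(delta_gtp(vc, 2.5))
  expect_equal(out2$sigma2_dgTP, -1)
  expect_true(out2$negative)

  vc0 <- dplyr::mutate(vc, sigma2_gTP = 0)
  expect_true(is.na(suppressWarnings(delta_gtp(vc0, 0.5))$ratio1))
})

test_that("across-year partition handles unbalanced timepoints and recovers truth", {
  set.seed(51)
  nl <- 250; yrs <- c(2019L, 2020L, 2021L)
  g <- rnorm(nl, sd = sqrt(3))
  gt <- rnorm(nl * 2, sd = sqrt(0.5))
  rows <- list()
  for (y in yrs) {
    tps <- if (y == 2019L) "TP6" else c("TP4", "TP6")  # merged late-malt year
    d <- expand.grid(line_id = sprintf("L%04d", 1:nl), timepoint = tps,
                     stringsAsFactors = FALSE)
    li <- as.integer(factor(d$line_id, levels = sprintf("L%04d", 1:nl)))
    ti <- ifelse(d$timepoint == "TP4", 1L, 2L)
    d$value <- 5 + 0.3 * (y - 2019) + 0.4 * ti + g[li] + gt[(li - 1) * 2 + ti] +
      rnorm(nrow(d), sd = sqrt(2))
    d$year <- y; d$trait <- "T1"
    rows[[length(rows) + 1]] <- d
  }
  d <- dplyr::bind_rows(rows)
  vc <- across_year_partition(d)
  expect_true(vc$converged)
  expect_equal(vc$sigma2_g, 3, tolerance = 0.45)
  expect_equal(vc$sigma2_gTP, 0.5, tolerance = 0.25)
  expect_equal(vc$sigma2_e, 2, tolerance = 0.3)

  h <- heritability(vc, y = 3)
  expect_true(h$H2 > 0 && h$H2 < 1)
})

test_that("heritability follows the across-year formula exactly", {
  vc <- tibble::tibble(trait = "X", sigma2_g = 1, sigma2_gTP = 0, sigma2_e = 3,
                       n_years = 3)
  expect_equal(heritability(vc, 3)$H2, 0.5)
  vc2 <- dplyr::mutate(vc, sigma2_g = 2, sigma2_gTP = 1)
  expect_equal(heritability(vc2, 3)$H2, 0.5)
  vc0 <- dplyr::mutate(vc, sigma2_g = 0)
  expect_equal(heritability(vc0, 3)$H2, 0)
  expect_error(heritability(dplyr::mutate(vc, sigma2_g = 0, sigma2_gTP = 0,
                                          sigma2_e = 0), 3), "zero")
  # monotone in sigma2_g and in the number of years
  h_seq <- vapply(c(0.5, 1, 2, 4), function(s)
    heritability(dplyr::mutate(vc, sigma2_g = s), 3)$H2, 1)
  expect_true(all(diff(h_seq) > 0))
  y_seq <- vapply(1:4, function(y) heritability(vc2, y)$H2, 1)
  expect_true(all(diff(y_seq) > 0))
  expect_true(all(c(h_seq, y_seq) >= 0 & c(h_seq, y_seq) <= 1))
})

test_that("partitions are invariant to relabelling lines", {
  d <- line_tp_data(nl = 80, seed = 61)
  v1 <- within_year_partition(d)
  perm <- setNames(sample(sprintf("Q%04d", 1:80)), unique(d$line_id))
  d2 <- dplyr::mutate(d, line_id = perm[line_id],
                      plot_id = paste0(line_id, "_P1"))
  v2 <- within_year_partition(d2)
  expect_equal(v1$sigma2_g, v2$sigma2_g, tolerance = 1e-6)
  expect_equal(v1$sigma2_gTP, v2$sigma2_gTP, tolerance = 1e-6)
})
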