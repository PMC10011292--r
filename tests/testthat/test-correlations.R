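test_that("HvMKK3 alleles are classified from the two diagnostic markers", {
  calls <- tibble::tibble(
    line_id = sprintf("L%d", 1:5),
    e165q = c("MUT", "WT", "WT", "WT", "MISSING"),
    linked50k = c("A", "A", "B", "MISSING", "A"))
  out <- classify_mkk3(calls)
  expect_equal(out$allele, c("Nstar", "N", "D", "UNKNOWN", "UNKNOWN"))
  # the linked-marker mapping is configurable
  flipped <- classify_mkk3(calls, linked_map = c(A = "D", B = "N"))
  expect_equal(flipped$allele[2:3], c("D", "N"))
})

test_that("genetic correlation recovers an analytic construction", {
  # trait B = line effects of A + independent noise; analytic r_g from the
  # construction: cov(uA, uA) / sqrt(s2a * (s2a + s2b_extra))
  ests <- vapply(1:8, function(s) {
    set.seed(300 + s)
    nl <- 250
    uA <- rnorm(nl, sd = 1)
    uB <- uA + rnorm(nl, sd = 1)        # analytic r_g = 1/sqrt(2)
    d <- expand.grid(line_id = sprintf("L%04d", 1:nl), year = c(2020L, 2021L),
                     trait = c("A", "B"), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    li <- as.integer(factor(d$line_id))
    d$value <- ifelse(d$trait == "A", uA[li], uB[li]) +
      rnorm(nrow(d), sd = 0.7)
    d$plot_id <- paste(d$line_id, d$year, sep = "_")
    genetic_correlation(d, "A", "B")$r_g
  }, 1)
  expect_equal(mean(ests), 1 / sqrt(2), tolerance = 0.05)
})

test_that("proportional traits sit at the correlation boundary", {
  set.seed(11)
  nl <- 80
  u <- rnorm(nl)
  d <- expand.grid(line_id = sprintf("L%03d", 1:nl), year = 2020L,
                   trait = c("A", "B"), rep = 1:2, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  li <- as.integer(factor(d$line_id))
  d$value <- ifelse(d$trait == "A", u[li], 2 * u[li]) +
    rnorm(nrow(d), sd = 0.05)
  d$plot_id <- paste(d$line_id, d$rep, sep = "_")
  out <- genetic_correlation(d, "A", "B")
  expect_gt(out$r_g, 0.99)
  expect_true(out$boundary)
})

test_that("r_g is invariant to positive affine rescaling and flips sign with negative", {
  d <- bivariate_data(nl = 150, rg = 0.6, seed = 12)
  base <- genetic_correlation(d, "A", "B")$r_g
  d2 <- dplyr::mutate(d, value = ifelse(trait == "B", 3 * value + 7, value))
  expect_equal(genetic_correlation(d2, "A", "B")$r_g, base, tolerance = 0.02)
  d3 <- dplyr::mutate(d, value = ifelse(trait == "B", -2 * value + 1, value))
  expect_equal(genetic_correlation(d3, "A", "B")$r_g, -base, tolerance = 0.02)
})

test_that("small groups are flagged low_n and a degenerate trait is caught", {
  d <- bivariate_data(nl = 10, rg = 0.5, seed = 13)
  out <- genetic_correlation(d, "A", "B")
  expect_true(out$low_n)
  # zero genetic variance in one trait
  dz <- bivariate_data(nl = 120, rg = 0, s2a = 0, seed = 14)
  rz <- suppressWarnings(genetic_correlation(dz, "A", "B"))
  expect_true(is.na(rz$r_g) || abs(rz$r_g) <= 1)
})

test_that("the scan emits one row per trait x timepoint x group with stars", {
  sim <- simulate_study(small_sim_config(), seed = 3)
  germ <- plot_germination_means(sim$plates)
  germ <- germ[!germ$line_id %in% sim$line_meta$line_id[sim$line_meta$is_check], ]
  malt <- plot_trait_means(
    sim$phenotypes[sim$phenotypes$line_id != sim$config$check_line, ])
  alleles <- classify_mkk3(sim$mkk3_calls)[, c("line_id", "allele")]
  scan <- correlation_scan(malt, germ, alleles = alleles,
                           malt_traits = c("FAN", "BG"),
                           timepoints = c("TP1", "TP4"))
  groups <- c("ALL", setdiff(sort(unique(alleles$allele)), "UNKNOWN"))
  expect_equal(nrow(scan), 2 * 2 * length(groups))
  expect_true(all(c("trait", "timepoint", "group", "r_g", "p", "star") %in%
                    names(scan)))
  all_fan_tp1 <- scan[scan$trait == "FAN" & scan$timepoint == "TP1" &
                        scan$group == "ALL", ]
  expect_gt(all_fan_tp1$r_g, 0.3)   # positive pleiotropy built into the truth
  bg <- scan[scan$trait == "BG" & scan$group == "ALL", ]
  expect_true(all(bg$r_g < 0))
})

test_that("phenotypic correlations match hand-computed Pearson values", {
  blues <- tibble::tibble(
    line_id = rep(sprintf("L%d", 1:5), 3),
    trait = rep(c("X", "Y", "Z"), each = 5),
    estimate = c(1, 2, 3, 4, 5,
                 2, 4, 6, 8, 10,      # identical to X after scaling
                 5, 3, 4, 1, 2))
  cc <- phenotypic_correlation_matrix(blues)
  expect_equal(cc["X", "Y"], 1)
  expect_equal(cc["X", "Z"], stats::cor(c(1:5), c(5, 3, 4, 1, 2)))
  expect_equal(diag(cc), c(X = 1, Y = 1, Z = 1))
  # anti-correlated pair
  blues2 <- tibble::tibble(line_id = rep(sprintf("L%d", 1:4), 2),
                           trait = rep(c("A", "B"), each = 4),
                           estimate = c(1, 2, 3, 4, 4, 3, 2, 1))
  expect_equal(phenotypic_correlation_matrix(blues2)["A", "B"], -1)
  # zero-variance trait excluded with a warning
  blues3 <- dplyr::bind_rows(blues, tibble::tibble(
    line_id = sprintf("L%d", 1:5), trait = "flat", estimate = 7))
  expect_warning(cc3 <- phenotypic_correlation_matrix(blues3), "zero-variance")
  expect_false("flat" %in% colnames(cc3))
})

test_that("biplot decomposition reproduces analytic eigenstructure", {
  id3 <- diag(3); colnames(id3) <- rownames(id3) <- c("a", "b", "c")
  bp <- biplot_decomposition(id3)
  expect_equal(bp$variance_explained, c(1, 1) / 3)

  ones <- matrix(1, 3, 3); dimnames(ones) <- dimnames(id3)
  bp1 <- biplot_decomposition(ones)   # rank one: PC1 explains everything
  expect_equal(bp1$variance_explained[1], 1)

  # constructed matrix with eigenvalues {2.2, 0.6, 0.2}
  set.seed(15)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  M <- Q %*% diag(c(2.2, 0.6, 0.2)) %*% t(Q)
  dimnames(M) <- dimnames(id3)
  bp2 <- biplot_decomposition(M)
  expect_equal(bp2$variance_explained, c(2.2, 0.6) / 3, tolerance = 1e-10)
  # loadings are eigenvectors scaled by sqrt(eigenvalue)
  expect_equal(sum(bp2$loadings$PC1^2), 2.2, tolerance = 1e-10)

  expect_error(biplot_decomposition(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})
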