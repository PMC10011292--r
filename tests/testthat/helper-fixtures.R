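# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced one-way layout: ng groups x r reps, known variance components
one_way_data <- function(ng = 50, r = 4, s2g = 2, s2e = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    g = rep(sprintf("g%03d", seq_len(ng)), each = r),
    y = rep(rnorm(ng, sd = sqrt(s2g)), each = r) + rnorm(ng * r, sd = sqrt(s2e))
  )
}

# ANOVA closed form for the balanced one-way design
one_way_anova <- function(d, r) {
  msw <- sum((d$y - stats::ave(d$y, d$g))^2) / (length(unique(d$g)) * (r - 1))
  msb <- r * stats::var(tapply(d$y, d$g, mean))
  list(s2g = (msb - msw) / r, s2e = msw)
}

# line x timepoint data with known components (model-3 shaped)
line_tp_data <- function(nl = 150, s2g = 2, s2gtp = 1, s2e = 1, reps = 2,
                         tps = c("TP4", "TP6"), seed = 1) {
  set.seed(seed)
  d <- expand.grid(line_id = sprintf("L%04d", seq_len(nl)), timepoint = tps,
                   tech_rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- rnorm(nl, sd = sqrt(s2g))
  gt <- rnorm(nl * length(tps), sd = sqrt(s2gtp))
  li <- as.integer(factor(d$line_id))
  ti <- as.integer(factor(d$timepoint))
  d$value <- 10 + 0.5 * (ti - 1) + g[li] + gt[(li - 1) * length(tps) + ti] +
    rnorm(nrow(d), sd = sqrt(s2e))
  d$plot_id <- paste0(d$line_id, "_P1")
  d$year <- 2020L
  d$trait <- "T1"
  d$location <- "L1"
  d$block <- "B1"
  tibble::as_tibble(d)
}

# stacked two-trait plot-mean data drawn directly from the bivariate model
bivariate_data <- function(nl = 200, rg = 0.5, s2a = 1, s2b = 1,
                           se_a = 1, se_b = 1, years = c(2020L, 2021L),
                           seed = 1) {
  set.seed(seed)
  cv <- rg * sqrt(s2a * s2b)
  u <- if (rg == 0) {
    cbind(rnorm(nl, sd = sqrt(s2a)), rnorm(nl, sd = sqrt(s2b)))
  } else {
    matrix(rnorm(nl * 2), nl) %*% chol(matrix(c(s2a, cv, cv, s2b), 2))
  }
  d <- expand.grid(line_id = sprintf("L%04d", seq_len(nl)), year = years,
                   trait = c("A", "B"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  li <- as.integer(factor(d$line_id))
  ti <- as.integer(factor(d$trait))
  d$value <- 2 * (ti - 1) + 0.3 * (d$year - years[1]) + u[cbind(li, ti)] +
    rnorm(nrow(d), sd = ifelse(ti == 1, se_a, se_b))
  d$plot_id <- paste0(d$line_id, "_", d$year)
  tibble::as_tibble(d)
}

# tiny but well-formed phenotype CSV content
tiny_phenotypes <- function() {
  tibble::tibble(
    plot_id = c("P1", "P1", "P2", "P2"),
    line_id = c("L1", "L1", "L2", "L2"),
    year = 2020L, location = "L1", block = "B1",
    trait = "FAN", timepoint = "TP4", tech_rep = c(1L, 2L, 1L, 2L),
    value = c(200, 204, 190, 194)
  )
}

# small simulated study used by several integration tests
small_sim_config <- function(...) {
  base <- list(
    cycle_sizes = c(C0 = 60L, C1G = 30L, C1P = 30L, C2G = 30L),
    years = c(2020L, 2021L),
    germ_timepoints = c("TP1", "TP4", "TP6"),
    malt_traits = default_malt_traits()[default_malt_traits()$trait %in%
                                          c("FAN", "BG", "MP"), ],
    n_markers = 30L)
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}
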