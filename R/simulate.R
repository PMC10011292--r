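#' Default malting-trait generator parameters
#'
#' One row per malting trait with the generator's trait scale: overall mean,
#' polygenic standard deviation, single-factor loading `lambda` tying the
#' trait's polygenic effect to the germination-rate polygenic factor (so the
#' within-allele genetic correlation with GI equals `lambda`), additive
#' effects of the N and N* dormancy alleles relative to D, after-ripening
#' change sd (`sd_dgTP`), plot-level sampling error sd (`sd_pltE`), assay
#' error sd (`sd_assay`), number of technical replicates and the shift of
#' the late malting timepoint relative to the early one. Values are chosen
#' to be realistic for the assay scales (AA in 20-deg DU, DP in deg-ASBC,
#' FAN and BG in ppm, ME/SP/MP/ST in percent).
#'
#' @return tibble of per-trait generator parameters.
#' @export
default_malt_traits <- function() {
  tibble::tribble(
    ~trait, ~mean, ~sd_poly, ~lambda, ~eff_N, ~eff_Nstar, ~sd_dgTP, ~sd_pltE, ~sd_assay, ~tech_reps, ~tp6_shift,
    "AA",    55,    4,    0.40,   2,    6,   1.0,  2.0,  1.5, 3L,   1.0,
    "DP",   130,   12,    0.10,   2,    4,   3.0,  6.0,  5.0, 3L,   2.0,
    "FAN",  200,   16,    0.50,   8,   25,   4.0,  8.0,  6.0, 3L,   4.0,
    "BG",   160,   40,   -0.35, -15,  -40,  12.0, 20.0, 15.0, 3L, -10.0,
    "ME",   79.5,  0.8,   0.20, 0.2,  0.6,   0.2,  0.4,  0.3, 2L,   0.1,
    "SP",    5.0,  0.45,  0.45, 0.15, 0.5,   0.1,  0.2, 0.15, 2L,  0.05,
    "MP",   12.5,  0.8,   0.15,   0,  0.3,  0.15,  0.3, 0.25, 2L,   0.0,
    "ST",    41,   3.5,   0.40, 1.5,    4,   0.8,  1.5,  1.2, 2L,   0.8
  )
}

#' Simulation configuration
#'
#' Defines the synthetic breeding population and trial design the generator
#' emulates: eight parents (seven families crossed to a common parent),
#' cycles C0 (n = 105), C1G (87), C1P (108), C2G (114), three trial years
#' with germination assayed at up to seven after-ripening timepoints on
#' 30-kernel plates in duplicate, malting at TP4/TP6 with duplicate or
#' triplicate technical replicates, a check cultivar inserted every 15
#' malting samples, a triallelic dormancy locus (D/N/N*) with pleiotropic
#' effects on the malting traits, and index selection heavily weighted
#' toward PHS resistance (low GI at TP1) driving cycles C1P (phenotypic),
#' C1G and C2G (genomic).
#'
#' @param ... overrides of any default listed below.
#' @return an `mg_sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_parents = 8L,
    n_families = 7L,
    cycle_sizes = c(C0 = 105L, C1G = 87L, C1P = 108L, C2G = 114L),
    years = c(2019L, 2020L, 2021L),
    tp_days = timepoint_days(),
    germ_timepoints = names(timepoint_days()),
    germ_reps = 2L,
    n_plated = 30L,
    malt_traits = default_malt_traits(),
    ## dormancy-locus after-ripening curve per allele: GI(t) tends to
    ## asymptote * t / (t + tau); mean germination day 1 + 2 tau_m/(t + tau_m)
    alleles = list(
      D     = list(asymptote = 6.5, tau = 60, tau_m = 40),
      N     = list(asymptote = 9.0, tau = 14, tau_m = 10),
      Nstar = list(asymptote = 9.9, tau = 3,  tau_m = 2)
    ),
    founder_alleles = c(P1 = "N", P2 = "Nstar", P3 = "N", P4 = "D",
                        P5 = "D", P6 = "Nstar", P7 = "N", P8 = "Nstar"),
    gi_poly_sd = 0.8,
    gi_year_effect = c(`2019` = 0.3, `2020` = 0, `2021` = -0.3),
    year_effect_scale = c(`2019` = 0.5, `2020` = 0, `2021` = -0.3),
    ## selection: index = -(w_gi * GI_TP1) - w_protein * MP, highest index kept
    selection = list(w_gi = 1, w_protein = 0.05, phen_error_sd = 0.4,
                     per_family = 2L, c2_top_n = 15L),
    malt_both_tp_frac = 0.55,
    year3_frac = 0.5,
    check_interval = 15L,
    check_line = "CHECK_Tradition",
    parent_reps = 3L,
    n_markers = 120L,
    marker_het = 0.02,
    marker_missing = 0.02
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("sim_config: unknown option(s): ",
                                paste(bad, collapse = ", ")))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && !is.data.frame(cfg[[nm]]) &&
        is.list(over[[nm]]) && !is.data.frame(over[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  stopifnot(all(cfg$cycle_sizes >= 0), cfg$n_plated > 0,
            all(cfg$malt_traits$sd_poly >= 0),
            all(abs(cfg$malt_traits$lambda) <= 1))
  structure(cfg, class = "mg_sim_config")
}

## polygenic covariance between GI factor and malt traits:
## u_GI = f (sd gi_poly_sd); u_trait = sd_poly (lambda f0 + sqrt(1-lambda^2) eps)
## where f0 is the standardised GI factor => cor(GI, trait) = lambda.
draw_polygenic <- function(n, cfg) {
  tr <- cfg$malt_traits
  f0 <- rnorm(n)
  eps <- matrix(rnorm(n * nrow(tr)), n)
  poly <- sweep(sweep(eps, 2, sqrt(1 - tr$lambda^2), `*`) +
                  outer(f0, tr$lambda), 2, tr$sd_poly, `*`)
  colnames(poly) <- tr$trait
  cbind(GI = f0 * cfg$gi_poly_sd, poly)
}

#' Simulate founders and selection cycles
#'
#' Builds the base population and its selected descendants: seven families
#' from crosses of seven founders to a common parent, stratified sampling
#' into C0, then truncation selection on a PHS-weighted index producing C1P
#' (phenotypic index: a noisy GI measurement), C1G (idealised genomic index:
#' the true breeding value) and C2G (second genomic cycle from C1G). Progeny
#' inherit one parental allele at the dormancy locus and a polygenic value
#' equal to the parent average plus a Mendelian-sampling draw at half the
#' polygenic variance.
#'
#' @param cfg an `mg_sim_config`.
#' @param seed integer seed.
#' @return `mg_population`: list with `lines` (line_id, cycle, family,
#'   allele, is_check), `polygenic` (matrix lines x (GI + malt traits)).
#' @export
simulate_founders_and_cycles <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "mg_sim_config"))
  set.seed(seed)
  npar <- cfg$n_parents
  par_ids <- paste0("P", seq_len(npar))
  common <- par_ids[npar]
  par_allele <- cfg$founder_alleles[par_ids]
  stopifnot(!anyNA(par_allele), all(par_allele %in% names(cfg$alleles)))
  par_poly <- draw_polygenic(npar, cfg)
  rownames(par_poly) <- par_ids

  new_id <- local({
    counter <- 0L
    function(prefix, n) {
      ids <- sprintf("%s_%04d", prefix, counter + seq_len(n))
      counter <<- counter + n
      ids
    }
  })

  cross <- function(id_a, id_b, n, prefix, allele_tab, poly_tab) {
    all_a <- allele_tab[id_a]; all_b <- allele_tab[id_b]
    pick <- stats::runif(n) < 0.5
    allele <- ifelse(pick, all_a, all_b)
    mid <- (poly_tab[id_a, , drop = FALSE] + poly_tab[id_b, , drop = FALSE]) / 2
    seg <- draw_polygenic(n, cfg) / sqrt(2)   # half the polygenic variance
    list(ids = new_id(prefix, n), allele = unname(allele), poly = mid + seg)
  }

  ## C0: stratified over the 7 families
  fam_parents <- par_ids[seq_len(cfg$n_families)]
  n_c0 <- cfg$cycle_sizes[["C0"]]
  fam_sizes <- diff(round(seq(0, n_c0, length.out = cfg$n_families + 1)))
  allele_tab <- par_allele
  poly_tab <- par_poly
  lines <- tibble(line_id = par_ids, cycle = "PARENT",
                  family = NA_character_, allele = unname(par_allele))
  c0_fam <- character(0)
  for (i in seq_along(fam_parents)) {
    if (fam_sizes[i] == 0) next
    cr <- cross(rep(fam_parents[i], fam_sizes[i]), rep(common, fam_sizes[i]),
                fam_sizes[i], "C0", allele_tab, poly_tab)
    allele_tab[cr$ids] <- cr$allele
    rownames(cr$poly) <- cr$ids
    poly_tab <- rbind(poly_tab, cr$poly)
    lines <- dplyr::bind_rows(lines, tibble(
      line_id = cr$ids, cycle = "C0", family = paste0("F", i), allele = cr$allele))
    c0_fam <- c(c0_fam, rep(paste0("F", i), fam_sizes[i]))
  }
  c0_ids <- lines$line_id[lines$cycle == "C0"]

  ## selection indices on C0
  gi_tp1 <- function(ids) {
    a <- allele_tab[ids]
    asym <- vapply(cfg$alleles[a], `[[`, 1, "asymptote")
    tau <- vapply(cfg$alleles[a], `[[`, 1, "tau")
    t1 <- cfg$tp_days[[1]]
    pmin(10, pmax(0, (asym + poly_tab[ids, "GI"]) * t1 / (t1 + tau)))
  }
  sel <- cfg$selection
  protein_bv <- function(ids) {
    if ("MP" %in% colnames(poly_tab)) poly_tab[ids, "MP"] else rep(0, length(ids))
  }
  idx_genomic <- function(ids) {
    -sel$w_gi * gi_tp1(ids) - sel$w_protein * protein_bv(ids)
  }
  idx_phenotypic <- function(ids) {
    -sel$w_gi * (gi_tp1(ids) + rnorm(length(ids), sd = sel$phen_error_sd)) -
      sel$w_protein * (protein_bv(ids) + rnorm(length(ids), sd = sel$phen_error_sd))
  }

  select_per_family <- function(ids, fams, index) {
    chosen <- character(0)
    for (f in unique(fams)) {
      in_f <- ids[fams == f]
      k <- min(sel$per_family, length(in_f))
      chosen <- c(chosen, in_f[order(index[match(in_f, ids)],
                                     decreasing = TRUE)][seq_len(k)])
    }
    chosen
  }

  intermate <- function(parents, n, prefix, cycle_label) {
    if (length(parents) < 2 || n == 0) return(invisible(NULL))
    pa <- sample(parents, n, replace = TRUE)
    pb <- vapply(pa, function(p) sample(setdiff(parents, p), 1), "")
    cr <- cross(pa, pb, n, prefix, allele_tab, poly_tab)
    allele_tab[cr$ids] <<- cr$allele
    rownames(cr$poly) <- cr$ids
    poly_tab <<- rbind(poly_tab, cr$poly)
    lines <<- dplyr::bind_rows(lines, tibble(
      line_id = cr$ids, cycle = cycle_label, family = NA_character_,
      allele = cr$allele))
    cr$ids
  }

  if (cfg$cycle_sizes[["C1P"]] > 0) {
    sel_p <- select_per_family(c0_ids, c0_fam, idx_phenotypic(c0_ids))
    intermate(sel_p, cfg$cycle_sizes[["C1P"]], "C1P", "C1P")
  }
  c1g_ids <- NULL
  if (cfg$cycle_sizes[["C1G"]] > 0) {
    sel_g <- select_per_family(c0_ids, c0_fam, idx_genomic(c0_ids))
    c1g_ids <- intermate(sel_g, cfg$cycle_sizes[["C1G"]], "C1G", "C1G")
  }
  if (cfg$cycle_sizes[["C2G"]] > 0 && length(c1g_ids)) {
    idx <- idx_genomic(c1g_ids)
    top <- c1g_ids[order(idx, decreasing = TRUE)][
      seq_len(min(sel$c2_top_n, length(c1g_ids)))]
    intermate(top, cfg$cycle_sizes[["C2G"]], "C2G", "C2G")
  }

  lines$is_check <- FALSE
  structure(list(lines = lines, polygenic = poly_tab[lines$line_id, , drop = FALSE],
                 config = cfg, seed = seed),
            class = "mg_population")
}

## deterministic latent germination state for a set of lines at day t
latent_germination <- function(pop, ids, t, year_eff = 0) {
  cfg <- pop$config
  a <- setNames(pop$lines$allele, pop$lines$line_id)[ids]
  asym <- vapply(cfg$alleles[a], `[[`, 1, "asymptote")
  tau <- vapply(cfg$alleles[a], `[[`, 1, "tau")
  tau_m <- vapply(cfg$alleles[a], `[[`, 1, "tau_m")
  u <- pop$polygenic[ids, "GI"]
  g <- pmin(10, pmax(0, asym * t / (t + tau) + u + year_eff))
  mday <- 1 + 2 * tau_m / (t + tau_m)
  pi <- pmin(1, pmax(0, g * mday / 10))
  list(gi = g, mday = mday, pi = pi)
}

## sample plate counts so the Eq.-1 statistic's expectation tracks latent GI
sample_plate <- function(n, pi, mday, n_plated) {
  k <- rbinom(n, n_plated, pi)
  ## mean germination day in [1,3] as a two-point mixture
  p1 <- pmax(0, 2 - mday); p3 <- pmax(0, mday - 2)
  p2 <- 1 - p1 - p3
  counts <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    if (k[i] > 0) {
      counts[i, ] <- as.integer(stats::rmultinom(1, k[i], c(p1[i], p2[i], p3[i])))
    }
  }
  counts
}

#' Simulate field trials, germination plates and malting assays
#'
#' Produces the full synthetic data set for a population: duplicate
#' 30-kernel germination plates per plot at each after-ripening timepoint
#' (kernel germination days drawn so the plate GI statistic is centred on
#' the latent after-ripening curve), malting-quality technical replicates
#' per plot at the design's malting timepoints (with the early/late subset
#' structure and the uncontrolled late-malted year labelled TP6), check
#' plots from a single fixed lot inserted every `check_interval` malting
#' samples, unlinked QC markers and the two diagnostic dormancy-locus
#' markers, and a ground-truth object recording every latent value.
#'
#' @param pop `mg_population` from [simulate_founders_and_cycles()].
#' @param seed integer seed (independent of the population seed).
#' @return `mg_sim` list: `phenotypes` (malting, phenotype schema), `plates`
#'   (germination counts), `line_meta`, `markers`, `mkk3_calls`, `truth`.
#' @export
simulate_trials <- function(pop, seed = 1) {
  stopifnot(inherits(pop, "mg_population"))
  cfg <- pop$config
  set.seed(seed + 1000003L)
  lines <- pop$lines
  tr <- cfg$malt_traits
  years <- cfg$years
  n_lines <- nrow(lines)

  ## which lines are grown each year (a later year may grow only a fraction)
  grown <- lapply(seq_along(years), function(iy) {
    if (iy == length(years) && length(years) >= 3 && cfg$year3_frac < 1) {
      keep <- lines |>
        dplyr::group_by(.data$cycle) |>
        dplyr::slice_sample(prop = cfg$year3_frac) |>
        dplyr::ungroup()
      union(keep$line_id, lines$line_id[lines$cycle == "PARENT"])
    } else lines$line_id
  })
  both_tp <- sample(lines$line_id, round(cfg$malt_both_tp_frac * n_lines))

  ## per line x trait x malt TP after-ripening deviation (shared across years)
  malt_tps <- c("TP4", "TP6")
  dg <- array(rnorm(n_lines * nrow(tr) * 2), c(n_lines, nrow(tr), 2))
  dg <- sweep(dg, 2, tr$sd_dgTP, `*`)
  dimnames(dg) <- list(lines$line_id, tr$trait, malt_tps)

  year_eff <- outer(tr$sd_poly, cfg$year_effect_scale[as.character(years)])
  rownames(year_eff) <- tr$trait

  plates_list <- list()
  pheno_list <- list()
  gi_truth_list <- list()

  for (iy in seq_along(years)) {
    yr <- years[iy]
    ids <- intersect(lines$line_id, grown[[iy]])
    ## one plot per line, parents replicated
    meta <- lines[match(ids, lines$line_id), ]
    reps <- ifelse(meta$cycle == "PARENT", cfg$parent_reps, 1L)
    plot_lines <- rep(ids, reps)
    n_plots <- length(plot_lines)
    plot_ids <- sprintf("Y%d_P%04d", yr, seq_len(n_plots))
    block <- paste0("B", ((seq_len(n_plots) - 1) %/% 25) + 1)

    ## germination plates
    gy <- cfg$gi_year_effect[as.character(yr)] %||% 0
    for (tp in cfg$germ_timepoints) {
      t_days <- cfg$tp_days[[tp]]
      lat <- latent_germination(pop, plot_lines, t_days, gy)
      for (r in seq_len(cfg$germ_reps)) {
        cnt <- sample_plate(n_plots, lat$pi, lat$mday, cfg$n_plated)
        plates_list[[length(plates_list) + 1]] <- tibble(
          plot_id = plot_ids, line_id = plot_lines, year = yr,
          timepoint = tp, rep = r,
          n24 = cnt[, 1], n48 = cnt[, 2], n72 = cnt[, 3],
          n_plated = cfg$n_plated)
      }
      gi_truth_list[[length(gi_truth_list) + 1]] <- tibble(
        line_id = plot_lines, year = yr, timepoint = tp,
        gi_latent = lat$gi)[!duplicated(plot_lines), ]
    }

    ## malting sample stream: which plot x malt-TP combinations are malted
    first_year <- iy == 1 && length(years) >= 3
    if (first_year) {
      ## uncontrolled late malting, assigned the TP6 label
      sched <- tibble(plot_id = plot_ids, line_id = plot_lines, tp = "TP6")
    } else {
      two <- plot_lines %in% both_tp
      sched <- dplyr::bind_rows(
        tibble(plot_id = plot_ids[two], line_id = plot_lines[two], tp = "TP4"),
        tibble(plot_id = plot_ids, line_id = plot_lines, tp = "TP6"))
    }
    ## insert the check every check_interval samples
    n_s <- nrow(sched)
    n_chk <- n_s %/% cfg$check_interval
    if (n_chk > 0) {
      chk <- tibble(plot_id = sprintf("Y%d_CHK%03d", yr, seq_len(n_chk)),
                    line_id = cfg$check_line,
                    tp = sched$tp[pmin(n_s, seq_len(n_chk) * cfg$check_interval)])
      sched <- dplyr::bind_rows(sched, chk)
    }

    ## malting values per trait x tech rep
    is_chk <- sched$line_id == cfg$check_line
    li <- match(sched$line_id, lines$line_id)     # NA for checks
    for (j in seq_len(nrow(tr))) {
      trait_j <- tr$trait[j]
      ci <- match(trait_j, colnames(pop$polygenic))
      gen <- ifelse(is_chk, 0,
                    pop$polygenic[cbind(pmax(li, 1), ci)] +
                      allele_effect(lines$allele[pmax(li, 1)], tr[j, ]))
      dgv <- ifelse(is_chk, 0, dg[cbind(pmax(li, 1), rep(j, nrow(sched)),
                                        match(sched$tp, malt_tps))])
      mu <- tr$mean[j] + year_eff[trait_j, as.character(yr)] +
        ifelse(sched$tp == "TP6", tr$tp6_shift[j], 0)
      plot_err <- rnorm(nrow(sched), sd = tr$sd_pltE[j])
      latent_plot <- mu + gen + dgv + plot_err
      for (r in seq_len(tr$tech_reps[j])) {
        pheno_list[[length(pheno_list) + 1]] <- tibble(
          plot_id = sched$plot_id, line_id = sched$line_id, year = yr,
          location = "L1",
          block = ifelse(is_chk, "CHK", block[match(sched$plot_id,
                                                    plot_ids)]),
          trait = trait_j, timepoint = sched$tp, tech_rep = r,
          value = latent_plot + rnorm(nrow(sched), sd = tr$sd_assay[j]))
      }
    }
  }

  phenotypes <- dplyr::bind_rows(pheno_list)
  plates <- dplyr::bind_rows(plates_list)

  line_meta <- dplyr::bind_rows(
    lines[, c("line_id", "cycle", "family", "is_check")],
    tibble(line_id = cfg$check_line, cycle = NA_character_,
           family = NA_character_, is_check = TRUE))

  ## unlinked biallelic QC markers + the two diagnostic dormancy markers
  mk <- simulate_markers(lines$line_id, cfg)
  calls <- tibble(
    line_id = lines$line_id,
    e165q = ifelse(lines$allele == "Nstar", "MUT", "WT"),
    linked50k = dplyr::case_when(lines$allele == "N" ~ "A",
                                 lines$allele == "D" ~ "B",
                                 TRUE ~ "A"))

  ## ground truth
  gen_vals <- vapply(seq_len(nrow(tr)), function(j) {
    pop$polygenic[lines$line_id, tr$trait[j]] + allele_effect(lines$allele, tr[j, ])
  }, numeric(n_lines))
  colnames(gen_vals) <- tr$trait
  truth <- list(
    config = cfg,
    lines = dplyr::bind_cols(lines,
                             as_tibble(gen_vals),
                             tibble(u_gi = pop$polygenic[lines$line_id, "GI"])),
    gi_latent = dplyr::bind_rows(gi_truth_list),
    seed = seed
  )

  structure(list(phenotypes = phenotypes, plates = plates,
                 line_meta = line_meta, markers = mk, mkk3_calls = calls,
                 truth = truth, config = cfg),
            class = "mg_sim")
}

allele_effect <- function(allele, trait_row) {
  ifelse(allele == "Nstar", trait_row$eff_Nstar,
         ifelse(allele == "N", trait_row$eff_N, 0))
}

simulate_markers <- function(ids, cfg) {
  n <- length(ids)
  m <- cfg$n_markers
  if (m == 0) return(tibble(line_id = character(0), marker_id = character(0),
                            genotype = character(0)))
  p <- stats::runif(m, 0.1, 0.9)
  geno <- vapply(seq_len(m), function(j) {
    g <- ifelse(stats::runif(n) < p[j], "A", "B")
    r <- stats::runif(n)
    g[r < cfg$marker_het] <- "HET"
    g[r > 1 - cfg$marker_missing] <- "MISSING"
    g
  }, character(n))
  tibble(line_id = rep(ids, m),
         marker_id = rep(sprintf("M%04d", seq_len(m)), each = n),
         genotype = as.vector(geno))
}

#' Ground-truth report for recovery tests
#'
#' Summarises the generator's realised truth as a tidy table: the realised
#' genetic correlation of each malting trait with the latent GI at TP1,
#' across all lines and within each dormancy allele group; realised per-cycle
#' genetic variances per trait; allele frequencies per cycle; and the
#' configured variance components (plot error, after-ripening change, assay
#' error).
#'
#' @param truth the `truth` element of an `mg_sim`.
#' @return tibble with columns `quantity`, `trait`, `group`, `value`.
#' @export
truth_report <- function(truth) {
  cfg <- truth$config
  tr <- cfg$malt_traits
  li <- truth$lines
  tp1 <- cfg$germ_timepoints[1]
  g1 <- truth$gi_latent[truth$gi_latent$timepoint == tp1 &
                          truth$gi_latent$year == cfg$years[
                            min(2, length(cfg$years))], ]
  li2 <- dplyr::inner_join(li, g1[, c("line_id", "gi_latent")], by = "line_id")

  rows <- list()
  groups <- c("ALL", intersect(c("D", "N", "Nstar"), unique(li2$allele)))
  for (gp in groups) {
    sub <- if (gp == "ALL") li2 else li2[li2$allele == gp, ]
    if (nrow(sub) < 3) next
    for (trait_j in tr$trait) {
      rows[[length(rows) + 1]] <- tibble(
        quantity = "rg_gi_tp1", trait = trait_j, group = gp,
        value = suppressWarnings(stats::cor(sub$gi_latent, sub[[trait_j]])))
    }
  }
  for (cyc in unique(li$cycle)) {
    sub <- li[li$cycle == cyc, ]
    if (nrow(sub) < 3) next
    for (trait_j in tr$trait) {
      rows[[length(rows) + 1]] <- tibble(
        quantity = "cycle_genetic_variance", trait = trait_j, group = cyc,
        value = stats::var(sub[[trait_j]]))
    }
    rows[[length(rows) + 1]] <- tibble(
      quantity = "nstar_frequency", trait = NA_character_, group = cyc,
      value = mean(sub$allele == "Nstar"))
  }
  for (j in seq_len(nrow(tr))) {
    rows[[length(rows) + 1]] <- tibble(
      quantity = c("sigma2_pltE", "sigma2_dgTP", "sigma2_assay", "sigma2_poly"),
      trait = tr$trait[j], group = NA_character_,
      value = c(tr$sd_pltE[j]^2, tr$sd_dgTP[j]^2, tr$sd_assay[j]^2,
                tr$sd_poly[j]^2))
  }
  dplyr::bind_rows(rows)
}

#' One-call study simulation
#'
#' Convenience wrapper: [simulate_founders_and_cycles()] then
#' [simulate_trials()] with seeds derived from one master seed.
#'
#' @param cfg an `mg_sim_config`.
#' @param seed master seed.
#' @return `mg_sim`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1) {
  pop <- simulate_founders_and_cycles(cfg, seed = seed)
  simulate_trials(pop, seed = seed)
}
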