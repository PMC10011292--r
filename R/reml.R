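#' Random-effect and residual structure constructors
#'
#' Declarative building blocks for [fit_lmm()]. A random term is defined by a
#' grouping factor (one data column or several, crossed via their interaction)
#' and a covariance structure:
#'
#' * `ranef_iid()` — a single variance shared by all levels,
#'   \eqn{u \sim N(0, \sigma^2 I)}.
#' * `ranef_diag()` — one variance per level of a stratifier `by` (each level of
#'   the grouping factor must belong to exactly one stratum, e.g. lines nested
#'   in selection cycles).
#' * `ranef_us2()` — an unstructured 2x2 covariance over the two levels of
#'   `trait`, crossed with the grouping factor; this is the structure used for
#'   bivariate genetic-correlation models.
#'
#' Residual structures are `resid_iid()` (homogeneous) or `resid_diag(by)`
#' (one residual variance per stratum, e.g. per year or per trait-year cell).
#'
#' @param group character vector of data column names; multiple columns are
#'   crossed into a single grouping factor.
#' @param by single column name defining the variance strata.
#' @param trait single column name of a two-level factor (bivariate stacking).
#' @return An object of class `mg_ranef` or `mg_resid` describing the term.
#' @seealso [fit_lmm()]
#' @export
ranef_iid <- function(group) {
  structure(list(kind = "iid", group = group), class = "mg_ranef")
}

#' @rdname ranef_iid
#' @export
ranef_diag <- function(group, by) {
  structure(list(kind = "diag", group = group, by = by), class = "mg_ranef")
}

#' @rdname ranef_iid
#' @export
ranef_us2 <- function(group, trait) {
  structure(list(kind = "us2", group = group, trait = trait), class = "mg_ranef")
}

#' @rdname ranef_iid
#' @export
resid_iid <- function() structure(list(kind = "iid"), class = "mg_resid")

#' @rdname ranef_iid
#' @export
resid_diag <- function(by) structure(list(kind = "diag", by = by), class = "mg_resid")

term_label <- function(r) {
  lab <- paste(r$group, collapse = ":")
  if (r$kind == "diag") lab <- paste0(lab, "|", r$by)
  if (r$kind == "us2") lab <- paste0(lab, "@", r$trait)
  lab
}

cross_factor <- function(data, cols) {
  stopifnot(all(cols %in% names(data)))
  f <- do.call(interaction, c(unname(as.list(data[cols])), list(drop = TRUE, sep = ":")))
  factor(f)
}

## align the entries of a dsCMatrix onto the nonzero pattern of a template
## dsCMatrix; returns the x-vector of the template with values filled in.
align_to_pattern <- function(mat, tmpl_keys, nnz) {
  mat <- as(as(mat, "symmetricMatrix"), "CsparseMatrix")
  j <- rep(seq_len(ncol(mat)), diff(mat@p))
  keys <- mat@i + 1 + (j - 1) * ncol(mat) * 1.0
  pos <- match(keys, tmpl_keys)
  if (anyNA(pos)) stop("internal: pattern misalignment")
  x <- numeric(nnz)
  x[pos] <- mat@x
  x
}

pattern_keys <- function(mat) {
  j <- rep(seq_len(ncol(mat)), diff(mat@p))
  mat@i + 1 + (j - 1) * ncol(mat) * 1.0
}

#' Fit a Gaussian linear mixed model by REML
#'
#' A direct implementation of restricted maximum likelihood for the model
#' family used throughout multi-environment malting/germination trials:
#' arbitrary fixed factorial terms, independent random terms with IID, per-
#' stratum (diagonal) or unstructured 2x2 covariance, and IID or per-stratum
#' residual variance. The restricted log-likelihood is evaluated through the
#' mixed-model equations with sparse Cholesky factorisation; an overall scale
#' parameter is profiled out analytically and the remaining variance ratios
#' are optimised on the log scale (the 2x2 structure through its Cholesky
#' factor, so the estimate is always positive semi-definite). The optimum is
#' confirmed from multiple deterministic starting points.
#'
#' @param data data frame with one row per observation.
#' @param fixed two-sided formula for the response and fixed effects,
#'   e.g. `value ~ year * timepoint`.
#' @param random list of random terms built with [ranef_iid()],
#'   [ranef_diag()] or [ranef_us2()]; may be empty (pure GLS fit).
#' @param residual residual structure from [resid_iid()] or [resid_diag()].
#' @param starts number of deterministic starting points (default 3).
#' @param control list; `rel_tol` (default 1e-12) and `max_iter` (default 500)
#'   are passed to the optimiser; `extra_starts` may hold additional starting
#'   vectors on the internal ratio scale (used to warm-start a full model
#'   from a nested reduced optimum in likelihood-ratio testing).
#' @return An object of class `mg_lmm` with elements `beta` (named fixed-effect
#'   estimates), `se`, `vcov_beta`, `varcomp` (tibble of variance components),
#'   `loglik_reml`, `converged`, `n_obs`, `n_fixed`, `aliased`, `n_dropped`
#'   (rows removed for missingness) and bookkeeping needed by [lrt()] and
#'   [wald_fixed()].
#' @examples
#' d <- tibble::tibble(
#'   g = rep(sprintf("g%02d", 1:20), each = 4),
#'   y = rep(rnorm(20), each = 4) + rnorm(80)
#' )
#' fit <- fit_lmm(d, y ~ 1, random = list(line = ranef_iid("g")))
#' fit$varcomp
#' @export
fit_lmm <- function(data, fixed, random = list(), residual = resid_iid(),
                    starts = 3, control = list()) {
  ctl <- modifyList(list(rel_tol = 1e-12, max_iter = 500), control)
  data <- as.data.frame(data)
  if (inherits(random, "mg_ranef")) random <- list(random)
  stopifnot(all(vapply(random, inherits, TRUE, "mg_ranef")),
            inherits(residual, "mg_resid"))

  resp <- all.vars(fixed[[2]])
  used <- unique(c(all.vars(fixed),
                   unlist(lapply(random, function(r) c(r$group, r$by, r$trait))),
                   residual$by))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    abort(paste0("fit_lmm: column(s) not in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[used])
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n < 2) abort("fit_lmm: fewer than 2 usable observations")

  y <- as.numeric(data[[resp]])

  ## fixed design, with aliased (rank-deficient) columns dropped and reported
  X <- model.matrix(fixed, data)
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[-keep_cols]
    X <- X[, sort(keep_cols), drop = FALSE]
  }
  p <- ncol(X)

  ## centre the response when an intercept is present: the restricted
  ## likelihood is shift-invariant, and centring makes that exact in floating
  ## point rather than up to optimiser tolerance
  y_shift <- 0
  if ("(Intercept)" %in% colnames(X)) {
    y_shift <- mean(y)
    y <- y - y_shift
  }

  ## random-effect design: one combined sparse Z, block bookkeeping per term
  terms_info <- vector("list", length(random))
  Zs <- vector("list", length(random))
  for (k in seq_along(random)) {
    r <- random[[k]]
    g <- cross_factor(data, r$group)
    if (r$kind %in% c("iid", "diag")) {
      q_k <- nlevels(g)
      Zk <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(g), x = 1,
                                 dims = c(n, q_k))
      if (r$kind == "diag") {
        bys <- factor(data[[r$by]])
        map <- tapply(as.integer(bys), g, function(v) unique(v))
        bad <- vapply(map, length, 1L) != 1L
        if (any(bad)) {
          abort(paste0("ranef_diag: grouping level(s) span multiple '", r$by,
                       "' strata: ", paste(names(map)[bad], collapse = ", ")))
        }
        terms_info[[k]] <- list(kind = "diag", label = term_label(r), q = q_k,
                                stratum = unlist(map),
                                stratum_levels = levels(bys), n_par = nlevels(bys))
      } else {
        terms_info[[k]] <- list(kind = "iid", label = term_label(r), q = q_k,
                                n_par = 1L)
      }
    } else {
      tr <- factor(data[[r$trait]])
      if (nlevels(tr) != 2)
        abort("ranef_us2: the trait stratifier must have exactly 2 levels")
      q_k <- nlevels(g) * 2L
      j <- (as.integer(g) - 1L) * 2L + as.integer(tr)
      Zk <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1, dims = c(n, q_k))
      terms_info[[k]] <- list(kind = "us2", label = term_label(r), q = q_k,
                              n_group = nlevels(g), trait_levels = levels(tr),
                              n_par = 3L)
    }
    Zs[[k]] <- Zk
  }
  q_total <- sum(vapply(terms_info, `[[`, 1L, "q"), 0L)
  if (q_total >= n) {
    abort(paste0("fit_lmm: model not identifiable: ", q_total,
                 " random levels for ", n, " observations (terms: ",
                 paste(vapply(terms_info, `[[`, "", "label"), collapse = ", "),
                 ")"))
  }
  Z <- if (length(Zs)) do.call(cbind, Zs) else NULL
  offs <- c(0L, cumsum(vapply(terms_info, `[[`, 1L, "q")))

  ## residual strata and per-stratum crossproducts; weights enter as scalars so
  ## every weighted crossproduct is a linear combination of precomputed pieces
  if (residual$kind == "iid") {
    rstrat <- factor(rep("all", n))
  } else {
    rstrat <- cross_factor(data, residual$by)
  }
  n_rs <- nlevels(rstrat)
  XtX_m <- matrix(0, p * p, n_rs)
  Xty_m <- matrix(0, p, n_rs)
  yty_v <- numeric(n_rs)
  n_v <- integer(n_rs)
  ZtX_m <- if (!is.null(Z)) matrix(0, q_total * p, n_rs)
  Zty_m <- if (!is.null(Z)) matrix(0, q_total, n_rs)
  ZtZ_list <- vector("list", n_rs)
  for (s in seq_len(n_rs)) {
    rows <- which(as.integer(rstrat) == s)
    Xs <- X[rows, , drop = FALSE]
    ys <- y[rows]
    n_v[s] <- length(rows)
    XtX_m[, s] <- crossprod(Xs)
    Xty_m[, s] <- crossprod(Xs, ys)
    yty_v[s] <- sum(ys^2)
    if (!is.null(Z)) {
      Zsub <- Z[rows, , drop = FALSE]
      ZtZ_list[[s]] <- forceSymmetric(crossprod(Zsub))
      ZtX_m[, s] <- as.matrix(crossprod(Zsub, Xs))
      Zty_m[, s] <- as.numeric(crossprod(Zsub, ys))
    }
  }

  ## parameter packing: per random term, then residual strata 2..S as ratios to
  ## stratum 1, whose scale is profiled out analytically
  n_par_terms <- vapply(terms_info, `[[`, 1L, "n_par")
  par_off <- c(0L, cumsum(n_par_terms))
  n_theta <- sum(n_par_terms) + n_rs - 1L
  n_vpar <- sum(n_par_terms) + n_rs   # reported parameter count (incl. scale)

  ## template sparse pattern for M = Ginv + sum_s w_s Z'Z_s, assembled by
  ## direct slot surgery to avoid repeated sparse arithmetic
  tmpl <- NULL; tmpl_keys <- NULL; nnz <- 0L
  Amat <- NULL; gidx <- vector("list", length(terms_info))
  if (!is.null(Z)) {
    gi <- integer(0); gj <- integer(0)
    for (k in seq_along(terms_info)) {
      ti <- terms_info[[k]]
      o <- offs[k]
      gi <- c(gi, o + seq_len(ti$q)); gj <- c(gj, o + seq_len(ti$q))
      if (ti$kind == "us2") {
        base <- o + (seq_len(ti$n_group) - 1L) * 2L
        gi <- c(gi, base + 1L); gj <- c(gj, base + 2L)
      }
    }
    Gpat <- Matrix::sparseMatrix(i = gi, j = gj, x = 1,
                                 dims = c(q_total, q_total), symmetric = TRUE)
    acc <- Gpat
    for (s in seq_len(n_rs)) acc <- acc + ZtZ_list[[s]]
    tmpl <- as(forceSymmetric(acc), "CsparseMatrix")
    tmpl_keys <- pattern_keys(tmpl)
    nnz <- length(tmpl@x)
    Amat <- vapply(seq_len(n_rs), function(s)
      align_to_pattern(ZtZ_list[[s]], tmpl_keys, nnz), numeric(nnz))
    ## positions of G^{-1} entries in the template x slot
    for (k in seq_along(terms_info)) {
      ti <- terms_info[[k]]
      o <- offs[k]
      dkeys <- (o + seq_len(ti$q)) + (o + seq_len(ti$q) - 1) * q_total * 1.0
      dpos <- match(dkeys, tmpl_keys)
      if (ti$kind == "us2") {
        base <- o + (seq_len(ti$n_group) - 1L) * 2L
        okeys <- (base + 1L) + (base + 2L - 1L) * q_total * 1.0
        opos <- match(okeys, tmpl_keys)
        gidx[[k]] <- list(diag = dpos, off = opos)
      } else {
        gidx[[k]] <- list(diag = dpos)
      }
    }
  }

  chol_env <- new.env(parent = emptyenv())
  two_pi <- log(2 * pi)
  np <- n - p

  ## G^{-1} values on the unit-scale parametrisation, plus log|G0|
  ginv_fill <- function(theta, xvec) {
    logdetG <- 0
    for (k in seq_along(terms_info)) {
      ti <- terms_info[[k]]
      th <- theta[(par_off[k] + 1):(par_off[k] + ti$n_par)]
      if (ti$kind == "iid") {
        v <- exp(th)
        xvec[gidx[[k]]$diag] <- xvec[gidx[[k]]$diag] + 1 / v
        logdetG <- logdetG + ti$q * th
      } else if (ti$kind == "diag") {
        v <- exp(th)[ti$stratum]
        xvec[gidx[[k]]$diag] <- xvec[gidx[[k]]$diag] + 1 / v
        logdetG <- logdetG + sum(log(v))
      } else {
        l11 <- exp(th[1]); l22 <- exp(th[2]); l21 <- th[3]
        s11 <- l11^2; s21 <- l11 * l21; s22 <- l21^2 + l22^2
        det_s <- s11 * s22 - s21^2
        inv11 <- s22 / det_s; inv22 <- s11 / det_s; inv21 <- -s21 / det_s
        ng <- ti$n_group
        d <- gidx[[k]]$diag
        xvec[d[seq(1, 2 * ng, 2)]] <- xvec[d[seq(1, 2 * ng, 2)]] + inv11
        xvec[d[seq(2, 2 * ng, 2)]] <- xvec[d[seq(2, 2 * ng, 2)]] + inv22
        xvec[gidx[[k]]$off] <- xvec[gidx[[k]]$off] + inv21
        logdetG <- logdetG + ng * log(det_s)
      }
    }
    list(x = xvec, logdetG = logdetG)
  }

  ## core evaluation at unit scale; returns profiled quantities
  eval_core <- function(theta) {
    rvar <- c(1, exp(theta[seq_len(n_rs - 1) + (n_theta - n_rs + 1)]))
    w <- 1 / rvar
    XtWX <- matrix(XtX_m %*% w, p, p)
    XtWy <- as.numeric(Xty_m %*% w)
    ytWy <- sum(yty_v * w)
    logdetR0 <- sum(n_v * log(rvar))
    if (is.null(Z)) {
      ch <- tryCatch(chol(XtWX), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
      yPy <- ytWy - sum(XtWy * beta)
      return(list(yPy = yPy, logdets = logdetR0 + 2 * sum(log(diag(ch))),
                  beta = beta, chXVX = ch))
    }
    ZtWX <- matrix(ZtX_m %*% w, q_total, p)
    ZtWy <- as.numeric(Zty_m %*% w)
    xs <- as.numeric(Amat %*% w)
    gf <- ginv_fill(theta, xs)
    Mx <- tmpl
    Mx@x <- gf$x
    Ch <- tryCatch({
      if (is.null(chol_env$Ch)) {
        chol_env$Ch <- Cholesky(Mx, LDL = FALSE)
        chol_env$Ch
      } else {
        Matrix::update(chol_env$Ch, Mx)
      }
    }, error = function(e) tryCatch(Cholesky(Mx, LDL = FALSE),
                                    error = function(e2) NULL))
    if (is.null(Ch)) return(NULL)
    logdetM <- 2 * as.numeric(Matrix::determinant(Ch, logarithm = TRUE,
                                                  sqrt = TRUE)$modulus)
    RHS <- cbind(ZtWX, ZtWy)
    S <- as.matrix(Matrix::solve(Ch, RHS, system = "A"))
    Cfull <- crossprod(RHS, S)
    XtVinvX <- XtWX - Cfull[1:p, 1:p, drop = FALSE]
    XtVinvy <- XtWy - Cfull[1:p, p + 1]
    ytVinvy <- ytWy - Cfull[p + 1, p + 1]
    ch <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), XtVinvy))
    yPy <- ytVinvy - sum(XtVinvy * beta)
    list(yPy = yPy,
         logdets = logdetR0 + gf$logdetG + logdetM + 2 * sum(log(diag(ch))),
         beta = beta, chXVX = ch, Ch = Ch, ZtWX = ZtWX, ZtWy = ZtWy)
  }

  objective <- function(theta) {
    core <- eval_core(theta)
    if (is.null(core) || !is.finite(core$yPy)) return(1e10)
    phi <- max(core$yPy / np, 1e-300)
    val <- np * (two_pi + 1 + log(phi)) + core$logdets
    if (!is.finite(val)) return(1e10)
    val
  }

  base_start <- numeric(n_theta)   # all ratios 1; us2 starts balanced
  mults <- c(0, log(25), -log(25), log(400), -log(400))[seq_len(max(1, starts))]
  lower <- rep(-30, n_theta); upper <- rep(30, n_theta)
  ratio_idx <- seq_len(n_theta)
  for (k in seq_along(terms_info)) {
    if (terms_info[[k]]$kind == "us2") {
      i3 <- par_off[k] + 3L
      lower[i3] <- -1e4; upper[i3] <- 1e4
      lower[par_off[k] + 1:2] <- -15; upper[par_off[k] + 1:2] <- 15
      ratio_idx <- setdiff(ratio_idx, i3)
    }
  }
  res_idx <- if (n_rs > 1) (n_theta - n_rs + 2):n_theta else integer(0)
  ratio_idx <- setdiff(ratio_idx, res_idx)  # residual ratios always start at 1
  us2_sd_idx <- unlist(lapply(seq_along(terms_info), function(k)
    if (terms_info[[k]]$kind == "us2") par_off[k] + 1:2))
  plain_idx <- setdiff(ratio_idx, us2_sd_idx)

  start_list <- lapply(mults, function(m) {
    st <- base_start
    st[plain_idx] <- st[plain_idx] + m          # log-variance ratios
    if (length(us2_sd_idx)) st[us2_sd_idx] <- st[us2_sd_idx] + m / 2
    st
  })
  ## warm starts, e.g. a nested reduced-model optimum when testing a
  ## covariance: guarantees the full fit is never under-optimised in an LRT
  for (es in ctl$extra_starts %||% list()) {
    if (length(es) == n_theta) start_list <- c(start_list, list(es))
  }
  if (n_theta == 0) {   # no free ratio parameters: profiled scale only
    val <- objective(numeric(0))
    best <- list(par = numeric(0), objective = val, convergence = 0L)
    opt_ok <- is.finite(val) && val < 1e9
    start_list <- list()
  } else {
    best <- NULL
    opt_ok <- FALSE
  }
  for (st in start_list) {
    st <- pmin(pmax(st, lower), upper)
    op <- tryCatch(
      nlminb(st, objective, lower = lower, upper = upper,
             control = list(rel.tol = ctl$rel_tol, iter.max = ctl$max_iter,
                            eval.max = 4L * ctl$max_iter)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$objective < best$objective - 1e-10) best <- op
    ## PORT reports several distinct convergence states; only hitting the
    ## iteration/evaluation limit counts as a failed optimisation
    if (op$convergence == 0 ||
        !grepl("iteration limit|evaluation limit", op$message %||% "")) {
      opt_ok <- TRUE
    }
  }
  if (is.null(best)) abort("fit_lmm: optimisation failed from every start")
  theta <- best$par
  converged <- opt_ok && is.finite(best$objective) && best$objective < 1e9

  ## final pass at the optimum
  core <- eval_core(theta)
  if (is.null(core)) abort("fit_lmm: singular system at the reported optimum")
  phi <- max(core$yPy / np, 1e-300)
  beta <- as.numeric(core$beta)
  names(beta) <- colnames(X)
  vcov_beta <- phi * chol2inv(core$chXVX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vcov_beta), 0))
  u_hat <- NULL
  if (!is.null(Z)) {
    ZtWres <- core$ZtWy - core$ZtWX %*% beta
    u_hat <- as.numeric(Matrix::solve(core$Ch, ZtWres, system = "A"))
  }
  if (y_shift != 0) beta["(Intercept)"] <- beta["(Intercept)"] + y_shift

  ## variance components on the original scale (ratios times profiled phi)
  vc_rows <- list()
  for (k in seq_along(terms_info)) {
    ti <- terms_info[[k]]
    th <- theta[(par_off[k] + 1):(par_off[k] + ti$n_par)]
    if (ti$kind == "iid") {
      vc_rows[[length(vc_rows) + 1]] <-
        tibble(term = ti$label, type = "variance", level = NA_character_,
               estimate = phi * exp(th))
    } else if (ti$kind == "diag") {
      vc_rows[[length(vc_rows) + 1]] <-
        tibble(term = ti$label, type = "variance", level = ti$stratum_levels,
               estimate = phi * exp(th))
    } else {
      l11 <- exp(th[1]); l22 <- exp(th[2]); l21 <- th[3]
      s11 <- l11^2; s21 <- l11 * l21; s22 <- l21^2 + l22^2
      corr <- s21 / sqrt(s11 * s22)
      vc_rows[[length(vc_rows) + 1]] <-
        tibble(term = ti$label,
               type = c("variance", "variance", "covariance", "correlation"),
               level = c(ti$trait_levels, "cov", "cor"),
               estimate = c(phi * s11, phi * s22, phi * s21, corr))
    }
  }
  rvar <- phi * c(1, exp(theta[seq_len(n_rs - 1) + (n_theta - n_rs + 1)]))
  vc_rows[[length(vc_rows) + 1]] <-
    tibble(term = ".residual", type = "variance",
           level = if (n_rs == 1) NA_character_ else levels(rstrat),
           estimate = rvar)
  varcomp <- dplyr::bind_rows(vc_rows)

  loglik <- -0.5 * best$objective
  structure(list(
    beta = beta, se = se, vcov_beta = vcov_beta, varcomp = varcomp,
    loglik_reml = loglik, deviance = best$objective,
    converged = converged, n_obs = n, n_fixed = p,
    aliased = aliased, n_dropped = n_dropped,
    fixed_formula = fixed, fixed_labels = colnames(X),
    theta = theta, phi = phi, u_hat = u_hat, terms_info = terms_info,
    residual_levels = levels(rstrat), n_par = n_vpar
  ), class = "mg_lmm")
}

#' @export
print.mg_lmm <- function(x, ...) {
  cat("Linear mixed model fit by REML\n")
  cat("  log-restricted-likelihood:", format(x$loglik_reml, digits = 8),
      if (!x$converged) " (NOT CONVERGED)" else "", "\n")
  cat("  n =", x$n_obs, " fixed rank =", x$n_fixed, "\n")
  cat("Variance components:\n")
  print(as.data.frame(x$varcomp), row.names = FALSE)
  invisible(x)
}

#' Extract a variance component from a fitted model
#'
#' @param fit an `mg_lmm` object.
#' @param term term label as shown in `fit$varcomp`.
#' @param level optional stratum / trait level.
#' @return numeric estimate (vector if several strata match).
#' @export
get_varcomp <- function(fit, term, level = NULL) {
  vc <- fit$varcomp
  rows <- vc$term == term
  if (!is.null(level)) rows <- rows & !is.na(vc$level) & vc$level == level
  out <- vc$estimate[rows]
  if (!length(out)) abort(paste0("no variance component '", term, "'",
                                 if (!is.null(level)) paste0(" level '", level, "'")))
  out
}

#' Likelihood-ratio test between two nested REML fits
#'
#' Valid only when both models share the same fixed-effects structure and data
#' (REML likelihoods are not comparable otherwise); this is enforced. The
#' statistic is clipped at zero and referred to a chi-square distribution.
#' For tests of a covariance parameter whose null value is interior (e.g. a
#' genetic correlation of zero) the nominal df = 1 chi-square applies; for
#' variance-homogeneity tests the chi-square is an approximation near the
#' boundary.
#'
#' @param full,reduced `mg_lmm` fits, reduced nested in full.
#' @param df degrees of freedom; defaults to the difference in the number of
#'   (co)variance parameters.
#' @return tibble with `stat`, `df`, `p`.
#' @export
lrt <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "mg_lmm"), inherits(reduced, "mg_lmm"))
  if (full$n_obs != reduced$n_obs ||
      !identical(full$fixed_labels, reduced$fixed_labels)) {
    abort(paste0("lrt: fits are not REML-comparable (fixed-effects structure ",
                 "or data differ)"))
  }
  if (is.null(df)) df <- full$n_par - reduced$n_par
  if (df <= 0) abort("lrt: reduced model is not nested in full (df <= 0)")
  stat <- max(0, 2 * (full$loglik_reml - reduced$loglik_reml))
  tibble(stat = stat, df = df, p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Wald tests for fixed effects
#'
#' Reports t = estimate / se per fixed-effect coefficient with approximate
#' degrees of freedom: `"residual"` uses n - rank(X); `"containment"`
#' additionally subtracts the number of random-effect levels (floored at 1).
#' Both are approximations to exact small-sample df; in this package's
#' simulation studies effect sizes are chosen so the df choice is immaterial.
#' Aliased (rank-deficient) coefficients are reported with `aliased = TRUE`
#' and no test.
#'
#' @param fit converged `mg_lmm` fit.
#' @param df_method `"residual"` (default) or `"containment"`.
#' @return tibble with columns effect, estimate, se, t, df, p, aliased.
#' @export
wald_fixed <- function(fit, df_method = c("residual", "containment")) {
  stopifnot(inherits(fit, "mg_lmm"))
  df_method <- match.arg(df_method)
  if (!fit$converged) warn("wald_fixed: fit did not converge; tests are unreliable")
  q_total <- sum(vapply(fit$terms_info, `[[`, 1L, "q"), 0L)
  df <- switch(df_method,
               residual = fit$n_obs - fit$n_fixed,
               containment = max(1, fit$n_obs - fit$n_fixed - q_total))
  est <- fit$beta
  se <- fit$se
  tstat <- est / se
  out <- tibble(
    effect = names(est), estimate = unname(est), se = unname(se),
    t = unname(tstat), df = df,
    p = 2 * pt(-abs(unname(tstat)), df = df),
    aliased = FALSE
  )
  if (length(fit$aliased)) {
    out <- dplyr::bind_rows(out, tibble(
      effect = fit$aliased, estimate = NA_real_, se = NA_real_,
      t = NA_real_, df = df, p = NA_real_, aliased = TRUE))
  }
  out
}
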