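#' Normalise trial values to the PS-12 level
#'
#' Every PS-trial contains the 12 cmH2O level, so per-trial values
#' (median ETPdi, median TV, RR) are expressed relative to their own value
#' at PS 12. The normalised value at PS 12 is exactly 1 and the operation
#' is idempotent. Trials without a PS-12 row are excluded and recorded in
#' the \code{excluded_trials} attribute.
#'
#' @param df long data.frame with columns \code{ps_level}, the trial
#'   identifier columns, and the value columns.
#' @param value_cols character vector of columns to normalise.
#' @param trial_cols columns identifying one PS-trial (default
#'   \code{c("patient", "trial")}).
#' @return the data.frame with each value column divided by its trial's
#'   PS-12 value; excluded trials (if any) listed in attribute
#'   \code{excluded_trials}.
#' @export
normalize_to_ps12 <- function(df, value_cols,
                              trial_cols = c("patient", "trial")) {
  stopifnot(all(c("ps_level", trial_cols, value_cols) %in% names(df)))
  key <- interaction(df[trial_cols], drop = TRUE)
  excluded <- character(0)
  parts <- lapply(split(df, key), function(g) {
    at12 <- g[g$ps_level == 12, , drop = FALSE]
    if (nrow(at12) != 1L) {
      id <- paste(vapply(trial_cols, function(cc) as.character(g[[cc]][1]),
                         character(1)), collapse = ".")
      excluded <<- c(excluded, id)
      return(NULL)
    }
    for (v in value_cols) {
      ref <- at12[[v]]
      if (!is.finite(ref) || ref == 0)
        stop("non-positive PS-12 reference for ", v, call. = FALSE)
      g[[v]] <- g[[v]] / ref
    }
    g
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    stop("no trial contains a PS-12 level", call. = FALSE)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "excluded_trials") <- unique(excluded)
  out
}

#' Within/total sum-of-squares decomposition
#'
#' Decomposes the total variation of a set of values into within-group
#' (within PS-trial) and between-group components:
#' SSw = sum over groups of squared deviations from the group mean,
#' SStot = squared deviations from the grand mean, SSw + SSb = SStot.
#' The ratio SSw/SStot quantifies how much of the total variation lives
#' inside trials; it is small for absolute neuro-ventilatory parameters
#' (dominated by between-patient scale) and rises after PS-12
#' normalisation.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length (one PS-trial each).
#' @return list: \code{ssw}, \code{ssb}, \code{sstot},
#'   \code{ssw_pct} (100 x SSw/SStot; NA with a flag if SStot = 0).
#' @export
variance_decomposition <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) >= 2L)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("at least 2 groups required", call. = FALSE)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[groups])^2)
  sstot <- sum((values - grand)^2)
  ssb <- sstot - ssw
  ssw_pct <- if (sstot > 0) 100 * ssw / sstot else NA_real_
  list(ssw = ssw, ssb = ssb, sstot = sstot, ssw_pct = ssw_pct,
       degenerate = sstot == 0)
}

#' Gaussian marginal regression with exchangeable working correlation
#'
#' Generalised-estimating-equation fit for clustered (repeated-measures)
#' data with identity link: iteratively reweighted least squares under an
#' exchangeable working correlation, with robust (sandwich) standard
#' errors that are valid even if the working correlation is wrong. With a
#' single cluster the fit falls back to ordinary least squares with
#' classical errors (and a warning), since a sandwich over one cluster is
#' meaningless.
#'
#' @param y response vector.
#' @param x covariate vector (a single regressor plus intercept).
#' @param cluster cluster identifier (e.g. patient).
#' @param max_iter,tol convergence controls.
#' @return list: \code{coef} (intercept, slope), \code{se} (robust),
#'   \code{ci} (95 percent, slope), \code{p} (slope, Wald z), \code{rho}
#'   (working correlation), \code{n_clusters}, \code{converged}.
#' @export
fit_gee <- function(y, x, cluster, max_iter = 50, tol = 1e-10) {
  stopifnot(length(y) == length(x), length(y) == length(cluster))
  cluster <- as.factor(cluster)
  X <- cbind(`(Intercept)` = 1, x = x)
  p <- ncol(X)
  n <- length(y)
  if (nlevels(droplevels(cluster)) < 2L) {
    warning("single cluster: falling back to ordinary least squares")
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    ci <- sm["x", 1] + c(-1, 1) * stats::qt(0.975, fit$df.residual) *
      sm["x", 2]
    return(list(coef = stats::coef(fit), se = sm[, 2], ci = ci,
                p = sm["x", 4], rho = NA_real_, n_clusters = 1L,
                converged = TRUE))
  }
  idx <- split(seq_len(n), cluster)
  beta <- stats::coef(stats::lm.fit(X, y))
  converged <- FALSE
  rho <- 0
  for (it in seq_len(max_iter)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (n - p)
    num <- 0; den <- 0
    for (ii in idx) {
      ei <- e[ii]
      ni <- length(ei)
      if (ni > 1L) {
        num <- num + (sum(ei)^2 - sum(ei^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    rho <- if (den > p) num / (phi * (den - p)) else 0
    rho <- max(min(rho, 0.99), -0.99)
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      yi <- y[ii]
      ni <- length(ii)
      # V^{-1} for phi * ((1-rho) I + rho J), Sherman-Morrison closed form
      a1 <- 1 / (phi * (1 - rho))
      a2 <- -rho / (phi * (1 - rho) * (1 + (ni - 1) * rho))
      XtVi <- a1 * t(Xi) + a2 * outer(colSums(Xi), rep(1, ni))
      A <- A + XtVi %*% Xi
      b <- b + XtVi %*% yi
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  # robust sandwich covariance
  e <- y - X %*% beta
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    ei <- e[ii]
    ni <- length(ii)
    a1 <- 1 / (phi * (1 - rho))
    a2 <- -rho / (phi * (1 - rho) * (1 + (ni - 1) * rho))
    XtVi <- a1 * t(Xi) + a2 * outer(colSums(Xi), rep(1, ni))
    A <- A + XtVi %*% Xi
    u <- XtVi %*% ei
    B <- B + u %*% t(u)
  }
  Ainv <- solve(A)
  G <- length(idx)
  # small-sample correction: G/(G-1) variance inflation, t reference with
  # G - p degrees of freedom (plain sandwich CIs undercover for few
  # clusters)
  V <- Ainv %*% B %*% Ainv * G / (G - 1)
  se <- sqrt(diag(V))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  dfree <- max(G - p, 1)
  tval <- beta[2] / se[2]
  ci <- beta[2] + c(-1, 1) * stats::qt(0.975, dfree) * se[2]
  list(coef = beta, se = se, ci = ci,
       p = 2 * stats::pt(-abs(tval), dfree), rho = rho,
       n_clusters = G, converged = converged)
}

#' Pressure-support response slopes of the normalised outcomes
#'
#' Fits, per outcome, the marginal linear model of 100 x normalised value
#' on the PS level centred at 3 cmH2O, clustering on patient with an
#' exchangeable working correlation (\code{\link{fit_gee}}). Slopes are
#' reported in percentage points per cmH2O of PS: under the study's
#' generating structure ETPdi and RR carry negative slopes versus PS
#' (they rise as PS is withdrawn) and TV a positive one.
#'
#' @param df normalised long table with columns \code{patient},
#'   \code{ps_level} and the outcome columns.
#' @param outcomes character vector of normalised outcome columns.
#' @param center PS level the model is centred at, cmH2O (default 3).
#' @return data.frame: \code{outcome}, \code{slope_pp_per_cmH2O},
#'   \code{se}, \code{ci_lo}, \code{ci_hi}, \code{p}, \code{rho},
#'   \code{n_clusters}.
#' @export
fit_ps_slopes <- function(df, outcomes = c("median_etpdi", "median_tv",
                                           "rr"),
                          center = 3) {
  stopifnot(all(c("patient", "ps_level", outcomes) %in% names(df)))
  x <- df$ps_level - center
  out <- lapply(outcomes, function(v) {
    fit <- fit_gee(100 * df[[v]], x, df$patient)
    data.frame(outcome = v, slope_pp_per_cmH2O = unname(fit$coef[2]),
               se = fit$se[2], ci_lo = fit$ci[1], ci_hi = fit$ci[2],
               p = fit$p, rho = fit$rho, n_clusters = fit$n_clusters)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Covariate screen for absolute ETPdi at PS 12
#'
#' Univariate screens of log-transformed ETPdi at the 12 cmH2O level
#' against trial-level covariates: linear regression (R-squared and p) for
#' continuous covariates, Wilcoxon rank-sum p for dichotomous ones,
#' Kruskal-Wallis p for multi-category ones. Continuous covariates
#' significant at \code{alpha} are re-tested in the clustered marginal
#' model (\code{\link{fit_gee}}) when a \code{patient} column is present,
#' to check whether the association survives the interdependence of
#' repeated trials. No multiplicity correction is applied (raw p-values
#' are reported; noted in the output attributes).
#'
#' @param records one row per PS-trial with an \code{etpdi_ps12} column
#'   (> 0) and covariate columns.
#' @param continuous,categorical character vectors of covariate columns.
#' @param alpha significance level for the GEE re-test (default 0.05).
#' @return list: \code{continuous} (covariate, r2_pct, p, gee_p, n),
#'   \code{categorical} (covariate, test, p, n), \code{skipped}.
#' @export
covariate_screen <- function(records, continuous = character(0),
                             categorical = character(0), alpha = 0.05) {
  stopifnot("etpdi_ps12" %in% names(records),
            all(records$etpdi_ps12 > 0))
  y <- log(records$etpdi_ps12)
  skipped <- character(0)
  cont <- lapply(continuous, function(v) {
    x <- records[[v]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 5L || stats::var(x[ok]) == 0) {
      skipped <<- c(skipped, v)
      return(NULL)
    }
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    gee_p <- NA_real_
    if (sm$coefficients[2, 4] < alpha && "patient" %in% names(records)) {
      gee_p <- fit_gee(y[ok], x[ok], records$patient[ok])$p
    }
    data.frame(covariate = v, r2_pct = 100 * sm$r.squared,
               p = sm$coefficients[2, 4], gee_p = gee_p, n = sum(ok))
  })
  cat_res <- lapply(categorical, function(v) {
    g <- droplevels(as.factor(records[[v]]))
    if (nlevels(g) < 2L) {
      skipped <<- c(skipped, v)
      return(NULL)
    }
    if (nlevels(g) == 2L) {
      p <- stats::wilcox.test(y ~ g, exact = FALSE)$p.value
      test <- "wilcoxon"
    } else {
      p <- stats::kruskal.test(y, g)$p.value
      test <- "kruskal-wallis"
    }
    data.frame(covariate = v, test = test, p = p, n = length(y))
  })
  out <- list(
    continuous = do.call(rbind, cont[!vapply(cont, is.null, logical(1))]),
    categorical = do.call(rbind,
                          cat_res[!vapply(cat_res, is.null, logical(1))]),
    skipped = skipped)
  attr(out, "multiplicity_correction") <- "none (raw p-values)"
  out
}

#' Association between ETPdi dispersion and NVC
#'
#' Univariate regression of per-level NVC on the relative dispersion
#' (IQR/median) of the level's ETPdi values. A positive slope means that
#' trials/levels with more breath-to-breath drive variability couple more
#' strongly to tidal volume.
#'
#' @param dispersion numeric vector of IQR/median values.
#' @param nvc numeric vector of NVC values (percent), same length.
#' @return list: \code{r2_pct}, \code{slope}, \code{p}, \code{n}.
#' @export
dispersion_vs_nvc <- function(dispersion, nvc) {
  ok <- is.finite(dispersion) & is.finite(nvc)
  if (sum(ok) < 5L)
    stop("at least 5 (dispersion, NVC) points required", call. = FALSE)
  if (stats::var(dispersion[ok]) == 0)
    stop("zero-variance dispersion: association undefined", call. = FALSE)
  fit <- stats::lm(nvc[ok] ~ dispersion[ok])
  sm <- summary(fit)
  list(r2_pct = 100 * sm$r.squared,
       slope = unname(stats::coef(fit)[2]),
       p = sm$coefficients[2, 4], n = sum(ok))
}

#' Relative dispersion (IQR/median)
#'
#' @param x numeric vector with positive median.
#' @return IQR/median using the shared percentile convention.
#' @export
relative_dispersion <- function(x) {
  m <- stats::median(x)
  if (m <= 0) stop("median must be > 0", call. = FALSE)
  (pctl(x, 75) - pctl(x, 25)) / m
}
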