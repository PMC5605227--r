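# Simultaneous chi-squared fit of the two-parameter linear-response model
# to phase-resetting (PRC), wedge and seasonal-entrainment datasets:
# beta1 and beta2 set the slopes of all curves; each dataset contributes
# one intercept (two for the PRC, one on each side of its breakpoint).

#' Construct an observation set for the global fit
#'
#' @param kind `"prc"`, `"wedge"` or `"seasonal"`.
#' @param response measured peak-time shifts (`prc`, `wedge`) or peak times
#'   (`seasonal`) in hours; one value per averaged condition.
#' @param sem positive standard errors of the responses.
#' @param theta_t clock phase at pulse start (cycles; `prc` and `wedge`).
#' @param delta dark-pulse duration in hours (`prc` and `wedge`).
#' @param tau day length in hours (`seasonal`).
#' @param T_h driving period in hours (`seasonal`).
#' @param side PRC-side labels (`"left"`/`"right"` of the breakpoint; `prc`
#'   only).
#' @param omega_L clock frequency in the light, cycles/hour (`prc`, `wedge`).
#' @return an `observation_set`.
#' @export
observation_set <- function(kind = c("prc", "wedge", "seasonal"),
                            response, sem, theta_t = NULL, delta = NULL,
                            tau = NULL, T_h = NULL, side = NULL,
                            omega_L = NULL) {
  kind <- match.arg(kind)
  n <- length(response)
  if (length(sem) != n || any(sem <= 0)) fail("sem must be positive, one per point")
  need <- function(x, nm) {
    if (is.null(x)) fail("kind '", kind, "' requires ", nm)
    rep_len(x, n)
  }
  if (kind %in% c("prc", "wedge")) {
    theta_t <- need(theta_t, "theta_t")
    delta <- need(delta, "delta")
    omega_L <- need(omega_L, "omega_L")[1]
  }
  if (kind == "prc") {
    side <- need(side, "side")
    if (!all(side %in% c("left", "right"))) fail("side must be left/right")
  }
  if (kind == "seasonal") {
    tau <- need(tau, "tau")
    T_h <- need(T_h, "T_h")
  }
  structure(list(kind = kind, response = response, sem = sem,
                 theta_t = theta_t, delta = delta, tau = tau, T_h = T_h,
                 side = side, omega_L = omega_L),
            class = "observation_set")
}

# flatten observation sets into one design table; group identifies the
# intercept each point uses
flatten_observations <- function(observations) {
  if (inherits(observations, "observation_set"))
    observations <- list(observations)
  rows <- lapply(observations, function(o) {
    grp <- switch(o$kind,
                  prc = paste0("C_prc_", o$side),
                  wedge = "C_wedge",
                  seasonal = "C_entrainment")
    data.frame(kind = o$kind, y = o$response, sem = o$sem,
               theta_t = o$theta_t %||% NA_real_,
               delta = o$delta %||% NA_real_,
               tau = o$tau %||% NA_real_, T_h = o$T_h %||% NA_real_,
               omega_L = if (is.null(o$omega_L)) NA_real_ else o$omega_L,
               group = grp)
  })
  do.call(rbind, rows)
}

# model prediction without the intercept term
beta_base_prediction <- function(tab, beta1, beta2) {
  ifelse(tab$kind == "seasonal",
         tab$tau * (1 - beta1 - beta2) + tab$T_h * beta1,
         tab$theta_t / (tab$omega_L * beta2) +
           tab$delta * (1 + beta1 / beta2))
}

#' Global chi-squared fit of the beta model
#'
#' Minimizes \eqn{\chi^2 = \sum_i ((y_i - y_{fit,i})/\sigma_i)^2} over
#' `beta1`, `beta2` and the per-dataset intercepts. For fixed slopes the
#' intercepts are profiled out in closed form (weighted mean residual per
#' intercept group), leaving a two-dimensional optimization started from
#' multiple random points. 95% confidence intervals come from the local
#' curvature of the chi-squared surface at the optimum.
#'
#' @param observations list of [observation_set()] objects (ideally one
#'   `prc`, one `wedge` and one `seasonal`; subsets are fit with a warning).
#' @param breakpoint PRC breakpoint phase in cycles (metadata, recorded in
#'   the result).
#' @param n_starts number of random starts (default 10).
#' @param seed RNG seed for the starts.
#' @return a `global_fit_result`: list with `beta1`, `beta2`, intercepts
#'   `C_prc_left`, `C_prc_right`, `C_wedge`, `C_entrainment`, `ci` (matrix
#'   of 95% bounds), `chisq`, `chisq_nu`, `dof`, `n`.
#' @export
fit_beta_model <- function(observations, breakpoint = NULL, n_starts = 10,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- flatten_observations(observations)
  kinds <- unique(tab$kind)
  if (!all(c("prc", "wedge", "seasonal") %in% kinds))
    warning("global fit with only: ", paste(kinds, collapse = ", "))
  if ("seasonal" %in% kinds && length(unique(tab$tau[tab$kind == "seasonal"])) < 2)
    fail("rank-deficient design: seasonal data needs at least two day lengths")
  groups <- sort(unique(tab$group))
  w <- 1 / tab$sem^2
  profile_chisq <- function(par) {
    if (abs(par[2]) < 1e-6) return(1e12)
    base <- beta_base_prediction(tab, par[1], par[2])
    r <- tab$y - base
    cs <- 0
    for (g in groups) {
      sel <- tab$group == g
      cg <- sum(w[sel] * r[sel]) / sum(w[sel])
      cs <- cs + sum(w[sel] * (r[sel] - cg)^2)
    }
    cs
  }
  starts <- rbind(c(-1, 1.5),
                  cbind(stats::runif(n_starts - 1, -3, 1),
                        sample(c(-1, 1), n_starts - 1, TRUE) *
                          stats::runif(n_starts - 1, 0.3, 3)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[s, ], profile_chisq, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  beta1 <- best$par[1]; beta2 <- best$par[2]
  base <- beta_base_prediction(tab, beta1, beta2)
  C <- vapply(groups, function(g) {
    sel <- tab$group == g
    sum(w[sel] * (tab$y - base)[sel]) / sum(w[sel])
  }, numeric(1))
  params <- c(beta1 = beta1, beta2 = beta2, C)
  full_chisq <- function(p) {
    base <- beta_base_prediction(tab, p[1], p[2])
    cvec <- p[-(1:2)][match(tab$group, groups)]
    sum(w * (tab$y - base - cvec)^2)
  }
  chisq <- full_chisq(params)
  dof <- nrow(tab) - length(params)
  H <- stats::optimHess(params, full_chisq)
  cov <- tryCatch(2 * solve(H), error = function(e) {
    ev <- eigen(H, symmetric = TRUE)
    dir <- paste(names(params)[which.max(abs(ev$vectors[, length(params)]))])
    fail("rank-deficient design: unconstrained direction along ", dir)
  })
  se <- sqrt(pmax(diag(cov), 0))
  ci <- cbind(lower = params - 1.96 * se, upper = params + 1.96 * se)
  rownames(ci) <- names(params)
  out <- list(beta1 = beta1, beta2 = beta2, ci = ci, chisq = chisq,
              dof = dof,
              chisq_nu = if (dof > 0) chisq / dof else NA_real_,
              n = nrow(tab), breakpoint = breakpoint,
              seasonal_slope = 1 - beta1 - beta2,
              wedge_slope = 1 + beta1 / beta2)
  for (g in groups) out[[g]] <- unname(C[g])
  structure(out, class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("<global_fit_result: beta1=%.3f beta2=%.3f chisq=%.2f (nu=%d, chisq_nu=%.2f)>\n",
              x$beta1, x$beta2, x$chisq, x$dof, x$chisq_nu))
  invisible(x)
}

#' Chi-squared of the beta model against observation sets
#'
#' @param observations list of [observation_set()] objects.
#' @param beta a [beta_model()] carrying slopes and all intercepts.
#' @return list with `chisq`, `dof` (`n - 6`) and `chisq_nu` (`NA` with a
#'   warning when `n <= 6`).
#' @export
chi_squared <- function(observations, beta) {
  tab <- flatten_observations(observations)
  base <- beta_base_prediction(tab, beta$beta1, beta$beta2)
  cvec <- c(C_prc_left = beta$C_prc_left, C_prc_right = beta$C_prc_right,
            C_wedge = beta$C_wedge, C_entrainment = beta$C_entrainment)
  pred <- base + cvec[tab$group]
  chisq <- sum(((tab$y - pred) / tab$sem)^2)
  dof <- nrow(tab) - 6
  if (dof <= 0) {
    warning("reduced chi-squared undefined with N <= 6")
    return(list(chisq = chisq, dof = dof, chisq_nu = NA_real_))
  }
  list(chisq = chisq, dof = dof, chisq_nu = chisq / dof)
}
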