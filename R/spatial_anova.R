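#' Moisture-detrended flux residuals
#'
#' Removes the temporal soil-moisture dependence from observed effluxes:
#' `r(x, t) = f(x, t) - (a + b swc_t + c swc_t^2)` using a fitted
#' [fit_moisture_quadratic()] response and the moisture of each
#' observation's day. What remains is the spatial (and unexplained) part of
#' the variation.
#'
#' @param estimates flux observations (`site_id`, `day_index`, `flux`).
#' @param mr a `moisture_response`.
#' @param env_d daily environment table supplying `swc` per `day_index`.
#' @return `estimates` with columns `swc` and `residual` added.
#' @export
residualize <- function(estimates, mr, env_d) {
  m <- match(estimates$day_index, env_d$day_index)
  if (anyNA(m)) stop("some observation days are missing from env_d",
                     call. = FALSE)
  swc <- env_d$swc[m]
  estimates$swc <- swc
  estimates$residual <- estimates$flux - (mr$a + mr$b * swc + mr$c * swc^2)
  estimates
}

#' Multiway ANOVA of spatial flux variation
#'
#' Sequential (Type I) analysis of variance of moisture-detrended efflux
#' residuals on collar-level covariates: topographic class (Top), log basal
#' area within 5 m (BA), canopy gap fraction (GF), and a one-off spatial soil
#' temperature (Temp), plus all six pairwise interactions, in that fixed
#' order. Continuous covariates are rescaled to unit variance (BA after log
#' transformation), so their coefficients are comparable effect sizes.
#' Because the decomposition is sequential, each term's explained variance
#' share depends on the order; shares plus the residual share sum to 100%.
#'
#' @param residuals observation-level data.frame with `residual` and
#'   `site_id`.
#' @param sites `collar_sites` table with `topo_class`, `basal_area_5m`,
#'   `gap_fraction`, `t_spatial`.
#' @param alpha significance level.
#' @return object of class `anova_table`: data.frame with `term`,
#'   `explained_pct`, `coefficient` (continuous terms only), `F`, `p`,
#'   `significant`; attributes `total_explained_pct` and `n`.
#' @export
anova_decompose <- function(residuals, sites, alpha = 0.05) {
  m <- match(residuals$site_id, sites$site_id)
  if (anyNA(m)) stop("unknown site_id in residuals", call. = FALSE)
  d <- data.frame(
    r = residuals$residual,
    Top = factor(sites$topo_class[m]),
    BA = as.numeric(scale(log(sites$basal_area_5m[m]))),
    GF = as.numeric(scale(sites$gap_fraction[m])),
    Temp = as.numeric(scale(sites$t_spatial[m]))
  )
  fit <- stats::lm(r ~ Top + BA + GF + Temp + Top:BA + Top:GF + Top:Temp +
                     BA:GF + BA:Temp + GF:Temp, data = d)
  if (any(is.na(stats::coef(fit)))) {
    warning("rank-deficient design: ",
            paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
            " aliased")
  }
  av <- stats::anova(fit)
  ss_total <- sum(av[["Sum Sq"]])
  terms <- rownames(av)[rownames(av) != "Residuals"]
  cf <- stats::coef(fit)
  coef_for <- function(term) {
    # single-coefficient continuous terms only (matches how effect sizes
    # are reported for unit-variance covariates)
    if (term %in% names(cf)) unname(cf[term]) else NA_real_
  }
  out <- data.frame(
    term = terms,
    explained_pct = 100 * av[terms, "Sum Sq"] / ss_total,
    coefficient = vapply(terms, coef_for, numeric(1)),
    F = av[terms, "F value"],
    p = av[terms, "Pr(>F)"]
  )
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "total_explained_pct") <- sum(out$explained_pct)
  attr(out, "residual_pct") <- 100 * av["Residuals", "Sum Sq"] / ss_total
  attr(out, "n") <- nrow(d)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("<anova_table> sequential ANOVA of moisture-detrended effluxes (n =",
      attr(x, "n"), ")\n")
  print.data.frame(cbind(x[1:2], coefficient = round(x$coefficient, 3),
                         F = round(x$F, 2), p = signif(x$p, 3)),
                   row.names = FALSE)
  cat(sprintf("  total explained: %.2f%%\n", attr(x, "total_explained_pct")))
  invisible(x)
}
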