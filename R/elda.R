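#' Single-hit potency estimation from a limiting-dilution table
#'
#' Fits the single-hit Poisson model P(well negative | dose d) = exp(-f d)
#' by maximum likelihood: a binomial GLM for the responding wells with
#' complementary log-log link and log-dose offset (slope fixed at 1), whose
#' intercept is log f. The structure-forming-unit frequency f is reported
#' as a potency "1/x" with a Wald (default) or profile-likelihood
#' confidence interval on the log-frequency scale.
#'
#' Tables in which every well responded (or none did) pin the estimate to a
#' boundary; these are flagged as non-estimable rather than returned as
#' silent numbers.
#'
#' @param table a [generate_limiting_dilution()] result or data frame with
#'   columns `dose_cells`, `n_wells`, `n_responding`.
#' @param ci `"wald"` or `"profile"`.
#' @param conf_level confidence level.
#' @return a `potency_estimate`: `frequency` (f), `potency` (x = 1/f, the
#'   "1 in x cells" scale), `log_f`, `se_log_f`, `ci_lower`/`ci_upper` (on
#'   x), `n_total_wells`, `log_lik`, `deviance`, `boundary`
#'   (`"none"`, `"all_responding"` or `"none_responding"`).
#' @examples
#' tab <- generate_limiting_dilution(1 / 3, seed = 2)
#' fit_single_hit(tab)
#' @export
fit_single_hit <- function(table, ci = c("wald", "profile"),
                           conf_level = 0.95) {
  ci <- match.arg(ci)
  table <- validate_ld_table(table)
  out <- list(frequency = NA_real_, potency = NA_real_, log_f = NA_real_,
              se_log_f = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
              n_total_wells = sum(table$n_wells), log_lik = NA_real_,
              deviance = NA_real_, boundary = "none",
              conf_level = conf_level)
  class(out) <- "potency_estimate"
  if (all(table$n_responding == table$n_wells)) {
    out$boundary <- "all_responding"
    warning("all wells responded: frequency is at the upper boundary, ",
            "not estimable")
    return(out)
  }
  if (all(table$n_responding == 0)) {
    out$boundary <- "none_responding"
    warning("no well responded: frequency is at the lower boundary, ",
            "not estimable")
    return(out)
  }
  fit <- glm(cbind(n_responding, n_wells - n_responding) ~ 1 +
               offset(log(dose_cells)),
             family = binomial(link = "cloglog"), data = table)
  lf <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci == "wald") {
    lo <- lf - z * se; hi <- lf + z * se
  } else {
    pr <- suppressMessages(suppressWarnings(
      confint(fit, level = conf_level)))
    lo <- unname(pr[1]); hi <- unname(pr[2])
    if (!all(is.finite(c(lo, hi)))) { lo <- lf - z * se; hi <- lf + z * se }
  }
  out$log_f <- lf
  out$se_log_f <- se
  out$frequency <- min(exp(lf), 1)
  out$potency <- 1 / out$frequency
  out$ci_lower <- 1 / exp(hi)   # larger f -> smaller x
  out$ci_upper <- 1 / exp(lo)
  out$log_lik <- as.numeric(stats::logLik(fit))
  out$deviance <- fit$deviance
  out
}

#' @export
print.potency_estimate <- function(x, ...) {
  if (x$boundary != "none") {
    cat("potency_estimate: non-estimable (", x$boundary, "), ",
        x$n_total_wells, " wells\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("potency 1/%.2f (%.0f%% CI 1/%.2f-1/%.2f), %d wells\n",
              x$potency, 100 * x$conf_level, x$ci_upper, x$ci_lower,
              x$n_total_wells))
  invisible(x)
}

#' Single-hit adequacy (slope) test
#'
#' Likelihood-ratio test comparing a complementary log-log regression of
#' well response on log dose with free slope against the single-hit model
#' (slope fixed at 1). Small p-values flag departures from the single-hit
#' assumption (e.g. cooperative, multi-cell origin of structures).
#'
#' @inheritParams fit_single_hit
#' @return list with `p_value`, `slope` (the free estimate), `lrt` and
#'   `df`.
#' @export
slope_test <- function(table) {
  table <- validate_ld_table(table)
  if (length(unique(table$dose_cells)) < 2)
    stop("slope test needs at least 2 distinct doses")
  if (all(table$n_responding == table$n_wells) ||
      all(table$n_responding == 0))
    stop("slope test needs both responding and non-responding wells")
  null_fit <- glm(cbind(n_responding, n_wells - n_responding) ~ 1 +
                    offset(log(dose_cells)),
                  family = binomial(link = "cloglog"), data = table)
  free_fit <- glm(cbind(n_responding, n_wells - n_responding) ~
                    log(dose_cells),
                  family = binomial(link = "cloglog"), data = table)
  lrt <- max(0, null_fit$deviance - free_fit$deviance)
  list(p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
       slope = unname(coef(free_fit)[2]), lrt = lrt, df = 1L)
}
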