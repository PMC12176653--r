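#' Summarize dose-response curves into AUC, GI50 and z-score matrices
#'
#' For every drug x clone viability curve: AUC is the trapezoidal integral
#' of viability over log10 concentration normalized by the log-range (a
#' flat curve at viability 1 gives AUC 1); GI50 is the log-linear
#' interpolated concentration of the 0.5 crossing, censored at the nearest
#' boundary concentration when the curve never crosses; per-drug z-scores
#' of AUC across clones use the population standard deviation (so two
#' clones give -1 and +1).
#'
#' @param curves nested list: `curves[[drug]][[clone]]` is a
#'   [generate_dose_response()] result or a list with `concentrations` and
#'   `viability`.
#' @return a `drug_response_summary`: matrices `auc`, `gi50`,
#'   `gi50_censored` (+1 above range, -1 below, 0 interpolated), `zscore`,
#'   and `skipped` (curves with < 2 finite points).
#' @export
drug_response_summary <- function(curves) {
  drugs <- names(curves)
  if (is.null(drugs)) stop("curves must be a named list (drug -> clone)")
  clones <- unique(unlist(lapply(curves, names)))
  if (is.null(clones)) stop("each drug needs a named list of clones")
  mk <- function() matrix(NA_real_, length(drugs), length(clones),
                          dimnames = list(drugs, clones))
  auc <- mk(); gi50 <- mk(); cens <- mk()
  skipped <- character()
  for (d in drugs) for (cl in names(curves[[d]])) {
    cv <- curves[[d]][[cl]]
    ok <- is.finite(cv$concentrations) & is.finite(cv$viability)
    if (sum(ok) < 2) {
      skipped <- c(skipped, paste(d, cl, sep = "/"))
      next
    }
    lc <- log10(cv$concentrations[ok])
    v <- cv$viability[ok]
    auc[d, cl] <- trapz(lc, v) / diff(range(lc))
    g <- gi50_interpolate(lc, v)
    gi50[d, cl] <- g$gi50
    cens[d, cl] <- g$censored
  }
  z <- t(apply(auc, 1, function(r) {
    if (all(is.na(r))) return(r)
    s <- sqrt(mean((r - mean(r, na.rm = TRUE))^2, na.rm = TRUE))
    if (!is.finite(s) || s == 0) return(r * 0)
    (r - mean(r, na.rm = TRUE)) / s
  }))
  dimnames(z) <- dimnames(auc)
  structure(list(auc = auc, gi50 = gi50, gi50_censored = cens, zscore = z,
                 skipped = skipped), class = "drug_response_summary")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# first downward crossing of 0.5, interpolated in log10 concentration
gi50_interpolate <- function(lc, v) {
  below <- which(v <= 0.5)
  if (!length(below)) return(list(gi50 = 10^max(lc), censored = 1))
  i <- below[1]
  if (i == 1) return(list(gi50 = 10^min(lc), censored = -1))
  f <- (0.5 - v[i - 1]) / (v[i] - v[i - 1])
  list(gi50 = 10^(lc[i - 1] + f * (lc[i] - lc[i - 1])), censored = 0)
}

#' @export
print.drug_response_summary <- function(x, ...) {
  cat("drug_response_summary:", nrow(x$auc), "drug(s) x", ncol(x$auc),
      "clone(s)\n")
  cat("AUC:\n"); print(round(x$auc, 3))
  cat("GI50:\n"); print(signif(x$gi50, 3))
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
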