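#' Fit a Hill dose-response curve
#'
#' Least-squares fit of the Hill equation
#' \deqn{r(C) = r_{max} \frac{C^n}{EC_{50}^n + C^n}}
#' to a tidy dose-response table. Acid tables (doses on the pH scale) are
#' converted to molar proton concentration `C = 10^(-pH)` before fitting, and
#' the fit additionally reports `ph50 = -log10(ec50)`. Optimization uses
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) with the Hill coefficient
#' bounded in `[0.3, 10]`, started at `n = 1`, `r_max = max(response)` and
#' `ec50` at the geometric median dose, with 5 multi-starts jittering
#' `log10(ec50)`; the converged start with the lowest residual sum of squares
#' is reported.
#'
#' @param table A `data.frame` with columns `dose` and `response` (and
#'   optionally `construct`, `stimulus_kind`, `replicate`), as produced by
#'   [simulate_dose_response()] or [read_dose()]. Rows of a single construct
#'   and stimulus kind.
#' @param stimulus_kind `"capsaicin"` (doses in uM) or `"acid"` (doses in pH
#'   units); defaults to the table's `stimulus_kind` column when present.
#' @param n_bounds Bounds for the Hill coefficient.
#' @param n_starts Number of multi-starts over jittered `log10(ec50)`.
#' @return An object of class `hill_fit`: `ec50`, `hill_n`, `r_max`, `rss`,
#'   `se` (named vector), `converged`, `n_obs`, and `ph50` for acid.
#' @examples
#' tab <- simulate_dose_response(1, 2, 100, c(0.1, 0.3, 1, 3, 10))
#' fit_hill(tab)$ec50  # 1
#' @export
fit_hill <- function(table, stimulus_kind = NULL,
                     n_bounds = c(0.3, 10), n_starts = 5) {
  stopifnot(is.data.frame(table), all(c("dose", "response") %in% names(table)))
  if (is.null(stimulus_kind)) {
    stimulus_kind <- if ("stimulus_kind" %in% names(table))
      unique(as.character(table$stimulus_kind)) else "capsaicin"
  }
  if (length(stimulus_kind) != 1)
    .stopf("table mixes stimulus kinds; fit one at a time")
  stimulus_kind <- match.arg(stimulus_kind, c("capsaicin", "acid"))

  conc <- if (stimulus_kind == "acid") 10^(-table$dose) else table$dose
  resp <- table$response
  ok <- is.finite(conc) & is.finite(resp)
  conc <- conc[ok]; resp <- resp[ok]
  if (length(unique(conc)) < 3) .stopf("need >= 3 distinct doses")
  if (any(resp < 0)) .stopf("responses must be non-negative")
  if (diff(range(resp)) == 0) .stopf("degenerate data: all responses equal")

  pos <- conc > 0
  ec50_0 <- exp(median(log(conc[pos])))
  rmax_0 <- max(resp)
  jitter <- 10^seq(-1, 1, length.out = n_starts)

  dat <- data.frame(conc = conc, resp = resp)
  best <- NULL
  for (j in jitter) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ r_max * conc^n / (ec50^n + conc^n), data = dat,
        start = list(r_max = rmax_0, ec50 = ec50_0 * j, n = 1),
        lower = c(r_max = 0, ec50 = .Machine$double.xmin, n = n_bounds[1]),
        upper = c(r_max = Inf, ec50 = Inf, n = n_bounds[2]),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    .stopf("Hill fit failed to converge from any of %d starts", n_starts)

  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    setNames(rep(NA_real_, 3), names(cf)))
  out <- list(ec50 = unname(cf["ec50"]), hill_n = unname(cf["n"]),
              r_max = unname(cf["r_max"]), rss = best$rss, se = se,
              converged = best$fit$convInfo$isConv, n_obs = length(resp),
              stimulus_kind = stimulus_kind)
  if (stimulus_kind == "acid") out$ph50 <- -log10(out$ec50)
  structure(out, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  unit <- if (x$stimulus_kind == "acid") "M [H+]" else "uM"
  cat(sprintf("Hill fit (%s, %d points): EC50 = %.4g %s, n = %.3f, r_max = %.4g\n",
              x$stimulus_kind, x$n_obs, x$ec50, unit, x$hill_n, x$r_max))
  if (!is.null(x$ph50)) cat(sprintf("  pH50 = %.3f\n", x$ph50))
  cat(sprintf("  RSS = %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Predict responses from a Hill fit
#'
#' @param object A `hill_fit`.
#' @param dose Doses on the input scale (uM, or pH for acid fits).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.hill_fit <- function(object, dose, ...) {
  conc <- if (object$stimulus_kind == "acid") 10^(-dose) else dose
  ifelse(conc == 0, 0,
         object$r_max * conc^object$hill_n /
           (object$ec50^object$hill_n + conc^object$hill_n))
}
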