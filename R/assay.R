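# Assay-side computations: the CCK-8 cell-viability formula and one-site
# saturation KD fitting with deterministic multi-start nonlinear least
# squares.

#' Cell viability from plate absorbances
#'
#' viability = 100 * (OD_test - OD_blank) / (OD_control - OD_blank).
#'
#' @param od_test,od_blank,od_control absorbance readings (vectors
#'   recycle).
#' @return viability in percent.
#' @export
viability <- function(od_test, od_blank, od_control) {
  if (any(od_control <= od_blank))
    stop("od_control must exceed od_blank", call. = FALSE)
  100 * (od_test - od_blank) / (od_control - od_blank)
}

one_site <- function(conc, baseline, a_max, kd)
  baseline + a_max * conc / (kd + conc)

#' Fit a one-site saturation binding curve
#'
#' Nonlinear least squares of response = baseline + a_max * c / (KD + c)
#' on the linear concentration scale (a log10 axis affects display, not
#' the likelihood). Initialization is a deterministic multi-start over a
#' log-spaced KD grid spanning the concentration range; the best
#' converged fit by residual sum of squares wins. An optional 4PL model
#' (Hill slope) is available for comparison.
#'
#' @param curve data frame with columns `concentration_uM` and `response`
#'   (or any two columns, taken in that order).
#' @param model `"one_site"` (default) or `"fourpl"`.
#' @param n_starts KD grid size (default 12).
#' @return a `binding_fit`: `kd` (uM), `a_max`, `baseline`, `rss`,
#'   `se` (approximate standard errors), `fitted`, `model`.
#' @export
fit_kd <- function(curve, model = c("one_site", "fourpl"), n_starts = 12L) {
  model <- match.arg(model)
  conc <- curve[[1]]
  resp <- curve[[2]]
  ok <- is.finite(conc) & is.finite(resp)
  conc <- conc[ok]; resp <- resp[ok]
  cu <- sort(unique(conc[conc > 0]))
  if (length(cu) < 2L || diff(range(resp)) < 1e-12)
    stop("degenerate fit: need >= 2 distinct positive concentrations ",
         "and non-constant responses", call. = FALSE)
  if (length(cu) < 4L || log10(max(cu) / min(cu)) < 2)
    warning("fewer than 4 concentrations or < 2 orders of magnitude ",
            "span; KD may be poorly determined")
  kd_grid <- 10^seq(log10(min(cu)), log10(max(cu)),
                    length.out = n_starts)
  dat <- data.frame(conc = conc, resp = resp)
  best <- NULL
  for (kd0 in kd_grid) {
    st <- list(baseline = min(resp), a_max = diff(range(resp)), kd = kd0)
    if (model == "fourpl") st$hill <- 1
    fml <- if (model == "one_site")
      resp ~ baseline + a_max * conc / (kd + conc)
    else
      resp ~ baseline + a_max / (1 + (kd / conc)^hill)
    fit <- tryCatch(
      nls(fml, data = dat, start = st, algorithm = "port",
          lower = c(baseline = -Inf, a_max = 1e-12, kd = 1e-9,
                    if (model == "fourpl") c(hill = 0.1)),
          control = list(warnOnly = FALSE, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("KD fit did not converge from any start", call. = FALSE)
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(kd = unname(cf["kd"]), a_max = unname(cf["a_max"]),
                 baseline = unname(cf["baseline"]),
                 hill = if (model == "fourpl") unname(cf["hill"]) else NULL,
                 rss = best$rss, se = se,
                 fitted = one_site(conc, cf["baseline"], cf["a_max"],
                                   cf["kd"]),
                 model = model),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("One-site fit: KD = %.4g uM, a_max = %.3g, baseline = %.3g, RSS = %.3g\n",
              x$kd, x$a_max, x$baseline, x$rss))
  invisible(x)
}

#' @importFrom stats nls residuals
NULL
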