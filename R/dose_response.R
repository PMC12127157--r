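# Four-parameter logistic dose-response fitting for the NKG2D reporter
# assay, and the EC50 defined as the absolute 50%-GFP+ crossing of the
# fitted curve (not the half-maximum midpoint: the two differ whenever the
# plateau is below 100%).

# increasing 4PL: response (%GFP+) vs dose
logistic4 <- function(x, bottom, top, hill, midpoint) {
  bottom + (top - bottom) / (1 + (midpoint / x)^hill)
}

PAR_LOWER <- c(bottom = 0,  top = 20,  hill = 1e-3)
PAR_UPPER <- c(bottom = 20, top = 100, hill = 10)

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (midpoint/x)^hill)`
#' to replicate %GFP+ measurements (replicates enter the loss
#' individually). Parameters are bounded (`bottom` in \[0, 20\], `top` in
#' \[20, 100\], `hill` in (0, 10\], `midpoint` in
#' \[min dose / 10, max dose * 10\]) and the bounded quasi-Newton
#' optimiser (L-BFGS-B) is run from a deterministic grid of five starts to
#' avoid local minima.
#'
#' @param data Data frame with columns `dose` (µg/mL, > 0) and `response`
#'   (%GFP+, in \[0, 100\]); at least 4 distinct doses. An activation assay
#'   is assumed: monotone-decreasing data are rejected.
#'
#' @return An object of class `sigmoid_fit`: a list with elements
#'   `bottom`, `top`, `hill`, `midpoint`, `rss`, `ec50` (the 50% crossing,
#'   `NA` when the curve never reaches 50%), `n` and `data`. Methods:
#'   [predict()][predict.sigmoid_fit], [tidy()], [glance()],
#'   [autoplot.sigmoid_fit()].
#' @export
fit_sigmoid <- function(data) {
  stopifnot(all(c("dose", "response") %in% names(data)))
  dose <- as.numeric(data$dose)
  resp <- as.numeric(data$response)
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(resp < 0 | resp > 100)) stop("responses must lie in [0, 100]")
  if (length(unique(dose)) < 4) stop("need at least 4 distinct doses")
  if (stats::sd(resp) == 0) stop("constant responses: nothing to fit")
  means <- tapply(resp, dose, mean)
  means <- means[order(as.numeric(names(means)))]
  if (all(diff(means) <= 0) && any(diff(means) < 0)) {
    stop("responses decrease with dose: not an activation dose-response")
  }

  m_lo <- min(dose) / 10
  m_hi <- max(dose) * 10
  b0 <- min(max(min(resp), PAR_LOWER["bottom"]), PAR_UPPER["bottom"])
  t0 <- min(max(max(resp), PAR_LOWER["top"]), PAR_UPPER["top"])
  gm <- exp(stats::quantile(log(dose), c(0.25, 0.5, 0.75), names = FALSE))
  starts <- list(
    c(hill = 1, midpoint = gm[2]),
    c(hill = 2, midpoint = gm[1]),
    c(hill = 2, midpoint = gm[3]),
    c(hill = 0.5, midpoint = gm[2]),
    c(hill = 4, midpoint = gm[2])
  )

  rss_fn <- function(par) {
    sum((resp - logistic4(dose, par[1], par[2], par[3], par[4]))^2)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(
        c(unname(b0), unname(t0), unname(s["hill"]), unname(s["midpoint"])),
        rss_fn, method = "L-BFGS-B",
        lower = c(unname(PAR_LOWER), m_lo),
        upper = c(unname(PAR_UPPER), m_hi),
        control = list(maxit = 500, factr = 1e1,
                       parscale = c(10, 50, 1, unname(gm[2])))
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$convergence != 0) next
    if (is.null(best) || fit$value < best$rss) {
      best <- list(bottom = fit$par[1], top = fit$par[2], hill = fit$par[3],
                   midpoint = fit$par[4], rss = fit$value)
    }
  }
  if (is.null(best)) stop("dose-response fit failed to converge from all starts")

  out <- structure(
    list(bottom = best$bottom, top = best$top, hill = best$hill,
         midpoint = best$midpoint, rss = best$rss,
         ec50 = NA_real_, n = length(resp),
         data = tibble::tibble(dose = dose, response = resp)),
    class = "sigmoid_fit"
  )
  out$ec50 <- ec50_crossing(out)
  out
}

#' Concentration at which the fitted curve crosses 50% GFP+
#'
#' Solved in closed form:
#' `x = midpoint * ((top - 50) / (50 - bottom))^(-1/hill)`, the unique
#' dose at which the increasing 4PL equals 50. Undefined (`NA`) when the
#' plateau never reaches 50% (`top <= 50`) or the baseline already
#' exceeds it (`bottom >= 50`).
#'
#' @param fit A `sigmoid_fit`, or a list with elements `bottom`, `top`,
#'   `hill`, `midpoint`.
#' @return The crossing concentration (µg/mL), or `NA_real_`.
#' @export
ec50_crossing <- function(fit) {
  if (fit$top <= 50 || fit$bottom >= 50) return(NA_real_)
  fit$midpoint * ((fit$top - 50) / (50 - fit$bottom))^(-1 / fit$hill)
}

#' Midpoint that places the 50% crossing at a given concentration
#'
#' Inverse of [ec50_crossing()]: used by the simulator to generate curves
#' whose true crossing is a prescribed value.
#'
#' @param crossing Target 50%-GFP+ crossing concentration.
#' @param bottom,top,hill Remaining 4PL parameters (`top > 50`,
#'   `bottom < 50`).
#' @return The 4PL `midpoint`.
#' @export
midpoint_for_crossing <- function(crossing, bottom = 0, top = 90, hill = 2) {
  if (top <= 50 || bottom >= 50) stop("curve cannot cross 50% with these plateaus")
  crossing * ((top - 50) / (50 - bottom))^(1 / hill)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose else {
    if (is.data.frame(newdata)) newdata$dose else newdata
  }
  logistic4(x, object$bottom, object$top, object$hill, object$midpoint)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> bottom=%.3g top=%.3g hill=%.3g midpoint=%.4g | ec50=%.4g rss=%.3g (n=%d)\n",
    x$bottom, x$top, x$hill, x$midpoint, x$ec50, x$rss, x$n
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "hill", "midpoint"),
    estimate = c(x$bottom, x$top, x$hill, x$midpoint)
  )
}

#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, ec50 = x$ec50, n = x$n)
}

#' Fit dose-response curves for many alleles
#'
#' @param data Data frame with columns `allele`, `dose`, `response`.
#' @return A tibble with one row per allele: the 4PL parameters, `rss` and
#'   `ec50`, plus a `fit` list column of `sigmoid_fit` objects.
#' @export
fit_dose_response <- function(data) {
  stopifnot(all(c("allele", "dose", "response") %in% names(data)))
  purrr::map_dfr(split(tibble::as_tibble(data), data$allele), function(sub) {
    f <- fit_sigmoid(sub)
    tibble::tibble(allele = sub$allele[1], bottom = f$bottom, top = f$top,
                   hill = f$hill, midpoint = f$midpoint, rss = f$rss,
                   ec50 = f$ec50, fit = list(f))
  })
}

#' Per-type EC50 means with a two-group test
#'
#' @param ec50s Data frame with columns `allele` and `ec50`.
#' @param calls Type calls (columns `allele`, `type`) covering every
#'   allele in `ec50s`.
#' @param test Passed to the same machinery as [summarize_by_type()].
#' @return A one-row tibble: `mean_I`, `sd_I`, `n_I`, `mean_II`, `sd_II`,
#'   `n_II`, `statistic`, `p_value`, `method`, `test_available`.
#' @export
ec50_group_means <- function(ec50s, calls, test = c("welch", "wilcoxon")) {
  stopifnot(all(c("allele", "ec50") %in% names(ec50s)))
  panel <- tibble::tibble(allele = ec50s$allele, mfi = ec50s$ec50)
  out <- summarize_by_type(panel, calls, test = test)
  out$reagent <- NULL
  out
}
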