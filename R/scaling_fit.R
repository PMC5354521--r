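# Allometric power-law fitting on log10-log10 scales and algebra on fitted
# exponents with quadrature propagation of standard errors.

#' Fit a power law y = c * x^b by log-log least squares
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`. The slope is the
#' allometric exponent `b`, `10^intercept` the multiplicative coefficient
#' `c`, and the standard errors are the usual OLS standard errors of slope
#' and intercept on the log10 scale, which is how cross-species scaling fits
#' are conventionally reported. The fit is unweighted; multiplicative
#' lognormal scatter around the power law corresponds exactly to the
#' homoscedastic additive error this model assumes in log space.
#'
#' Non-positive measurements are rejected outright (with the offending
#' record indices) rather than offset: silently adding pseudo-counts would
#' bias the exponent.
#'
#' @param x Positive predictor values (e.g. cell volume in um^3), or a data
#'   frame with columns `x` and `y` (as produced by [generate_power_law()]).
#' @param y Positive response values; omit when `x` is a data frame.
#' @return An object of class `power_law_fit`: a list with `coefficient`,
#'   `exponent`, `se_log_coefficient` (SE of the log10 intercept),
#'   `se_exponent`, `r_squared`, `n`, and the underlying `lm` fit as
#'   `model`.
#' @seealso [predict.power_law_fit()], [combine_exponents()]
#' @examples
#' x <- c(1, 2, 4, 8, 16)
#' fit_power_law(x, 2 * x^0.5)
#' @export
fit_power_law <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x))) {
      stop_invalid("data frame input must have columns `x` and `y`")
    }
    y <- x$y
    x <- x$x
  }
  if (length(x) != length(y)) stop_invalid("`x` and `y` lengths differ")
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad)) {
    stop_invalid("power-law fitting requires positive finite x and y; ",
                 "offending record(s): ", paste(bad, collapse = ", "))
  }
  if (length(x) < 3) {
    stop_invalid("at least 3 records are required to fit a power law (got ",
                 length(x), ")")
  }
  lx <- log10(x)
  ly <- log10(y)
  model <- stats::lm(ly ~ lx)
  # summary.lm warns on noiseless data ("essentially perfect fit"); exact
  # power laws are legitimate inputs here, so silence just that warning
  sm <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  # a noiseless power law leaves residuals at rounding level; the summary
  # then reports r.squared slightly below 1 and tiny but nonzero SEs, which
  # is the honest answer, so no special-casing here
  structure(
    list(coefficient = 10^co[1, 1],
         exponent = co[2, 1],
         se_log_coefficient = co[1, 2],
         se_exponent = co[2, 2],
         r_squared = sm$r.squared,
         n = length(x),
         model = model),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (n = %d): y = %.4g * x^%.4g\n",
              x$n, x$coefficient, x$exponent))
  cat(sprintf("  exponent SE %.3g, log10-intercept SE %.3g, r^2 = %.3f\n",
              x$se_exponent, x$se_log_coefficient, x$r_squared))
  invisible(x)
}

#' Predict from a power-law fit
#'
#' Evaluates `coefficient * x^exponent`.
#'
#' @param object A `power_law_fit`.
#' @param x Positive values of the predictor.
#' @param ... Unused.
#' @return Predicted response values.
#' @export
predict.power_law_fit <- function(object, x, ...) {
  check_positive(x, "x")
  object$coefficient * x^object$exponent
}

# Coerce an exponent-with-SE out of a fit, a list, or a numeric (value, se)
as_exponent_estimate <- function(obj) {
  if (inherits(obj, "power_law_fit")) {
    return(c(exponent = obj$exponent, se = obj$se_exponent))
  }
  if (is.list(obj) && !is.null(obj$exponent)) {
    return(c(exponent = obj$exponent,
             se = if (is.null(obj$se)) 0 else obj$se))
  }
  if (is.numeric(obj) && length(obj) %in% 1:2) {
    return(c(exponent = obj[[1]], se = if (length(obj) == 2) obj[[2]] else 0))
  }
  stop_invalid("cannot interpret `", deparse(substitute(obj)),
               "` as an exponent estimate")
}

#' Combine scaling exponents with error propagation
#'
#' When two power laws are composed, exponents add (`multiply`, as in
#' `y = x^a` and `z = y * x^b`) or subtract (`divide`, as in a per-time or
#' per-volume rate). Standard errors combine in quadrature under an
#' independence assumption:
#' \deqn{SE = \sqrt{SE_a^2 + SE_b^2}.}
#' For example, a growth budget scaling as `V^0.97` (SE 0.04) divided by a
#' division time scaling as `V^-0.17` (SE 0.11) gives a biomass-accumulation
#' rate scaling as `V^1.14` with SE `sqrt(0.04^2 + 0.11^2) = 0.12`.
#'
#' @param a,b Exponent estimates: a [fit_power_law()] result, a
#'   `list(exponent =, se =)`, or a numeric `c(value, se)` (a bare value is
#'   taken as exact, SE 0).
#' @param operation `"multiply"` (exponents add) or `"divide"` (subtract).
#' @return A list with `exponent` and `se`.
#' @examples
#' combine_exponents(c(0.97, 0.04), "divide", c(-0.17, 0.11))
#' @export
combine_exponents <- function(a, operation = c("multiply", "divide"), b) {
  operation <- match.arg(operation)
  ea <- as_exponent_estimate(a)
  eb <- as_exponent_estimate(b)
  if (ea[["se"]] < 0 || eb[["se"]] < 0) stop_invalid("SEs must be >= 0")
  value <- if (operation == "multiply") {
    ea[["exponent"]] + eb[["exponent"]]
  } else {
    ea[["exponent"]] - eb[["exponent"]]
  }
  list(exponent = value, se = sqrt(ea[["se"]]^2 + eb[["se"]]^2))
}

#' Read a scaling dataset from a TSV file
#'
#' Two numeric columns `x` and `y`, with optional `label` and `group`
#' columns, as used for cross-species scaling relations.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A data frame with columns `x`, `y`, `label`, `group`.
#' @export
read_scaling_dataset <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(tab))) {
    stop_invalid("scaling dataset must have columns `x` and `y`")
  }
  if (is.null(tab$label)) tab$label <- paste0("record_", seq_len(nrow(tab)))
  if (is.null(tab$group)) tab$group <- NA_character_
  tab[c("x", "y", "label", "group")]
}

#' Export a power-law fit as a one-row data frame
#'
#' All scalar fields of a [fit_power_law()] result, suitable for writing as
#' TSV or JSON in reports.
#'
#' @param fit A `power_law_fit`.
#' @param trait Optional trait name recorded in the first column.
#' @return A one-row data frame.
#' @export
fit_report <- function(fit, trait = NA_character_) {
  stopifnot(inherits(fit, "power_law_fit"))
  data.frame(trait = trait,
             coefficient = fit$coefficient,
             exponent = fit$exponent,
             se_log_coefficient = fit$se_log_coefficient,
             se_exponent = fit$se_exponent,
             r_squared = fit$r_squared,
             n = fit$n,
             stringsAsFactors = FALSE)
}
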