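#' Image-based BMI proxy
#'
#' Screening cohorts often lack measured BMI, but two quantities extracted
#' from the mammogram itself track it: the image-based breast-fat fraction
#' and the compressed breast thickness. The proxy is an ordinary
#' least-squares model
#'
#' \deqn{\widehat{BMI} = \beta_0 + \beta_{thk} \cdot thickness_{mm} +
#'   \beta_{fat} \cdot fat}
#'
#' with predictions clamped to the physiologically plausible range
#' (10, 80) kg/m^2. The coefficients are serialisable to JSON so a different
#' calibrated estimator can be dropped in without touching the pipeline; the
#' fitted proxy exists to gate the stable-BMI subgroup, not to report BMI.
#'
#' @param data A data frame with columns `fat_measure` (fraction in `[0, 1]`),
#'   `thickness_mm` (mm) and `bmi` (kg/m^2); rows with any of the three
#'   missing are dropped.
#' @return An object of class `bmi_proxy` with elements `coefficients`
#'   (named: `intercept`, `thickness_mm`, `fat_measure`), `sigma` (residual
#'   SD) and `n`. `tidy()`/`glance()` methods return tibbles.
#' @examples
#' d <- data.frame(thickness_mm = runif(50, 30, 80), fat_measure = runif(50))
#' d$bmi <- 10 + 0.2 * d$thickness_mm + 5 * d$fat_measure
#' fit <- fit_bmi_proxy(d)
#' estimate_bmi(fit, fat_measure = 0.5, thickness_mm = 50)
#' @export
fit_bmi_proxy <- function(data) {
  df <- tibble::as_tibble(data)[c("fat_measure", "thickness_mm", "bmi")]
  df <- df[complete.cases(df), ]
  if (nrow(df) < 10) {
    abort("BMI proxy needs at least 10 complete (fat, thickness, bmi) records")
  }
  if (sd(df$fat_measure) == 0 || sd(df$thickness_mm) == 0) {
    abort("rank-deficient design: a predictor is constant")
  }
  fit <- lm(bmi ~ thickness_mm + fat_measure, data = df)
  cf <- coef(fit)
  if (anyNA(cf) || any(!is.finite(cf))) {
    abort("BMI proxy fit produced non-finite coefficients")
  }
  structure(
    list(
      coefficients = c(intercept = unname(cf[["(Intercept)"]]),
                       thickness_mm = unname(cf[["thickness_mm"]]),
                       fat_measure = unname(cf[["fat_measure"]])),
      sigma = sqrt(sum(fit$residuals^2) / fit$df.residual),
      n = nrow(df)
    ),
    class = "bmi_proxy"
  )
}

#' Construct a BMI proxy from known coefficients
#'
#' @param intercept,thickness_mm,fat_measure Model coefficients (kg/m^2;
#'   kg/m^2 per mm; kg/m^2 per unit fat fraction).
#' @param sigma Residual SD (kg/m^2), if known.
#' @return A `bmi_proxy` object.
#' @export
bmi_proxy_model <- function(intercept, thickness_mm = 0, fat_measure = 0,
                            sigma = NA_real_) {
  stopifnot(is.finite(intercept), is.finite(thickness_mm), is.finite(fat_measure))
  structure(
    list(coefficients = c(intercept = intercept, thickness_mm = thickness_mm,
                          fat_measure = fat_measure),
         sigma = sigma, n = NA_integer_),
    class = "bmi_proxy"
  )
}

#' Predict BMI from image features
#'
#' @param model A fitted `bmi_proxy`.
#' @param fat_measure,thickness_mm Image features (vectors recycle).
#' @return BMI estimates in kg/m^2, clamped to (10, 80).
#' @export
estimate_bmi <- function(model, fat_measure, thickness_mm) {
  if (!inherits(model, "bmi_proxy")) {
    abort("`model` must be a fitted bmi_proxy object")
  }
  cf <- model$coefficients
  pred <- cf[["intercept"]] + cf[["thickness_mm"]] * thickness_mm +
    cf[["fat_measure"]] * fat_measure
  pmin(pmax(pred, 10), 80)
}

#' @export
print.bmi_proxy <- function(x, ...) {
  cf <- x$coefficients
  cat("Image-based BMI proxy (OLS)\n")
  cat(sprintf("  BMI = %.3f + %.4f * thickness_mm + %.3f * fat_measure\n",
              cf[["intercept"]], cf[["thickness_mm"]], cf[["fat_measure"]]))
  cat(sprintf("  residual SD = %.3f kg/m^2 (n = %s)\n", x$sigma,
              format(x$n)))
  invisible(x)
}

#' @rdname fit_bmi_proxy
#' @param x A `bmi_proxy` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.bmi_proxy <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_bmi_proxy
#' @exportS3Method generics::glance
#' @export
glance.bmi_proxy <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, nobs = x$n)
}

#' Read/write BMI-proxy coefficients as JSON
#'
#' @param model A `bmi_proxy` object.
#' @param path JSON file path.
#' @return `write_bmi_proxy()` returns `path` invisibly; `read_bmi_proxy()`
#'   returns a `bmi_proxy` object.
#' @export
write_bmi_proxy <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients), sigma = model$sigma),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_bmi_proxy
#' @export
read_bmi_proxy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bmi_proxy_model(
    intercept = obj$coefficients$intercept,
    thickness_mm = obj$coefficients$thickness_mm,
    fat_measure = obj$coefficients$fat_measure,
    sigma = obj$sigma %||% NA_real_
  )
}
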