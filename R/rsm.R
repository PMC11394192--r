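quad_terms <- c("a0", "a1", "a2", "a3", "a11", "a22", "a33", "a12", "a13", "a23")

# Evaluate the 10-term quadratic a0 + sum ai xi + sum aii xi^2 + sum aij xi xj
eval_quad <- function(coefs, x1, x2, x3) {
  coefs <- unname(coefs)
  coefs[1] + coefs[2] * x1 + coefs[3] * x2 + coefs[4] * x3 +
    coefs[5] * x1^2 + coefs[6] * x2^2 + coefs[7] * x3^2 +
    coefs[8] * x1 * x2 + coefs[9] * x1 * x3 + coefs[10] * x2 * x3
}

# Exact algebraic expansion of the affine coding map x = (X - c)/h applied to
# a quadratic given in coded units, yielding the actual-unit coefficients.
coded_to_uncoded <- function(a, space) {
  cc <- space$center; h <- half_range(space)
  a <- unname(a)
  lin <- a[2:4]; quad <- a[5:7]; int <- a[8:10]  # a12, a13, a23
  b0 <- a[1] - sum(lin * cc / h) + sum(quad * cc^2 / h^2) +
    int[1] * cc[1] * cc[2] / (h[1] * h[2]) +
    int[2] * cc[1] * cc[3] / (h[1] * h[3]) +
    int[3] * cc[2] * cc[3] / (h[2] * h[3])
  b_int <- c(int[1] / (h[1] * h[2]), int[2] / (h[1] * h[3]), int[3] / (h[2] * h[3]))
  b_lin <- lin / h - 2 * quad * cc / h^2
  b_lin[1] <- b_lin[1] - b_int[1] * cc[2] - b_int[2] * cc[3]
  b_lin[2] <- b_lin[2] - b_int[1] * cc[1] - b_int[3] * cc[3]
  b_lin[3] <- b_lin[3] - b_int[2] * cc[1] - b_int[3] * cc[2]
  stats::setNames(c(b0, b_lin, quad / h^2, b_int), quad_terms)
}

# Inverse expansion: actual-unit coefficients to coded units.
uncoded_to_coded <- function(b, space) {
  cc <- space$center; h <- half_range(space)
  b <- unname(b)
  lin <- b[2:4]; quad <- b[5:7]; int <- b[8:10]
  a0 <- b[1] + sum(lin * cc) + sum(quad * cc^2) +
    int[1] * cc[1] * cc[2] + int[2] * cc[1] * cc[3] + int[3] * cc[2] * cc[3]
  a_lin <- numeric(3)
  a_lin[1] <- h[1] * (lin[1] + 2 * quad[1] * cc[1] + int[1] * cc[2] + int[2] * cc[3])
  a_lin[2] <- h[2] * (lin[2] + 2 * quad[2] * cc[2] + int[1] * cc[1] + int[3] * cc[3])
  a_lin[3] <- h[3] * (lin[3] + 2 * quad[3] * cc[3] + int[2] * cc[1] + int[3] * cc[2])
  a_int <- c(int[1] * h[1] * h[2], int[2] * h[1] * h[3], int[3] * h[2] * h[3])
  stats::setNames(c(a0, a_lin, quad * h^2, a_int), quad_terms)
}

#' Construct a second-order response-surface model from known coefficients
#'
#' Builds a `quadratic_model` directly from a 10-coefficient vector in the
#' order `(a0, a1, a2, a3, a11, a22, a33, a12, a13, a23)` — intercept, linear,
#' quadratic, then two-way interaction terms for factors 1..3.  This is how
#' published regression equations are brought into the package for prediction
#' and optimization.
#'
#' @param coefficients numeric vector of length 10 (see order above).
#' @param space the [od_factor_space()] defining the coding map.
#' @param response name of the response the surface describes.
#' @param form `"uncoded"` if the coefficients are in actual units,
#'   `"coded"` if in coded (-1..+1) units.
#' @return A `quadratic_model` with both coefficient forms; fit diagnostics
#'   are `NA` (the model was not fitted to data).
#' @export
quadratic_model <- function(coefficients, space = od_factor_space(),
                            response = "response",
                            form = c("uncoded", "coded")) {
  form <- match.arg(form)
  if (length(coefficients) != 10L || any(!is.finite(coefficients)))
    stop("need 10 finite coefficients", call. = FALSE)
  if (form == "uncoded") {
    uncoded <- stats::setNames(unname(coefficients), quad_terms)
    coded <- uncoded_to_coded(uncoded, space)
  } else {
    coded <- stats::setNames(unname(coefficients), quad_terms)
    uncoded <- coded_to_uncoded(coded, space)
  }
  structure(
    list(response = response, coded_coeffs = coded, uncoded_coeffs = uncoded,
         factor_space = space, r2 = NA_real_, r2_adj = NA_real_,
         p_model = NA_real_, p_lack_of_fit = NA_real_,
         residual_df = NA_integer_, fit = NULL),
    class = "quadratic_model"
  )
}

coded_model_matrix <- function(coded) {
  x1 <- coded[, 1]; x2 <- coded[, 2]; x3 <- coded[, 3]
  cbind(1, x1, x2, x3, x1^2, x2^2, x3^2, x1 * x2, x1 * x3, x2 * x3)
}

#' Fit the second-order polynomial to design runs
#'
#' Ordinary least squares of a response on the 10-term quadratic basis
#' (intercept, 3 linear, 3 pure quadratic, 3 two-way interactions) in coded
#' units.  Actual-unit coefficients are obtained by exact algebraic expansion
#' of the coding map, so the two forms predict identically.  The lack-of-fit
#' test uses pure error from replicated design points (the center replicates
#' in a Box-Behnken design); with fewer than 2 replicates at any point the
#' lack-of-fit p-value is reported as `NA`.
#'
#' @param design a [bbd_design()] (or any data frame with coded columns
#'   `x1, x2, x3` and a `"factor_space"` attribute).
#' @param y numeric response vector, one value per run.
#' @param response response name stored in the model.
#' @return A `quadratic_model` with coefficients in both unit systems, R^2,
#'   adjusted R^2, overall-model F-test p-value, lack-of-fit p-value and
#'   residual degrees of freedom.
#' @seealso [anova_table()] for per-coefficient tests.
#' @export
fit_quadratic <- function(design, y, response = "response") {
  space <- attr(design, "factor_space")
  if (is.null(space)) stop("design carries no factor_space attribute", call. = FALSE)
  if (length(y) != nrow(design) || any(!is.finite(y)))
    stop("y must be finite with one value per run", call. = FALSE)
  coded <- as.matrix(design[, c("x1", "x2", "x3")])
  X <- coded_model_matrix(coded)
  if (nrow(X) < 11L)
    stop("need >= 10 runs plus at least 1 residual degree of freedom", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("singular design: quadratic model is not estimable", call. = FALSE)

  df <- data.frame(y = y, x1 = coded[, 1], x2 = coded[, 2], x3 = coded[, 3])
  fit <- stats::lm(y ~ x1 + x2 + x3 + I(x1^2) + I(x2^2) + I(x3^2) +
                     x1:x2 + x1:x3 + x2:x3, data = df)
  coefs <- stats::setNames(unname(stats::coef(fit)), quad_terms)
  sm <- summary(fit)
  p_model <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))

  structure(
    list(response = response, coded_coeffs = coefs,
         uncoded_coeffs = coded_to_uncoded(coefs, space),
         factor_space = space,
         r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
         p_model = p_model,
         p_lack_of_fit = lack_of_fit_p(coded, y, fit),
         residual_df = fit$df.residual, fit = fit),
    class = "quadratic_model"
  )
}

# Lack-of-fit F test: pure error pooled over replicated design points.
lack_of_fit_p <- function(coded, y, fit) {
  key <- apply(round(coded, 8), 1, paste, collapse = "/")
  groups <- split(y, key)
  reps <- groups[lengths(groups) > 1L]
  if (!length(reps)) return(NA_real_)
  ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- sum(lengths(reps) - 1L)
  ss_res <- sum(stats::residuals(fit)^2)
  df_lof <- fit$df.residual - df_pe
  if (df_lof < 1L) return(NA_real_)
  ss_lof <- max(ss_res - ss_pe, 0)
  if (ss_pe <= 0) return(NA_real_)
  f <- (ss_lof / df_lof) / (ss_pe / df_pe)
  stats::pf(f, df_lof, df_pe, lower.tail = FALSE)
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat("Second-order response surface for", x$response, "\n")
  cat("Coded coefficients:\n")
  print(round(x$coded_coeffs, 5))
  if (!is.na(x$r2))
    cat(sprintf("R2 = %.4f (adj %.4f), model p = %.3g, lack-of-fit p = %s\n",
                x$r2, x$r2_adj, x$p_model,
                ifelse(is.na(x$p_lack_of_fit), "NA",
                       format(x$p_lack_of_fit, digits = 3))))
  invisible(x)
}

#' Predict a response from a fitted or constructed quadratic model
#'
#' @param object a `quadratic_model`.
#' @param newdata factor settings in actual units: a length-3 vector
#'   `c(temperature, time, glycerol)`, a matrix, or a data frame with
#'   factor-named columns.
#' @param units `"actual"` (default) evaluates the uncoded form;
#'   `"coded"` treats `newdata` as coded units and evaluates the coded form.
#'   Both forms agree to numerical tolerance by construction.
#' @param ... unused.
#' @return Numeric vector of predicted response values.
#' @export
predict.quadratic_model <- function(object, newdata, units = c("actual", "coded"),
                                    ...) {
  units <- match.arg(units)
  x <- as_factor_matrix(newdata, object$factor_space)
  co <- if (units == "actual") object$uncoded_coeffs else object$coded_coeffs
  unname(eval_quad(co, x[, 1], x[, 2], x[, 3]))
}

#' @export
coef.quadratic_model <- function(object, form = c("coded", "uncoded"), ...) {
  form <- match.arg(form)
  if (form == "coded") object$coded_coeffs else object$uncoded_coeffs
}

#' Coefficient-level ANOVA for a fitted response-surface model
#'
#' Per-coefficient t tests (coded units) with significance stars at the 95%
#' confidence level, plus the overall model F test and the lack-of-fit test
#' based on pure error from replicated points.
#'
#' @param model a `quadratic_model` returned by [fit_quadratic()].
#' @return A data frame with columns `term`, `estimate`, `std_error`,
#'   `t_value`, `p_value`, `starred`; attributes `p_model`, `r2`, `r2_adj`
#'   and `p_lack_of_fit` carry the whole-model diagnostics.
#' @export
anova_table <- function(model) {
  if (is.null(model$fit))
    stop("model was constructed from coefficients, not fitted; no ANOVA available",
         call. = FALSE)
  ct <- summary(model$fit)$coefficients
  out <- data.frame(
    term = quad_terms,
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    t_value = unname(ct[, 3]),
    p_value = unname(ct[, 4]),
    starred = unname(ct[, 4]) < 0.05,
    row.names = NULL
  )
  attr(out, "p_model") <- model$p_model
  attr(out, "r2") <- model$r2
  attr(out, "r2_adj") <- model$r2_adj
  attr(out, "p_lack_of_fit") <- model$p_lack_of_fit
  out
}
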