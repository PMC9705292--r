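#' Significance stars for a p-value
#'
#' "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05 (strict
#' inequalities), "" otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Two-sample pooled-variance Student's t-test
#'
#' Compares disease and control group means with the classical
#' equal-variance (pooled) unpaired t-test. The reported difference is
#' MS minus HV, with its 95% confidence interval from the t distribution
#' on n1 + n2 - 2 degrees of freedom.
#'
#' @param ms_values,hv_values Numeric vectors, each with at least 2 finite
#'   values.
#' @return A \code{group_comparison}: list with \code{difference},
#'   \code{ci95}, \code{p_value}, \code{stars}, \code{t}, \code{df},
#'   \code{n} (per-group counts), \code{means}.
#' @export
ttest_two_sample <- function(ms_values, hv_values) {
  ms_values <- ms_values[!is.na(ms_values)]
  hv_values <- hv_values[!is.na(hv_values)]
  if (length(ms_values) < 2 || length(hv_values) < 2)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(ms_values, hv_values, var.equal = TRUE,
                      conf.level = 0.95)
  structure(list(difference = unname(tt$estimate[1] - tt$estimate[2]),
                 ci95 = as.numeric(tt$conf.int),
                 p_value = tt$p.value,
                 stars = p_stars(tt$p.value),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 n = c(MS = length(ms_values), HV = length(hv_values)),
                 means = c(MS = mean(ms_values), HV = mean(hv_values))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "MS - HV difference %.4g (95%% CI %.4g to %.4g), t(%d) = %.3f, p = %.4g %s\n",
    x$difference, x$ci95[1], x$ci95[2], x$df, x$t, x$p_value, x$stars))
  invisible(x)
}

#' Fit a disease-coefficient linear regression
#'
#' Ordinary least squares of an outcome on a subset of the predictors
#' disease (1 = MS), age (years) and sex (1 = female), always with an
#' intercept. Coefficient p-values come from the t distribution; adjusted
#' R-squared and the overall model F-test p-value are reported, along with
#' residuals, leverages and Cook's distances for the robustness stage.
#'
#' @param y Outcome vector.
#' @param covariates data.frame with numeric columns \code{disease},
#'   \code{age}, \code{sex} (or any subset covering \code{include}).
#' @param include Character subset of predictors to include; default all
#'   three.
#' @return A \code{regression_fit}: list with \code{coefficients} (matrix
#'   with estimate, se, t, p), \code{included}, \code{adjusted_r2},
#'   \code{model_p}, \code{residuals}, \code{cooks_d}, \code{leverage},
#'   \code{n}, and the underlying \code{lm} object as \code{fit}.
#' @export
fit_linear_model <- function(y, covariates,
                             include = c("disease", "age", "sex")) {
  stopifnot(is.data.frame(covariates), length(include) >= 1,
            all(include %in% names(covariates)))
  d <- covariates[, include, drop = FALSE]
  d$.y <- y
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) <= length(include) + 1)
    stop("too few observations for the requested design")
  fit <- stats::lm(.y ~ ., data = d)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("singular design: collinear column(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  model_p <- if (!is.null(sm$fstatistic))
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE)) else NA_real_
  h <- stats::hatvalues(fit)
  D <- stats::cooks.distance(fit)
  if (any(h >= 1 - 1e-12)) {
    warning("observation(s) with leverage 1: Cook's distance infinite")
    D[h >= 1 - 1e-12] <- Inf
  }
  structure(list(coefficients = sm$coefficients, included = include,
                 adjusted_r2 = sm$adj.r.squared, model_p = model_p,
                 residuals = stats::residuals(fit),
                 cooks_d = as.numeric(D), leverage = as.numeric(h),
                 n = nrow(d), fit = fit, data = d),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Linear model (n = %d): %s; adj R^2 = %.3f, model p = %.4g\n",
              x$n, paste(x$included, collapse = " + "),
              x$adjusted_r2, x$model_p))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Cook's distances of a fitted model
#'
#' Per-observation influence: \eqn{D_i = r_i^2 h_i / (p (1 - h_i))} with
#' \eqn{r_i} the internally standardised residual, \eqn{h_i} the leverage
#' and \eqn{p} the number of estimated coefficients; algebraically equal to
#' the leave-one-out coefficient-shift form.
#'
#' @param fit A \code{regression_fit}.
#' @return Numeric vector of Cook's distances (Inf where leverage is 1).
#' @export
cooks_distances <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  fit$cooks_d
}

#' Confounder selection by the adjusted-R-squared-and-significance rule
#'
#' Disease is always included. Candidates (age, then sex, in that fixed
#' order) are added one at a time and kept only if the addition strictly
#' increases adjusted R-squared AND the added coefficient is significant at
#' \code{alpha}. The audit trail records both criteria for every candidate.
#'
#' @param y Outcome vector.
#' @param covariates data.frame with disease, age, sex columns.
#' @param candidates Candidate confounders in evaluation order.
#' @param alpha Significance level for the added coefficient; default 0.05.
#' @return List with \code{include} (selected predictors), \code{fit} (the
#'   final \code{regression_fit}), and \code{audit} (data.frame: candidate,
#'   adj_r2_without, adj_r2_with, p_value, included).
#' @export
select_confounders <- function(y, covariates,
                               candidates = c("age", "sex"),
                               alpha = 0.05) {
  include <- "disease"
  current <- fit_linear_model(y, covariates, include)
  audit <- list()
  for (cand in candidates) {
    trial <- fit_linear_model(y, covariates, c(include, cand))
    p_cand <- trial$coefficients[cand, 4]
    gain <- trial$adjusted_r2 > current$adjusted_r2
    keep <- gain && p_cand < alpha
    audit[[length(audit) + 1]] <- data.frame(
      candidate = cand, adj_r2_without = current$adjusted_r2,
      adj_r2_with = trial$adjusted_r2, p_value = p_cand,
      included = keep, stringsAsFactors = FALSE)
    if (keep) {
      include <- c(include, cand)
      current <- trial
    }
  }
  list(include = include, fit = current, audit = do.call(rbind, audit))
}

#' Robustness check: refit with influential observations removed
#'
#' A single (non-iterative) pass: observations whose Cook's distance
#' exceeds 3 times the mean Cook's distance are removed and the model is
#' refitted once on the remainder. When no point exceeds the threshold the
#' refit is the original fit; when removal would leave too few observations
#' an error is raised and nothing is removed.
#'
#' @param fit A \code{regression_fit}.
#' @return A \code{robustness_result}: list with \code{original},
#'   \code{removed} (row indices into the fitted data), \code{refit}, and
#'   \code{shift} (refit minus original coefficients).
#' @export
robustness_refit <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  D <- fit$cooks_d
  thr <- 3 * mean(D)
  removed <- which(D > thr)
  if (length(removed) == 0) {
    return(structure(list(original = fit, removed = integer(0), refit = fit,
                          shift = stats::setNames(
                            rep(0, nrow(fit$coefficients)),
                            rownames(fit$coefficients))),
                     class = "robustness_result"))
  }
  d <- fit$data
  keep <- setdiff(seq_len(nrow(d)), removed)
  if (length(keep) <= length(fit$included) + 1)
    stop("removing influential points would leave too few observations; nothing removed")
  refit <- fit_linear_model(d$.y[keep],
                            d[keep, fit$included, drop = FALSE],
                            fit$included)
  shift <- refit$coefficients[, 1] - fit$coefficients[, 1]
  structure(list(original = fit, removed = removed, refit = refit,
                 shift = shift),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Robustness refit: %d influential point(s) removed (Cook's D > 3 x mean)\n",
              length(x$removed)))
  print(round(x$shift, 6))
  invisible(x)
}

#' Residual diagnostics for a fitted model
#'
#' Quantitative counterparts of the visual normality checks applied to
#' regression residuals: five-number summary (box plot), histogram counts,
#' normal-quantile pairs (Q-Q plot), sample skewness, excess kurtosis, and
#' a Shapiro-Wilk p-value. Constant residuals are flagged degenerate.
#'
#' @param fit A \code{regression_fit}.
#' @return List with \code{n}, \code{degenerate}, \code{fivenum},
#'   \code{histogram} (breaks/counts), \code{qq} (theoretical, sample),
#'   \code{skewness}, \code{excess_kurtosis}, \code{shapiro_p}.
#' @export
residual_diagnostics <- function(fit) {
  r <- as.numeric(fit$residuals)
  n <- length(r)
  if (n < 3) stop("need at least 3 residuals for diagnostics")
  if (stats::sd(r) < 1e-12 * max(1, mean(abs(r))))
    return(list(n = n, degenerate = TRUE, fivenum = stats::fivenum(r),
                histogram = NULL, qq = NULL, skewness = NA_real_,
                excess_kurtosis = NA_real_, shapiro_p = NA_real_))
  m <- mean(r); s <- stats::sd(r)
  z <- (r - m) / s
  h <- graphics::hist(r, plot = FALSE)
  rs <- if (n > 5000) r[round(seq(1, n, length.out = 5000))] else r
  list(n = n, degenerate = FALSE,
       fivenum = stats::fivenum(r),
       histogram = list(breaks = h$breaks, counts = h$counts),
       qq = list(theoretical = stats::qnorm(stats::ppoints(n)),
                 sample = sort(r)),
       skewness = mean(z^3),
       excess_kurtosis = mean(z^4) - 3,
       shapiro_p = stats::shapiro.test(rs)$p.value)
}
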