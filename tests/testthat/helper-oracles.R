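# Independent oracles and fixture builders shared across tests.

# Stereographic projection computed the long way: lift to 3-D, draw the ray
# from the antipode of the tangent point through the surface point, and
# intersect it with the tangent plane.
project_3d_oracle <- function(ecc, mer, R, s) {
  P <- R * c(sin(ecc) * cos(mer), sin(ecc) * sin(mer), cos(ecc))
  A <- c(0, 0, -R)                       # antipode of tangent point (+z pole)
  t <- (R - A[3]) / (P[3] - A[3])        # intersect plane z = R
  q <- A + t * (P - A)
  c(q[1], q[2]) * s                      # px, relative to the image centre
}

# Brute-force least squares: minimise the RSS with BFGS + analytic
# gradient, restarting from the previous optimum until converged.
ols_brute_force <- function(y, X) {
  rss <- function(b) sum((y - X %*% b)^2)
  grad <- function(b) as.numeric(-2 * t(X) %*% (y - X %*% b))
  par <- rep(0, ncol(X))
  for (i in 1:8) {
    fit <- stats::optim(par, rss, grad, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-16))
    if (max(abs(fit$par - par)) < 1e-12) break
    par <- fit$par
  }
  fit$par
}

# Cook's distance by explicit leave-one-out refits.
cooks_loo_oracle <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- X %*% beta
  s2 <- sum((y - fitted)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    bi <- solve(crossprod(X[-i, , drop = FALSE]),
                crossprod(X[-i, , drop = FALSE], y[-i]))
    sum((fitted - X %*% bi)^2) / (p * s2)
  }, 0)
}

# Pooled two-sample t statistic and p, coded from the textbook formulas.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# A cohort configuration with every systematic effect switched off.
null_cohort_config <- function(n = 30, noise = 1, seed = 1) {
  outs <- c(oct_outcomes(), vessel_outcomes())
  zero <- stats::setNames(rep(0, length(outs)), outs)
  cohort_config(n_per_group = c(MS = n, HV = n),
                beta_disease = zero, beta_age = zero, beta_sex = zero,
                noise_sd = stats::setNames(rep(noise, length(outs)), outs),
                p_optic_neuritis = 0, seed = seed)
}

# Disease/age/sex covariate frame for stats fixtures.
make_cov <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(disease = rep(c(1, 0), length.out = n),
             age = stats::runif(n, 20, 80),
             sex = stats::rbinom(n, 1, 0.5))
}

# A small OCT record table with full control over the fields.
make_oct_record <- function(subject_id, eye = "OD", visit_date,
                            quality_score = 30, rnfl_global = 100,
                            macular_volume = 8.7, pregnancy_visit = FALSE) {
  data.frame(subject_id = subject_id, eye = eye,
             visit_date = as.Date(visit_date),
             quality_score = quality_score, art = 100,
             rnfl_global = rnfl_global, rnfl_t = 70, rnfl_ti = 143,
             rnfl_ts = 136, rnfl_n = 76, rnfl_ni = 111, rnfl_ns = 103,
             macular_volume = macular_volume,
             pregnancy_visit = pregnancy_visit,
             stringsAsFactors = FALSE)
}

make_subjects <- function(ids, group = "HV", on = FALSE, path = FALSE,
                          myopia = FALSE) {
  data.frame(subject_id = ids, group = group,
             age = 40, sex = "F", subtype = ifelse(group == "MS", "RRMS", "none"),
             optic_neuritis_history = on, retinal_pathology = path,
             high_myopia = myopia, stringsAsFactors = FALSE)
}
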