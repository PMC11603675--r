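#' Descriptive summary with both printed interval conventions
#'
#' Moment-based skewness `g1 = m3 / m2^1.5` and excess kurtosis
#' `g2 = m4 / m2^2 - 3` (the bias-adjusted sample versions `G1`, `G2` are
#' available with `adjusted = TRUE`). Two interval conventions are
#' computed, because published descriptive tables use both under the same
#' "(95% CI)" heading: `ci_mean` is the standard-error-based confidence
#' interval of the mean (`mean +/- 1.96 sd / sqrt(n)`), while `range_1_96sd`
#' is the population-spread band (`mean +/- 1.96 sd`).
#'
#' @param x numeric vector, `n >= 2`
#' @param adjusted use bias-adjusted skewness/kurtosis estimators
#' @return one-row data.frame: `n`, `mean`, `sd`, `min`, `max`,
#'   `skewness`, `excess_kurtosis`, `ci_lo`, `ci_hi`, `range_lo`, `range_hi`
#' @export
describeValues <- function(x, adjusted = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("insufficient data: need at least 2 values")
  m <- mean(x)
  s <- stats::sd(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- if (m2 > 0) m3 / m2^1.5 else 0
  g2 <- if (m2 > 0) m4 / m2^2 - 3 else 0
  if (adjusted) {
    if (n > 2) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    if (n > 3) g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  ci <- intervalFromSummary(m, s, n, kind = "ci_mean")
  rg <- intervalFromSummary(m, s, kind = "range")
  data.frame(n = n, mean = m, sd = s, min = min(x), max = max(x),
             skewness = g1, excess_kurtosis = g2,
             ci_lo = ci[1], ci_hi = ci[2],
             range_lo = rg[1], range_hi = rg[2])
}

#' Recompute a printed 95% interval from summary statistics
#'
#' `kind = "ci_mean"` gives `mean +/- 1.96 sd / sqrt(n)` (the confidence
#' interval of the mean); `kind = "range"` gives `mean +/- 1.96 sd` (the
#' spread band). 1.96 is used as the normal 97.5% quantile throughout;
#' rounding is left to presentation.
#'
#' @param mean,sd summary statistics (`sd >= 0`)
#' @param n sample size (required for `ci_mean`)
#' @param kind `"ci_mean"` or `"range"`
#' @return numeric(2): lower and upper bound
#' @export
intervalFromSummary <- function(mean, sd, n = NULL,
                                kind = c("ci_mean", "range")) {
  kind <- match.arg(kind)
  if (sd < 0) stop("sd must be >= 0")
  half <- if (kind == "ci_mean") {
    if (is.null(n) || n < 1) stop("n is required for kind = 'ci_mean'")
    1.96 * sd / sqrt(n)
  } else 1.96 * sd
  c(lower = mean - half, upper = mean + half)
}

#' Assign the cohort age group
#'
#' Integer-year binning into 4-12, 13-16 and 17-20 years.
#'
#' @param age_years numeric age(s) in years, within `[4, 21)`
#' @return factor with levels `4-12`, `13-16`, `17-20`
#' @export
assignAgeGroup <- function(age_years) {
  yr <- floor(age_years)
  if (any(is.na(yr)) || any(yr < 4 | yr > 20))
    stop("age out of range: groups are defined for 4-20 years")
  cut(yr, breaks = c(3.5, 12.5, 16.5, 20.5),
      labels = c("4-12", "13-16", "17-20"))
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Fits `y = X beta + b[group] + eps` with `b ~ N(0, sigma_b^2)` and
#' `eps ~ N(0, sigma_e^2)` by profiling the REML criterion over the
#' variance ratio `lambda = sigma_b^2 / sigma_e^2` (1-D bounded search on
#' log lambda; the grouped structure lets all quantities be accumulated
#' per group in closed form). Fixed effects are estimated by generalized
#' least squares at the optimum; inference is Wald-z with 1.96-based 95%
#' confidence intervals. Reference levels follow the ordering of the
#' factor levels in `data`.
#'
#' @param data a measurement table (see [sampleCohort()])
#' @param formula fixed-effects formula, e.g.
#'   `response ~ sex + age_group + teeth + side + roi`
#' @param group name of the grouping column (default `"patient_id"`)
#' @return an [LmmFit-class]
#' @export
fitLmm <- function(data, formula, group = "patient_id") {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- factor(data[[group]][as.integer(rownames(mf))])
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 groups")
  g <- droplevels(g)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design error: aliased terms ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  n <- length(y); p <- ncol(X); m <- nlevels(g)
  gi <- split(seq_len(n), g)
  ni <- lengths(gi)
  # per-group sufficient statistics
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  S1x <- do.call(rbind, lapply(gi, function(i)
    colSums(X[i, , drop = FALSE])))             # m x p group sums of X
  S1y <- vapply(gi, function(i) sum(y[i]), numeric(1))

  prof <- function(loglam) {
    lam <- exp(loglam)
    gam <- lam / (1 + lam * ni)
    A <- XtX - t(S1x) %*% (S1x * gam) # X' V*^-1 X
    bvec <- Xty - t(S1x) %*% (gam * S1y)
    yy <- yty - sum(gam * S1y^2)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), bvec))
    rss <- max(yy - sum(bvec * beta), 1e-12)
    sigma2 <- rss / (n - p)
    obj <- (n - p) * log(sigma2) + sum(log1p(lam * ni)) +
      2 * sum(log(diag(ch)))
    list(obj = obj, beta = beta, sigma2 = sigma2, chol = ch, lam = lam)
  }

  opt <- stats::optimize(function(l) prof(l)$obj, interval = c(-13, 13),
                         tol = 1e-9)
  fit <- prof(opt$minimum)
  converged <- is.finite(fit$obj) # boundary lambda ~ 0 is still a valid fit
  beta <- as.numeric(fit$beta)
  Ainv <- chol2inv(fit$chol)
  vc <- fit$sigma2 * Ainv
  se <- sqrt(diag(vc))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  ct <- data.frame(term = colnames(X), estimate = beta, se = se,
                   lower = beta - 1.96 * se, upper = beta + 1.96 * se,
                   z = z, p = pval, row.names = NULL)
  sigma_e <- sqrt(fit$sigma2)
  sigma_b <- sqrt(fit$lam * fit$sigma2)
  dimnames(vc) <- list(colnames(X), colnames(X))
  new("LmmFit", coefTable = ct, sigmaB = sigma_b, sigmaE = sigma_e,
      lambda = fit$lam, nGroups = as.integer(m), nObs = as.integer(n),
      logREML = -fit$obj / 2, converged = converged, vcov = vc)
}

# midranks of a vector
midrank <- function(v) rank(v, ties.method = "average")

#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' Two-sided. With `n1 + n2 <= 12` (default) the null distribution of U is
#' enumerated over all assignments of the pooled observations, which
#' handles ties exactly; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty)
#' @param exact logical or `NULL` (auto by combined size)
#' @return list with `statistic` (U for `x`), `p_value`, `method`
#' @export
mannWhitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  if (is.null(exact)) exact <- (n1 + n2) <= 12
  pooled <- c(x, y)
  rk <- midrank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(idx) sum(rk[idx])) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sig <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_corr))
    if (sig == 0) return(list(statistic = c(U = U), p_value = 1,
                              method = "degenerate (all tied)"))
    zc <- (U - mu - 0.5 * sign(U - mu)) / sig
    p <- min(1, 2 * stats::pnorm(-abs(zc)))
    if (U == mu) p <- 1
    method <- "normal approximation, tie + continuity corrected"
  }
  list(statistic = c(U = U), p_value = p, method = method)
}

#' Wilcoxon signed-rank test (exact enumeration for small samples)
#'
#' Two-sided, on paired differences; zero differences are dropped. With
#' `n <= 12` non-zero differences the sign-pattern null distribution is
#' enumerated exactly (ties handled via midranks); otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param diffs numeric vector of differences
#' @param exact logical or `NULL` (auto by size)
#' @return list with `statistic` (W, positive-rank sum), `p_value`, `method`
#' @export
wilcoxonSignedRank <- function(diffs, exact = NULL) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("undefined test: all differences are zero")
  if (is.null(exact)) exact <- n <= 12
  rk <- midrank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  if (exact) {
    Ws <- vapply(0:(2^n - 1), function(mask)
      sum(rk[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0]),
      numeric(1))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    tie_tab <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    sig <- sqrt(sig2)
    if (sig == 0) return(list(statistic = c(W = W), p_value = 1,
                              method = "degenerate (all tied)"))
    zc <- (W - mu - 0.5 * sign(W - mu)) / sig
    p <- min(1, 2 * stats::pnorm(-abs(zc)))
    if (W == mu) p <- 1
    method <- "normal approximation, tie + continuity corrected"
  }
  list(statistic = c(W = W), p_value = p, method = method)
}

#' Average statistically dependent measurements per patient
#'
#' Collapses repeated measurements of the same palate to one row per
#' patient x condition before nonparametric testing, avoiding
#' pseudoreplication. Patient-level covariates that are constant within
#' each group are carried through.
#'
#' @param table a measurement table with a `response` column
#' @param condition names of condition columns defining the strata within
#'   patient (empty = average everything per patient)
#' @param patient name of the patient id column
#' @return reduced data.frame, one row per patient x condition
#' @export
averageDependent <- function(table, condition = character(),
                             patient = "patient_id") {
  keys <- c(patient, condition)
  key <- interaction(table[keys], drop = TRUE, lex.order = TRUE)
  resp <- tapply(table$response, key, mean)
  first <- table[!duplicated(key), , drop = FALSE]
  first <- first[order(interaction(first[keys], drop = TRUE,
                                   lex.order = TRUE)), , drop = FALSE]
  # drop columns that vary within groups (they are no longer well defined)
  constant <- vapply(names(table), function(cn) {
    if (cn %in% c(keys, "response")) return(TRUE)
    all(tapply(as.character(table[[cn]]), key,
               function(v) length(unique(v)) == 1L))
  }, logical(1))
  out <- first[, names(table)[constant], drop = FALSE]
  out$response <- as.numeric(resp[levels(key)])
  rownames(out) <- NULL
  out
}

#' Smooth an age trend with a cubic smoothing spline
#'
#' Smoothing is chosen by generalized cross-validation unless `spar` is
#' given; the fitted curve is evaluated on an age grid.
#'
#' @param ages,values paired observations (>= 4 distinct ages)
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]
#' @param n_grid number of grid points
#' @return list with `age` (grid), `fit` (curve values), `spar`, `lambda`
#'   and the underlying `smooth.spline` object as `model`
#' @export
smoothAgeTrend <- function(ages, values, spar = NULL, n_grid = 50) {
  ok <- !is.na(ages) & !is.na(values)
  ages <- ages[ok]; values <- values[ok]
  if (length(unique(ages)) < 4)
    stop("insufficient data: need at least 4 distinct ages")
  fit <- if (is.null(spar))
    stats::smooth.spline(ages, values, cv = FALSE)
  else
    stats::smooth.spline(ages, values, spar = spar)
  grid <- seq(min(ages), max(ages), length.out = n_grid)
  pred <- stats::predict(fit, grid)
  list(age = pred$x, fit = pred$y, spar = fit$spar, lambda = fit$lambda,
       model = fit)
}
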