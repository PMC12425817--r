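#' SBS-based tumor subtype assignment
#'
#' Aging activity (SBS1 + SBS5) and HRD activity (SBS3) are each cut into
#' cohort tertiles (empirical 33.33/66.67 percentiles; values equal to a
#' cut point fall in the lower tertile) and collapsed to low (T1/T2)
#' versus high (T3). The 2x2 combination defines four subtypes:
#' subtype 1 = low aging / high HRD, subtype 2 = low/low,
#' subtype 3 = high aging / low HRD, subtype 4 = high/high.
#'
#' @param exposures Samples x signatures matrix or data frame containing
#'   columns \code{SBS1}, \code{SBS5}, \code{SBS3}.
#' @param mode Use absolute counts (\code{"counts"}, default) or
#'   per-sample proportions (\code{"proportions"}) as activity.
#' @return Data frame: \code{sample_id}, \code{aging_activity},
#'   \code{hrd_activity}, \code{aging_tertile}, \code{hrd_tertile},
#'   \code{aging_level}, \code{hrd_level}, \code{subtype}.
#' @export
assign_sbs_subtype <- function(exposures, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  exposures <- as.data.frame(exposures)
  need <- c("SBS1", "SBS5", "SBS3")
  if (!all(need %in% names(exposures))) {
    stop("exposures must contain SBS1, SBS5 and SBS3 columns")
  }
  if (nrow(exposures) < 3L) stop("cohort must contain at least 3 samples")
  sample_id <- rownames(exposures)
  if (is.null(sample_id)) sample_id <- as.character(seq_len(nrow(exposures)))
  scale_tot <- if (mode == "proportions") {
    tot <- rowSums(exposures[, intersect(names(exposures),
      c("SBS1", "SBS2", "SBS3", "SBS5", "SBS13"))])
    ifelse(tot > 0, tot, 1)
  } else 1
  aging <- (exposures$SBS1 + exposures$SBS5) / scale_tot
  hrd <- exposures$SBS3 / scale_tot
  tertile <- function(x) {
    q <- stats::quantile(x, probs = c(1, 2) / 3, names = FALSE, type = 7)
    if (q[1] == q[2]) {
      stop("tertile cut points are degenerate (tied activities); ",
           "consider mode = 'proportions' or inspect the exposures")
    }
    cut_pts <- c(-Inf, q, Inf)
    as.integer(cut(x, breaks = cut_pts, labels = FALSE, right = TRUE))
  }
  aging_t <- tertile(aging)
  hrd_t <- tertile(hrd)
  aging_level <- ifelse(aging_t == 3L, "high", "low")
  hrd_level <- ifelse(hrd_t == 3L, "high", "low")
  subtype <- integer(length(aging_level))
  subtype[aging_level == "low" & hrd_level == "high"] <- 1L
  subtype[aging_level == "low" & hrd_level == "low"] <- 2L
  subtype[aging_level == "high" & hrd_level == "low"] <- 3L
  subtype[aging_level == "high" & hrd_level == "high"] <- 4L
  data.frame(sample_id = sample_id, aging_activity = aging,
             hrd_activity = hrd,
             aging_tertile = paste0("T", aging_t),
             hrd_tertile = paste0("T", hrd_t),
             aging_level = aging_level, hrd_level = hrd_level,
             subtype = subtype, stringsAsFactors = FALSE)
}

#' Two-group feature comparison (Wilcoxon rank-sum)
#'
#' Exact two-sided rank-sum p-value when the combined sample size is at
#' most 20 and there are no ties; normal approximation with tie
#' correction otherwise.
#'
#' @param x,y Numeric feature values in the two groups.
#' @return Two-sided p-value.
#' @export
compare_features <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

#' Logistic odds of subtype 1 versus subtype 3 by age and BMI
#'
#' Fits a logistic regression (IRLS via \code{stats::glm}) of subtype 1
#' (versus subtype 3) on age and BMI, reporting odds ratios per 10-year
#' age increment and per 5 kg/m2 BMI increment with Wald confidence
#' intervals and p-values. Complete separation is detected and handled by
#' a weakly ridge-penalized refit, flagged in the output.
#'
#' @param subtype Integer vector with values 1 and 3 (other subtypes are
#'   dropped).
#' @param age Age at diagnosis (years).
#' @param bmi Body mass index (kg/m2).
#' @return Data frame, one row per covariate: \code{covariate},
#'   \code{increment}, \code{or}, \code{ci_lo}, \code{ci_hi}, \code{p},
#'   \code{separation}.
#' @export
subtype_odds <- function(subtype, age, bmi) {
  keep <- subtype %in% c(1L, 3L) & !is.na(age) & !is.na(bmi)
  subtype <- subtype[keep]; age <- age[keep]; bmi <- bmi[keep]
  if (!any(subtype == 1L) || !any(subtype == 3L)) {
    stop("both subtype groups must be non-empty")
  }
  y <- as.integer(subtype == 1L)
  fit <- suppressWarnings(stats::glm(y ~ age + bmi, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8) &&
    max(abs(stats::coef(fit))) > 10
  if (sep) {
    co <- ridge_logistic(cbind(age = age, bmi = bmi), y, lambda = 1e-2)
    est <- co$coef[-1]; se <- co$se[-1]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[-1, "Estimate"]; se <- sm[-1, "Std. Error"]
  }
  inc <- c(age = 10, bmi = 5)
  data.frame(
    covariate = c("age", "bmi"), increment = unname(inc),
    or = exp(est * inc),
    ci_lo = exp((est - 1.96 * se) * inc),
    ci_hi = exp((est + 1.96 * se) * inc),
    p = 2 * stats::pnorm(-abs(est / se)),
    separation = sep, stringsAsFactors = FALSE)
}

# L2-penalized logistic regression by IRLS (intercept unpenalized)
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100L) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X1, X1 * w) + pen
    new_beta <- solve(A, crossprod(X1, w * z))
    if (max(abs(new_beta - beta)) < 1e-10) { beta <- new_beta; break }
    beta <- new_beta
  }
  cov <- solve(crossprod(X1, X1 * pmax(mu * (1 - mu), 1e-10)) + pen)
  list(coef = as.numeric(beta), se = sqrt(diag(cov)))
}

#' Kaplan-Meier curves with log-rank test
#'
#' @param time Follow-up time (months).
#' @param event Event indicator (1 = death, 0 = censored).
#' @param group Group labels.
#' @return List: \code{fit} (a \code{survival::survfit} object),
#'   \code{chisq}, \code{df}, \code{p} (log-rank; NA when no events).
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(all(time > 0))
  df <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(event) == 0 || nlevels(df$group) < 2L) {
    return(list(fit = fit, chisq = NA_real_, df = NA_integer_, p = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd$n) - 1L
  list(fit = fit, chisq = unname(sd$chisq), df = dfree,
       p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE))
}

#' Cox proportional hazards for a group contrast
#'
#' Partial-likelihood fit with Efron tie handling, optionally adjusted
#' for covariates; reports the hazard ratio of each non-reference group
#' level with Wald 95\% CI and p-value.
#'
#' @param time,event Survival time and event indicator.
#' @param group Factor (first level is the reference).
#' @param covariates Optional data frame of adjustment covariates.
#' @param ties Tie-handling method (default \code{"efron"}).
#' @return Data frame: \code{contrast}, \code{hr}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, with the fitted model as attribute
#'   \code{fit}.
#' @export
cox_hr <- function(time, event, group, covariates = NULL, ties = "efron") {
  stopifnot(all(time > 0))
  df <- data.frame(time = time, event = event, group = factor(group))
  rhs <- "group"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    rhs <- paste(c("group", names(covariates)), collapse = " + ")
  }
  nevent <- sum(event)
  if (nevent < nlevels(df$group) - 1L) stop("too few events to fit the model")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
    data = df, ties = ties)
  sm <- summary(fit)
  idx <- grep("^group", rownames(sm$coefficients))
  co <- sm$coefficients[idx, , drop = FALSE]
  out <- data.frame(
    contrast = sub("^group", "", rownames(co)),
    hr = exp(co[, "coef"]),
    ci_lo = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_hi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
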