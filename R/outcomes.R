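#' Best mRECIST response over a follow-up series
#'
#' Best response under the ordering PD < SD < PR < CR, with the earliest
#' day on which the best category was achieved. Tumours frequently migrate
#' toward response late (stable disease at 3 months converting to complete
#' response later), so the best over the whole study period is used, not
#' the first assessment.
#'
#' @param series a data.frame with columns \code{day} (>= 0) and
#'   \code{mrecist} (CR/PR/SD/PD), or its string encoding
#'   \code{"90:SD;180:CR"}.
#' @return \code{list(best = <label>, day = <earliest day achieving it>,
#'   complete_response = , objective_response = )}. Objective response is
#'   CR or PR; it is implied by complete response.
#' @export
best_response <- function(series) {
  if (is.character(series) && length(series) == 1L)
    series <- parse_mrecist_series(series)
  if (!nrow(series)) stop("empty mRECIST series")
  if (any(series$day < 0)) stop("mRECIST series days must be >= 0")
  lv <- factor(as.character(series$mrecist), levels = .mrecist_levels,
               ordered = TRUE)
  if (any(is.na(lv)))
    stop("unknown mRECIST token: ",
         as.character(series$mrecist)[is.na(lv)][1])
  best <- max(lv)
  day <- min(series$day[lv == best])
  list(best = as.character(best), day = day,
       complete_response = best == "CR",
       objective_response = best >= "PR")
}

#' Univariate screening at the multivariate entry threshold
#'
#' Fits one single-predictor model per feature — logistic regression for a
#' dichotomous outcome, or a single-covariate Cox proportional-hazards
#' model when \code{time}/\code{event} are given — and keeps features with
#' p <= alpha (default 0.20, the conventional entry threshold for
#' multivariate analysis). Constant features are excluded with a warning
#' rather than an error.
#'
#' @param data cohort data.frame.
#' @param features character vector of feature column names.
#' @param outcome name of a logical/0-1 outcome column (dichotomous route).
#' @param time,event column names for the time-to-event route.
#' @param alpha entry threshold.
#' @return data.frame (class \code{uva_screen}) with columns
#'   \code{feature}, \code{p_value}, \code{selected}.
#' @export
univariate_screen <- function(data, features, outcome = NULL, time = NULL,
                              event = NULL, alpha = 0.20) {
  survival_mode <- !is.null(time)
  if (survival_mode && is.null(event))
    stop("supply both 'time' and 'event' for the survival screen")
  if (!survival_mode && is.null(outcome))
    stop("supply 'outcome', or 'time' + 'event'")
  if (!survival_mode) {
    y <- as.integer(data[[outcome]])
    if (length(unique(y)) < 2)
      stop("need both outcome classes present")
  }
  res <- lapply(features, function(f) {
    x <- data[[f]]
    if (length(unique(x)) < 2) {
      warning("feature '", f, "' is constant; excluded from the screen")
      return(data.frame(feature = f, p_value = NA_real_, selected = FALSE))
    }
    # likelihood-ratio p-values: robust where Wald degenerates (separation)
    p <- if (survival_mode) {
      fit <- survival::coxph(
        survival::Surv(data[[time]], data[[event]]) ~ x, ties = "efron")
      unname(summary(fit)$logtest["pvalue"])
    } else {
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                    lower.tail = FALSE)
    }
    data.frame(feature = f, p_value = p, selected = is.finite(p) & p <= alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("uva_screen", "data.frame"), alpha = alpha)
}

#' Multivariate logistic regression for a dichotomous outcome
#'
#' Maximum-likelihood logistic fit with two-sided Wald p-values, predicted
#' probabilities, and the ROC AUC of the linear predictor. Requires n >
#' 10 x number of features. Before fitting, pairs of features with
#' |correlation| > 0.9 are pruned (the later-listed one is dropped with a
#' message): the Dx metrics are near-duplicates by construction and would
#' otherwise destabilise the fit. Non-convergence or quasi-separation is
#' reported as an error, never silently.
#'
#' @param data cohort data.frame.
#' @param features character vector of predictor columns.
#' @param outcome logical/0-1 outcome column name.
#' @param prune_correlated drop later-listed features with pairwise
#'   |cor| > 0.9 (default TRUE).
#' @return Object of class \code{logit_mva}: coefficient table
#'   (estimate, se, z, p), dropped features, fitted probabilities, AUC.
#' @export
logistic_mva <- function(data, features, outcome, prune_correlated = TRUE) {
  y <- as.integer(data[[outcome]])
  if (length(unique(y)) < 2) stop("need both outcome classes present")
  kept <- features
  dropped <- character(0)
  if (prune_correlated && length(features) > 1) {
    cm <- abs(stats::cor(data[, features, drop = FALSE]))
    for (j in seq_along(features)[-1]) {
      f <- features[j]
      earlier <- intersect(kept, features[seq_len(j - 1)])
      if (length(earlier) && any(cm[f, earlier] > 0.9, na.rm = TRUE)) {
        kept <- setdiff(kept, f)
        dropped <- c(dropped, f)
      }
    }
    if (length(dropped))
      message("dropped collinear feature(s): ", paste(dropped, collapse = ", "))
  }
  if (nrow(data) <= 10 * length(kept))
    stop("need n > 10 x number of features (have n = ", nrow(data),
         ", features = ", length(kept), ")")
  fml <- if (length(kept)) stats::reformulate(kept, response = ".y")
         else stats::as.formula(".y ~ 1")
  d <- data[, kept, drop = FALSE]
  d$.y <- y
  fit <- stats::glm(fml, data = d, family = stats::binomial())
  if (!fit$converged)
    stop("logistic regression did not converge")
  ct <- stats::coef(summary(fit))
  # diverging estimate + exploding SE marks quasi-complete separation;
  # merely extreme fitted probabilities from large covariates do not
  if (any(abs(ct[, 1]) > 15 & ct[, 2] > 15))
    stop("quasi-complete separation detected in logistic regression")
  prob <- stats::fitted(fit)
  colnames(ct) <- c("estimate", "se", "z", "p_value")
  auc <- if (length(kept) >= 1)
    roc_auc(stats::predict(fit, type = "link"), y == 1)$auc else NA_real_
  structure(list(coefficients = ct, features = kept, dropped = dropped,
                 fitted_probabilities = prob, auc = auc, fit = fit),
            class = "logit_mva")
}

#' @export
print.logit_mva <- function(x, ...) {
  cat(sprintf("<logit_mva> %d feature(s), AUC %.3f\n",
              length(x$features), x$auc))
  if (length(x$dropped))
    cat("  dropped (collinear):", paste(x$dropped, collapse = ", "), "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron handling of tied event times; hazard
#' ratios with Wald p-values.
#'
#' @param data cohort data.frame.
#' @param features predictor column names.
#' @param time,event column names: survival time (months, > 0) and event
#'   indicator.
#' @return Object of class \code{cox_mva}: coefficient table (coef,
#'   hazard_ratio, se, z, p), n, number of events.
#' @export
cox_mva <- function(data, features, time, event) {
  tt <- data[[time]]; ev <- as.integer(data[[event]])
  if (any(tt <= 0)) stop("survival times must be > 0")
  if (sum(ev) < 1) stop("all records censored: no events to model")
  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                  ") ~ ", paste(features, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  s <- summary(fit)
  ct <- cbind(coef = s$coefficients[, "coef"],
              hazard_ratio = s$coefficients[, "exp(coef)"],
              se = s$coefficients[, "se(coef)"],
              z = s$coefficients[, "z"],
              p_value = s$coefficients[, "Pr(>|z|)"])
  rownames(ct) <- rownames(s$coefficients)
  structure(list(coefficients = ct, n = s$n, n_events = s$nevent, fit = fit),
            class = "cox_mva")
}

#' @export
print.cox_mva <- function(x, ...) {
  cat(sprintf("<cox_mva> n = %d, events = %d (Efron ties)\n", x$n, x$n_events))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit survival estimates per group, group medians (the first
#' time the curve drops to 0.5 or below; undefined if it never does), and
#' the two-sided unstratified log-rank test.
#'
#' @param time survival times (months).
#' @param event event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @param group two-level grouping vector.
#' @return Object of class \code{km_logrank}: per-group curve data.frames
#'   (time, surv, n_risk, n_event), medians, log-rank chi-square and p.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("need exactly two non-empty groups")
  if (sum(event) < 1) stop("no events observed")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_id <- rep(seq_along(fit$strata), fit$strata)
  curves <- lapply(seq_along(fit$strata), function(k) {
    sel <- strata_id == k
    data.frame(time = fit$time[sel], surv = fit$surv[sel],
               n_risk = fit$n.risk[sel], n_event = fit$n.event[sel])
  })
  names(curves) <- sub("^group=", "", names(fit$strata))
  medians <- vapply(curves, function(cv) {
    i <- which(cv$surv <= 0.5)
    if (length(i)) cv$time[min(i)] else NA_real_
  }, numeric(1))
  lr <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, medians = medians,
                 logrank_chisq = lr$chisq, p_value = p),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("<km_logrank>\n")
  for (g in names(x$curves))
    cat(sprintf("  %s: median %s months\n", g,
                ifelse(is.na(x$medians[g]), "not reached",
                       sprintf("%.1f", x$medians[g]))))
  cat(sprintf("  log-rank chi-square %.3f, p = %.4g\n",
              x$logrank_chisq, x$p_value))
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, col = c(1, 2), ...) {
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(x$curves, `[[`, "time")))),
                 ylim = c(0, 1), xlab = "Months", ylab = "Survival fraction",
                 ...)
  for (k in seq_along(x$curves)) {
    cv <- x$curves[[k]]
    graphics::lines(c(0, cv$time), c(1, cv$surv), type = "s", col = col[k])
  }
  graphics::legend("topright", legend = names(x$curves), col = col, lty = 1)
  invisible(x)
}

#' One-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Classical one-way F test plus Fisher's Least Significant Difference
#' pairwise t tests on the pooled within-group variance (no multiplicity
#' adjustment, as is conventional for LSD after a significant F). Dose
#' comparisons between responders and non-responders are conventionally
#' one-sided (the hypothesis is directional: responders receive more);
#' \code{one_sided = TRUE} halves the pairwise p when the observed
#' difference lies in the hypothesized direction (earlier factor level
#' larger) and takes the complement otherwise.
#'
#' @param values numeric response vector.
#' @param group grouping factor (>= 2 groups, >= 2 values each).
#' @param one_sided make pairwise LSD tests one-sided.
#' @return Object of class \code{anova_lsd}: F, df, p, group means, and a
#'   pairwise table.
#' @export
anova_lsd <- function(values, group, one_sided = FALSE) {
  group <- as.factor(group)
  tab <- table(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("each group needs >= 2 values")
  if (all(tapply(values, group, stats::var) == 0))
    stop("zero within-group variance in all groups")
  fit <- stats::aov(values ~ group)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfr <- an["Residuals", "Df"]
  means <- tapply(values, group, mean)
  lev <- levels(group)
  pairs <- utils::combn(lev, 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(mse * (1 / tab[[i]] + 1 / tab[[j]]))
    tstat <- diff / se
    p2 <- 2 * stats::pt(-abs(tstat), dfr)
    p <- if (!one_sided) p2
         else if (diff > 0) p2 / 2 else 1 - p2 / 2
    data.frame(group1 = i, group2 = j, diff = diff, se = se, t = tstat,
               p_value = p)
  })
  pw <- do.call(rbind, pw)
  rownames(pw) <- NULL
  structure(list(F = an["group", "F value"], df = c(an["group", "Df"], dfr),
                 p_value = an["group", "Pr(>F)"], group_means = means,
                 pairwise = pw, one_sided = one_sided),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("<anova_lsd> F(%d, %d) = %.4f, p = %.4g%s\n",
              x$df[1], x$df[2], x$F, x$p_value,
              if (x$one_sided) " (pairwise one-sided)" else ""))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' ROC curve and AUC by the trapezoidal rule
#'
#' Builds the full ROC curve over the observed score thresholds and
#' integrates it by trapezoids; with ties counted one half this equals the
#' Mann-Whitney U statistic divided by n1*n2. The direction is
#' auto-oriented: if higher scores associate with the negative class the
#' score is flipped and \code{direction = "negative"} is reported, so the
#' returned AUC is always >= 0.5.
#'
#' @param score numeric predictor.
#' @param outcome logical (or 0/1) class labels; both classes required.
#' @return Object of class \code{roc_curve}: \code{auc}, \code{direction}
#'   (\code{"positive"} or \code{"negative"}), and the curve data.frame
#'   (threshold, fpr, tpr).
#' @export
roc_auc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  if (length(score) != length(outcome)) stop("length mismatch")
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  curve <- roc_points(score, outcome)
  auc <- trapezoid_auc(curve$fpr, curve$tpr)
  direction <- "positive"
  if (auc < 0.5) {
    curve <- roc_points(-score, outcome)
    auc <- trapezoid_auc(curve$fpr, curve$tpr)
    curve$threshold <- -curve$threshold
    direction <- "negative"
  }
  structure(list(auc = auc, direction = direction, curve = curve),
            class = "roc_curve")
}

roc_points <- function(score, outcome) {
  th <- sort(unique(score), decreasing = TRUE)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  tpr <- vapply(th, function(t) sum(score >= t & outcome) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(score >= t & !outcome) / n0, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- c(fpr[o], 1); tpr <- c(tpr[o], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f (%s direction), %d thresholds\n",
              x$auc, x$direction, nrow(x$curve) - 1))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
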