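check_labels <- function(labels) {
  y <- as.logical(labels)
  if (any(is.na(y))) stop_nm("labels must be binary with no NA")
  if (!any(y) || all(y)) stop_nm("both outcome classes must be present")
  y
}

# Placement values of the Mann-Whitney AUC: V10 per positive, V01 per
# negative; mean of either is the AUC (ties counted 1/2).
placements <- function(scores, y) {
  x <- scores[y]; z <- scores[!y]
  m <- length(x); n <- length(z)
  r_all <- rank(c(x, z), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(z, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Mann-Whitney AUC
#'
#' Area under the empirical ROC curve: the proportion of
#' positive-negative score pairs ranked concordantly, ties counted 1/2.
#'
#' @param scores numeric predictor values (higher = more likely positive).
#' @param labels binary outcome, coercible to logical.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  y <- check_labels(labels)
  placements(scores, y)$auc
}

delong_var <- function(pl) {
  stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
}

#' Empirical ROC curve with DeLong confidence interval
#'
#' Sensitivity/specificity over all score thresholds, the Mann-Whitney
#' AUC, and a Wald confidence interval using the DeLong variance
#' estimator. With `direction = "auto"` the score is negated when its raw
#' AUC falls below 0.5, so predictors whose low values indicate the event
#' (e.g. coma scores) are oriented automatically; the orientation is
#' recorded.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome.
#' @param name score label carried into reports.
#' @param direction `"auto"`, `">"` (higher score = positive) or `"<"`.
#' @param conf confidence level (default 0.95).
#' @return Object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `ci`, `se`, `direction`, `name`, `oriented_scores`.
#' @export
roc_curve <- function(scores, labels, name = deparse(substitute(scores)),
                      direction = c("auto", ">", "<"), conf = 0.95) {
  y <- check_labels(labels)
  direction <- match.arg(direction)
  if (direction == "auto")
    direction <- if (auc_mw(scores, y) >= 0.5) ">" else "<"
  s <- if (direction == ">") scores else -scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(s[y] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!y] < t), numeric(1))
  pl <- placements(s, y)
  se <- sqrt(delong_var(pl))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = pl$auc,
                 ci = c(max(0, pl$auc - zq * se), min(1, pl$auc + zq * se)),
                 se = se, direction = direction, name = name,
                 oriented_scores = s, labels = y),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %s: AUC %.3f (%.3f-%.3f), direction '%s'\n",
              x$name, x$auc, x$ci[1], x$ci[2], x$direction))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("%s (AUC %.3f)", x$name, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' placement-value covariance estimator; `z = dAUC / SE(dAUC)` is referred
#' to the standard normal, two-sided. Identical scores give a degenerate
#' zero-variance comparison, reported with `p = 1`.
#'
#' @param scores_a,scores_b paired numeric scores.
#' @param labels binary outcome common to both.
#' @param names length-2 character, model labels.
#' @return Object of class `delong_comparison`: `auc_a`, `auc_b`, `delta`,
#'   `se`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        names = c("A", "B")) {
  y <- check_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stop_nm("scores must be paired on identical subjects")
  pa <- placements(scores_a, y)
  pb <- placements(scores_b, y)
  v <- stats::var(pa$v10) / pa$m + stats::var(pb$v10) / pa$m -
    2 * stats::cov(pa$v10, pb$v10) / pa$m +
    stats::var(pa$v01) / pa$n + stats::var(pb$v01) / pa$n -
    2 * stats::cov(pa$v01, pb$v01) / pa$n
  v <- max(v, 0)
  delta <- pa$auc - pb$auc
  if (v == 0) {
    degenerate <- TRUE
    z <- 0
    p <- if (abs(delta) < .Machine$double.eps^0.5) 1 else 0
  } else {
    degenerate <- FALSE
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 se = sqrt(v), z = z, p = p, degenerate = degenerate,
                 names = names),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("<delong_comparison> %s (AUC %.3f) vs %s (AUC %.3f): dAUC %+.3f, z = %.2f, p = %.4g%s\n",
              x$names[1], x$auc_a, x$names[2], x$auc_b, x$delta, x$z, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

glm_wald_table <- function(fit, conf = 0.95) {
  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             z = sm[, 3], p = sm[, 4],
             or = exp(sm[, 1]),
             ci_lo = exp(sm[, 1] - zq * sm[, 2]),
             ci_hi = exp(sm[, 1] + zq * sm[, 2]),
             row.names = NULL)
}

check_fit <- function(fit, vars) {
  co <- stats::coef(fit)[-1]
  eps <- 1e-8
  bad <- !fit$converged | any(abs(co) > 15, na.rm = TRUE) |
    (any(fit$fitted.values > 1 - eps) && any(fit$fitted.values < eps) &&
       max(abs(co), na.rm = TRUE) > 10)
  if (bad) {
    worst <- if (length(co)) names(co)[which.max(abs(co))] else "(intercept)"
    stop_nm("logistic fit failed (non-convergence or separation); ",
            "offending variable: ", worst)
  }
}

#' Backward stepwise logistic regression
#'
#' Fits a binomial GLM on the candidate variables and iteratively removes
#' the least significant one (largest Wald p above `removal_alpha`,
#' default 0.10), refitting after each removal, until every remaining
#' variable satisfies the criterion. Wald confidence intervals on the
#' odds ratios. A full step log is retained.
#'
#' @param records data.frame of covariates and outcome.
#' @param candidates names of candidate predictor columns (typically the
#'   univariate-screen survivors).
#' @param outcome binary outcome column name (default `"died90"`).
#' @param removal_alpha retention threshold on the Wald p (default 0.10);
#'   1 keeps the full model, 0 reduces to intercept-only.
#' @param conf confidence level for odds-ratio intervals.
#' @return Object of class `logistic_model`: `coefficients` (term,
#'   estimate, se, z, p, or, ci_lo, ci_hi), `fitted`, `retained`,
#'   `steps` (removal log), `fit` (the final `glm`).
#' @export
backward_logistic <- function(records, candidates, outcome = "died90",
                              removal_alpha = 0.10, conf = 0.95) {
  y <- check_labels(records[[outcome]])
  miss <- setdiff(candidates, names(records))
  if (length(miss)) stop_nm("candidate column(s) not found: ",
                            paste(miss, collapse = ", "))
  if (min(sum(y), sum(!y)) < 5 * length(candidates))
    warning("fewer than 5 events per candidate variable; estimates may be unstable")
  dat <- records[, candidates, drop = FALSE]
  dat$.y <- y
  vars <- candidates
  steps <- list()
  repeat {
    fml <- if (length(vars)) stats::reformulate(vars, ".y") else .y ~ 1
    fit <- stats::glm(fml, family = stats::binomial(), data = dat)
    check_fit(fit, vars)
    if (!length(vars)) break
    tab <- glm_wald_table(fit, conf)
    ptab <- tab[tab$term != "(Intercept)", ]
    worst <- which.max(ptab$p)
    if (ptab$p[worst] <= removal_alpha) break
    steps[[length(steps) + 1]] <- data.frame(step = length(steps) + 1,
                                             removed = ptab$term[worst],
                                             p = ptab$p[worst])
    vars <- setdiff(vars, ptab$term[worst])
  }
  structure(list(coefficients = glm_wald_table(fit, conf),
                 fitted = unname(fit$fitted.values),
                 retained = vars,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(step = integer(), removed = character(),
                                         p = numeric()),
                 removal_alpha = removal_alpha, fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> retained: %s\n",
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(intercept only)"))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  if (nrow(x$steps)) {
    cat("removal log:\n")
    print(x$steps, row.names = FALSE)
  }
  invisible(x)
}

#' Compare the five candidate prognostic models
#'
#' Builds ROC curves for the four single-variable models (admission coma
#' score, hematoma volume, unaffected-side pulsatility index, delta/alpha
#' ratio) and for the combined Doppler+EEG model whose score is the fitted
#' probability of a logistic regression on UPI and DAR together, then runs
#' pairwise DeLong tests of the combined model against each single model.
#' Single-variable scores are auto-oriented so each AUC is at least 0.5.
#'
#' @param records cohort data.frame carrying the model variables and outcome.
#' @param vars named character vector mapping the canonical model names
#'   `gcs`, `volume`, `upi`, `dar` to columns of `records`.
#' @param outcome binary outcome column (default `"died90"`).
#' @return Object of class `model_comparison`: `aucs` (model, auc, ci_lo,
#'   ci_hi), `comparisons` (combined vs each single: delta, z, p), `rocs`
#'   (list of [roc_curve] objects), `combined_fit` (the logistic model).
#' @export
compare_five_models <- function(records,
                                vars = c(gcs = "gcs", volume = "hematoma_volume",
                                         upi = "upi", dar = "dar"),
                                outcome = "died90") {
  y <- check_labels(records[[outcome]])
  miss <- setdiff(vars, names(records))
  if (length(miss)) stop_nm("column(s) not found: ", paste(miss, collapse = ", "))
  dat <- data.frame(upi = records[[vars[["upi"]]]],
                    dar = records[[vars[["dar"]]]], .y = y)
  fit <- stats::glm(.y ~ upi + dar, family = stats::binomial(), data = dat)
  check_fit(fit, c("upi", "dar"))
  scores <- list(gcs = records[[vars[["gcs"]]]],
                 volume = records[[vars[["volume"]]]],
                 upi = records[[vars[["upi"]]]],
                 dar = records[[vars[["dar"]]]],
                 combined = unname(fit$fitted.values))
  rocs <- lapply(names(scores), function(nm)
    roc_curve(scores[[nm]], y, name = nm, direction = "auto"))
  names(rocs) <- names(scores)
  aucs <- data.frame(model = names(rocs),
                     auc = vapply(rocs, `[[`, numeric(1), "auc"),
                     ci_lo = vapply(rocs, function(r) r$ci[1], numeric(1)),
                     ci_hi = vapply(rocs, function(r) r$ci[2], numeric(1)),
                     row.names = NULL)
  singles <- setdiff(names(scores), "combined")
  comparisons <- do.call(rbind, lapply(singles, function(nm) {
    dl <- delong_test(rocs$combined$oriented_scores, rocs[[nm]]$oriented_scores,
                      y, names = c("combined", nm))
    data.frame(model_a = "combined", model_b = nm, auc_a = dl$auc_a,
               auc_b = dl$auc_b, delta = dl$delta, z = dl$z, p = dl$p)
  }))
  structure(list(aucs = aucs, comparisons = comparisons, rocs = rocs,
                 combined_fit = fit),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  tab <- x$aucs; tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  cat("DeLong tests, combined vs single:\n")
  tab <- x$comparisons
  tab[3:7] <- lapply(tab[3:7], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
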