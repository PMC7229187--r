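# The SIOI construction and evaluation chain: LASSO-penalized Cox
# screening (glmnet, 10-fold CV), random-forest mean-decrease-Gini ranking
# (500 trees, classification on the disease-specific-death label),
# correlation pruning, maximally selected log-rank cutpoints, iterative
# removal of the least significant component, combinatorial categorization
# (+/+/+ ... -/-/-), and univariate / forward-stepwise Cox and KM
# evaluation with censoring horizons.

# ---- survival utilities ----------------------------------------------------

#' Censor a survival table at an administrative horizon
#'
#' @param survival Data frame with `time_months` and `event`.
#' @param horizon_months Horizon (> 0).
#' @return The table with times truncated at the horizon and events beyond
#'   it recoded as censored.
#' @export
censor_at <- function(survival, horizon_months) {
  if (horizon_months <= 0) stop("horizon must be positive")
  over <- survival$time_months > horizon_months
  survival$event[over] <- 0L
  survival$time_months[over] <- horizon_months
  survival
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; monotone
#' likelihood (perfect separation) is flagged, not silently returned as a
#' huge finite coefficient.
#'
#' @param x Predictor (numeric vector or factor).
#' @param survival Data frame with `time_months`, `event`.
#' @return A `cox_fit` list: `coef`, `hr`, `ci_lower`, `ci_upper`, `p`
#'   (Wald), `loglik`, `n_events`, `infinite_flag`.
#' @export
cox_univariate <- function(x, survival) {
  if (sum(survival$event) < 1) stop("at least one event is required")
  if (length(unique(x[!is.na(x)])) < 2) {
    stop("predictor must take at least two distinct values")
  }
  dat <- data.frame(time = survival$time_months, event = survival$event, x = x)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  k <- nrow(co)
  structure(list(
    coef = unname(co[k, "coef"]),
    hr = unname(co[k, "exp(coef)"]),
    ci_lower = unname(ci[k, 3]),
    ci_upper = unname(ci[k, 4]),
    p = unname(co[k, "Pr(>|z|)"]),
    loglik = fit$loglik[2],
    n_events = sum(dat$event),
    infinite_flag = warned || abs(co[k, "coef"]) > 15,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: HR = %.3f (95%% CI %.3f-%.3f), p = %.4g, events = %d%s\n",
              x$hr, x$ci_lower, x$ci_upper, x$p, x$n_events,
              if (x$infinite_flag) " [monotone-likelihood flag]" else ""))
  invisible(x)
}

#' Forward-stepwise multivariate Cox regression
#'
#' Enters predictors one at a time by likelihood-ratio test at `entry_p`,
#' recording the order of entry. A collinear duplicate of an entered
#' predictor adds no partial likelihood and never enters.
#'
#' @param predictors Data frame of candidate predictors (complete cases).
#' @param survival Data frame with `time_months`, `event`.
#' @param entry_p Likelihood-ratio entry threshold (default 0.05).
#' @return List with `entered` (names in entry order), `fit` (final
#'   `coxph` or NULL), `trace` (per-step candidate p-values), `note`.
#' @export
cox_multivariate_forward <- function(predictors, survival, entry_p = 0.05) {
  dat <- cbind(data.frame(time = survival$time_months,
                          event = survival$event), predictors)
  cand <- names(predictors)
  entered <- character(0)
  trace <- list()
  ll_current <- survival::coxph(survival::Surv(time, event) ~ 1,
                                data = dat)$loglik[1]
  fit_current <- NULL
  repeat {
    remaining <- setdiff(cand, entered)
    if (!length(remaining)) break
    pvals <- vapply(remaining, function(v) {
      f <- tryCatch(suppressWarnings(survival::coxph(
        stats::reformulate(c(entered, v), response = "survival::Surv(time, event)"),
        data = dat, ties = "efron")), error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      lr <- 2 * (f$loglik[2] - if (is.null(fit_current)) ll_current
                 else fit_current$loglik[2])
      if (!is.finite(lr) || lr <= 0) return(1)
      stats::pchisq(lr, df = 1, lower.tail = FALSE)
    }, numeric(1))
    trace[[length(trace) + 1]] <- pvals
    best <- which.min(pvals)
    if (!length(best) || is.na(pvals[best]) || pvals[best] >= entry_p) break
    entered <- c(entered, remaining[best])
    fit_current <- suppressWarnings(survival::coxph(
      stats::reformulate(entered, response = "survival::Surv(time, event)"),
      data = dat, ties = "efron"))
  }
  list(entered = entered, fit = fit_current, trace = trace,
       note = if (!length(entered)) "no predictor met the entry criterion" else NULL)
}

#' Kaplan-Meier curves with a log-rank test
#'
#' @param group Grouping vector (factor/character).
#' @param survival Data frame with `time_months`, `event`.
#' @return List with `curves` (data frame: group, time, n_risk, n_event,
#'   surv), `logrank_p` (NA for a single group), and the `survfit` object.
#' @export
km_curves <- function(group, survival) {
  g <- as.factor(group)
  empty <- levels(g)[tabulate(g, nbins = nlevels(g)) == 0]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  dat <- data.frame(time = survival$time_months, event = survival$event, g = g)
  sf <- survival::survfit(survival::Surv(time, event) ~ g, data = dat)
  strata <- if (is.null(sf$strata)) {
    rep(levels(g)[1], length(sf$time))
  } else {
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  curves <- data.frame(group = strata, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  logrank_p <- NA_real_
  if (nlevels(g) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
    logrank_p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1,
                               lower.tail = FALSE)
  }
  list(curves = curves, logrank_p = logrank_p, survfit = sf)
}

#' KM survival probability of each group at a landmark time
#'
#' @inheritParams km_curves
#' @param at_months Landmark time.
#' @return Named vector of S(at_months) per group (1 when no event has
#'   occurred by then; the last estimate is carried forward beyond follow-up).
#' @export
km_survival_at <- function(group, survival, at_months) {
  g <- as.factor(group)
  out <- stats::setNames(rep(NA_real_, nlevels(g)), levels(g))
  for (lv in levels(g)) {
    idx <- which(g == lv)
    if (!length(idx)) next
    sf <- survival::survfit(
      survival::Surv(time_months, event) ~ 1, data = survival[idx, ])
    sm <- summary(sf, times = at_months, extend = TRUE)
    out[lv] <- sm$surv
  }
  out
}

# ---- log-rank statistic and cutpoints -------------------------------------

# Standardized log-rank statistic for a binary split: z = (O1 - E1)/sqrt(V)
# with the hypergeometric variance at each distinct event time. group is
# logical (TRUE = "group 1", the side above the candidate cutoff).
# Vectorised over event times so the cutpoint scan stays cheap.
logrank_z <- function(time, event, group) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  group <- as.logical(group)[ord]
  n <- length(time)
  is_ev <- event == 1
  if (!any(is_ev)) return(list(z = 0, o1 = 0, e1 = 0, v = 0))
  et <- unique(time[is_ev])              # sorted, since time is sorted
  n_lt <- findInterval(et, time, left.open = TRUE)  # subjects with t < et
  n_t <- n - n_lt
  suf_g <- rev(cumsum(rev(group)))       # group members with t >= time[i]
  n1_t <- suf_g[n_lt + 1L]
  m <- match(time[is_ev], et)
  d_t <- tabulate(m, length(et))
  d1_t <- as.numeric(rowsum(as.numeric(group[is_ev]), m))
  o1 <- sum(d1_t)
  e1 <- sum(d_t * n1_t / n_t)
  ok <- n_t > 1
  v <- sum((d_t * (n1_t / n_t) * (1 - n1_t / n_t) *
              (n_t - d_t) / (n_t - 1))[ok])
  z <- if (v > 0) (o1 - e1) / sqrt(v) else 0
  list(z = z, o1 = o1, e1 = e1, v = v)
}

#' Optimal survival cutpoint by the maximally selected log-rank statistic
#'
#' Scans candidate cutoffs (midpoints between sorted distinct values) whose
#' splits leave both groups with at least `min_group_prop` of the cohort,
#' and picks the cutoff maximizing |z| of the standardized log-rank
#' statistic; ties go to the smallest cutoff. The favorable direction is
#' the side of the cut with higher survival (fewer deaths than expected).
#'
#' @param values Feature values (raw scale).
#' @param survival Data frame with `time_months`, `event`.
#' @param min_group_prop Minimum group share (default 0.1).
#' @param feature Optional feature name stored in the rule.
#' @return A `cutpoint_rule`: `feature`, `cutoff`, `favorable_direction`
#'   (`"above"`/`"below"`), `statistic` (|z|).
#' @export
optimal_cutpoint <- function(values, survival, min_group_prop = 0.1,
                             feature = NA_character_) {
  ok <- is.finite(values)
  v <- values[ok]
  time <- survival$time_months[ok]
  event <- survival$event[ok]
  if (length(unique(v)) < 2) stop("constant feature: no cutpoint exists")
  if (sum(event) < 1) stop("at least one event is required")
  n <- length(v)
  uv <- sort(unique(v))
  cands <- (uv[-1] + uv[-length(uv)]) / 2
  n_above <- vapply(cands, function(c) sum(v > c), 0L)
  admissible <- n_above >= min_group_prop * n &
    (n - n_above) >= min_group_prop * n
  cands <- cands[admissible]
  if (!length(cands)) stop("no admissible cutoff under the group-size constraint")
  best_z <- -Inf
  best_cut <- NA_real_
  best_sign <- 0
  for (c in cands) {
    lr <- logrank_z(time, event, v > c)
    if (abs(lr$z) > best_z + 1e-12) {   # strict improvement: ties keep the
      best_z <- abs(lr$z)               # smallest cutoff (cands are sorted)
      best_cut <- c
      best_sign <- sign(lr$o1 - lr$e1)
    }
  }
  structure(list(
    feature = feature,
    cutoff = best_cut,
    favorable_direction = if (best_sign < 0) "above" else "below",
    statistic = best_z
  ), class = "cutpoint_rule")
}

#' Binarize a feature against a cutpoint rule
#'
#' The favorable flag is strict: `value > cutoff` for direction "above",
#' `value < cutoff` for "below"; equality — including values within 1e-9
#' relative of the cutoff, so a ratio computed in floating point still
#' lands on its boundary — is unfavorable. Missing values
#' yield `NA`, except TB-proximity features of zero-bud cases under the
#' "favorable" policy (absent budding is the prognostically good state),
#' which are flagged favorable.
#'
#' @param values Feature values (raw scale).
#' @param rule A [optimal_cutpoint()] rule.
#' @param zero_bud Logical vector marking zero-bud patients (optional).
#' @param zero_bud_policy `"favorable"` (default), `"missing"`, `"zero"`.
#' @return Logical favorable flags (NA = missing, patient excluded from
#'   the index with a logged reason).
#' @export
binarize <- function(values, rule, zero_bud = NULL,
                     zero_bud_policy = "favorable") {
  if (!is.null(zero_bud) && zero_bud_policy == "zero") {
    values[zero_bud & !is.finite(values)] <- 0
  }
  eps <- 1e-9 * max(1, abs(rule$cutoff))
  flag <- if (rule$favorable_direction == "above") values > rule$cutoff + eps
          else values < rule$cutoff - eps
  flag[is.infinite(values)] <- (rule$favorable_direction == "above") ==
    (values[is.infinite(values)] > 0)
  if (!is.null(zero_bud) && zero_bud_policy == "favorable") {
    flag[zero_bud & is.na(flag)] <- TRUE
  }
  flag
}

# ---- screening chain -------------------------------------------------------

#' LASSO-penalized Cox feature screening
#'
#' Features are z-scored, then fit with `glmnet` (coordinate descent) under
#' the Cox partial likelihood; lambda is chosen by k-fold cross-validated
#' deviance at the minimum (or the one-standard-error rule). Constant
#' columns are dropped with a warning; non-finite values are imputed with
#' the column median (both recorded in the result).
#'
#' @param features Numeric matrix / data frame (patients x features).
#' @param survival Data frame with `time_months`, `event`.
#' @param folds CV folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param lambda Optional fixed lambda (skips cross-validation).
#' @return List: `selected`, `coefficients` (named, at the chosen lambda),
#'   `lambda`, `dropped_constant`, `imputed`, `cv` (lambda/deviance path).
#' @export
lasso_cox_select <- function(features, survival, folds = 10, seed = 1L,
                             lambda_rule = c("min", "1se"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (sum(survival$event) < 1) stop("at least one event is required")
  imputed <- character(0)
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) {
      X[bad, j] <- stats::median(X[!bad, j])
      imputed <- c(imputed, colnames(X)[j])
    }
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  Xs <- scale(X)
  y <- survival::Surv(survival$time_months, survival$event)
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(Xs, y, family = "cox", standardize = FALSE)
    beta <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
    names(beta) <- rownames(stats::coef(fit, s = lambda))
    lam <- lambda
    cvout <- NULL
  } else {
    set.seed(seed)
    foldid <- sample(rep(seq_len(folds), length.out = nrow(Xs)))
    cv <- glmnet::cv.glmnet(Xs, y, family = "cox", foldid = foldid,
                            standardize = FALSE)
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    beta <- as.numeric(stats::coef(cv, s = lam))
    names(beta) <- rownames(stats::coef(cv, s = lam))
    cvout <- list(lambda = cv$lambda, cvm = cv$cvm, lambda_min = cv$lambda.min,
                  lambda_1se = cv$lambda.1se)
  }
  nz <- beta[beta != 0]
  list(selected = names(nz), coefficients = nz, lambda = lam,
       dropped_constant = dropped, imputed = imputed, cv = cvout)
}

#' Random-forest mean-decrease-Gini ranking
#'
#' Fits a 500-tree classification forest on the binary disease-specific
#' death label and ranks features by mean decrease in Gini impurity (sum of
#' impurity decreases at splits on the feature, averaged over trees); the
#' out-of-bag error is attached.
#'
#' @param features Numeric matrix / data frame of the candidate features.
#' @param event Binary death labels.
#' @param n_trees Number of trees (default 500).
#' @param seed Seed for the forest.
#' @return Data frame (`feature`, `gini`) in decreasing Gini order, with
#'   attribute `oob_error`.
#' @export
rf_gini_rank <- function(features, event, n_trees = 500, seed = 1L) {
  y <- factor(event, levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("both event classes must be present")
  }
  X <- as.data.frame(features)
  for (j in seq_along(X)) {
    bad <- !is.finite(X[[j]])
    if (any(bad)) X[[j]][bad] <- stats::median(X[[j]][!bad])
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees)
  gini <- rf$importance[, "MeanDecreaseGini"]
  out <- data.frame(feature = rownames(rf$importance),
                    gini = as.numeric(gini), stringsAsFactors = FALSE)
  out <- out[order(-out$gini, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "oob_error") <- unname(rf$err.rate[n_trees, "OOB"])
  out
}

#' Keep features with mean decrease Gini strictly above a threshold
#'
#' @param ranked Data frame from [rf_gini_rank()].
#' @param threshold Gini threshold (default 3.0).
#' @return The filtered data frame (possibly empty).
#' @export
gini_filter <- function(ranked, threshold = 3.0) {
  ranked[ranked$gini > threshold, , drop = FALSE]
}

#' Greedy correlation pruning
#'
#' Walks the candidates in decreasing Gini order and keeps a feature iff
#' its absolute Spearman correlation with every already-kept feature is
#' below `prune_threshold` — of any highly correlated pair, only the one
#' with the higher Gini survives.
#'
#' @param ranked Data frame (`feature`, `gini`) in decreasing Gini order.
#' @param spearman Correlation matrix covering the candidate features.
#' @param prune_threshold Absolute-correlation threshold (default 0.8).
#' @return The kept subset of `ranked`, plus attribute `pruned_pairs`.
#' @export
prune_correlated <- function(ranked, spearman, prune_threshold = 0.8) {
  kept <- character(0)
  pruned <- list()
  for (i in seq_len(nrow(ranked))) {
    f <- ranked$feature[i]
    r <- abs(spearman[f, kept])
    r[is.na(r)] <- 0
    if (!length(kept) || all(r < prune_threshold)) {
      kept <- c(kept, f)
    } else {
      pruned[[length(pruned) + 1]] <- list(
        dropped = f, against = kept[which.max(r)], r = max(r))
    }
  }
  out <- ranked[ranked$feature %in% kept, , drop = FALSE]
  attr(out, "pruned_pairs") <- pruned
  out
}

# ---- index assembly --------------------------------------------------------

#' Iterative refinement of the component set
#'
#' Starting from all candidate components (binary favorable flags), the
#' loop fits a univariate Cox model to the combinatorial index (count of
#' favorable flags, ordinal, encoded so that fewer favorable flags means
#' higher hazard), identifies the component whose own univariate Cox p is
#' largest, tentatively removes it, and commits the removal only if the
#' index criterion (Wald p by default, likelihood-ratio chi-square
#' alternatively) does not worsen. Deterministic given its input.
#'
#' @param flags Logical matrix (patients x components), complete rows used.
#' @param survival Data frame with `time_months`, `event`.
#' @param criterion `"wald"` (default) or `"lrt"`.
#' @return List: `kept` (component names), `trace` (per-step record).
#' @export
iterative_refine <- function(flags, survival, criterion = c("wald", "lrt")) {
  criterion <- match.arg(criterion)
  flags <- as.matrix(flags)
  if (is.null(colnames(flags))) {
    colnames(flags) <- paste0("component_", seq_len(ncol(flags)))
  }
  crit_p <- function(cols) {
    idx <- rowSums(!flags[, cols, drop = FALSE])  # unfavorable count
    if (length(unique(idx[stats::complete.cases(idx)])) < 2) return(Inf)
    f <- cox_univariate(idx, survival)
    if (criterion == "wald") f$p else {
      null_ll <- survival::coxph(
        survival::Surv(survival$time_months, survival$event) ~ 1)$loglik[1]
      stats::pchisq(2 * (f$loglik - null_ll), df = 1, lower.tail = FALSE)
    }
  }
  current <- colnames(flags)
  p_current <- crit_p(current)
  trace <- list(list(step = "initial", components = current, p = p_current))
  while (length(current) > 1) {
    comp_p <- vapply(current, function(cl) {
      v <- flags[, cl]
      if (length(unique(v[!is.na(v)])) < 2) return(Inf)
      cox_univariate(as.numeric(!v), survival)$p
    }, numeric(1))
    worst <- names(which.max(comp_p))
    cand <- setdiff(current, worst)
    p_cand <- crit_p(cand)
    step <- list(step = "try_remove", removed = worst,
                 component_p = comp_p, p_before = p_current, p_after = p_cand)
    if (!is.finite(p_cand) || p_cand > p_current) {
      step$decision <- "undo"
      trace[[length(trace) + 1]] <- step
      break
    }
    step$decision <- "commit"
    trace[[length(trace) + 1]] <- step
    current <- cand
    p_current <- p_cand
  }
  list(kept = current, trace = trace)
}

#' Assign the combinatorial SIOI category
#'
#' With k components (k = 3 in the published index), the favorable-count
#' tiers are: all favorable -> "+/+/+" (tier-2 low-risk), exactly one
#' unfavorable -> "+/+/-", otherwise "+/-/- or -/-/-". Patients with a
#' missing flag are excluded (NA category) and listed in the `excluded`
#' attribute.
#'
#' @param flags Logical matrix (patients x components) of favorable flags.
#' @return Data frame: `n_favorable`, `tier3`, `tier2`.
#' @export
sioi_assign <- function(flags) {
  flags <- as.matrix(flags)
  k <- ncol(flags)
  n_fav <- rowSums(flags)
  tier3 <- ifelse(n_fav == k, "+/+/+",
                  ifelse(n_fav == k - 1, "+/+/-", "+/-/- or -/-/-"))
  tier3 <- factor(tier3, levels = c("+/+/+", "+/+/-", "+/-/- or -/-/-"))
  tier2 <- factor(ifelse(n_fav == k, "low-risk", "high-risk"),
                  levels = c("low-risk", "high-risk"))
  out <- data.frame(n_favorable = n_fav, tier3 = tier3, tier2 = tier2)
  excl <- which(is.na(n_fav))
  if (length(excl)) {
    message(length(excl), " patient(s) excluded from SIOI (missing component flag)")
  }
  attr(out, "excluded") <- excl
  out
}
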