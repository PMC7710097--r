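# Statistical evaluation: stepwise-AIC logistic selection over the nine
# pre-operative candidates, ROC/AUROC with DeLong variance and test,
# Youden operating point, variance-inflation collinearity check, and the
# rank-based tests (rank-sum for length of stay, Spearman for
# imaging-histology correlations).

#' Build the nine-candidate predictor matrix
#'
#' Assembles the candidate predictors for the stepwise logistic model from
#' a pre-operative (wide) cohort table: age, BMI, creatinine, bilirubin,
#' liver volume, lesion volume, ln(FLR%), liver fat (PDFF) and liver cT1,
#' plus the binary outcome and an eligibility flag (at least
#' `min_resected_fraction` of the liver removed and complete data). FLR
#' enters on the natural-log scale, matching the composite-score term.
#'
#' @param preop data.frame with columns `age_y, bmi, creatinine_umol_l,
#'   bilirubin_umol_l, liver_volume_ml, lesion_volume_ml, flr_percent,
#'   pdff_percent, ct1_ms` and an outcome column.
#' @param outcome logical/0-1 vector of poor-outcome labels (same order).
#' @param min_resected_fraction eligibility filter (default 0.10,
#'   inclusive).
#' @return data.frame of class `predictor_matrix` with the nine candidates,
#'   `outcome` and `eligible`.
#' @export
predictor_matrix <- function(preop, outcome, min_resected_fraction = 0.10) {
  cols <- c(age = "age_y", bmi = "bmi", creatinine = "creatinine_umol_l",
            bilirubin = "bilirubin_umol_l", liver_volume = "liver_volume_ml",
            lesion_volume = "lesion_volume_ml", liver_fat = "pdff_percent",
            ct1 = "ct1_ms")
  missing <- setdiff(c(cols, "flr_percent"), names(preop))
  if (length(missing)) {
    stop("predictor table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.data.frame(lapply(cols, function(cl) as.double(preop[[cl]])))
  X$log_flr <- log(preop$flr_percent)
  X$outcome <- as.integer(outcome)
  resected <- resected_fraction(preop$flr_percent)
  complete <- stats::complete.cases(X)
  # inclusive at the boundary, robust to float noise (FLR 90% qualifies)
  X$eligible <- complete & !is.na(resected) &
    resected >= min_resected_fraction - 1e-12
  class(X) <- c("predictor_matrix", "data.frame")
  X
}

CANDIDATE_PREDICTORS <- c("age", "bmi", "creatinine", "bilirubin",
                          "liver_volume", "lesion_volume", "log_flr",
                          "liver_fat", "ct1")

#' Bidirectional stepwise-AIC logistic regression
#'
#' Starting from the intercept-only logistic model, repeatedly adds or
#' drops the single candidate term giving the largest AIC improvement and
#' stops when no move improves the AIC. Fits are maximum-likelihood
#' logistic regressions (IRLS). Perfect separation is flagged rather than
#' failing, with coefficients reported at the convergence cap.
#'
#' @param X a [predictor_matrix()] (only `eligible` rows are used), or any
#'   data.frame with an `outcome` column.
#' @param candidates character vector of candidate columns.
#' @return list with `selected` (term names), `coefficients`, `aic`,
#'   `aic_trace` (the step path), `separation` flag and the fitted `model`.
#' @export
stepwise_logistic_aic <- function(X, candidates = CANDIDATE_PREDICTORS) {
  dat <- as.data.frame(X)
  if (!is.null(dat$eligible)) dat <- dat[dat$eligible, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat[c("outcome", candidates)]), ,
             drop = FALSE]
  tab <- table(dat$outcome)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need at least 2 eligible patients in each outcome class",
         call. = FALSE)
  }
  separation <- FALSE
  h <- function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
      separation <<- TRUE
    invokeRestart("muffleWarning")
  }
  fit <- withCallingHandlers({
    null <- stats::glm(outcome ~ 1, family = stats::binomial(), data = dat)
    upper <- stats::reformulate(candidates, response = "outcome")
    stats::step(null, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0)
  }, warning = h)
  list(selected = setdiff(attr(stats::terms(fit), "term.labels"), character()),
       coefficients = stats::coef(fit),
       aic = stats::AIC(fit),
       aic_trace = fit$anova,
       separation = separation,
       model = fit)
}

# DeLong structural components: for each positive score, the placement
# against the negatives (ties count 1/2), and vice versa
.delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi),
       auc = mean(psi), m = length(pos), n = length(neg))
}

# variance/covariance that degrade to 0 for singleton samples
.var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)
.cov0 <- function(m) if (nrow(m) < 2L) matrix(0, 2, 2) else stats::cov(m)

.check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be binary (0/1 or logical)", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  labels
}

#' AUROC with DeLong variance and confidence interval
#'
#' The area under the ROC curve equals the Mann-Whitney statistic
#' normalised by the number of positive-negative pairs, ties counted 1/2.
#' The variance uses DeLong's structural components; the two-sided CI is a
#' Wald interval on the logit scale.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels binary outcome.
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `var`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
auroc <- function(scores, labels, conf_level = 0.95) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  cmp <- .delong_components(scores, labels)
  v <- .var0(cmp$v10) / cmp$m + .var0(cmp$v01) / cmp$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (cmp$auc <= 0 || cmp$auc >= 1 || v == 0) {
    c(cmp$auc, cmp$auc)
  } else {
    se_logit <- sqrt(v) / (cmp$auc * (1 - cmp$auc))
    stats::plogis(stats::qlogis(cmp$auc) + c(-1, 1) * z * se_logit)
  }
  list(auc = cmp$auc, var = v, ci = ci, n_pos = cmp$m, n_neg = cmp$n)
}

#' Youden-index operating threshold
#'
#' Scans all candidate cut-points (midpoints between adjacent distinct
#' scores, plus the extremes) and returns the threshold maximising
#' sensitivity + specificity - 1; a score is called positive when it is at
#' or above the threshold. Ties are broken towards higher specificity,
#' then towards the higher threshold.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels binary outcome.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- .check_labels(labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-spec[best], -cand[best])][1]
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two scores measured on the same
#' patients, via the covariance of the DeLong structural components.
#' Identical or rank-equivalent scores give `z = 0, p = 1` exactly.
#'
#' @param scores_a,scores_b the two predictors (same patients, same order).
#' @param labels binary outcome.
#' @return list with `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  diff <- ca$auc - cb$auc
  s10 <- .cov0(cbind(ca$v10, cb$v10))
  s01 <- .cov0(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  if (v < 1e-14) {
    if (abs(diff) < 1e-12) {
      return(list(auc_a = ca$auc, auc_b = cb$auc, z = 0, p = 1))
    }
    stop("degenerate variance in DeLong comparison", call. = FALSE)
  }
  z <- diff / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Variance-inflation collinearity check
#'
#' Regresses each candidate on the remaining candidates and reports
#' `VIF = 1 / (1 - R^2)`; constant columns are flagged with infinite VIF.
#'
#' @param X a [predictor_matrix()] or data.frame of candidates.
#' @param candidates candidate columns to check.
#' @param vif_limit flagging threshold (default 10).
#' @return data.frame with `predictor`, `vif`, `flagged`.
#' @export
collinearity_check <- function(X, candidates = CANDIDATE_PREDICTORS,
                               vif_limit = 10) {
  dat <- as.data.frame(X)
  if (!is.null(dat$eligible)) dat <- dat[dat$eligible, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat[candidates]), candidates,
             drop = FALSE]
  vif <- vapply(candidates, function(cl) {
    y <- dat[[cl]]
    if (stats::var(y) == 0) return(Inf)
    fit <- stats::lm(stats::reformulate(setdiff(candidates, cl),
                                        response = cl), data = dat)
    # a perfect auxiliary fit (duplicated column) is a legitimate input
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = candidates, vif = vif,
             flagged = !is.finite(vif) | vif > vif_limit,
             row.names = NULL)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution for small samples
#' (all group assignments, feasible up to ~1e5 partitions, covering total
#' n of 10 and beyond); otherwise a tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y the two groups.
#' @param exact force exact enumeration (`TRUE`/`FALSE`); default chooses
#'   by partition count.
#' @return list with `statistic` (rank sum of `x`), `p`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 members", call. = FALSE)
  }
  all_v <- c(x, y)
  r <- rank(all_v)
  nx <- length(x); ny <- length(y); n <- nx + ny
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  n_part <- choose(n, nx)
  if (is.null(exact)) exact <- n_part <= 1e5
  if (exact) {
    combs <- utils::combn(n, nx)
    ws <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(all_v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = w, p = p, method = method)
}

#' Spearman rank correlation with t approximation
#'
#' @param x,y paired observations.
#' @return list with `rho`, `p` (two-sided, t approximation), `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(list(rho = rho, p = 0, n = n))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Cohort-level rank tests
#'
#' (1) Two-sided rank-sum comparison of length of stay between patients
#' with elevated vs normal pre-operative cT1, within the eligible subset
#' (at least `min_resected_fraction` of the liver removed); (2) Spearman
#' correlations of cT1 with histological ballooning and inflammation and
#' of PDFF with steatosis.
#'
#' @param preop pre-operative cohort table (see [cohort_preop()]) with
#'   `los_days, ct1_ms, pdff_percent, flr_percent, nas_ballooning,
#'   nas_inflammation, nas_steatosis`.
#' @param ct1_threshold_ms cT1 upper limit of normal (default 795).
#' @param min_resected_fraction eligibility filter for the length-of-stay
#'   comparison (default 0.10).
#' @return list with `wilcoxon_los` (`p`, group medians, `n`) and
#'   `spearman` (data.frame of rho/p per pair).
#' @export
rank_tests <- function(preop, ct1_threshold_ms = 795,
                       min_resected_fraction = 0.10) {
  elig <- resected_fraction(preop$flr_percent) >=
    min_resected_fraction - 1e-12 &
    is.finite(preop$los_days) & is.finite(preop$ct1_ms)
  sub <- preop[elig, , drop = FALSE]
  grp <- classify_ct1(sub$ct1_ms, ct1_threshold_ms)
  if (sum(grp == "elevated") < 2L || sum(grp == "normal") < 2L) {
    stop("each cT1 group needs at least 2 eligible patients", call. = FALSE)
  }
  rs <- rank_sum_test(sub$los_days[grp == "elevated"],
                      sub$los_days[grp == "normal"])
  wil <- list(p = rs$p,
              median_elevated = stats::median(sub$los_days[grp == "elevated"]),
              median_normal = stats::median(sub$los_days[grp == "normal"]),
              n = nrow(sub))
  pairs <- list(
    c("ct1_ms", "nas_ballooning"),
    c("ct1_ms", "nas_inflammation"),
    c("pdff_percent", "nas_steatosis")
  )
  sp <- do.call(rbind, lapply(pairs, function(p2) {
    r <- spearman_cor(preop[[p2[1]]], preop[[p2[2]]])
    data.frame(x = p2[1], y = p2[2], rho = r$rho, p = r$p, n = r$n)
  }))
  list(wilcoxon_los = wil, spearman = sp)
}
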