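# Survival nomogram from a multivariable Cox model: each predictor is
# mapped affinely to points so that the strongest predictor (largest
# |beta| x range) spans 0-100; total points are an affine bijection of the
# linear predictor; survival at a horizon comes from the Breslow baseline,
# S(t | x) = S0(t)^exp(lp(x) - lp at covariate means).  Performance is
# the cumulative-case / dynamic-control AUC with inverse-probability-of-
# censoring weights.

#' Backward (or forward) stepwise Cox selection
#'
#' Backward: start from all candidates, repeatedly drop the largest Wald
#' p-value until every retained predictor has `p < alpha`. Forward: start
#' empty, repeatedly add the candidate with the smallest Wald p-value
#' while it is below `alpha`. Both are deterministic given the data;
#' perfectly collinear duplicates are resolved by input order (first
#' kept).
#'
#' @param covariates data.frame of candidate predictors.
#' @param time,event survival and event flag.
#' @param alpha retention threshold (default 0.05).
#' @param direction `"backward"` (default) or `"forward"`.
#' @return list with `fit` (`coxph` or `NULL`), `table`, `kept`,
#'   `eliminated` (in order of removal), `intercept_only` flag.
#' @export
stepwise_select <- function(covariates, time, event, alpha = 0.05,
                            direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  covariates <- as.data.frame(covariates)
  eliminated <- character(0)
  if (direction == "backward") {
    keep <- names(covariates)
    repeat {
      if (!length(keep)) break
      cx <- suppressWarnings(
        cox_multivariable(covariates[keep], time, event))
      keep <- cx$table$covariate
      worst <- which.max(cx$table$p_value)
      if (cx$table$p_value[worst] < alpha) {
        return(list(fit = cx$fit, table = cx$table, kept = keep,
                    eliminated = eliminated, intercept_only = FALSE))
      }
      eliminated <- c(eliminated, keep[worst])
      keep <- keep[-worst]
    }
  } else {
    keep <- character(0)
    pool <- names(covariates)
    repeat {
      if (!length(pool)) break
      trial <- lapply(pool, function(v) {
        suppressWarnings(
          cox_multivariable(covariates[c(keep, v)], time, event))
      })
      pv <- vapply(seq_along(pool), function(i) {
        tb <- trial[[i]]$table
        tb$p_value[tb$covariate == pool[i]]
      }, numeric(1))
      best <- which.min(pv)
      if (!is.finite(pv[best]) || pv[best] >= alpha) break
      keep <- c(keep, pool[best])
      pool <- pool[-best]
    }
    if (length(keep)) {
      cx <- suppressWarnings(cox_multivariable(covariates[keep], time, event))
      return(list(fit = cx$fit, table = cx$table, kept = cx$table$covariate,
                  eliminated = setdiff(names(covariates), keep),
                  intercept_only = FALSE))
    }
  }
  warning("stepwise selection eliminated every candidate")
  list(fit = NULL, table = NULL, kept = character(0),
       eliminated = eliminated, intercept_only = TRUE)
}

# Breslow baseline cumulative hazard of a coxph fit, on the linear
# predictor scale centered at the covariate means (the coxph convention).
breslow_baseline <- function(fit) {
  y <- fit$y
  stopifnot(!is.null(y))
  ym <- as.matrix(unclass(y))
  time <- ym[, 1]
  status <- ym[, ncol(ym)]
  lp <- fit$linear.predictors  # centered at fit$means
  elp <- exp(lp)
  ut <- sort(unique(time[status == 1]))
  h0 <- vapply(ut, function(tk) {
    sum(status == 1 & time == tk) / sum(elp[time >= tk])
  }, numeric(1))
  data.frame(time = ut, cumhaz = cumsum(h0))
}

# Step-function lookup of the cumulative hazard (right-continuous).
cumhaz_at <- function(baseline, t) {
  vapply(t, function(tt) {
    if (tt < baseline$time[1]) return(0)
    baseline$cumhaz[max(which(baseline$time <= tt))]
  }, numeric(1))
}

#' Build a survival nomogram from a multivariable Cox fit
#'
#' Per-predictor points are `100 * beta_j * (x - ref_j) / M` with `ref_j`
#' the range end minimising `beta_j * x` (so points are non-negative and
#' grow with hazard) and `M = max_j |beta_j| * range_j`; exactly one
#' predictor reaches 100 at its range extreme. Total points are an affine
#' bijection of the linear predictor, and horizon survival uses the
#' Breslow baseline.
#'
#' @param fit multivariable `coxph` (e.g. from [stepwise_select()]).
#' @param data data.frame holding the fitted predictors; defines their
#'   observed ranges.
#' @param horizons months at which survival is tabulated (default
#'   6, 12, 24).
#' @return `nomogram_spec` list: `predictors`, `betas`, `ranges`, `refs`,
#'   `scale` (points per unit of linear predictor is `100 / M`), `means`,
#'   `baseline`, `horizons`, `max_points`.
#' @export
build_nomogram <- function(fit, data, horizons = c(6, 12, 24)) {
  betas <- coef(fit)
  vars <- gsub("`", "", names(betas))
  stopifnot(all(vars %in% names(data)))
  rng <- vapply(vars, function(v) range(data[[v]]), numeric(2))
  width <- rng[2, ] - rng[1, ]
  if (any(width == 0)) {
    stop("zero-range predictor(s): ",
         paste(vars[width == 0], collapse = ", "))
  }
  M <- max(abs(betas) * width)
  refs <- ifelse(betas > 0, rng[1, ], rng[2, ])
  structure(list(
    predictors = vars,
    betas = setNames(unname(betas), vars),
    ranges = setNames(asplit(rng, 2), vars),
    refs = setNames(unname(refs), vars),
    M = M,
    means = setNames(unname(fit$means), vars),
    baseline = breslow_baseline(fit),
    horizons = horizons,
    max_points = sum(abs(betas) * width) / M * 100
  ), class = "nomogram_spec")
}

#' Per-predictor nomogram points for one patient
#'
#' Values outside the fitted range are clipped with an extrapolation
#' warning.
#'
#' @param spec `nomogram_spec`.
#' @param patient named list/vector of predictor values.
#' @return named numeric vector of points (plus `total`).
#' @export
nomogram_points <- function(spec, patient) {
  pts <- vapply(spec$predictors, function(v) {
    x <- patient[[v]]
    r <- spec$ranges[[v]]
    if (x < r[1] || x > r[2]) {
      warning("predictor ", v, " = ", x, " outside fitted range [",
              r[1], ", ", r[2], "]; clipped")
      x <- min(max(x, r[1]), r[2])
    }
    100 * spec$betas[[v]] * (x - spec$refs[[v]]) / spec$M
  }, numeric(1))
  c(pts, total = sum(pts))
}

#' Survival probability from a nomogram
#'
#' Maps the patient's total points back to the linear predictor and
#' evaluates `S0(t)^exp(lp - lp_mean)` on the Breslow baseline
#' (right-continuous step interpolation); `t = 0` gives 1.
#'
#' @param spec `nomogram_spec`.
#' @param patient named predictor values.
#' @param t months (vectorised).
#' @return survival probabilities in `[0, 1]`, non-increasing in `t`.
#' @export
predict_survival <- function(spec, patient, t) {
  pts <- nomogram_points(spec, patient)
  total <- pts[["total"]]
  # invert the affine point map: lp(x) - lp(refs) = total * M / 100
  lp_ref <- sum(spec$betas * spec$refs)
  lp <- lp_ref + total * spec$M / 100
  lp_centered <- lp - sum(spec$betas * spec$means)
  H <- cumhaz_at(spec$baseline, t)
  exp(-H * exp(lp_centered))
}

#' Serialise a nomogram to JSON
#'
#' @param spec `nomogram_spec`.
#' @param path output path.
#' @export
write_nomogram <- function(spec, path) {
  out <- list(
    predictors = spec$predictors,
    betas = as.list(spec$betas),
    ranges = lapply(spec$ranges, as.numeric),
    refs = as.list(spec$refs),
    M = spec$M,
    means = as.list(spec$means),
    horizons = spec$horizons,
    max_points = spec$max_points,
    baseline = spec$baseline
  )
  write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Time-dependent ROC AUC under right censoring
#'
#' Cumulative-case / dynamic-control AUC at horizon `t`: cases are
#' patients with an observed event by `t`, controls those still at risk
#' past `t`; pairs are weighted by inverse probability of censoring
#' (Kaplan-Meier estimator of the censoring distribution, left limit at
#' the case's event time). With no censoring this reduces to the
#' empirical rank-sum AUC of cases versus survivors.
#'
#' @param scores per-patient risk scores (higher = riskier).
#' @param time,event survival and event flag.
#' @param t horizon in months.
#' @return list with `t`, `auc`, `n_cases`, `n_controls`,
#'   `scheme = "ipcw_km"`; `auc` is `NA` with a message when either side
#'   is empty.
#' @export
time_dependent_auc <- function(scores, time, event, t) {
  stopifnot(length(scores) == length(time))
  cases <- which(time <= t & event == 1)
  controls <- which(time > t)
  if (!length(cases) || !length(controls)) {
    message("no ", if (length(cases)) "controls" else "cases",
            " at t = ", t, "; AUC undefined")
    return(list(t = t, auc = NA_real_, n_cases = length(cases),
                n_controls = length(controls), scheme = "ipcw_km"))
  }
  # KM of the censoring distribution G(t); weights 1/G(T_case-) and 1/G(t)
  cfit <- survfit(Surv(time, 1 - event) ~ 1)
  G <- function(tt) {
    # left-continuous evaluation: P(censoring time >= tt)
    vapply(tt, function(u) {
      idx <- which(cfit$time < u)
      if (!length(idx)) 1 else cfit$surv[max(idx)]
    }, numeric(1))
  }
  w_case <- 1 / G(time[cases])
  w_ctrl <- rep(1 / G(t), length(controls))
  sc <- scores[cases]
  sx <- scores[controls]
  conc <- outer(sc, sx, ">") + 0.5 * outer(sc, sx, "==")
  wmat <- outer(w_case, w_ctrl)
  auc <- sum(wmat * conc) / sum(wmat)
  list(t = t, auc = auc, n_cases = length(cases),
       n_controls = length(controls), scheme = "ipcw_km")
}
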