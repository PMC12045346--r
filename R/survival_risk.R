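# Cox-based prognostic machinery: univariate screens of MHBs and clinical
# biomarkers, a composite score C = sum(beta_i * M_i) over a reduced MHB
# panel, multi-modal risk scores R from multivariable Cox coefficients,
# median-split stratification with Kaplan-Meier/log-rank, and the Pearson
# screen of MHL against predicted ctDNA fraction.

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; Wald confidence
#' interval and p-value. Non-convergence or a monotone likelihood
#' (infinite or wildly unstable coefficient) flags the fit so selection
#' steps can exclude it.
#'
#' @param x numeric covariate per patient.
#' @param time,event survival in months and event flag (1 = death).
#' @param name covariate label.
#' @return `cox_fit` list: `name`, `beta`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value`, `n`, `n_events`, `flagged`, `fit` (the
#'   underlying `coxph`).
#' @export
cox_univariate <- function(x, time, event, name = "x") {
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (sum(event) < 2) stop("need >= 2 events")
  if (length(unique(x[!is.na(x)])) < 2) stop("covariate is constant")
  df <- data.frame(x = x, time = time, event = event)
  flagged <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, data = df, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  beta <- unname(coef(fit))
  se <- sqrt(unname(vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 100) flagged <- TRUE
  structure(list(
    name = name, beta = beta, se = se, hr = exp(beta),
    ci_lower = exp(beta - qnorm(0.975) * se),
    ci_upper = exp(beta + qnorm(0.975) * se),
    p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
    n = s$n, n_events = s$nevent, flagged = flagged, fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s: HR %.3f (95%% CI %.3f-%.3f), p %.3g%s\n",
              x$name, x$hr, x$ci_lower, x$ci_upper, x$p_value,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Multivariable Cox fit on a covariate table
#'
#' Constant columns are dropped with a warning; perfectly collinear
#' columns are resolved by `coxph` (later column gets `NA`) and then
#' dropped deterministically, keeping the earlier column by input order.
#'
#' @param covariates data.frame of numeric covariates (one row per
#'   patient).
#' @param time,event survival and event flag.
#' @return list with `fit` (`coxph`), `table` (per-covariate beta, HR,
#'   CI, p), `dropped` (names removed before/after fitting), `flagged`.
#' @export
cox_multivariable <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) {
    length(unique(v[!is.na(v)])) < 2
  }, logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[!const]
  }
  if (!ncol(covariates)) stop("no usable covariates")
  df <- cbind(covariates, .time = time, .event = event)
  flagged <- FALSE
  fml <- as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  collinear <- names(which(is.na(coef(fit))))
  if (length(collinear)) {
    warning("dropping collinear covariate(s): ",
            paste(collinear, collapse = ", "))
    covariates <- covariates[setdiff(names(covariates), collinear)]
    return(cox_multivariable(covariates, time, event))
  }
  s <- summary(fit)
  tab <- data.frame(
    covariate = names(coef(fit)),
    beta = unname(coef(fit)),
    hr = unname(exp(coef(fit))),
    ci_lower = unname(exp(coef(fit) - qnorm(0.975) * sqrt(diag(vcov(fit))))),
    ci_upper = unname(exp(coef(fit) + qnorm(0.975) * sqrt(diag(vcov(fit))))),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$covariate <- gsub("`", "", tab$covariate)
  list(fit = fit, table = tab, dropped = names(which(const)),
       flagged = flagged)
}

#' Reduce candidate DMRs to a gene-unique prognostic panel
#'
#' Ranks candidates by `rank_p` ascending (here the mHSPC-vs-mCRPC Welch
#' p-value; the transition into castration resistance), keeps those with
#' univariate Cox `p < alpha`, truncates to the `top_k` best, then
#' collapses blocks representing the same gene region to the one with the
#' highest hazard ratio (ties broken by leftmost genomic start).
#'
#' @param candidates data.frame with `mhb_id`, `gene`, `rank_p`, `start`.
#' @param fits named list of `cox_fit`, one per candidate `mhb_id`.
#' @param top_k panel size before gene collapsing (default 20).
#' @param alpha Cox significance gate (default 0.05).
#' @return data.frame of panel members: `mhb_id, gene, beta, hr, p_value`.
#' @export
select_panel <- function(candidates, fits, top_k = 20L, alpha = 0.05) {
  stopifnot(all(candidates$mhb_id %in% names(fits)))
  cand <- candidates
  cand$cox_p <- vapply(fits[cand$mhb_id], `[[`, numeric(1), "p_value")
  cand$hr <- vapply(fits[cand$mhb_id], `[[`, numeric(1), "hr")
  cand$beta <- vapply(fits[cand$mhb_id], `[[`, numeric(1), "beta")
  cand$flagged <- vapply(fits[cand$mhb_id], `[[`, logical(1), "flagged")
  cand <- cand[!cand$flagged & cand$cox_p < alpha, , drop = FALSE]
  cand <- cand[order(cand$rank_p, cand$mhb_id), , drop = FALSE]
  if (nrow(cand) < top_k) {
    warning("only ", nrow(cand), " significant candidates (< top_k = ",
            top_k, "); using all")
  }
  cand <- head(cand, top_k)
  # one block per gene: highest HR wins, leftmost start breaks ties
  cand <- cand[order(cand$gene, -cand$hr, cand$start), , drop = FALSE]
  cand <- cand[!duplicated(cand$gene), , drop = FALSE]
  cand <- cand[order(cand$rank_p, cand$mhb_id), , drop = FALSE]
  rownames(cand) <- NULL
  data.frame(mhb_id = cand$mhb_id, gene = cand$gene, beta = cand$beta,
             hr = cand$hr, p_value = cand$cox_p,
             stringsAsFactors = FALSE)
}

#' MHB-based composite score
#'
#' `C = sum_i beta_i * M_i` over the panel, with `beta_i` the member's
#' univariate Cox coefficient and `M_i` the patient's MHL value.
#'
#' @param panel data.frame from [select_panel()] (`mhb_id`, `beta`).
#' @param m `mhl_matrix` (imputed) containing the panel blocks.
#' @return named numeric vector, one composite value per sample.
#' @export
composite_score <- function(panel, m) {
  stopifnot(all(panel$mhb_id %in% m$mhb_ids))
  x <- m$values[, panel$mhb_id, drop = FALSE]
  drop(x %*% panel$beta)
}

#' Multi-modal risk score with median split
#'
#' Fits a multivariable Cox model on the supplied components (composite
#' score, log2 clinical biomarkers, raw ctDNA fraction, ...), forms
#' `R = sum_j beta_j * x_j`, and splits at the median: strictly greater
#' than the median is high-risk, at or below is low-risk.
#'
#' @param components data.frame of per-patient component values.
#' @param time,event survival and event flag.
#' @return list with `score` (numeric), `group` (factor low/high),
#'   `median`, `cox` (the [cox_multivariable()] result).
#' @export
risk_score <- function(components, time, event) {
  cx <- cox_multivariable(components, time, event)
  used <- cx$table$covariate
  x <- as.matrix(as.data.frame(components)[used])
  r <- drop(x %*% cx$table$beta)
  med <- median(r)
  group <- factor(ifelse(r > med, "high", "low"), levels = c("low", "high"))
  list(score = setNames(r, rownames(components)), group = group,
       median = med, cox = cx)
}

#' Kaplan-Meier curves, group medians and log-rank test
#'
#' Product-limit estimates per group; median survival is the first time
#' the KM curve drops to 0.5 or below (`NA` = not reached); two-group
#' log-rank statistic and p-value.
#'
#' @param group two-level factor (low/high or similar).
#' @param time,event survival and event flag.
#' @return list with `curves` (data.frame time, surv, n_risk, n_event,
#'   group), `medians` (named numeric), `chisq`, `p_value`.
#' @export
km_logrank <- function(group, time, event) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("need exactly two nonempty groups")
  df <- data.frame(time = time, event = event, group = group)
  sf <- survfit(Surv(time, event) ~ group, data = df)
  strata_id <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                       n_event = sf$n.event,
                       group = sub("^group=", "", strata_id),
                       stringsAsFactors = FALSE)
  medians <- vapply(levels(group), function(g) {
    cv <- curves[curves$group == g, , drop = FALSE]
    hit <- which(cv$surv <= 0.5)
    if (length(hit)) cv$time[min(hit)] else NA_real_
  }, numeric(1))
  sd_ <- survdiff(Surv(time, event) ~ group, data = df)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(curves = curves, medians = medians, chisq = unname(sd_$chisq),
       p_value = p)
}

#' Pearson screen of MHL against predicted ctDNA fraction
#'
#' Restricts to patients with fraction strictly above `min_fraction`
#' (the published analysis excluded the 0-1% range), then for every block
#' with strictly more than `min_nonmissing` observed values among the
#' eligible patients computes the Pearson correlation with fraction and
#' flags blocks with `r > r_cutoff` and `p < alpha`.
#'
#' @param m `mhl_matrix` (unimputed; missingness gates eligibility).
#' @param fractions predicted ctDNA fraction per sample (0-1 scale),
#'   aligned with the matrix rows.
#' @param min_fraction exclusion bound (default 0.01).
#' @param min_nonmissing minimum observed fraction per block (default
#'   0.5, strict).
#' @param r_cutoff,alpha flag cutoffs (defaults 0.5, 0.05).
#' @return list with `table` (mhb_id, n, r, p_value, flagged, skipped),
#'   `n_eligible`, `prop_flagged` (among tested blocks).
#' @export
ctdna_correlation_screen <- function(m, fractions, min_fraction = 0.01,
                                     min_nonmissing = 0.5, r_cutoff = 0.5,
                                     alpha = 0.05) {
  stopifnot(length(fractions) == nrow(m$values))
  eligible <- !is.na(fractions) & fractions > min_fraction
  if (sum(eligible) < 3) {
    stop("ctDNA correlation screen aborted: only ", sum(eligible),
         " patients with fraction > ", min_fraction)
  }
  x <- m$values[eligible, , drop = FALSE]
  f <- fractions[eligible]
  rows <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    obs <- !is.na(v)
    if (mean(obs) <= min_nonmissing || sum(obs) < 3 ||
        sd(v[obs]) == 0 || sd(f[obs]) == 0) {
      return(data.frame(mhb_id = m$mhb_ids[j], n = sum(obs), r = NA_real_,
                        p_value = NA_real_, flagged = FALSE,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    ct <- cor.test(v[obs], f[obs], method = "pearson")
    data.frame(mhb_id = m$mhb_ids[j], n = sum(obs),
               r = unname(ct$estimate), p_value = ct$p.value,
               flagged = unname(ct$estimate) > r_cutoff &&
                 ct$p.value < alpha,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tested <- !tab$skipped
  list(table = tab, n_eligible = sum(eligible),
       prop_flagged = if (any(tested)) mean(tab$flagged[tested]) else
         NA_real_)
}
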