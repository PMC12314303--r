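## Linear mixed-effects modelling of task-period x condition effects with
## patient and unit-within-patient random intercepts, Bonferroni model
## families and post-hoc contrasts.

## Bonferroni-corrected per-model alpha by outcome family: power uses six
## models (3 regions x 2 bands), PLV three (one per selected range), net
## GC is tested at the nominal level.
FAMILY_ALPHA <- c(power = 0.05 / 6, plv = 0.05 / 3, netgc = 0.05)

#' Fit the task-period x condition mixed model
#'
#' Fits \code{value ~ taskPeriod * condition + (1 | patient) +
#' (1 | patient:unit)} with treatment coding (baseline period and the
#' "same" condition as references) and Satterthwaite degrees of freedom.
#' A singular fit is refit without the nested unit term and flagged.  The
#' family-wise alpha applied is 0.05/6 for power outcomes, 0.05/3 for
#' PLV and 0.05 for net GC.
#'
#' @param table data.frame with columns \code{patient}, a unit column
#'   (\code{channel} or \code{pair_id}), \code{period}, \code{condition}
#'   and the outcome column.
#' @param outcome "power", "plv" or "netgc" (picks the outcome column
#'   \code{mean_power} / \code{mean_plv} / \code{mean_net_gc} and the
#'   alpha family).
#' @param alphaFamily override the family-wise alpha.
#' @return A list of class \code{ModelFitResult}: \code{fit} (the
#'   lmerModLmerTest object), \code{fixed} (data.frame of estimates, SE,
#'   df, t, p, significant at the family alpha), \code{ranef_var},
#'   \code{alpha}, \code{singular}, \code{dfMethod}.
#' @export
fitPeriodConditionLMM <- function(table, outcome = c("power", "plv", "netgc"),
                                  alphaFamily = NULL) {
  outcome <- match.arg(outcome)
  valueCol <- switch(outcome, power = "mean_power", plv = "mean_plv",
                     netgc = "mean_net_gc")
  if (!valueCol %in% names(table))
    stop("table lacks outcome column ", valueCol)
  unitCol <- intersect(c("channel", "pair_id", "unit"), names(table))[1]
  if (is.na(unitCol)) stop("table lacks a unit column (channel/pair_id)")
  alpha <- if (is.null(alphaFamily)) FAMILY_ALPHA[[outcome]] else alphaFamily
  df <- data.frame(
    value = table[[valueCol]],
    taskPeriod = factor(table$period,
                        levels = intersect(PERIODS, unique(table$period))),
    condition = factor(table$condition, levels = CONDITIONS),
    patient = factor(table$patient),
    unit = factor(table[[unitCol]]))
  if (nlevels(df$patient) < 2) stop("need >= 2 patients")
  if (nlevels(df$unit) < 2) stop("need >= 2 units (channels/pairs)")
  cells <- table(df$taskPeriod, df$condition)
  if (any(cells == 0)) stop("all period x condition cells must be populated")
  if (stats::sd(df$value) == 0) {
    ## degenerate outcome: no variance, nothing to estimate
    terms <- c("(Intercept)",
               paste0("taskPeriod", levels(df$taskPeriod)[-1]),
               "conditiondifferent",
               paste0("taskPeriod", levels(df$taskPeriod)[-1],
                      ":conditiondifferent"))
    fixed <- data.frame(term = terms, estimate = 0, se = 0, df = NA_real_,
                        t = NA_real_, p = 1, significant = FALSE)
    fixed$estimate[1] <- df$value[1]
    return(structure(list(fit = NULL, fixed = fixed,
                          ranef_var = data.frame(grp = character(),
                                                 vcov = numeric()),
                          alpha = alpha, outcome = outcome,
                          singular = TRUE, dfMethod = "none"),
                     class = "ModelFitResult"))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lmerTest::lmer(
    value ~ taskPeriod * condition + (1 | patient) + (1 | patient:unit),
    data = df, REML = TRUE, control = ctrl)
  singular <- lme4::isSingular(fit)
  if (singular) {
    fit <- lmerTest::lmer(value ~ taskPeriod * condition + (1 | patient),
                          data = df, REML = TRUE, control = ctrl)
  }
  sm <- summary(fit)$coefficients
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    aliased <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      significant = sm[, "Pr(>|t|)"] < alpha,
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, fixed = fixed,
                 ranef_var = vc[, c("grp", "vcov")], alpha = alpha,
                 outcome = outcome, singular = singular,
                 dfMethod = "Satterthwaite"),
            class = "ModelFitResult")
}

#' Post-hoc contrasts for the fitted mixed model
#'
#' Pairwise task-period contrasts (averaged over condition) and
#' within-period condition contrasts from the fixed-effect covariance,
#' with Satterthwaite degrees of freedom; p-values are reported raw and
#' Bonferroni-adjusted within each contrast family.  Estimated marginal
#' means (and therefore all contrasts) are invariant to the reference
#' levels used in fitting.
#'
#' @param fitResult a \code{ModelFitResult}.
#' @param which "period", "condition" or both (default).
#' @param custom optional named list of custom period-contrast weight
#'   vectors (one weight per task-period level, in model order); tested
#'   as an additional family.
#' @return data.frame: family, contrast, estimate, se, df, t, p, p_adj.
#' @export
posthocContrasts <- function(fitResult,
                             which = c("period", "condition"),
                             custom = NULL) {
  stopifnot(inherits(fitResult, "ModelFitResult"))
  if (is.null(fitResult$fit)) stop("degenerate fit: no contrasts available")
  which <- match.arg(which, several.ok = TRUE)
  fit <- fitResult$fit
  out <- list()
  grab <- function(ct, family, label) {
    tr <- if (!is.null(ct$t.ratio)) ct$t.ratio else ct$z.ratio
    data.frame(family = family, contrast = label,
               estimate = ct$estimate, se = ct$SE,
               df = if (!is.null(ct$df)) ct$df else NA_real_,
               t = tr, p = ct$p.value,
               p_adj = pmin(1, ct$p.value * nrow(ct)))
  }
  if ("period" %in% which) {
    emm <- suppressMessages(
      emmeans::emmeans(fit, ~ taskPeriod, lmer.df = "satterthwaite"))
    ct <- summary(emmeans::contrast(emm, method = "pairwise",
                                    adjust = "none"))
    out[[length(out) + 1L]] <- grab(ct, "period",
                                    as.character(ct$contrast))
  }
  if ("condition" %in% which) {
    emm <- suppressMessages(
      emmeans::emmeans(fit, ~ condition | taskPeriod,
                       lmer.df = "satterthwaite"))
    ct <- summary(emmeans::contrast(emm, method = "pairwise",
                                    adjust = "none"))
    out[[length(out) + 1L]] <- grab(
      ct, "condition",
      paste(as.character(ct$contrast), "@", as.character(ct$taskPeriod)))
  }
  if (!is.null(custom)) {
    emm <- suppressMessages(
      emmeans::emmeans(fit, ~ taskPeriod, lmer.df = "satterthwaite"))
    ct <- summary(emmeans::contrast(emm, method = custom, adjust = "none"))
    ## a zero-weight (self) contrast has SE 0: report p = 1, not NaN
    ct$p.value[ct$SE == 0 & ct$estimate == 0] <- 1
    out[[length(out) + 1L]] <- grab(ct, "custom",
                                    as.character(ct$contrast))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
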