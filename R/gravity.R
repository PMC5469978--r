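#' Build the gravity-model design table
#'
#' One row per ordered population pair (origin i, destination j). The
#' response is `ln_flow = ln(1 - D_PS(i,j))`; `ln_w` is the natural log of
#' Euclidean distance; at-site covariates are attached to the destination
#' node of each row (production/attraction), between-site covariates are
#' symmetric across orientations. Covariates are z-standardised with the
#' means/SDs stored as attributes. Pairs with D_PS = 1 (zero flow) are
#' dropped with a warning.
#'
#' @param dps `dist_matrix` of D_PS values
#' @param geo `dist_matrix` of geographic distances (m)
#' @param at_site data.frame: population plus at-site covariate columns
#' @param between data.frame: pop_i, pop_j plus between-site columns
#'   (unordered pairs; applied to both orientations)
#' @param attach `"destination"` (default) or `"origin"` for at-site
#'   covariates
#' @return a `flow_table` data.frame: from, to, flow, ln_flow, ln_w,
#'   covariates
#' @export
build_flow_table <- function(dps, geo, at_site = NULL, between = NULL,
                             attach = c("destination", "origin")) {
  attach <- match.arg(attach)
  if (!identical(rownames(dps), rownames(geo)))
    stop("dps and geo matrices must share labels in the same order")
  pops <- rownames(dps)
  n <- length(pops)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i != idx$j, ]
  df <- data.frame(from = pops[idx$i], to = pops[idx$j],
                   flow = 1 - unclass(dps)[cbind(idx$i, idx$j)],
                   w = unclass(geo)[cbind(idx$i, idx$j)])
  zero <- df$flow <= 0
  if (any(zero)) {
    warning(sum(zero), " pair orientation(s) dropped: D_PS = 1 (zero flow)")
    df <- df[!zero, ]
  }
  df$ln_flow <- log(df$flow)
  df$ln_w <- log(df$w)
  df$w <- NULL
  scaling <- list()
  if (!is.null(at_site)) {
    key <- if (attach == "destination") df$to else df$from
    m <- match(key, at_site$population)
    if (anyNA(m)) stop("at-site covariates missing for some populations")
    for (nm in setdiff(names(at_site), "population"))
      df[[nm]] <- at_site[[nm]][m]
  }
  if (!is.null(between)) {
    key_fwd <- paste(between$pop_i, between$pop_j)
    key_rev <- paste(between$pop_j, between$pop_i)
    want <- paste(df$from, df$to)
    m <- match(want, key_fwd)
    m2 <- match(want, key_rev)
    m[is.na(m)] <- m2[is.na(m)]
    if (anyNA(m)) stop("between-site covariates missing for some pairs")
    for (nm in setdiff(names(between), c("pop_i", "pop_j")))
      df[[nm]] <- between[[nm]][m]
  }
  covars <- setdiff(names(df), c("from", "to", "flow", "ln_flow", "ln_w"))
  for (nm in covars) {
    mu <- mean(df[[nm]]); sdv <- stats::sd(df[[nm]])
    if (sdv == 0) {
      warning("constant covariate '", nm, "' left unstandardised")
      scaling[[nm]] <- c(mean = mu, sd = 0)
    } else {
      df[[nm]] <- (df[[nm]] - mu) / sdv
      scaling[[nm]] <- c(mean = mu, sd = sdv)
    }
  }
  attr(df, "scaling") <- scaling
  attr(df, "covariates") <- covars
  class(df) <- c("flow_table", "data.frame")
  df
}

#' Screen covariate pairs for collinearity
#'
#' Flags covariate pairs with |Pearson r| at or above the threshold; the
#' candidate-model generator refuses any model containing a forbidden
#' pair. Constant covariates are excluded outright.
#'
#' @param table a `flow_table` (or data.frame of covariates)
#' @param threshold absolute-correlation cutoff (default 0.7)
#' @param covariates columns to screen (default the stored covariate set)
#' @return list: `cor` (correlation matrix), `forbidden` (two-column
#'   matrix of disallowed pairs), `constant` (dropped covariates)
#' @export
screen_collinearity <- function(table, threshold = 0.7,
                                covariates = attr(table, "covariates")) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(covariates))
    covariates <- setdiff(names(table), c("from", "to", "flow", "ln_flow"))
  x <- as.data.frame(table)[covariates]
  constant <- covariates[vapply(x, function(v) stats::sd(v) == 0, logical(1))]
  keep <- setdiff(covariates, constant)
  cm <- stats::cor(x[keep])
  bad <- which(abs(cm) >= threshold & upper.tri(cm), arr.ind = TRUE)
  forbidden <- cbind(keep[bad[, 1]], keep[bad[, 2]])
  list(cor = cm, forbidden = forbidden, constant = constant)
}

model_formula <- function(covariates, random = "from") {
  rhs <- paste(c("ln_w", covariates), collapse = " + ")
  stats::as.formula(sprintf("ln_flow ~ %s + (1 | %s)", rhs, random))
}

#' Fit one singly constrained gravity model
#'
#' Maximum-likelihood linear mixed model
#' `ln T_ij = b0 + b_w ln w_ij + X beta + u_i + e_ij` with a random
#' intercept on the origin node (`u_i`), realising the single constraint.
#' AICc uses `k` = fixed effects (incl. intercept) + 2 variance
#' parameters.
#'
#' @param table a `flow_table`
#' @param covariates character vector of covariate columns (may be empty
#'   for the distance-only null model)
#' @param random grouping column for the random intercept (default origin
#'   `"from"`; `"both"` adds a destination intercept as well)
#' @return a `gravity_fit`: list with `model` (lmerMod), `spec`,
#'   `coefficients`, `sigma_u`, `sigma_e`, `logLik`, `k`, `n_obs`, `AIC`,
#'   `AICc`, `conditional_r2`, `marginal_r2`
#' @export
fit_gravity <- function(table, covariates = character(0), random = "from") {
  stopifnot(length(unique(table$from)) >= 2)
  if (identical(random, "both")) {
    rhs <- paste(c("ln_w", covariates), collapse = " + ")
    form <- stats::as.formula(
      sprintf("ln_flow ~ %s + (1 | from) + (1 | to)", rhs))
  } else {
    form <- model_formula(covariates, random)
  }
  n_obs <- nrow(table)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = as.data.frame(table), REML = FALSE),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("singular|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- sum(vc$vcov[vc$grp != "Residual"])
  sigma_e <- vc$vcov[vc$grp == "Residual"]
  ll <- stats::logLik(fit)
  n_rand <- sum(vc$grp != "Residual")
  k <- length(beta) + n_rand + 1L
  if (n_obs <= k + 1L) stop("too few observations for AICc with k = ", k)
  aic <- -2 * as.numeric(ll) + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n_obs - k - 1)
  structure(list(model = fit, spec = covariates, coefficients = beta,
                 sigma_u = sigma_u, sigma_e = sigma_e,
                 logLik = as.numeric(ll), k = k, n_obs = n_obs,
                 AIC = aic, AICc = aicc,
                 conditional_r2 = conditional_r2_(fit),
                 marginal_r2 = marginal_r2_(fit)),
            class = "gravity_fit")
}

# variance of the fixed-effect linear predictor over rows
fixed_variance <- function(fit) {
  pred <- stats::model.matrix(fit) %*% lme4::fixef(fit)
  mean((pred - mean(pred))^2)
}

conditional_r2_ <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  su <- sum(vc$vcov[vc$grp != "Residual"])
  se <- vc$vcov[vc$grp == "Residual"]
  sf <- fixed_variance(fit)
  (sf + su) / (sf + su + se)
}

marginal_r2_ <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  su <- sum(vc$vcov[vc$grp != "Residual"])
  se <- vc$vcov[vc$grp == "Residual"]
  sf <- fixed_variance(fit)
  sf / (sf + su + se)
}

#' Conditional R-squared of a gravity fit
#'
#' Proportion of variance explained by fixed plus random effects
#' (Nakagawa & Schielzeth): `(s2_f + s2_u) / (s2_f + s2_u + s2_e)` with
#' `s2_f` the variance of the fixed-effect linear predictor.
#'
#' @param fit a `gravity_fit`
#' @return scalar in [0, 1]
#' @export
conditional_r2 <- function(fit) fit$conditional_r2

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf("gravity_fit: ln_flow ~ ln_w%s + (1|origin)\n",
              if (length(x$spec)) paste0(" + ", paste(x$spec, collapse = " + "))
              else ""))
  cat(sprintf("  AICc %.2f, logLik %.2f, k %d, cond R2 %.3f\n",
              x$AICc, x$logLik, x$k, x$conditional_r2))
  invisible(x)
}

#' Rank a candidate model set by AICc
#'
#' Fits the distance-only null model plus every candidate covariate
#' subset, dropping any candidate containing a forbidden collinear pair,
#' and reports Delta AICc, Akaike weights `w_m = exp(-D_m/2) /
#' sum exp(-D/2)`, and conditional R^2. Failed fits are reported and
#' excluded.
#'
#' @param table a `flow_table`
#' @param candidate_specs list of character vectors (covariate subsets);
#'   the empty (distance-only) spec is added automatically
#' @param at_site_vars,between_site_vars variable classification used for
#'   the model `type` column
#' @param threshold collinearity cutoff passed to [screen_collinearity()]
#' @param random random-effect structure for [fit_gravity()]
#' @return a `gravity_selection`: data.frame (model, type, k, AICc,
#'   delta_AICc, weight, conditional_r2) with the fits attached
#' @export
model_selection <- function(table, candidate_specs,
                            at_site_vars = character(0),
                            between_site_vars = character(0),
                            threshold = 0.7, random = "from") {
  scr <- screen_collinearity(table, threshold = threshold)
  forbidden <- scr$forbidden
  admissible <- function(spec) {
    if (any(spec %in% scr$constant)) return(FALSE)
    if (nrow(forbidden) == 0L) return(TRUE)
    !any(apply(forbidden, 1, function(p) all(p %in% spec)))
  }
  specs <- c(list(character(0)), candidate_specs)
  specs <- specs[!duplicated(vapply(specs, function(s)
    paste(sort(s), collapse = "+"), character(1)))]
  keep <- vapply(specs, admissible, logical(1))
  if (any(!keep))
    message(sum(!keep), " candidate model(s) dropped by collinearity screen")
  specs <- specs[keep]
  fits <- lapply(specs, function(sp)
    tryCatch(fit_gravity(table, sp, random = random), error = function(e) e))
  failed <- vapply(fits, inherits, logical(1), "error")
  if (any(failed))
    warning(sum(failed), " model fit(s) failed and were excluded")
  specs <- specs[!failed]; fits <- fits[!failed]
  model_type <- vapply(specs, function(sp) {
    has_at <- any(sp %in% at_site_vars)
    has_bw <- any(sp %in% between_site_vars)
    if (has_at && has_bw) "at+between"
    else if (has_at) "at" else if (has_bw) "between" else "distance"
  }, character(1))
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  delta <- aicc - min(aicc)
  weight <- exp(-delta / 2) / sum(exp(-delta / 2))
  out <- data.frame(
    model = vapply(specs, function(sp)
      paste(c("w", sp), collapse = " + "), character(1)),
    type = model_type,
    k = vapply(fits, `[[`, numeric(1), "k"),
    AICc = aicc, delta_AICc = delta, weight = weight,
    conditional_r2 = vapply(fits, `[[`, numeric(1), "conditional_r2"))
  out <- out[order(out$delta_AICc), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "specs") <- specs
  class(out) <- c("gravity_selection", "data.frame")
  out
}

#' Cumulative Akaike weight per variable
#'
#' Sums the Akaike weights of every model containing each variable.
#'
#' @param ranked a `gravity_selection`
#' @param variables which variables to report (default: all that occur)
#' @return named numeric vector in [0, 1]
#' @export
cumulative_variable_weight <- function(ranked, variables = NULL) {
  specs <- attr(ranked, "specs")
  ord <- order(vapply(attr(ranked, "fits"), `[[`, numeric(1), "AICc"))
  # align specs with the sorted table rows
  specs <- specs[ord]
  all_vars <- unique(unlist(specs))
  if (is.null(variables)) variables <- all_vars
  unknown <- setdiff(variables, c(all_vars, "ln_w"))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  vapply(variables, function(v)
    sum(ranked$weight[vapply(specs, function(sp) v %in% sp, logical(1))]),
    numeric(1))
}

#' AICc from AIC
#' @param aic AIC value
#' @param k parameter count
#' @param n_obs number of observations
#' @return small-sample corrected AICc
#' @export
aicc_from_aic <- function(aic, k, n_obs) {
  aic + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Akaike weights from Delta-AICc values
#' @param delta vector of Delta AICc
#' @return weights summing to 1
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}
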