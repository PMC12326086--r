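# Habitat-conditioned mixed-model selection: response transforms, VIF-based
# collinearity pruning, exhaustive marginality-respecting subset search under
# ML, Delta-AIC < 2 / max-r2 / parsimony selection, Cook's-distance outlier
# refitting, and the habitat-vs-identity independence diagnostic.
#
# Fixed random structure throughout: random intercepts for loft and for bird
# nested in loft. Models are compared by AIC from maximum-likelihood fits
# (fixed structures differ); the final reported coefficient table comes from
# an REML refit of the selected structure.

#' Apply a response transform
#'
#' @param values numeric vector.
#' @param transform `"identity"` or `"sqrt"`.
#' @return transformed values.
#' @export
apply_transform <- function(values, transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  if (transform == "identity") return(values)
  if (any(values < 0, na.rm = TRUE))
    stop("sqrt transform requires non-negative values", call. = FALSE)
  sqrt(values)
}

.term_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]
.is_interaction <- function(term) grepl(":", term, fixed = TRUE)

.random_part <- "(1 | loft_id) + (1 | loft_id:bird_id)"

.build_formula <- function(response, terms, transform = "identity",
                           random = TRUE) {
  lhs <- if (transform == "sqrt") sprintf("sqrt(%s)", response) else response
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (random) rhs <- paste(rhs, "+", .random_part)
  as.formula(paste(lhs, "~", rhs))
}

#' Iteratively prune collinear terms by variance inflation factor
#'
#' Main-effect terms are tested with the generalized VIF scaled by degrees
#' of freedom (GVIF^(1/(2 Df)) squared, so continuous terms reduce to the
#' plain VIF); the highest-scoring term is dropped while the maximum exceeds
#' `threshold`. Interaction terms are never VIF-tested against their own
#' parents; they are dropped when a parent is dropped. Exact collinearity
#' (a singular design) drops the later-ordered offender.
#'
#' @param data data.frame holding the predictor columns.
#' @param fixed_terms character vector of candidate terms (interactions as
#'   `"a:b"`).
#' @param threshold VIF threshold (default 5).
#' @return list with `retained` (terms kept, mains then surviving
#'   interactions) and `removed` (data.frame of `term`, `vif`).
#' @export
vif_prune <- function(data, fixed_terms, threshold = 5) {
  mains <- fixed_terms[!vapply(fixed_terms, .is_interaction, logical(1))]
  inters <- setdiff(fixed_terms, mains)
  stopifnot(length(mains) >= 1)
  removed <- data.frame(term = character(0), vif = numeric(0))
  repeat {
    if (length(mains) < 2L) break
    df <- data[stats::complete.cases(data[mains]), mains, drop = FALSE]
    if (nrow(df) <= length(mains))
      stop("too few complete rows for VIF pruning", call. = FALSE)
    df$.y <- seq_len(nrow(df))        # VIF depends on the design only
    fit <- lm(.y ~ ., data = df)
    if (anyNA(coef(fit))) {
      asgn <- attr(model.matrix(fit), "assign")
      labs <- attr(terms(fit), "term.labels")
      bad_terms <- unique(labs[asgn[is.na(coef(fit))]])
      drop_term <- bad_terms[length(bad_terms)]     # later-ordered offender
      removed <- rbind(removed, data.frame(term = drop_term, vif = Inf))
      mains <- setdiff(mains, drop_term)
      next
    }
    v <- car::vif(fit)
    if (is.matrix(v)) {
      score <- stats::setNames(v[, "GVIF^(1/(2*Df))"]^2, rownames(v))
    } else {
      score <- v
    }
    if (max(score) <= threshold) break
    drop_term <- names(score)[which.max(score)]
    removed <- rbind(removed,
                     data.frame(term = drop_term, vif = max(score)))
    mains <- setdiff(mains, drop_term)
  }
  inters <- inters[vapply(inters, function(tt)
    all(.term_parents(tt) %in% mains), logical(1))]
  list(retained = c(mains, inters), removed = removed)
}

#' Enumerate all fixed-effect subsets respecting marginality
#'
#' Every subset of the main effects, each combined with every subset of the
#' interaction terms whose parents are all present; includes the
#' intercept-only model.
#'
#' @param terms character vector of candidate terms.
#' @param max_specs refuse (rather than silently subsample) beyond this many
#'   specifications (default 2^14).
#' @return list of character vectors (term subsets).
#' @export
enumerate_subsets <- function(terms, max_specs = 2^14) {
  stopifnot(length(terms) >= 1)
  mains <- terms[!vapply(terms, .is_interaction, logical(1))]
  inters <- setdiff(terms, mains)
  n_specs <- 0
  for (mask in 0:(2^length(mains) - 1)) {
    present <- mains[bitwAnd(mask, 2^(seq_along(mains) - 1)) > 0]
    k <- sum(vapply(inters, function(tt)
      all(.term_parents(tt) %in% present), logical(1)))
    n_specs <- n_specs + 2^k
  }
  if (n_specs > max_specs)
    stop("model space has ", n_specs, " specifications (> ", max_specs,
         "); refusing exhaustive search", call. = FALSE)
  specs <- vector("list", n_specs)
  i <- 0L
  for (mask in 0:(2^length(mains) - 1)) {
    present <- mains[bitwAnd(mask, 2^(seq_along(mains) - 1)) > 0]
    ok_int <- inters[vapply(inters, function(tt)
      all(.term_parents(tt) %in% present), logical(1))]
    for (imask in 0:(2^length(ok_int) - 1)) {
      inc <- ok_int[bitwAnd(imask, 2^(seq_along(ok_int) - 1)) > 0]
      i <- i + 1L
      specs[[i]] <- c(present, inc)
    }
  }
  specs
}

.prep_model_data <- function(data, response, terms, reference = "open") {
  vars <- unique(c(response, unlist(lapply(terms, .term_parents)),
                   "bird_id", "loft_id"))
  vars <- intersect(vars, names(data))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if ("habitat" %in% names(df))
    df$habitat <- stats::relevel(factor(df$habitat, levels = .habitat_levels),
                                 ref = reference)
  if ("position" %in% names(df))
    df$position <- factor(df$position, levels = c("back", "front"))
  df$bird_id <- factor(df$bird_id)
  df$loft_id <- factor(df$loft_id)
  df
}

#' Fit one linear mixed model specification
#'
#' Maximum-likelihood fit (REML = FALSE, since AICs compare fixed
#' structures) with random intercepts for loft and bird-within-loft. The fit
#' is flagged singular when lme4 reports a boundary fit or any random-effect
#' variance falls below 1e-8 of the residual variance; r2 is the marginal
#' (fixed-effects) r2: variance of the fixed-effect predictions over the
#' total (fixed + random + residual) variance.
#'
#' @param data data.frame with the response, predictors, `bird_id`,
#'   `loft_id` (and `habitat` as a 3-level factor where used).
#' @param response response column name.
#' @param terms character vector of fixed-effect terms (may be empty).
#' @param transform `"identity"` or `"sqrt"` applied to the response.
#' @param reference habitat reference level (default `"open"`).
#' @param reml fit by REML instead of ML (used for final reports).
#' @return an `lmm_fit` object (list with `fit`, `aic`, `r2`, `n_obs`,
#'   `singular`, `converged`, `terms`, `response`, `transform`).
#' @export
fit_lmm <- function(data, response, terms = character(0),
                    transform = "identity", reference = "open",
                    reml = FALSE) {
  df <- .prep_model_data(data, response, terms, reference)
  if (transform == "sqrt") apply_transform(df[[response]], "sqrt")  # domain
  fml <- .build_formula(response, terms, transform)
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(suppressMessages(lme4::lmer(fml, data = df, REML = reml)),
             error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    out <- list(response = response, transform = transform, terms = terms,
                fit = NULL, aic = NA_real_, r2 = NA_real_, n_obs = nrow(df),
                singular = NA, converged = FALSE,
                message = conditionMessage(fit))
    class(out) <- "lmm_fit"
    return(out)
  }
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- !any(grepl("failed to converge", c(warns, conv_msgs %||% "")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  re_var <- vc$vcov[vc$grp != "Residual"]
  singular <- any(re_var < 1e-8 * sigma2)
  mu_f <- model.matrix(fit) %*% lme4::fixef(fit)
  var_f <- var(as.numeric(mu_f))
  r2 <- var_f / (var_f + sum(re_var) + sigma2)
  out <- list(response = response, transform = transform, terms = terms,
              fit = fit, aic = AIC(fit), r2 = as.numeric(r2),
              n_obs = nrow(df), singular = singular, converged = converged,
              reference = reference)
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: %s%s ~ %s\n",
              x$response, if (x$transform == "sqrt") " (sqrt)" else "",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  cat(sprintf("  n = %d, AIC = %.2f, marginal r2 = %.4f, singular = %s, converged = %s\n",
              x$n_obs, x$aic, x$r2, x$singular, x$converged))
  invisible(x)
}

#' Select the best model from a candidate list
#'
#' Among converged, non-singular fits within Delta-AIC < 2 of the minimum
#' AIC: pick the highest marginal r2; where r2 values match to the nearest
#' fifth decimal place, the model with the fewest fixed terms wins; any
#' residual tie goes to the lowest AIC.
#'
#' @param fits list of `lmm_fit` objects.
#' @return the selected `lmm_fit`.
#' @export
select_best <- function(fits) {
  ok <- vapply(fits, function(f)
    isTRUE(f$converged) && isFALSE(f$singular) && is.finite(f$aic),
    logical(1))
  if (!any(ok))
    stop("no converged, non-singular candidate fits", call. = FALSE)
  fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  cand <- fits[aics - min(aics) < 2]
  r2 <- round(vapply(cand, `[[`, numeric(1), "r2"), 5)
  cand <- cand[r2 == max(r2)]
  nt <- vapply(cand, function(f) length(f$terms), integer(1))
  cand <- cand[nt == min(nt)]
  aic2 <- vapply(cand, `[[`, numeric(1), "aic")
  cand[[which.min(aic2)]]
}

#' Closed-form Cook's distances from the fixed-effects projection
#'
#' D_i = r_i^2 h_i / (p (1 - h_i)) with leverage h_i from the fixed-effects
#' hat matrix and internally studentized residual r_i, computed on the
#' marginal (fixed-effects) regression of the transformed response. In the
#' fixed-effects limit this is the classical OLS Cook's distance.
#'
#' @param data data.frame of the modelling rows.
#' @param response,terms,transform,reference as in [fit_lmm()].
#' @return numeric vector of distances, one per complete-case row.
#' @export
cooks_distances <- function(data, response, terms, transform = "identity",
                            reference = "open") {
  df <- .prep_model_data(data, response, terms, reference)
  y <- apply_transform(df[[response]], transform)
  X <- model.matrix(.build_formula(response, terms, "identity",
                                   random = FALSE), df)
  qrX <- qr(X)
  p <- qrX$rank
  h <- rowSums(qr.Q(qrX)[, seq_len(p), drop = FALSE]^2)
  e <- qr.resid(qrX, y)
  n <- length(y)
  s2 <- sum(e^2) / (n - p)
  r2 <- e^2 / (s2 * (1 - h))
  d <- r2 * h / (p * (1 - h))
  d
}

#' Remove influential observations and refit
#'
#' Computes Cook's distances (see [cooks_distances()]), removes rows
#' exceeding the threshold (default 4/n) once — no iteration — and refits
#' the same specification. Aborts with a diagnostic when removal would empty
#' a habitat level.
#'
#' @param fit an `lmm_fit`.
#' @param data the data the fit was built from.
#' @param threshold Cook's distance cutoff; `NULL` means 4/n.
#' @return list(`fit` = refitted `lmm_fit`, `removed` = number of rows
#'   removed).
#' @export
cooks_refit <- function(fit, data, threshold = NULL) {
  df <- .prep_model_data(data, fit$response, fit$terms,
                         fit$reference %||% "open")
  d <- cooks_distances(df, fit$response, fit$terms, fit$transform,
                       fit$reference %||% "open")
  thr <- threshold %||% (4 / length(d))
  keep <- d <= thr
  if ("habitat" %in% names(df) && any(.term_parents_in(fit$terms, "habitat"))) {
    if (!all(.habitat_levels %in% unique(as.character(df$habitat[keep]))) &&
        all(.habitat_levels %in% unique(as.character(df$habitat))))
      stop("outlier removal would empty a habitat level; aborting refit",
           call. = FALSE)
  }
  refit <- fit_lmm(df[keep, , drop = FALSE], fit$response, fit$terms,
                   fit$transform, fit$reference %||% "open", reml = FALSE)
  list(fit = refit, removed = sum(!keep))
}

.term_parents_in <- function(terms, var) {
  vapply(terms, function(tt) var %in% .term_parents(tt), logical(1))
}

#' Coefficient table for a selected model (REML refit)
#'
#' Refits the selected structure by REML and reports, per fixed-effect
#' coefficient: estimate, standard error, the term-level F statistic
#' (Satterthwaite), and the coefficient p-value.
#'
#' @param fit an `lmm_fit`.
#' @param data the modelling data (post outlier removal, typically).
#' @return data.frame with `term`, `coefficient`, `estimate`, `se`,
#'   `F`, `p`.
#' @export
coef_table <- function(fit, data) {
  df <- .prep_model_data(data, fit$response, fit$terms,
                         fit$reference %||% "open")
  fml <- .build_formula(fit$response, fit$terms, fit$transform)
  m <- lmerTest::lmer(fml, data = df, REML = TRUE)
  sm <- summary(m)$coefficients
  X <- model.matrix(m)
  asgn <- attr(X, "assign")
  labs <- attr(terms(m), "term.labels")
  term_of <- c("(Intercept)", labs)[asgn + 1L]
  Ftab <- tryCatch(as.data.frame(stats::anova(m)), error = function(e) NULL)
  Fval <- rep(NA_real_, nrow(sm))
  if (!is.null(Ftab) && nrow(Ftab))
    Fval <- Ftab[term_of, "F value"]
  data.frame(term = term_of,
             coefficient = rownames(sm),
             estimate = sm[, "Estimate"],
             se = sm[, "Std. Error"],
             F = as.numeric(Fval),
             p = sm[, "Pr(>|t|)"],
             row.names = NULL)
}

#' Marginal habitat effects from a fitted model
#'
#' The effect of each habitat level against the reference, evaluated at the
#' mean of any covariates the habitat term interacts with (so a model that
#' happens to retain e.g. a habitat-by-flight-time interaction still yields
#' the average habitat contrast). Standard errors come from the
#' fixed-effects covariance of the corresponding contrast vector.
#'
#' @param fit an `lmm_fit` whose terms include `habitat`.
#' @return data.frame with `level`, `estimate`, `se`.
#' @export
habitat_effects <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"), !is.null(fit$fit))
  fe <- lme4::fixef(fit$fit)
  V <- as.matrix(vcov(fit$fit))
  mf <- stats::model.frame(fit$fit)
  levels_ <- setdiff(.habitat_levels, fit$reference %||% "open")
  out <- lapply(levels_, function(lv) {
    cname <- paste0("habitat", lv)
    if (!cname %in% names(fe)) return(NULL)
    cv <- stats::setNames(numeric(length(fe)), names(fe))
    cv[cname] <- 1
    in_level <- mf$habitat == lv
    for (nm in names(fe)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(parts) == 2 && cname %in% parts) {
        mod <- setdiff(parts, cname)
        # evaluate at the mean of the modifier over this level's rows:
        # habitat and flight time are spatially collinear, so the contrast
        # is identified there rather than at the grand mean
        if (mod %in% names(mf) && is.numeric(mf[[mod]]))
          cv[nm] <- mean(mf[[mod]][in_level])
      }
    }
    data.frame(level = lv, estimate = sum(cv * fe),
               se = sqrt(drop(t(cv) %*% V %*% cv)))
  })
  do.call(rbind, out)
}

#' Habitat layer vs bird/loft independence diagnostic
#'
#' Multinomial logistic regression of habitat category on an identity column
#' (bird or loft), likelihood-ratio tested against the intercept-only model.
#' A non-significant result supports using the identity as a random effect
#' alongside habitat as a fixed effect.
#'
#' @param data data.frame with a `habitat` column.
#' @param predictor identity column name (default `"bird_id"`).
#' @return list(`deviance`, `df`, `p_value`).
#' @export
layer_independence_check <- function(data, predictor = "bird_id") {
  hab <- factor(data$habitat)
  if (nlevels(droplevels(hab)) < 2L)
    stop("habitat has a single level; independence check is degenerate",
         call. = FALSE)
  df <- data.frame(habitat = droplevels(hab),
                   g = factor(data[[predictor]]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  full <- nnet::multinom(habitat ~ g, data = df, trace = FALSE,
                         maxit = 200)
  null <- nnet::multinom(habitat ~ 1, data = df, trace = FALSE)
  stat <- null$deviance - full$deviance
  dof <- full$edf - null$edf
  list(deviance = stat, df = dof,
       p_value = pchisq(stat, dof, lower.tail = FALSE))
}

#' Full model-selection run for one response
#'
#' VIF pruning, exhaustive marginality-respecting subset search by ML,
#' Delta-AIC < 2 / max-r2 / parsimony selection, single-pass Cook's outlier
#' removal, and an REML coefficient report.
#'
#' @param data track-record data.frame (typically post-subsampling).
#' @param response response column name.
#' @param candidate_terms fixed-effect terms of the full model.
#' @param transform `"identity"` or `"sqrt"`.
#' @param reference habitat reference level.
#' @param vif_threshold VIF cutoff (default 5).
#' @param cooks_threshold Cook's cutoff; `NULL` means 4/n.
#' @return a `model_report`: list with the selected fit, final (post-outlier)
#'   fit, coefficient table, and a selection log. When every candidate fit
#'   is singular or non-convergent the report carries
#'   `status = "all_singular"` instead of a selection.
#' @export
select_model <- function(data, response, candidate_terms,
                         transform = "identity", reference = "open",
                         vif_threshold = 5, cooks_threshold = NULL) {
  pr <- vif_prune(data, candidate_terms, vif_threshold)
  specs <- enumerate_subsets(pr$retained)
  fits <- lapply(specs, function(tt)
    fit_lmm(data, response, tt, transform, reference))
  best <- tryCatch(select_best(fits), error = function(e) e)
  if (inherits(best, "error")) {
    out <- list(response = response, status = "all_singular",
                message = conditionMessage(best),
                pruned = pr$removed, n_candidates = length(fits),
                n_singular = sum(vapply(fits, function(f)
                  isTRUE(f$singular), logical(1))))
    class(out) <- "model_report"
    return(out)
  }
  cr <- cooks_refit(best, data, cooks_threshold)
  tab_data <- {
    df <- .prep_model_data(data, response, best$terms, reference)
    d <- cooks_distances(df, response, best$terms, transform, reference)
    thr <- cooks_threshold %||% (4 / length(d))
    df[d <= thr, , drop = FALSE]
  }
  tab <- coef_table(cr$fit, tab_data)
  out <- list(response = response, status = "ok", transform = transform,
              pruned = pr$removed, n_candidates = length(fits),
              selected = best, final = cr$fit, removed_outliers = cr$removed,
              table = tab)
  class(out) <- "model_report"
  out
}

#' @export
print.model_report <- function(x, ...) {
  cat("model_report:", x$response, "\n")
  if (identical(x$status, "all_singular")) {
    cat("  all", x$n_candidates,
        "candidate fits singular or non-convergent; no model selected\n")
    return(invisible(x))
  }
  cat(sprintf("  selected: %s\n  AIC = %.2f, marginal r2 = %.4f, n = %d, outliers removed = %d\n",
              if (length(x$final$terms))
                paste(x$final$terms, collapse = " + ") else "(intercept only)",
              x$final$aic, x$final$r2, x$final$n_obs, x$removed_outliers))
  print(x$table, digits = 3)
  invisible(x)
}
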