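#' Mixed-effects models of stimulation effects
#'
#' Trial-level outcomes (invigoration, maintenance, wanting, exertion) are
#' modeled with dummy-coded fixed effects for stimulation, reward type,
#' reward magnitude, difficulty, the reward magnitude x difficulty
#' interaction, and interactions of stimulation with each of these terms;
#' stimulation order and side enter as mean-centered participant-level
#' covariates. Intercept and trial-level slopes are random by participant.
#' t-contrasts are two-tailed with participant-level approximate degrees of
#' freedom `n_participants - q - 1` (q = number of participant-level
#' covariates), the hierarchical-linear-models convention.
#'
#' @name stim_stats
NULL

prepare_model_frame <- function(dataset, outcome) {
  d <- left_join(dataset$trials, dataset$participants, by = "participant")
  d$order_c <- d$stim_order - mean(dataset$participants$stim_order)
  d$side_c <- d$stim_side - mean(dataset$participants$stim_side)
  d$outcome <- d[[outcome]]
  d[!is.na(d$outcome) & !is.na(d$wanting) & !is.na(d$exertion), ]
}

fixed_rhs <- function(covariates = c("order_c", "side_c"),
                      cross_level_side = FALSE) {
  terms <- c("stimulation", "reward_type", "reward_magnitude", "difficulty",
             "reward_magnitude:difficulty",
             "stimulation:reward_type", "stimulation:reward_magnitude",
             "stimulation:difficulty",
             "stimulation:reward_magnitude:difficulty",
             covariates)
  if (cross_level_side) {
    terms <- c(terms, "side_c:stimulation:reward_type")
  }
  paste(terms, collapse = " + ")
}

random_rhs <- function(random) {
  slopes <- paste("stimulation", "reward_type", "reward_magnitude",
                  "difficulty", sep = " + ")
  switch(random,
         full = sprintf("(1 + %s | participant)", slopes),
         diagonal = sprintf("(1 + %s || participant)", slopes),
         minimal = "(1 + stimulation | participant)")
}

#' Fit a mixed-effects model of stimulation effects
#'
#' REML fit via lme4 with two-tailed t-contrasts at participant-level
#' approximate df. A singular or non-converging fit of the full unstructured
#' random-effects covariance automatically falls back to a diagonal
#' covariance (noted in the result).
#'
#' @param dataset an [effort_dataset()].
#' @param outcome one of `"invigoration"`, `"maintenance"`, `"wanting"`,
#'   `"exertion"`.
#' @param random random-effects structure: `"full"` (unstructured covariance
#'   over intercept + condition slopes), `"diagonal"`, or `"minimal"`
#'   (intercept + stimulation slope).
#' @param covariates participant-level mean-centered covariates (default
#'   stimulation order and side).
#' @param cross_level_side include the cross-level interaction of stimulation
#'   side with stimulation x reward type.
#' @param REML fit by REML (default) or ML.
#' @return object of class `stim_model`: `coefficients` tibble
#'   (term, b, se, t, df, p), the lme4 `fit`, `df`, and metadata.
#' @export
fit_stim_model <- function(dataset, outcome = "invigoration",
                           random = c("full", "diagonal", "minimal"),
                           covariates = c("order_c", "side_c"),
                           cross_level_side = FALSE, REML = TRUE) {
  random <- match.arg(random)
  d <- prepare_model_frame(dataset, outcome)
  stopifnot(length(unique(d$participant)) >= 2)
  form <- function(r) {
    as.formula(paste("outcome ~", fixed_rhs(covariates, cross_level_side),
                     "+", random_rhs(r)))
  }
  fallback <- FALSE
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form(random), data = d, REML = REML)))
  if (random == "full" &&
      (lme4::isSingular(fit, tol = 1e-4) ||
       length(fit@optinfo$conv$lme4$messages) > 0)) {
    fallback <- TRUE
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(form("diagonal"), data = d, REML = REML)))
  }
  n_part <- length(unique(d$participant))
  df <- n_part - length(covariates) - 1
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  t <- b / se
  coefs <- tibble(term = names(b), b = unname(b), se = unname(se),
                  t = unname(t), df = df,
                  p = 2 * pt(-abs(unname(t)), df))
  structure(
    list(coefficients = coefs, fit = fit, outcome = outcome, df = df,
         n_participants = n_part, random = if (fallback) "diagonal" else
           random, fallback = fallback, REML = REML),
    class = "stim_model")
}

#' @export
print.stim_model <- function(x, ...) {
  cat(sprintf("<stim_model> outcome: %s | %d participants | df = %d%s\n",
              x$outcome, x$n_participants, x$df,
              if (x$fallback) " | diagonal fallback" else ""))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Marginal stimulation contrast of a fitted model
#'
#' The taVNS - sham effect averaged across the condition cells: with dummy
#' coding this is the `stimulation` coefficient plus half of each two-way
#' stimulation interaction and a quarter of the three-way. Because the
#' contrast loads with weight 1 on the participant-level stimulation slope,
#' its standard error is driven by the random-slope variance and is well
#' calibrated; the raw `stimulation` coefficient is instead the contrast in
#' the reference cells only.
#'
#' @param model a [fit_stim_model()] result.
#' @return one-row tibble with `b`, `se`, `t`, `df`, `p` (two-tailed, at the
#'   model's participant-level df).
#' @export
stim_contrast <- function(model) {
  stopifnot(inherits(model, "stim_model"))
  co <- model$coefficients
  V <- as.matrix(vcov(model$fit))
  cvec <- setNames(numeric(nrow(co)), co$term)
  cvec["stimulation"] <- 1
  for (tm in c("stimulation:reward_type", "stimulation:reward_magnitude",
               "stimulation:difficulty")) {
    if (tm %in% co$term) cvec[tm] <- 0.5
  }
  if ("stimulation:reward_magnitude:difficulty" %in% co$term) {
    cvec["stimulation:reward_magnitude:difficulty"] <- 0.25
  }
  b <- sum(cvec * co$b)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  tstat <- b / se
  tibble(b = b, se = se, t = tstat, df = model$df,
         p = 2 * pt(-abs(tstat), model$df))
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Both models are refitted by maximum likelihood on the same rows and
#' compared by the likelihood-ratio chi-square with df equal to the
#' parameter-count difference.
#'
#' @param model_restricted,model_extended `stim_model` objects with nested
#'   fixed/random structures fitted to the same data.
#' @return list with `chisq`, `df`, `p`.
#' @export
nested_comparison <- function(model_restricted, model_extended) {
  f1 <- model_restricted$fit; f2 <- model_extended$fit
  if (nobs(f1) != nobs(f2)) {
    stop_field("models were fitted to different rows; not nested")
  }
  r1 <- suppressWarnings(suppressMessages(refit_ml(f1)))
  r2 <- suppressWarnings(suppressMessages(refit_ml(f2)))
  df1 <- attr(logLik(r1), "df"); df2 <- attr(logLik(r2), "df")
  if (df2 < df1) stop_field("extended model has fewer parameters; not nested")
  chisq <- max(0, 2 * (as.numeric(logLik(r2)) - as.numeric(logLik(r1))))
  df <- df2 - df1
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

refit_ml <- function(fit) {
  if (isTRUE(lme4::isREML(fit))) lme4::refitML(fit) else fit
}

#' Order-corrected individual stimulation effects
#'
#' Per participant, the ordinary-least-squares coefficient of the outcome on
#' the stimulation dummy across that participant's trials; the effects are
#' then residualized for (mean-centered) stimulation order across
#' participants, with the grand mean added back. Participants missing a
#' session are skipped with a message.
#'
#' @param dataset an [effort_dataset()].
#' @param outcome outcome column name.
#' @param order_correct residualize for stimulation order (default TRUE).
#' @return tibble with `participant` and `effect`.
#' @export
individual_stim_effects <- function(dataset, outcome = "invigoration",
                                    order_correct = TRUE) {
  d <- prepare_model_frame(dataset, outcome)
  eff <- vapply(split(d, d$participant), function(di) {
    if (length(unique(di$session)) < 2) return(NA_real_)
    coef(lm(outcome ~ stimulation, data = di))[["stimulation"]]
  }, numeric(1))
  skipped <- names(eff)[is.na(eff)]
  if (length(skipped)) {
    message("skipping participant(s) missing a session: ",
            paste(skipped, collapse = ", "))
  }
  out <- tibble(participant = names(eff), effect = unname(eff))
  out <- out[!is.na(out$effect), ]
  if (order_correct) {
    ord <- dataset$participants$stim_order[
      match(out$participant, dataset$participants$participant)]
    ord_c <- ord - mean(ord)
    if (var(ord_c) > 0) {
      out$effect <- unname(residuals(lm(out$effect ~ ord_c))) +
        mean(out$effect)
    }
  }
  out
}

#' Jeffreys-Zellner-Siow Bayes factor for a one-sample effect
#'
#' Two-sided BF10 for the mean of `effects` against 0 under a Cauchy(0, r)
#' prior on the standardized effect size, computed by numerical integration
#' of the non-central t likelihood over the prior:
#' `BF10 = integral dt(t; nu, delta sqrt(n)) dCauchy(delta; 0, r) ddelta /
#' dt(t; nu, 0)`.
#'
#' @param effects numeric vector of individual effects (n >= 3) — or pass
#'   `t` and `n` directly.
#' @param cauchy_scale prior scale r (default 0.707).
#' @param t,n alternatively, the one-sample t statistic and sample size.
#' @return BF10 (numeric).
#' @export
jzs_bayes_factor <- function(effects = NULL, cauchy_scale = 0.707,
                             t = NULL, n = NULL) {
  if (is.null(t)) {
    effects <- effects[!is.na(effects)]
    if (length(effects) < 3) stop_field("need n >= 3 effects")
    if (sd(effects) == 0) {
      stop_field("zero variance in effects; t statistic undefined")
    }
    n <- length(effects)
    t <- mean(effects) / (sd(effects) / sqrt(n))
  }
  nu <- n - 1
  like <- function(delta) {
    suppressWarnings(dt(t, df = nu, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, cauchy_scale)
  }
  m1 <- integrate(like, -Inf, Inf, rel.tol = 1e-9,
                  stop.on.error = FALSE)$value
  m0 <- dt(t, df = nu)
  m1 / m0
}

#' Blinding check: exact binomial test of guess accuracy
#'
#' @param n_correct correct condition guesses.
#' @param n_guesses total guesses (> 0).
#' @return list with `accuracy` (percent) and two-sided exact binomial `p`
#'   against chance (0.5).
#' @export
blinding_binomial_test <- function(n_correct, n_guesses) {
  if (n_guesses <= 0) stop_field("n_guesses must be > 0")
  if (n_correct < 0 || n_correct > n_guesses) {
    stop_field("need 0 <= n_correct <= n_guesses")
  }
  bt <- binom.test(n_correct, n_guesses, p = 0.5)
  list(accuracy = 100 * n_correct / n_guesses, p = bt$p.value)
}

#' Effect size relative to the model intercept
#'
#' @param b fixed-effect estimate.
#' @param intercept model intercept (non-zero).
#' @return `100 * b / intercept`, in percent.
#' @export
relative_effect <- function(b, intercept) {
  if (intercept == 0) stop_field("intercept must be non-zero")
  100 * b / intercept
}
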