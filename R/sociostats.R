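# Group-level statistics: nuisance adjustment of performance scores,
# random-effect analysis of species and opponent effects, Sobel mediation
# and species-feature regressions of ToM sophistication.

#' Adjust per-session scores for non-specific session effects
#'
#' Regresses out, per individual, the effect of session repetition and of
#' the time elapsed since the previous session by ordinary least squares,
#' returning residuals plus the individual's grand mean. Idempotent: the
#' nuisance regressors explain nothing in already-adjusted scores.
#'
#' @param scores data.frame with columns `individual_id`, `session_index`,
#'   `day_gap` and `score` (e.g. per-session win rates).
#' @return the input with an `adjusted` column added.
#' @export
adjust_performance <- function(scores) {
  stopifnot(all(c("individual_id", "session_index", "day_gap", "score") %in%
                  names(scores)))
  parts <- split(scores, scores$individual_id)
  out <- lapply(parts, function(d) {
    if (nrow(d) < 3) stop("need >= 3 sessions per individual")
    x1 <- d$session_index - mean(d$session_index)
    x2 <- d$day_gap - mean(d$day_gap)
    keep <- c(sd(x1) > 0, sd(x2) > 0)
    if (!all(keep)) warning("rank-deficient nuisance design: column dropped")
    X <- cbind(x1, x2)[, keep, drop = FALSE]
    if (ncol(X) == 0) {
      d$adjusted <- d$score
    } else {
      fit <- lm.fit(cbind(1, X), d$score)
      d$adjusted <- residuals(fit) + mean(d$score)
    }
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# nested-model F test between two lm fits (textbook extra-sum-of-squares)
nested_f <- function(fit0, fit1) {
  rss0 <- sum(residuals(fit0)^2)
  rss1 <- sum(residuals(fit1)^2)
  df_num <- fit0$df.residual - fit1$df.residual
  df_den <- fit1$df.residual
  f <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  list(F = f, df1 = df_num, df2 = df_den,
       R2 = (rss0 - rss1) / rss0,
       p = pf(f, df_num, df_den, lower.tail = FALSE))
}

#' Random-effect analysis of species and opponent effects on performance
#'
#' Mixed two-stratum analysis of adjusted per-condition scores. The
#' within-individual stratum fits subject intercepts plus the opponent
#' effect, the species-by-opponent interaction and optional
#' covariate-by-opponent interactions, testing each term by nested-model
#' comparison. The between-individual stratum tests the species effect on
#' individual mean scores, and weighted linear contrasts test continuous
#' species features (e.g. endocranial volume, group size) there.
#'
#' @param scores data.frame with one row per individual x condition:
#'   columns `individual_id`, `species`, `opponent`, `score`.
#' @param covariates optional data.frame of individual covariates (one row
#'   per individual, with `individual_id`) whose interaction with opponent
#'   enters the within stratum.
#' @param feature_contrasts optional data.frame `species`, plus one column
#'   per continuous feature to test as a weighted linear contrast across
#'   species.
#' @return a list of test records (each with `F`, `df1`, `df2`, `R2`, `p`).
#' @export
effects_regression <- function(scores, covariates = NULL,
                               feature_contrasts = NULL) {
  need <- c("individual_id", "species", "opponent", "score")
  stopifnot(all(need %in% names(scores)))
  d <- scores
  d$individual_id <- factor(d$individual_id)
  d$species <- factor(d$species)
  d$opponent <- factor(d$opponent)
  if (any(table(d$individual_id, d$opponent) == 0))
    stop("design not fully crossed: missing individual x opponent cells")
  if (!is.null(covariates)) {
    d <- merge(d, covariates, by = "individual_id", sort = FALSE)
  }
  cov_names <- if (is.null(covariates))
    character(0) else setdiff(names(covariates), "individual_id")

  # within-individual stratum; with a single species the model reduces to
  # one-way repeated-measures ANOVA on the opponent factor
  multi_species <- nlevels(d$species) > 1
  base_terms <- "individual_id"
  cov_terms <- if (length(cov_names))
    paste0(cov_names, ":opponent") else character(0)
  form <- function(terms) {
    as.formula(paste("score ~", paste(terms, collapse = " + ")))
  }
  fit_no_opp <- lm(form(c(base_terms, cov_terms)), data = d)
  fit_no_int <- lm(form(c(base_terms, "opponent", cov_terms)), data = d)
  tests <- list(opponent = nested_f(fit_no_opp, fit_no_int))
  if (multi_species) {
    fit_full <- lm(form(c(base_terms, "opponent", cov_terms,
                          "species:opponent")), data = d)
    tests$species_x_opponent <- nested_f(fit_no_int, fit_full)
  }

  # between-individual stratum: species effect on individual means
  means <- aggregate(score ~ individual_id + species, data = d, FUN = mean)
  if (multi_species) {
    fit_b1 <- lm(score ~ species, data = means)
    fit_b0 <- lm(score ~ 1, data = means)
    tests$species <- nested_f(fit_b0, fit_b1)
  } else {
    fit_b0 <- lm(score ~ 1, data = means)
  }

  if (!is.null(feature_contrasts)) {
    stopifnot("species" %in% names(feature_contrasts))
    fm <- merge(means, feature_contrasts, by = "species", sort = FALSE)
    for (fc in setdiff(names(feature_contrasts), "species")) {
      x <- fm[[fc]]
      fitc <- lm(fm$score ~ x)
      tests[[fc]] <- nested_f(fit_b0, fitc)
    }
  }
  tests
}

#' Sobel mediation test
#'
#' Tests whether `mediator` carries the effect of `x` on `y`: with `a` the
#' slope of `mediator ~ x` and `b` the slope of `mediator` in
#' `y ~ x + mediator`, the statistic is
#' `z = a b / sqrt(a^2 se_b^2 + b^2 se_a^2)` with a two-sided normal
#' p-value.
#'
#' @param x,mediator,y numeric vectors of equal length (n >= 10).
#' @return a list with `z`, `p`, `a`, `b`, `se_a`, `se_b`.
#' @export
sobel_mediation <- function(x, mediator, y) {
  n <- length(x)
  stopifnot(length(mediator) == n, length(y) == n, n >= 10)
  if (sd(x) == 0 || sd(mediator) == 0 || sd(y) == 0)
    stop("zero-variance input")
  f1 <- summary(lm(mediator ~ x))$coefficients
  f2 <- summary(lm(y ~ x + mediator))$coefficients
  a <- f1["x", "Estimate"]; se_a <- f1["x", "Std. Error"]
  b <- f2["mediator", "Estimate"]; se_b <- f2["mediator", "Std. Error"]
  z <- a * b / sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  list(z = z, p = 2 * pnorm(-abs(z)), a = a, b = b, se_a = se_a, se_b = se_b)
}

#' Species-feature regression of ToM sophistication
#'
#' Pairwise Pearson correlations of species pToM against each feature
#' (log-transformed by default) and a concurrent multiple regression of
#' pToM on the included features, with one- and two-sided p-values.
#'
#' @param ptom_species data.frame with columns `species` and `ptom`.
#' @param features a species feature table with column `species` plus
#'   feature columns (e.g. `ecv`, `group_size`).
#' @param include feature columns to use.
#' @param log_features log-transform features before analysis (default
#'   TRUE, matching the customary log-log scale for allometric features).
#' @param interaction include the pairwise interaction of the first two
#'   features in the multiple regression.
#' @return a list with `pairwise` (data.frame: feature, r, p_two_sided,
#'   p_one_sided, degenerate) and `regression` (coefficient table plus
#'   adjusted R2), or `regression = NULL` when fewer than 4 species.
#' @export
species_feature_regression <- function(ptom_species, features,
                                       include = c("ecv", "group_size"),
                                       log_features = TRUE,
                                       interaction = FALSE) {
  stopifnot(all(c("species", "ptom") %in% names(ptom_species)))
  stopifnot(all(include %in% names(features)))
  d <- merge(ptom_species, features, by = "species", sort = FALSE)
  if (nrow(d) < 4) stop("need >= 4 species")
  X <- d[include]
  if (log_features) X <- log(X)
  y <- d$ptom

  pairwise <- do.call(rbind, lapply(include, function(fc) {
    x <- X[[fc]]
    if (sd(y) == 0 || sd(x) == 0) {
      return(data.frame(feature = fc, r = NA_real_, p_two_sided = NA_real_,
                        p_one_sided = NA_real_, degenerate = TRUE))
    }
    ct <- cor.test(x, y)
    ct1 <- cor.test(x, y, alternative = "greater")
    data.frame(feature = fc, r = unname(ct$estimate),
               p_two_sided = ct$p.value, p_one_sided = ct1$p.value,
               degenerate = FALSE)
  }))

  regression <- NULL
  if (sd(y) > 0) {
    df <- data.frame(ptom = y, X)
    terms <- include
    if (interaction && length(include) >= 2)
      terms <- c(terms, paste(include[1], include[2], sep = ":"))
    fit <- lm(as.formula(paste("ptom ~", paste(terms, collapse = " + "))),
              data = df)
    sm <- summary(fit)
    kap <- kappa(model.matrix(fit))
    if (kap > 1e3) warning("ill-conditioned feature design (kappa = ",
                           signif(kap, 3), ")")
    regression <- list(coefficients = sm$coefficients,
                       adj_r_squared = sm$adj.r.squared)
  }
  list(pairwise = pairwise, regression = regression)
}
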