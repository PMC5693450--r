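# Synthetic cohorts with the study's structure and known ground truth,
# plus the confusion and parameter-recovery harnesses.

#' Synthetic species feature table
#'
#' Seven primate-like species with plausible endocranial volumes (cm^3),
#' mean social group sizes, neocortex ratios and life expectancies. The
#' values are synthetic placeholders shipped for simulation studies (see
#' the packaged file `species_features_synthetic.csv`); any user table with
#' the same columns can be substituted.
#'
#' @return a data.frame with columns `species`, `ecv_cm3`, `group_size`,
#'   `neocortex_ratio`, `life_expectancy`.
#' @export
species_features <- function() {
  read.csv(system.file("extdata", "species_features_synthetic.csv",
                       package = "tomassay"))
}

#' The study's published per-species sample sizes
#'
#' @return named integer vector of individuals per species (7 species,
#'   mean 5.7, SD 1.8).
#' @export
study_sample_sizes <- function() {
  c(orangutan = 7L, chimpanzee = 6L, western_gorilla = 5L,
    lion_tailed_macaque = 4L, rhesus_macaque = 5L, sooty_mangabey = 9L,
    ring_tailed_lemur = 4L)
}

# default per-species mixture over generating models: the ToM-family weight
# increases with ECV rank, emulating the scaffolding scenario under study
default_mixtures <- function(species_tab) {
  n <- nrow(species_tab)
  rk <- rank(species_tab$ecv_cm3, ties.method = "first")
  tom_split <- c("Inf-coop" = 0.45, "Inf-comp" = 0.10, "1ToM-coop" = 0.30,
                 "1ToM-comp" = 0.05, "2ToM-coop" = 0.07, "2ToM-comp" = 0.03)
  notom_split <- c("BN" = 0.10, "WS" = 0.30, "RL" = 0.30, "0ToM" = 0.30)
  mix <- lapply(seq_len(n), function(i) {
    w <- 0.15 + 0.7 * (rk[i] - 1) / (n - 1)
    c(tom_split * w, notom_split * (1 - w))[model_ids()]
  })
  names(mix) <- species_tab$species
  mix
}

# sample natural-scale generating parameters for one cohort individual.
# Unlike the near-greedy artificial agents, simulated subjects emulate
# animal-like choice stochasticity (temperature around 0.5), which is also
# what keeps the candidate models mutually discriminable: at ceiling
# determinism several models predict the same choices and evidence cannot
# separate them. Volatility is centred per family: 0-ToM subjects track a
# nonstationary action stream (vol ~ 0.5), recursive agents track the
# quasi-stationary parameters of their opponent model (vol ~ 0.05).
sample_agent_params <- function(model_id) {
  vol_centre <- if (grepl("^[12]ToM", model_id)) 0.05 else 0.5
  list(vol = exp(rnorm(1, log(vol_centre), 0.5)),
       beta = exp(rnorm(1, log(0.5), 0.5)),
       bias = rnorm(1, 0, 0.3),
       alpha = plogis(rnorm(1, 0, 0.7)),
       eta = plogis(rnorm(1, 0.85, 0.5)),
       lambda = exp(rnorm(1, log(0.5), 0.4)))
}

#' Specify a synthetic cohort
#'
#' @param species species feature table (default [species_features()]).
#' @param n_per_species individuals per species: a single number or a
#'   vector along species (default 5).
#' @param mixtures named list (per species) of probability vectors over the
#'   ten generating models; defaults to a ToM weight increasing with ECV.
#' @param design the session protocol, a [protocol_design()].
#' @param seed master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(species = species_features(), n_per_species = 5,
                        mixtures = default_mixtures(species),
                        design = protocol_design(), seed = 1) {
  n_per_species <- rep_len(n_per_species, nrow(species))
  stopifnot(identical(sort(names(mixtures)), sort(species$species)))
  for (m in mixtures) {
    stopifnot(length(m) == 10, abs(sum(m) - 1) < 1e-8, all(m >= 0))
  }
  structure(list(species = species, n_per_species = n_per_species,
                 mixtures = mixtures, design = design, seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of individuals through the session protocol
#'
#' For each individual: a generating model is drawn from its species
#' mixture, parameters are sampled, covariates assigned, and the full
#' session protocol run. Byte-identical outputs for identical specs.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `trials` (tidy trial log: `individual_id`,
#'   `species`, `session_index`, `condition`, `trial`, `a_self`, `a_op`,
#'   `reward`, `day_gap`, `included`), `truth` (ground-truth generating
#'   model and parameters per individual) and `covariates` (age, sex,
#'   rearing).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sp <- spec$species
  with_seed(spec$seed, {
    trials <- list(); truth <- list(); covs <- list()
    idx <- 0L
    for (i in seq_len(nrow(sp))) {
      mix <- spec$mixtures[[sp$species[i]]]
      for (j in seq_len(spec$n_per_species[i])) {
        idx <- idx + 1L
        id <- sprintf("%s_%02d", sp$species[i], j)
        model <- sample(names(mix), 1, prob = mix)
        pars <- sample_agent_params(model)
        subject <- agent_spec(model, pars, role = "seeker")
        seed_i <- sample.int(.Machine$integer.max - 1L, 1)
        tr <- run_protocol(subject, spec$design, seed = seed_i,
                           individual_index = idx)
        tr$individual_id <- id
        tr$species <- sp$species[i]
        trials[[idx]] <- tr
        act <- active_params(model)
        truth[[idx]] <- data.frame(
          individual_id = id, species = sp$species[i], model_id = model,
          family = tom_models()$family[tom_models()$model_id == model],
          beta = pars$beta, bias = pars$bias, vol = pars$vol,
          alpha = pars$alpha, eta = pars$eta, lambda = pars$lambda,
          seed = seed_i, stringsAsFactors = FALSE)
        covs[[idx]] <- data.frame(
          individual_id = id, species = sp$species[i],
          age_norm = runif(1, 0.2, 0.9),
          sex = rbinom(1, 1, 0.5),
          rearing = rbinom(1, 1, 0.5))
      }
    }
    list(trials = do.call(rbind, trials),
         truth = do.call(rbind, truth),
         covariates = do.call(rbind, covs))
  })
}

#' Model-identifiability confusion analysis
#'
#' Simulates individuals from each generating model, inverts the full model
#' set on each and tabulates the best-evidence model, yielding the 10x10
#' confusion matrix and its ToM/no-ToM family aggregation.
#'
#' @param n_per_model simulated individuals per generating model (>= 5 for
#'   a meaningful table; errors if < 1).
#' @param design session protocol (default [reduced_design()]).
#' @param seed master seed.
#' @param opts fitting options.
#' @return a list with `counts` (10x10: generating x best model), `family`
#'   (2x2 proportions), `failures` (inversion errors, counted separately).
#' @export
confusion_analysis <- function(n_per_model = 5, design = reduced_design(),
                               seed = 1, opts = fit_options()) {
  if (n_per_model < 1) stop("n_per_model must be >= 1")
  ids <- model_ids()
  counts <- matrix(0L, 10, 10, dimnames = list(generating = ids, best = ids))
  failures <- 0L
  seeds <- child_seeds(seed, 10 * n_per_model)
  k <- 0L
  for (m in ids) {
    for (r in seq_len(n_per_model)) {
      k <- k + 1L
      tr <- with_seed(seeds[k], {
        pars <- sample_agent_params(m)
        run_protocol(agent_spec(m, pars, role = "seeker"), design,
                     seed = seeds[k], individual_index = k)
      })
      ev <- tryCatch(
        vapply(ids, function(mm) {
          sum(vapply(conditions(), function(cc)
            fit_condition(mm, tr[tr$condition == cc, ],
                          opts = opts)$free_energy, numeric(1)))
        }, numeric(1)),
        error = function(e) NULL)
      if (is.null(ev)) { failures <- failures + 1L; next }
      counts[m, names(which.max(ev))] <- counts[m, names(which.max(ev))] + 1L
    }
  }
  fam <- tom_models()$family
  fam_counts <- rbind(
    notom = colSums(counts[fam == "notom", , drop = FALSE]),
    tom = colSums(counts[fam == "tom", , drop = FALSE]))
  fam_mat <- cbind(notom = rowSums(fam_counts[, fam == "notom", drop = FALSE]),
                   tom = rowSums(fam_counts[, fam == "tom", drop = FALSE]))
  fam_prop <- fam_mat / pmax(rowSums(fam_mat), 1)
  list(counts = counts, family = fam_prop, failures = failures)
}

#' Parameter-recovery study for one model
#'
#' Simulates choice data at each grid point, refits the generating model
#' and reports the posterior mean, its error and whether the 95% posterior
#' interval covers the truth.
#'
#' @param model_id the generating (and fitted) model.
#' @param grid data.frame of natural-scale parameter values, one column per
#'   parameter to vary (e.g. `alpha`); other parameters take defaults.
#' @param n_seeds replicate simulations per grid point.
#' @param design session protocol (default [reduced_design()]).
#' @param seed master seed.
#' @param opts fitting options.
#' @return a data.frame with one row per grid point x seed x parameter:
#'   truth, posterior mean and SD (transformed scale) and 95% coverage.
#' @export
parameter_recovery <- function(model_id, grid, n_seeds = 20,
                               design = reduced_design(), seed = 1,
                               opts = fit_options()) {
  if (NROW(grid) == 0)
    return(data.frame(grid_point = integer(0), seed = integer(0),
                      param = character(0), truth = numeric(0),
                      post_mean = numeric(0), post_sd = numeric(0),
                      covered = logical(0)))
  grid <- as.data.frame(grid)
  seeds <- child_seeds(seed, NROW(grid) * n_seeds)
  tonat <- function(name, value) switch(name,
    log_vol = exp(value), log_beta = exp(value), log_lambda = exp(value),
    logit_alpha = plogis(value), logit_eta = plogis(value), value)
  totrans <- function(name, value) switch(name,
    vol = c(log_vol = log(value)), beta = c(log_beta = log(value)),
    lambda = c(log_lambda = log(value)), alpha = c(logit_alpha = qlogis(value)),
    eta = c(logit_eta = qlogis(value)), bias = c(bias = value))
  out <- list(); k <- 0L
  for (g in seq_len(NROW(grid))) {
    for (r in seq_len(n_seeds)) {
      k <- k + 1L
      res <- with_seed(seeds[k], {
        pars <- sample_agent_params(model_id)
        for (nm in names(grid)) pars[[nm]] <- grid[[nm]][g]
        tr <- run_protocol(agent_spec(model_id, pars, role = "seeker"),
                           design, seed = seeds[k], individual_index = k)
        fit <- fit_condition(model_id, tr, opts = opts)
        truth_t <- unlist(lapply(names(grid), function(nm)
          totrans(nm, grid[[nm]][g])))
        rows <- lapply(names(truth_t), function(tn) {
          mu <- fit$post_mean[[tn]]
          sdv <- sqrt(diag(fit$post_cov))[[which(names(fit$post_mean) == tn)]]
          data.frame(grid_point = g, seed = r, param = tn,
                     truth = truth_t[[tn]], post_mean = mu, post_sd = sdv,
                     covered = abs(mu - truth_t[[tn]]) <= 1.96 * sdv)
        })
        do.call(rbind, rows)
      })
      out[[k]] <- res
    }
  }
  do.call(rbind, out)
}
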