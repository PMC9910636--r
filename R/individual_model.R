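#' Sampler settings for the MCMC fits
#'
#' @param chains number of chains.
#' @param adapt adaptation (warmup) iterations per chain.
#' @param iter kept iterations per chain.
#' @param seed integer seed; chain c uses `seed + c` for its RNG stream.
#' @param rhat_max convergence gate: largest acceptable split R-hat.
#' @return A list of class `sampler_settings`.
#' @export
sampler_settings <- function(chains = 4L, adapt = 500L, iter = 1000L,
                             seed = 1L, rhat_max = 1.05) {
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 iter = as.integer(iter), seed = as.integer(seed),
                 rhat_max = rhat_max), class = "sampler_settings")
}

#' Build model inputs from dyad records
#'
#' Subsets one feature, validates the match counts, mean-centers age and
#' position, and builds the index arrays for the child, group and community
#' varying effects. Shape and colour are fitted as separate models, so the
#' design holds a single feature.
#'
#' @param records dyad table (see [simulate_dyads()] for the schema).
#' @param feature `"shape"` or `"color"`.
#' @return A list of class `individual_design` with outcome vectors `y`, `n`,
#'   covariates, index arrays and the centering constants.
#' @export
build_design <- function(records, feature = c("shape", "color")) {
  feature <- match.arg(feature)
  need <- c("child_id", "group_id", "community", "condition", "position",
            "age_years", "sex", "feature", "y_matches", "n_max")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("dyad table is missing columns: ",
                         paste(miss, collapse = ", "))
  d <- records[records$feature == feature, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for feature ", feature)
  if (any(d$n_max < 1L)) stop("n_max must be >= 1")
  if (any(d$y_matches < 0L | d$y_matches > d$n_max)) {
    stop("y_matches must lie in [0, n_max]")
  }
  comm_levels <- sort(unique(d$community))
  group_levels <- sort(unique(d$group_id))
  child_levels <- sort(unique(d$child_id))
  structure(list(
    feature = feature,
    y = as.integer(d$y_matches), n = as.integer(d$n_max),
    cond = as.numeric(d$condition == "observed"),
    sex = as.numeric(d$sex == "male"),
    age = d$age_years - mean(d$age_years),
    pos = d$position - mean(d$position),
    comm = match(d$community, comm_levels),
    grp = match(d$group_id, group_levels),
    child = match(d$child_id, child_levels),
    centers = list(age = mean(d$age_years), position = mean(d$position)),
    levels = list(community = comm_levels, group = group_levels,
                  child = child_levels),
    N = nrow(d)
  ), class = "individual_design")
}

jags_full_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- a[comm[i]] + u_comm[comm[i]] + u_g[grp[i]] + u_ch[child[i]] +
      (b_cond + bc[comm[i]]) * cond[i] +
      b_pos * pos[i] + b_sex * sex[i] + b_sexcond * sex[i] * cond[i] +
      (b_age + ba[comm[i]]) * age[i] +
      (b_agecond + bac[comm[i]]) * age[i] * cond[i]
  }
  for (k in 1:K) {
    a[k] ~ dnorm(0, 0.4444444444)
    u_comm[k] ~ dnorm(0, tau_comm)
    bc[k] ~ dnorm(0, 1)
    ba[k] ~ dnorm(0, 1)
    bac[k] ~ dnorm(0, 1)
  }
  for (j in 1:J) { u_g[j] ~ dnorm(0, tau_g) }
  for (c in 1:C) { u_ch[c] ~ dnorm(0, tau_ch) }
  b_cond ~ dnorm(0, 1)
  b_pos ~ dnorm(0, 1)
  b_sex ~ dnorm(0, 1)
  b_sexcond ~ dnorm(0, 1)
  b_age ~ dnorm(0, 1)
  b_agecond ~ dnorm(0, 1)
  sd_comm ~ dexp(1)
  sd_g ~ dexp(1)
  sd_ch ~ dexp(1)
  tau_comm <- pow(sd_comm, -2)
  tau_g <- pow(sd_g, -2)
  tau_ch <- pow(sd_ch, -2)
}"

jags_age_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- a[comm[i]] + u_g[grp[i]] + u_ch[child[i]] +
      (b_age + ba[comm[i]]) * age[i] +
      (b_cond + bc[comm[i]]) * cond[i] +
      (b_agecond + bac[comm[i]]) * age[i] * cond[i]
  }
  for (k in 1:K) {
    a[k] ~ dnorm(mu_a, tau_comm)
    ba[k] ~ dnorm(0, tau_ba)
    bc[k] ~ dnorm(0, tau_bc)
    bac[k] ~ dnorm(0, tau_bac)
  }
  for (j in 1:J) { u_g[j] ~ dnorm(0, tau_g) }
  for (c in 1:C) { u_ch[c] ~ dnorm(0, tau_ch) }
  mu_a ~ dnorm(0, 0.4444444444)
  b_age ~ dnorm(0, 1)
  b_cond ~ dnorm(0, 1)
  b_agecond ~ dnorm(0, 1)
  sd_comm ~ dexp(1)
  sd_ba ~ dexp(1)
  sd_bc ~ dexp(1)
  sd_bac ~ dexp(1)
  sd_g ~ dexp(1)
  sd_ch ~ dexp(1)
  tau_comm <- pow(sd_comm, -2)
  tau_ba <- pow(sd_ba, -2)
  tau_bc <- pow(sd_bc, -2)
  tau_bac <- pow(sd_bac, -2)
  tau_g <- pow(sd_g, -2)
  tau_ch <- pow(sd_ch, -2)
}"

#' Construct a posterior-draws object
#'
#' Container for MCMC output: a draws matrix with named parameter columns, a
#' chain index per row, the model identifier, and the metadata needed to
#' evaluate linear predictors (centering constants, factor levels).
#'
#' @param draws numeric matrix, total kept draws x parameters, with column
#'   names in JAGS style (`"a[1]"`, `"b_cond"`, ...).
#' @param chain integer vector of chain ids, one per row.
#' @param model one of `"individual_full"`, `"individual_age"`, `"chain"`.
#' @param meta list of model metadata.
#' @param diagnostics per-parameter diagnostic table, or `NULL`.
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, chain, model, meta = list(),
                            diagnostics = NULL) {
  stopifnot(is.matrix(draws), nrow(draws) == length(chain))
  structure(list(draws = draws, chain = chain, model = model, meta = meta,
                 diagnostics = diagnostics),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws: %s, %d draws x %d parameters, %d chains>\n",
              x$model, nrow(x$draws), ncol(x$draws),
              length(unique(x$chain))))
  if (!is.null(x$diagnostics)) {
    bad <- x$diagnostics$rhat > x$meta$rhat_max
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      cat("convergence flagged for:",
          paste(x$diagnostics$parameter[bad], collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Extract a parameter's draws
#' @param fit a [posterior_draws()] object.
#' @param name parameter name, e.g. `"b_cond"` or `"a[2]"`.
#' @return Numeric vector of draws.
#' @export
param_draws <- function(fit, name) {
  if (!name %in% colnames(fit$draws)) stop("unknown parameter: ", name)
  fit$draws[, name]
}

run_jags <- function(model_string, data, monitors, settings, use_glm = TRUE) {
  # The glm module's block samplers are essential for the redundantly
  # parameterised binomial models but scale badly on the large Bernoulli
  # graph of the chain model, so module use is chosen per model.
  if (use_glm) {
    rjags::load.module("glm", quiet = TRUE)
  } else if ("glm" %in% rjags::list.modules()) {
    rjags::unload.module("glm", quiet = TRUE)
  }
  inits <- lapply(seq_len(settings$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = settings$seed + c)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = settings$chains,
                          n.adapt = settings$adapt, quiet = TRUE)
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = settings$iter)
  draws <- do.call(rbind, lapply(samp, as.matrix))
  chain <- rep(seq_len(settings$chains), each = settings$iter)
  list(draws = draws, chain = chain)
}

mcmc_diagnostics <- function(draws, chain, rhat_max) {
  chains <- sort(unique(chain))
  per_param <- function(j) {
    mat <- vapply(chains, function(c) draws[chain == c, j], numeric(sum(chain == chains[1])))
    rhat <- split_rhat(mat)
    ess <- tryCatch(
      sum(coda::effectiveSize(coda::as.mcmc.list(
        lapply(seq_len(ncol(mat)), function(cc) coda::mcmc(mat[, cc]))))),
      error = function(e) NA_real_)
    c(rhat = rhat, ess = ess)
  }
  dg <- t(vapply(seq_len(ncol(draws)), per_param, numeric(2)))
  out <- data.frame(parameter = colnames(draws), rhat = dg[, "rhat"],
                    ess = dg[, "ess"], stringsAsFactors = FALSE)
  flagged <- out$parameter[!is.na(out$rhat) & out$rhat > rhat_max]
  if (length(flagged)) {
    warning("convergence gate: split R-hat above ", rhat_max, " for ",
            paste(flagged, collapse = ", "))
  }
  out
}

#' Fit the full multilevel binomial copying-fidelity model
#'
#' Binomial likelihood with logit link for one feature's match counts:
#' community-indexed intercepts and community-indexed condition, age and
#' age-by-condition effects, plus overall condition, position, sex,
#' sex-by-condition, age and age-by-condition terms, and varying intercepts
#' for child, group and community. Priors are weakly informative: Normal(0,
#' 1.5) on intercepts, Normal(0, 1) on slopes, Exponential(1) on varying-
#' effect SDs. Sampled with JAGS; split R-hat above the gate triggers a
#' warning and the fit is flagged, never silently accepted.
#'
#' @param design an [build_design()] result.
#' @param settings a [sampler_settings()].
#' @return A [posterior_draws()] object with `model = "individual_full"`.
#' @export
fit_full_model <- function(design, settings = sampler_settings()) {
  stopifnot(inherits(design, "individual_design"))
  data <- list(y = design$y, n = design$n, N = design$N,
               K = length(design$levels$community),
               J = length(design$levels$group),
               C = length(design$levels$child),
               comm = design$comm, grp = design$grp, child = design$child,
               cond = design$cond, sex = design$sex,
               age = design$age, pos = design$pos)
  monitors <- c("a", "u_comm", "b_cond", "bc", "b_pos", "b_sex", "b_sexcond",
                "b_age", "ba", "b_agecond", "bac", "sd_comm", "sd_g", "sd_ch")
  res <- run_jags(jags_full_model, data, monitors, settings)
  diag <- mcmc_diagnostics(res$draws, res$chain, settings$rhat_max)
  posterior_draws(res$draws, res$chain, "individual_full",
                  meta = list(feature = design$feature,
                              centers = design$centers,
                              levels = design$levels,
                              rhat_max = settings$rhat_max),
                  diagnostics = diag)
}

#' Fit the age-pattern model
#'
#' Reduced model for interpreting the age-by-condition-by-community
#' interaction: age, condition and their interaction with
#' community-varying slopes and intercepts (hierarchical, partially pooled);
#' position and sex are deliberately excluded. Child and group varying
#' intercepts are retained for the nested data structure.
#'
#' @inheritParams fit_full_model
#' @return A [posterior_draws()] object with `model = "individual_age"`.
#' @export
fit_age_model <- function(design, settings = sampler_settings()) {
  stopifnot(inherits(design, "individual_design"))
  data <- list(y = design$y, n = design$n, N = design$N,
               K = length(design$levels$community),
               J = length(design$levels$group),
               C = length(design$levels$child),
               comm = design$comm, grp = design$grp, child = design$child,
               cond = design$cond, age = design$age)
  monitors <- c("a", "mu_a", "b_age", "ba", "b_cond", "bc", "b_agecond",
                "bac", "sd_comm", "sd_ba", "sd_bc", "sd_bac", "sd_g", "sd_ch")
  res <- run_jags(jags_age_model, data, monitors, settings)
  diag <- mcmc_diagnostics(res$draws, res$chain, settings$rhat_max)
  posterior_draws(res$draws, res$chain, "individual_age",
                  meta = list(feature = design$feature,
                              centers = design$centers,
                              levels = design$levels,
                              rhat_max = settings$rhat_max),
                  diagnostics = diag)
}

as_condition01 <- function(condition) {
  if (is.character(condition)) {
    if (!condition %in% c("observed", "unobserved")) {
      stop("unknown condition level: ", condition)
    }
    return(as.numeric(condition == "observed"))
  }
  stopifnot(condition >= 0, condition <= 1)
  condition
}

as_sex01 <- function(sex) {
  if (is.character(sex)) {
    if (!sex %in% c("male", "female")) stop("unknown sex level: ", sex)
    return(as.numeric(sex == "male"))
  }
  stopifnot(sex >= 0, sex <= 1)
  sex
}

individual_eta <- function(fit, comm_k, cond, sex, age_c, pos_c) {
  d <- fit$draws
  g <- function(nm) d[, nm]
  idx <- function(nm) jags_col(fit, nm, comm_k)
  if (fit$model == "individual_full") {
    idx("a") + idx("u_comm") +
      (g("b_cond") + idx("bc")) * cond +
      g("b_pos") * pos_c + g("b_sex") * sex +
      g("b_sexcond") * sex * cond +
      (g("b_age") + idx("ba")) * age_c +
      (g("b_agecond") + idx("bac")) * age_c * cond
  } else if (fit$model == "individual_age") {
    idx("a") +
      (g("b_age") + idx("ba")) * age_c +
      (g("b_cond") + idx("bc")) * cond +
      (g("b_agecond") + idx("bac")) * age_c * cond
  } else {
    stop("not an individual-model fit")
  }
}

#' Posterior predicted copying probability on the outcome scale
#'
#' Evaluates the inverse-logit of the linear predictor draw by draw. Child
#' and group varying intercepts are set to zero (the population median); with
#' `marginal = TRUE` the prediction instead averages the probability over
#' their fitted SDs by quadrature on normal quantile nodes. Community can be
#' a level label or `NULL`, in which case predictions are averaged over all
#' fitted communities with equal weight.
#'
#' @param fit an individual-model [posterior_draws()] object.
#' @param condition `"observed"`, `"unobserved"`, or a number in \[0, 1\]
#'   (0.5 averages the two conditions).
#' @param community community label, or `NULL` to average over communities.
#' @param age age in years, or `NULL` for the sample mean.
#' @param position chain position, or `NULL` for the sample mean (ignored by
#'   the age-pattern model).
#' @param sex `"male"`, `"female"`, or a number in \[0, 1\] (default 0.5,
#'   the sex-balanced prediction).
#' @param marginal integrate over child and group varying intercepts?
#' @param nodes quadrature nodes for `marginal = TRUE`.
#' @return Numeric vector: predicted probability per posterior draw.
#' @export
predict_probability <- function(fit, condition, community = NULL, age = NULL,
                                position = NULL, sex = 0.5,
                                marginal = FALSE, nodes = 21L) {
  stopifnot(inherits(fit, "posterior_draws"))
  cond <- as_condition01(condition)
  sex <- as_sex01(sex)
  age_c <- if (is.null(age)) 0 else age - fit$meta$centers$age
  pos_c <- if (is.null(position)) 0 else position - fit$meta$centers$position
  comm_levels <- fit$meta$levels$community
  ks <- if (is.null(community)) seq_along(comm_levels) else {
    k <- match(community, comm_levels)
    if (is.na(k)) stop("unknown community level: ", community)
    k
  }
  etas <- vapply(ks, function(k) individual_eta(fit, k, cond, sex, age_c, pos_c),
                 numeric(nrow(fit$draws)))
  if (!marginal) {
    p <- rowMeans(stats::plogis(etas))
  } else {
    sd_re <- sqrt(param_draws(fit, "sd_g")^2 + param_draws(fit, "sd_ch")^2)
    z <- stats::qnorm((seq_len(nodes) - 0.5) / nodes)
    p <- rowMeans(vapply(seq_len(ncol(etas)), function(j) {
      rowMeans(vapply(z, function(zz) stats::plogis(etas[, j] + sd_re * zz),
                      numeric(nrow(etas))))
    }, numeric(nrow(etas))))
  }
  unname(p)
}

#' Posterior contrast between two predictor settings
#'
#' Per-draw difference of predicted probabilities between two settings (and
#' possibly two fits, e.g. the shape and colour models, paired draw by draw),
#' summarised by its mean and 89% HPDI on the outcome scale.
#'
#' @param fit_a,fit_b individual-model fits with equal draw counts
#'   (`fit_b` defaults to `fit_a`).
#' @param setting_a,setting_b lists of arguments for [predict_probability()].
#' @param mass interval mass, default 0.89.
#' @return A list of class `contrast_summary`: `mean`, `hpdi`, `mass`,
#'   `draws` (per-draw differences).
#' @export
contrast <- function(fit_a, setting_a, setting_b, fit_b = fit_a, mass = 0.89) {
  p_a <- do.call(predict_probability, c(list(fit = fit_a), setting_a))
  p_b <- do.call(predict_probability, c(list(fit = fit_b), setting_b))
  if (length(p_a) != length(p_b)) {
    stop("the two fits must have equal numbers of draws")
  }
  d <- p_a - p_b
  structure(list(mean = mean(d), hpdi = hpdi(d, mass), mass = mass,
                 draws = d), class = "contrast_summary")
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf("contrast: mean %.3f, %d%% HPDI [%.3f, %.3f]\n",
              x$mean, round(100 * x$mass), x$hpdi[1], x$hpdi[2]))
  invisible(x)
}

#' Summary table of a fitted model
#'
#' One row per monitored parameter: posterior mean, 89% percentile interval,
#' 89% HPDI, effective sample size and split R-hat.
#'
#' @param fit a [posterior_draws()] object.
#' @param mass interval mass.
#' @return Data frame in the summary CSV schema.
#' @export
fit_summary <- function(fit, mass = 0.89) {
  out <- lapply(colnames(fit$draws), function(nm) {
    s <- summarize_draws(fit$draws[, nm], chains = fit$chain, mass = mass)
    cbind(parameter = nm, s, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(fit$diagnostics)) {
    res$rhat <- fit$diagnostics$rhat[match(res$parameter,
                                           fit$diagnostics$parameter)]
    res$ess <- fit$diagnostics$ess[match(res$parameter,
                                         fit$diagnostics$parameter)]
  }
  rownames(res) <- NULL
  res
}
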