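#' Settings for the chain-transmission model
#'
#' @inheritParams sampler_settings
#' @param include_varying include varying intercepts for individual id and
#'   chain position? The study model includes both; pure recovery runs on
#'   record-level simulations without individual effects can switch them off.
#' @param dirichlet_prior concentration of the Dirichlet prior on the
#'   monotonic simplex increments.
#' @return A list of class `chain_settings`.
#' @export
chain_settings <- function(chains = 4L, adapt = 500L, iter = 1000L,
                           seed = 1L, rhat_max = 1.05,
                           include_varying = TRUE, dirichlet_prior = 2) {
  structure(c(sampler_settings(chains, adapt, iter, seed, rhat_max),
              list(include_varying = include_varying,
                   dirichlet_prior = dirichlet_prior)),
            class = c("chain_settings", "sampler_settings"))
}

chain_model_string <- function(include_varying) {
  varying_lp <- if (include_varying) " + u_id[id[i]] + u_pos[pos[i]]" else ""
  # Varying effects are swept to mean zero inside the model: position levels
  # are nearly collinear with the transition stage, and without the sweep the
  # position block can absorb level shared with the stratum intercepts,
  # mis-centering predictions taken at the population center.
  varying_priors <- if (include_varying) "
  for (m in 1:M) { u_id_raw[m] ~ dnorm(0, tau_id) }
  for (q in 1:Q) { u_pos_raw[q] ~ dnorm(0, tau_pos) }
  mean_id <- mean(u_id_raw)
  mean_pos <- mean(u_pos_raw)
  for (m in 1:M) { u_id[m] <- u_id_raw[m] - mean_id }
  for (q in 1:Q) { u_pos[q] <- u_pos_raw[q] - mean_pos }
  sd_id ~ dexp(1)
  sd_pos ~ dexp(1)
  tau_id <- pow(sd_id, -2)
  tau_pos <- pow(sd_pos, -2)
" else ""
  paste0("
model {
  for (i in 1:N) {
    y[i] ~ dbern(p[i])
    logit(p[i]) <- alpha[s[i]] + bmono[s[i]] * cum[s[i], t[i]]", varying_lp, "
  }
  for (k in 1:S) {
    alpha[k] ~ dnorm(mu_alpha, tau_alpha)
    bmono[k] ~ dnorm(0, 1)
    delta[k, 1:5] ~ ddirch(d_prior)
    cum[k, 1] <- 0
    for (tt in 2:6) { cum[k, tt] <- cum[k, tt - 1] + delta[k, tt - 1] }
  }
  mu_alpha ~ dnorm(0, 0.16)
  sd_alpha ~ dexp(1)
  tau_alpha <- pow(sd_alpha, -2)
", varying_priors, "}
")
}

#' Keep only at-risk chain records
#'
#' The transition model is conditional: a record enters the likelihood only
#' if the feature was still present in the model run the child copied from.
#' Within each (group, original block, feature) series ordered by transition
#' stage, records up to and including the first loss are at risk; later
#' records (forced zeros) are dropped.
#'
#' @param records chain table with `group_id` and `original_block_id` columns
#'   (returned unchanged when either is absent, e.g. for record-level
#'   simulations that only emit at-risk rows).
#' @return The filtered chain table.
#' @export
at_risk_records <- function(records) {
  if (!all(c("group_id", "original_block_id") %in% names(records))) {
    return(records)
  }
  key <- interaction(records$group_id, records$original_block_id,
                     records$feature, drop = TRUE)
  keep <- rep(TRUE, nrow(records))
  for (lev in levels(key)) {
    idx <- which(key == lev)
    idx <- idx[order(records$transition_stage[idx])]
    z <- which(records$transmitted[idx] == 0L)
    if (length(z)) keep[idx[-seq_len(z[1])]] <- FALSE
  }
  records[keep, , drop = FALSE]
}

#' Fit the Bernoulli chain-transmission model with monotonic stage effects
#'
#' Each at-risk record is a Bernoulli trial: was the original block's feature
#' reproduced at its transition stage? The linear predictor for stratum k
#' (community x condition x feature) at transition t is
#' `alpha_k + bmono_k * sum(delta_k[1:(t-1)])`, where `delta_k` is a length-5
#' simplex with a Dirichlet prior. Transition 1 carries the intercept alone
#' and transition 6 the full effect `alpha_k + bmono_k`, so the six implied
#' transition probabilities change monotonically in the direction of
#' `sign(bmono_k)` while step sizes are free. Stratum intercepts are
#' partially pooled around a common mean. Varying intercepts for individual
#' id and chain position are included by default and centered to mean zero
#' inside the model, keeping stratum predictions at the population center
#' identified despite the near-collinearity of position and stage. Strata
#' present in `strata` but without records are fitted from the prior alone
#' and flagged.
#'
#' @param records chain table (see [simulate_chain_records()] for the
#'   schema); non-at-risk rows are removed with [at_risk_records()].
#' @param settings a [chain_settings()].
#' @param strata optional data frame of `community`, `condition`, `feature`
#'   combinations to index; defaults to the combinations observed.
#' @return A [posterior_draws()] object with `model = "chain"`; the stratum
#'   table is in `meta$strata` with per-stratum record counts.
#' @export
fit_chain_model <- function(records, settings = chain_settings(),
                            strata = NULL) {
  need <- c("child_id", "community", "condition", "position",
            "transition_stage", "feature", "transmitted")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("chain table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!records$transition_stage %in% 1:6)) {
    stop("transition stages must lie in 1..6")
  }
  d <- at_risk_records(records)
  if (is.null(strata)) {
    strata <- unique(d[, c("community", "condition", "feature")])
    strata <- strata[order(strata$community, strata$condition,
                           strata$feature), , drop = FALSE]
  }
  strata$stratum <- seq_len(nrow(strata))
  skey <- function(x) paste(x$community, x$condition, x$feature)
  s <- match(skey(d), skey(strata))
  if (anyNA(s)) stop("records outside the supplied stratum grid")
  strata$n_records <- as.integer(table(factor(s, levels = strata$stratum)))
  if (any(strata$n_records == 0L)) {
    warning("strata without records (prior-only posterior): ",
            paste(skey(strata)[strata$n_records == 0L], collapse = "; "))
  }
  id_levels <- sort(unique(d$child_id))
  pos_levels <- sort(unique(d$position))
  data <- list(y = as.integer(d$transmitted), N = nrow(d),
               s = s, t = as.integer(d$transition_stage),
               S = nrow(strata),
               d_prior = rep(settings$dirichlet_prior, 5))
  monitors <- c("alpha", "bmono", "delta", "mu_alpha", "sd_alpha")
  if (settings$include_varying) {
    data$id <- match(d$child_id, id_levels)
    data$pos <- match(d$position, pos_levels)
    data$M <- length(id_levels)
    data$Q <- length(pos_levels)
    monitors <- c(monitors, "sd_id", "sd_pos")
  }
  res <- run_jags(chain_model_string(settings$include_varying),
                  data, monitors, settings, use_glm = FALSE)
  diag <- mcmc_diagnostics(res$draws, res$chain, settings$rhat_max)
  posterior_draws(res$draws, res$chain, "chain",
                  meta = list(strata = strata, id_levels = id_levels,
                              pos_levels = pos_levels,
                              rhat_max = settings$rhat_max),
                  diagnostics = diag)
}

# JAGS drops the index from monitor names of length-1 nodes
jags_col <- function(fit, name, k) {
  nm <- sprintf("%s[%d]", name, k)
  if (nm %in% colnames(fit$draws)) return(fit$draws[, nm])
  if (k == 1L && name %in% colnames(fit$draws)) return(fit$draws[, name])
  stop("parameter not found: ", nm)
}

find_stratum <- function(fit, community, condition, feature) {
  st <- fit$meta$strata
  k <- which(st$community == community & st$condition == condition &
               st$feature == feature)
  if (length(k) != 1L) {
    stop("unknown stratum: ", paste(community, condition, feature))
  }
  st$stratum[k]
}

#' Per-draw conditional transition probabilities of a stratum
#'
#' Inverse-logit of the stratum's per-transition linear predictor with
#' varying effects at the population center: for each posterior draw, the six
#' probabilities that a feature present at stage t is reproduced at stage
#' t + 1.
#'
#' @param fit a chain-model [posterior_draws()] object.
#' @param community,condition,feature stratum labels.
#' @return Numeric matrix, draws x 6.
#' @export
conditional_transition_probs <- function(fit, community, condition, feature) {
  stopifnot(fit$model == "chain")
  k <- find_stratum(fit, community, condition, feature)
  alpha <- jags_col(fit, "alpha", k)
  bmono <- jags_col(fit, "bmono", k)
  dn <- sprintf("delta[%d,%d]", k, 1:5)
  delta <- fit$draws[, dn, drop = FALSE]
  cum <- cbind(0, t(apply(delta, 1L, cumsum)))
  p <- stats::plogis(alpha + bmono * cum)
  colnames(p) <- paste0("t", 1:6)
  p
}

#' Cumulative feature-survival curve
#'
#' Probability that an original feature is still present at each transmission
#' stage, obtained by multiplying the preceding conditional transition
#' probabilities within every posterior draw (so interval bounds are computed
#' on the curve itself): S(1) = 1 at the initial run, and
#' S(k + 1) = S(k) * p_k for transitions k = 1..6.
#'
#' @param transition_probs draws x 6 matrix of conditional transition
#'   probabilities (a length-6 vector is treated as a single draw).
#' @param mass interval mass for the per-stage HPDI.
#' @return A data frame of class `survival_curve`: `stage` (1..7), `mean`,
#'   `hpdi_low`, `hpdi_high`; the per-draw curves are kept in the `draws`
#'   attribute.
#' @export
cumulative_survival <- function(transition_probs, mass = 0.89) {
  if (is.vector(transition_probs)) {
    transition_probs <- matrix(transition_probs, nrow = 1L)
  }
  if (ncol(transition_probs) != 6L) {
    stop("expected 6 transition probabilities per draw")
  }
  if (any(transition_probs < 0 | transition_probs > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  surv <- cbind(1, t(apply(transition_probs, 1L, cumprod)))
  colnames(surv) <- paste0("stage", 1:7)
  if (nrow(surv) >= 2L) {
    hp <- apply(surv, 2L, hpdi, mass = mass)
  } else {
    hp <- rbind(surv[1L, ], surv[1L, ])
  }
  out <- data.frame(stage = 1:7, mean = colMeans(surv),
                    hpdi_low = hp[1L, ], hpdi_high = hp[2L, ])
  rownames(out) <- NULL
  attr(out, "draws") <- surv
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Survival curves for every stratum of a chain fit
#'
#' @param fit a chain-model [posterior_draws()] object.
#' @param mass interval mass.
#' @return Data frame: `community`, `condition`, `feature`, `stage`, `mean`,
#'   `hpdi_low`, `hpdi_high` (strata x 7 stages rows).
#' @export
survival_table <- function(fit, mass = 0.89) {
  st <- fit$meta$strata
  out <- lapply(seq_len(nrow(st)), function(i) {
    p <- conditional_transition_probs(fit, st$community[i], st$condition[i],
                                      st$feature[i])
    sc <- cumulative_survival(p, mass)
    data.frame(community = st$community[i], condition = st$condition[i],
               feature = st$feature[i], as.data.frame(sc),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
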