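#' Study configuration for the synthetic-study generator
#'
#' Defaults mirror the design of the field study being emulated: five
#' communities, 16 groups per community (80 groups), groups of six children in
#' the observed condition and five in the unobserved condition (conditions
#' alternate across groups within a community), ages drawn from a normal
#' distribution with mean 9.1 y and SD 1.45 y truncated to 5.9--13.3 y, and a
#' 55% male fraction.
#'
#' @param n_communities number of communities (labelled A, B, ...).
#' @param groups_per_community groups sampled in each community.
#' @param group_size_observed,group_size_unobserved children per group by
#'   condition.
#' @param age_mean,age_sd,age_range truncated-normal age distribution (years).
#' @param male_fraction probability a child is male.
#' @param initial the experimenter's 8-block model run.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_communities = 5L,
                         groups_per_community = 16L,
                         group_size_observed = 6L,
                         group_size_unobserved = 5L,
                         age_mean = 9.1, age_sd = 1.45,
                         age_range = c(5.9, 13.3),
                         male_fraction = 0.55,
                         initial = initial_run()) {
  if (n_communities < 1L || groups_per_community < 1L) {
    stop("community and group counts must be positive")
  }
  structure(list(
    n_communities = as.integer(n_communities),
    groups_per_community = as.integer(groups_per_community),
    group_size_observed = as.integer(group_size_observed),
    group_size_unobserved = as.integer(group_size_unobserved),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    male_fraction = male_fraction, initial = initial
  ), class = "study_config")
}

#' Generative parameter set for the synthetic study
#'
#' All parameters of the data-generating process, fully known so that model
#' fits can be checked against the truth. Logit-scale baselines default to
#' outcome-scale copying probabilities of 0.85 (shape) and 0.55 (color); the
#' per-transition chain retention sequences default to a mildly declining
#' shape sequence and a sharply declining colour sequence whose stage-7
#' products (about 0.60 and 0.08) match the qualitative picture the analysis
#' is designed to detect. Covariate effects default to zero except a small
#' positive age and position slope; the dismantle probability and the
#' behavioural exclusion rates default to the field study's observed
#' frequencies.
#'
#' @param baseline named numeric, logit-scale intercept per feature.
#' @param b_condition,b_sex,b_sex_condition,b_position,b_age,b_age_condition
#'   logit-scale slopes (condition: observed vs unobserved; sex: male vs
#'   female; age and position are centered before use).
#' @param community_offsets,b_age_community,b_condition_community,b_age_condition_community
#'   per-community logit-scale effects, length `n_communities`.
#' @param sd_community,sd_group,sd_child varying-intercept SDs (logit scale).
#' @param chain_shape,chain_color length-6 per-transition retention
#'   probabilities, each monotone (non-increasing or non-decreasing); used for
#'   every community and condition unless `chain_probs` is supplied.
#' @param chain_probs optional 4-d array `[community, condition, feature, 6]`
#'   overriding the two sequences stratum by stratum.
#' @param dismantle_prob probability a built run is dismantled (and the chain
#'   state not advanced).
#' @param exclusion_rates named behavioural exclusion probabilities.
#' @param n_max_range inclusive range of the per-dyad maximum unit count.
#' @return A list of class `true_params`.
#' @export
true_params <- function(baseline = c(shape = stats::qlogis(0.85),
                                     color = stats::qlogis(0.55)),
                        b_condition = 0, b_sex = 0, b_sex_condition = 0,
                        b_position = 0.1, b_age = 0.1, b_age_condition = 0,
                        community_offsets = rep(0, 5),
                        b_age_community = rep(0, 5),
                        b_condition_community = rep(0, 5),
                        b_age_condition_community = rep(0, 5),
                        sd_community = 0.25, sd_group = 0.25, sd_child = 0.5,
                        chain_shape = c(0.95, 0.94, 0.93, 0.92, 0.91, 0.90),
                        chain_color = c(0.85, 0.80, 0.72, 0.62, 0.55, 0.50),
                        chain_probs = NULL,
                        dismantle_prob = 10 / 394,
                        exclusion_rates = c(built_nothing = 44, dismantled_runs = 6,
                                            no_orientation = 6, too_few_bricks = 2,
                                            participated_twice = 1, camera_error = 1) / 394,
                        n_max_range = c(5L, 13L)) {
  stopifnot(all(c("shape", "color") %in% names(baseline)))
  for (s in list(chain_shape, chain_color)) {
    if (length(s) != 6L || any(s < 0 | s > 1)) {
      stop("chain retention sequences must be 6 probabilities")
    }
    d <- diff(s)
    if (!(all(d <= 1e-12) || all(d >= -1e-12))) {
      stop("chain retention sequences must be monotone")
    }
  }
  if (any(exclusion_rates < 0) || sum(exclusion_rates) > 1) {
    stop("exclusion rates must be non-negative and sum to at most 1")
  }
  stopifnot(sd_community >= 0, sd_group >= 0, sd_child >= 0,
            dismantle_prob >= 0, dismantle_prob <= 1)
  structure(list(
    baseline = baseline, b_condition = b_condition, b_sex = b_sex,
    b_sex_condition = b_sex_condition, b_position = b_position,
    b_age = b_age, b_age_condition = b_age_condition,
    community_offsets = community_offsets,
    b_age_community = b_age_community,
    b_condition_community = b_condition_community,
    b_age_condition_community = b_age_condition_community,
    sd_community = sd_community, sd_group = sd_group, sd_child = sd_child,
    chain_shape = chain_shape, chain_color = chain_color,
    chain_probs = chain_probs, dismantle_prob = dismantle_prob,
    exclusion_rates = exclusion_rates, n_max_range = n_max_range
  ), class = "true_params")
}

#' Per-transition retention probability for one stratum
#' @noRd
stratum_probs <- function(params, community_index, condition01, feature) {
  if (!is.null(params$chain_probs)) {
    return(params$chain_probs[community_index, condition01 + 1L, feature, ])
  }
  if (feature == "shape") params$chain_shape else params$chain_color
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a participant roster
#'
#' Deterministic given `(config, seed)`: every child receives a community,
#' group, group-level condition, within-group position, age and sex.
#'
#' @param config a [study_config()].
#' @param seed integer RNG seed.
#' @return Data frame: `child_id`, `group_id`, `community`, `condition`,
#'   `position`, `age_years`, `sex`.
#' @export
simulate_roster <- function(config = study_config(), seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (ci in seq_len(config$n_communities)) {
    comm <- LETTERS[ci]
    for (gi in seq_len(config$groups_per_community)) {
      cond <- if (gi %% 2L == 1L) "observed" else "unobserved"
      size <- if (cond == "observed") config$group_size_observed else
        config$group_size_unobserved
      gid <- sprintf("%s_g%02d", comm, gi)
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = gid, community = comm, condition = cond,
        position = seq_len(size),
        age_years = rtruncnorm1(size, config$age_mean, config$age_sd,
                                config$age_range[1], config$age_range[2]),
        sex = ifelse(stats::runif(size) < config$male_fraction,
                     "male", "female"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(child_id = sprintf("%s_p%d", out$group_id, out$position), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Linear predictor of the dyadic copying model under known parameters
#' @noRd
dyad_eta <- function(roster, params, feature, effects) {
  ci <- match(roster$community, LETTERS)
  cond <- as.numeric(roster$condition == "observed")
  sex <- as.numeric(roster$sex == "male")
  age_c <- roster$age_years - mean(roster$age_years)
  pos_c <- roster$position - mean(roster$position)
  params$baseline[[feature]] +
    params$community_offsets[ci] +
    effects$u_comm[ci] + effects$u_group[match(roster$group_id, effects$groups)] +
    effects$u_child[match(roster$child_id, effects$children)] +
    (params$b_condition + params$b_condition_community[ci]) * cond +
    params$b_position * pos_c + params$b_sex * sex +
    params$b_sex_condition * sex * cond +
    (params$b_age + params$b_age_community[ci]) * age_c +
    (params$b_age_condition + params$b_age_condition_community[ci]) * age_c * cond
}

#' Simulate dyad-level copying records
#'
#' For each child and feature, draws the maximum unit count `n_max` uniformly
#' from `params$n_max_range` and the match count `y` from
#' `Binomial(n_max, p)`, where `logit(p)` is the child's linear predictor
#' under `params` with community, group and child varying intercepts drawn
#' from their SDs (shared across the two features of a child).
#'
#' @param roster output of [simulate_roster()].
#' @param params a [true_params()].
#' @param seed integer RNG seed.
#' @return Data frame in the dyad-table schema: `child_id`, `group_id`,
#'   `community`, `condition`, `position`, `age_years`, `sex`, `feature`,
#'   `y_matches`, `n_max`.
#' @export
simulate_dyads <- function(roster, params = true_params(), seed = 1L) {
  set.seed(seed)
  comms <- sort(unique(roster$community))
  groups <- sort(unique(roster$group_id))
  children <- roster$child_id
  effects <- list(
    u_comm = stats::rnorm(length(LETTERS), 0, params$sd_community),
    u_group = stats::rnorm(length(groups), 0, params$sd_group),
    u_child = stats::rnorm(length(children), 0, params$sd_child),
    groups = groups, children = children
  )
  out <- list()
  for (feature in c("shape", "color")) {
    eta <- dyad_eta(roster, params, feature, effects)
    n_max <- sample(seq.int(params$n_max_range[1], params$n_max_range[2]),
                    nrow(roster), replace = TRUE)
    y <- stats::rbinom(nrow(roster), n_max, stats::plogis(eta))
    out[[feature]] <- data.frame(
      roster[, c("child_id", "group_id", "community", "condition",
                 "position", "age_years", "sex")],
      feature = feature, y_matches = y, n_max = n_max,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

next_shape <- function(s) {
  cl <- shape_classes()
  cl[match(s, cl) %% length(cl) + 1L]
}
next_color <- function(cl, palette = default_palette()) {
  palette[match(cl, palette) %% length(palette) + 1L]
}

#' Simulate symbolic marble runs along transmission chains
#'
#' Each child's run is generated block by block from the group's current
#' "alive" state of the eight original blocks: a block's shape (and,
#' independently, its colour) survives into the child's run with the
#' per-transition retention probability of the child's stratum and stage; a
#' lost feature is replaced in place by a different shape class or colour, so
#' runs keep eight blocks and the latent transmission events are recoverable
#' exactly by [binarize_chain()]. With probability `params$dismantle_prob` a
#' run is dismantled (emitted truncated to four bricks so the dismantle rule
#' recognises it); such a run produces no transmission events and the next
#' child copies the previous model.
#'
#' @inheritParams simulate_dyads
#' @param initial the experimenter's 8-block run.
#' @return A list: `archive` (named list of groups, each a list of
#'   `marble_run`s in position order), `latent` (data frame of ground-truth
#'   chain records in the chain-table schema), `initial`.
#' @export
simulate_runs <- function(roster, params = true_params(), seed = 1L,
                          initial = initial_run()) {
  set.seed(seed)
  archive <- list()
  latent <- list()
  for (gid in unique(roster$group_id)) {
    kids <- roster[roster$group_id == gid, , drop = FALSE]
    kids <- kids[order(kids$position), , drop = FALSE]
    ci <- match(kids$community[1], LETTERS)
    cond01 <- as.numeric(kids$condition[1] == "observed")
    alive_s <- rep(TRUE, 8L)
    alive_c <- rep(TRUE, 8L)
    stage <- 1L
    runs <- list()
    for (j in seq_len(nrow(kids))) {
      p_s <- stratum_probs(params, ci, cond01, "shape")[min(stage, 6L)]
      p_c <- stratum_probs(params, ci, cond01, "color")[min(stage, 6L)]
      tr_s <- alive_s & (stats::runif(8L) < p_s)
      tr_c <- alive_c & (stats::runif(8L) < p_c)
      shapes <- ifelse(tr_s, initial$shape_class, next_shape(initial$shape_class))
      colors <- ifelse(tr_c, initial$color, next_color(initial$color))
      dismantled <- stats::runif(1L) < params$dismantle_prob
      if (dismantled) {
        run <- marble_run(shapes[1:4], colors[1:4], builder = kids$child_id[j])
      } else {
        run <- marble_run(shapes, colors, builder = kids$child_id[j])
        latent[[length(latent) + 1L]] <- data.frame(
          child_id = kids$child_id[j], group_id = gid,
          community = kids$community[1], condition = kids$condition[1],
          position = kids$position[j], transition_stage = min(stage, 6L),
          original_block_id = rep(1:8, 2L),
          feature = rep(c("shape", "color"), each = 8L),
          transmitted = as.integer(c(tr_s, tr_c)),
          stringsAsFactors = FALSE
        )
        alive_s <- tr_s
        alive_c <- tr_c
        stage <- stage + 1L
      }
      runs[[j]] <- run
    }
    archive[[gid]] <- runs
  }
  latent <- do.call(rbind, latent)
  rownames(latent) <- NULL
  list(archive = archive, latent = latent, initial = initial)
}

#' Simulate coded chain records directly
#'
#' Record-level counterpart of [simulate_runs()] for exercising the chain
#' model without the symbolic layer: each chain is one (group x block x
#' feature) series followed through at most six transitions under a known
#' per-transition retention sequence, stopping once the feature is lost
#' (records are emitted only while the feature is at risk).
#'
#' @param n_chains number of independent series.
#' @param probs length-6 vector of per-transition retention probabilities.
#' @param seed integer RNG seed.
#' @param community,condition,feature stratum labels attached to the records.
#' @return Data frame in the chain-table schema.
#' @export
simulate_chain_records <- function(n_chains, probs, seed = 1L,
                                   community = "A", condition = "unobserved",
                                   feature = "shape") {
  stopifnot(length(probs) == 6L, all(probs >= 0 & probs <= 1))
  set.seed(seed)
  rows <- list()
  for (j in seq_len(n_chains)) {
    alive <- TRUE
    for (t in 1:6) {
      if (!alive) break
      y <- stats::rbinom(1L, 1L, probs[t])
      rows[[length(rows) + 1L]] <- data.frame(
        child_id = sprintf("c%05d_t%d", j, t),
        group_id = sprintf("g%05d", j),
        community = community, condition = condition,
        position = t, transition_stage = t,
        original_block_id = 1L, feature = feature, transmitted = y,
        stringsAsFactors = FALSE
      )
      alive <- y == 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw an exclusion ledger for a simulated roster
#'
#' Behavioural exclusion reasons are assigned by independent categorical draws
#' at `params$exclusion_rates`; children who escape behavioural exclusion are
#' coded `first_position_drop` when at position 1 and `none` otherwise.
#'
#' @inheritParams simulate_dyads
#' @return Ledger data frame (`child_id`, `community`, `condition`, `sex`,
#'   `reason`) accepted by [apply_exclusions()].
#' @export
inject_exclusions <- function(roster, params = true_params(), seed = 1L) {
  rates <- params$exclusion_rates
  if (any(rates < 0) || sum(rates) > 1) {
    stop("exclusion rates must be non-negative and sum to at most 1")
  }
  set.seed(seed)
  reasons <- c(names(rates), "none")
  probs <- c(rates, 1 - sum(rates))
  reason <- sample(reasons, nrow(roster), replace = TRUE, prob = probs)
  reason[reason == "none" & roster$position == 1L] <- "first_position_drop"
  data.frame(child_id = roster$child_id, community = roster$community,
             condition = roster$condition, sex = roster$sex,
             reason = reason, stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper drawing a roster, dyad records, symbolic runs with
#' their latent chain records, and an exclusion ledger from one seed.
#'
#' @inheritParams simulate_roster
#' @param params a [true_params()].
#' @return A list: `roster`, `dyads`, `runs` (see [simulate_runs()]),
#'   `ledger`, `config`, `params`, `seed`.
#' @export
simulate_study <- function(config = study_config(), params = true_params(),
                           seed = 1L) {
  roster <- simulate_roster(config, seed)
  dyads <- simulate_dyads(roster, params, seed + 1L)
  runs <- simulate_runs(roster, params, seed + 2L, initial = config$initial)
  ledger <- inject_exclusions(roster, params, seed + 3L)
  list(roster = roster, dyads = dyads, runs = runs, ledger = ledger,
       config = config, params = params, seed = seed)
}
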