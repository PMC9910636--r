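#' Simulate a study and write the dataset bundle to disk
#'
#' Writes the roster, the dyad and latent chain tables, the symbolic run
#' archive, the exclusion ledger, the generative parameters and a manifest
#' (seed, row counts, md5 checksums) to `outdir`.
#'
#' @param config a [study_config()].
#' @param params a [true_params()].
#' @param seed integer seed; fully determines the bundle.
#' @param outdir output directory, created if needed.
#' @return Invisibly, the [simulate_study()] bundle.
#' @export
run_simulate <- function(config = study_config(), params = true_params(),
                         seed = 1L, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config, params, seed)
  utils::write.csv(study$roster, file.path(outdir, "roster.csv"),
                   row.names = FALSE)
  write_dyad_table(study$dyads, file.path(outdir, "dyads.csv"))
  write_chain_table(study$runs$latent, file.path(outdir, "chains.csv"))
  write_run_archive(study$runs$archive, study$runs$initial,
                    file.path(outdir, "runs.json"))
  utils::write.csv(study$ledger, file.path(outdir, "ledger.csv"),
                   row.names = FALSE)
  write_true_params(params, file.path(outdir, "true_params.yaml"))
  files <- c("roster.csv", "dyads.csv", "chains.csv", "runs.json",
             "ledger.csv", "true_params.yaml")
  manifest <- list(
    seed = seed,
    n_children = nrow(study$roster),
    n_dyad_records = nrow(study$dyads),
    n_chain_records = nrow(study$runs$latent),
    md5 = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(study)
}

#' Code a run archive into dyad and chain tables
#'
#' Applies the marble-run codec to a symbolic archive: every child is coded
#' against the model run they actually saw (the most recent accepted
#' predecessor build, or the initial run), and chain-level transmission of
#' the eight original blocks is binarised with [binarize_chain()].
#'
#' @param archive named list of groups of [marble_run()]s (as produced by
#'   [simulate_runs()] or read with [read_run_archive()]).
#' @param initial the experimenter's initial run.
#' @param roster roster table supplying covariates (`child_id`, `group_id`,
#'   `community`, `condition`, `position`, `age_years`, `sex`).
#' @param outdir optional directory to write `dyads_coded.csv` and
#'   `chains_coded.csv`.
#' @return A list with the coded `dyads` and `chains` tables.
#' @export
run_code <- function(archive, initial, roster, outdir = NULL) {
  dyads <- list()
  chains <- list()
  for (gid in names(archive)) {
    runs <- archive[[gid]]
    model <- initial
    for (j in seq_along(runs)) {
      run <- runs[[j]]
      coding <- code_dyad(run, model)
      info <- roster[roster$child_id == attr(run, "builder"), , drop = FALSE]
      if (nrow(info) != 1L) {
        stop("builder ", attr(run, "builder"), " not found in roster")
      }
      info <- info[c(1L, 1L), ]  # one row per feature
      rownames(info) <- NULL
      dyads[[length(dyads) + 1L]] <- data.frame(
        info[, c("child_id", "group_id", "community", "condition",
                 "position", "age_years", "sex")],
        feature = c("shape", "color"),
        y_matches = c(coding$shape_matches, coding$color_matches),
        n_max = coding$max_units,
        stringsAsFactors = FALSE
      )
      if (apply_dismantle_rule(run)) model <- run
    }
    ch <- binarize_chain(runs, initial)
    if (!is.null(ch) && nrow(ch)) {
      info <- roster[match(ch$child_id, roster$child_id), , drop = FALSE]
      ch$group_id <- info$group_id
      ch$community <- info$community
      ch$condition <- info$condition
      chains[[length(chains) + 1L]] <- ch
    }
  }
  dyads <- do.call(rbind, dyads)
  chains <- do.call(rbind, chains)
  rownames(dyads) <- rownames(chains) <- NULL
  chains <- chains[, chain_schema]
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_dyad_table(dyads, file.path(outdir, "dyads_coded.csv"))
    write_chain_table(chains, file.path(outdir, "chains_coded.csv"))
  }
  list(dyads = dyads, chains = chains)
}

#' Fit one of the study models and write its summaries
#'
#' @param data dyad table (individual models) or chain table (chain model).
#' @param which `"individual-full"`, `"individual-age"` or `"chain"`.
#' @param feature feature to model for the individual fits.
#' @param settings [sampler_settings()] or [chain_settings()].
#' @param outdir optional directory for the summary CSV and diagnostics log.
#' @return The [posterior_draws()] fit.
#' @export
run_fit <- function(data, which = c("individual-full", "individual-age",
                                    "chain"),
                    feature = "shape", settings = NULL, outdir = NULL) {
  which <- match.arg(which)
  fit <- switch(which,
    "individual-full" = fit_full_model(build_design(data, feature),
                                       settings %||% sampler_settings()),
    "individual-age" = fit_age_model(build_design(data, feature),
                                     settings %||% sampler_settings()),
    "chain" = fit_chain_model(data, settings %||% chain_settings())
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tag <- if (which == "chain") "chain" else paste0(which, "_", feature)
    utils::write.csv(fit_summary(fit),
                     file.path(outdir, paste0("summary_", tag, ".csv")),
                     row.names = FALSE)
    writeLines(c(sprintf("model: %s", which),
                 sprintf("draws: %d x %d chains", nrow(fit$draws),
                         length(unique(fit$chain))),
                 sprintf("max split R-hat: %.4f",
                         max(fit$diagnostics$rhat, na.rm = TRUE))),
               file.path(outdir, paste0("diagnostics_", tag, ".log")))
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Report survival curves from a chain fit
#'
#' Writes the per-stratum survival table (strata x 7 stages) and, optionally,
#' one survival plot per condition.
#'
#' @param fit a chain-model [posterior_draws()] object.
#' @param outdir output directory.
#' @param plots draw base-graphics survival curves to a PDF?
#' @return The survival table, invisibly.
#' @export
run_report <- function(fit, outdir, plots = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- survival_table(fit)
  utils::write.csv(tab, file.path(outdir, "survival_curves.csv"),
                   row.names = FALSE)
  if (plots) {
    grDevices::pdf(file.path(outdir, "survival_curves.pdf"), width = 8,
                   height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (cond in unique(tab$condition)) {
      sub <- tab[tab$condition == cond, ]
      graphics::plot(NULL, xlim = c(1, 7), ylim = c(0, 1),
                     xlab = "transmission stage", ylab = "survival",
                     main = paste("condition:", cond))
      cols <- c(shape = "darkorange", color = "darkgreen")
      for (feat in unique(sub$feature)) {
        for (comm in unique(sub$community)) {
          cc <- sub[sub$feature == feat & sub$community == comm, ]
          graphics::lines(cc$stage, cc$mean, col = cols[[feat]])
        }
      }
      graphics::legend("bottomleft", legend = names(cols), col = cols,
                       lty = 1, bty = "n")
    }
  }
  invisible(tab)
}

#' Run the whole pipeline from one seed
#'
#' Simulate, code, apply the exclusion cascade, fit the individual models for
#' both features and the chain model, and report survival curves. Identical
#' `(config, params, seed, settings)` give identical outputs.
#'
#' @inheritParams run_simulate
#' @param settings sampler settings shared by the fits (chain fits add the
#'   varying-effect defaults).
#' @param outdir output directory.
#' @param plots forwarded to [run_report()].
#' @return A list with the study bundle, coded tables, fits and the survival
#'   table.
#' @export
run_all <- function(config = study_config(), params = true_params(),
                    seed = 1L, settings = sampler_settings(),
                    outdir, plots = FALSE) {
  study <- run_simulate(config, params, seed, outdir)
  coded <- run_code(study$runs$archive, study$runs$initial, study$roster,
                    outdir)
  keep_ind <- apply_exclusions(study$ledger, "individual")$retained
  keep_ch <- apply_exclusions(study$ledger, "chain")$retained
  dyads <- coded$dyads[coded$dyads$child_id %in% keep_ind, , drop = FALSE]
  chains <- coded$chains[coded$chains$child_id %in% keep_ch, , drop = FALSE]
  fits <- list(
    shape = run_fit(dyads, "individual-full", "shape", settings, outdir),
    color = run_fit(dyads, "individual-full", "color", settings, outdir),
    chain = run_fit(chains, "chain",
                    settings = chain_settings(settings$chains, settings$adapt,
                                              settings$iter, settings$seed,
                                              settings$rhat_max),
                    outdir = outdir)
  )
  surv <- run_report(fits$chain, outdir, plots = plots)
  list(study = study, coded = coded, fits = fits, survival = surv)
}
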