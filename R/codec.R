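#' Code a dyad: match counts between a child's run and its model run
#'
#' The two runs are decomposed into coding units and compared position by
#' position (left-anchored alignment along the adhesive strip). The maximum
#' possible number of matching units is the unit count of the longer run;
#' positions present in only one run count as mismatches for both features.
#'
#' @param child_run,model_run non-empty [marble_run()]s.
#' @return A list with integer fields `max_units`, `shape_matches`,
#'   `color_matches`.
#' @examples
#' m <- marble_run(c("RAMP", "DOUBLE"), c("red", "blue"))
#' c1 <- marble_run(c("RAMP", "CUBE"), c("red", "blue"))
#' code_dyad(c1, m)
#' @export
code_dyad <- function(child_run, model_run) {
  uc <- decompose_to_units(child_run)
  um <- decompose_to_units(model_run)
  k <- min(nrow(uc), nrow(um))
  list(
    max_units = max(nrow(uc), nrow(um)),
    shape_matches = sum(uc$unit_tag[seq_len(k)] == um$unit_tag[seq_len(k)]),
    color_matches = sum(uc$color[seq_len(k)] == um$color[seq_len(k)])
  )
}

#' Dismantle rule for built runs
#'
#' A child's run is kept as the model for the next child only if it has
#' between five and eleven bricks; simpler and more complex runs are
#' dismantled so every child faces a task of comparable difficulty.
#'
#' @param run a [marble_run()].
#' @return `TRUE` if the run is accepted (5--11 bricks), `FALSE` otherwise.
#' @export
apply_dismantle_rule <- function(run) {
  n <- n_bricks(run)
  n >= 5L && n <= 11L
}

#' Assign transmission stages along a chain
#'
#' The experimenter's initial run sits at stage 1. The model shown to a child
#' is the most recent accepted build, so a child's model stage is one plus the
#' number of accepted predecessor builds, and the child's own transmission
#' event is the transition from that stage to the next. When a predecessor's
#' run was dismantled the transmission stage lags the child's position.
#'
#' @param accepted logical vector, one element per child in position order:
#'   was that child's build kept as the next model?
#' @param max_stage largest transition index (6, the maximum chain length).
#' @return Integer vector of transition stages, one per child.
#' @examples
#' assign_stages(c(TRUE, TRUE, FALSE, TRUE))  # 1 2 3 3
#' @export
assign_stages <- function(accepted, max_stage = 6L) {
  accepted <- as.logical(accepted)
  if (anyNA(accepted)) stop("`accepted` must not contain NA")
  stage <- 1L + c(0L, cumsum(accepted[-length(accepted)]))
  if (length(accepted) == 0L) stage <- integer(0)
  pmin(stage, max_stage)
}

#' Binarise chain-level transmission of the original blocks
#'
#' For every accepted child run and each of the eight blocks of the initial
#' run, scores whether the block's shape and colour were reproduced. A block's
#' shape is reproduced when the child's run carries a block of the same shape
#' class at the same position; its colour is reproduced when the block at that
#' position has the original colour. Feature loss is irreversible: once a
#' feature is scored 0 at some stage it is scored 0 for every later child in
#' that group, even if a later child happens to match the original again.
#'
#' Children whose runs fail the dismantle rule produce no records and do not
#' advance the chain state: the next child copies the previous accepted model.
#'
#' @param group_runs list of [marble_run()]s in position order (the initial
#'   run excluded); each run's `builder` attribute identifies the child.
#' @param initial_run the experimenter's 8-block model run.
#' @return A data frame with one row per accepted child x original block x
#'   feature: `child_id`, `position`, `transition_stage`, `original_block_id`,
#'   `feature`, `transmitted`.
#' @export
binarize_chain <- function(group_runs, initial_run) {
  if (n_bricks(initial_run) != 8L) {
    stop("the initial run must have exactly 8 blocks")
  }
  accepted <- vapply(group_runs, apply_dismantle_rule, logical(1))
  stages <- assign_stages(accepted)
  alive_shape <- rep(TRUE, 8L)
  alive_color <- rep(TRUE, 8L)
  out <- vector("list", length(group_runs))
  for (j in seq_along(group_runs)) {
    if (!accepted[j]) next
    run <- group_runs[[j]]
    have <- seq_len(8L) <= nrow(run)
    rep_shape <- have &
      c(run$shape_class[seq_len(min(8L, nrow(run)))],
        rep(NA, 8L - min(8L, nrow(run)))) == initial_run$shape_class
    rep_color <- have &
      c(run$color[seq_len(min(8L, nrow(run)))],
        rep(NA, 8L - min(8L, nrow(run)))) == initial_run$color
    rep_shape[is.na(rep_shape)] <- FALSE
    rep_color[is.na(rep_color)] <- FALSE
    tr_shape <- alive_shape & rep_shape
    tr_color <- alive_color & rep_color
    out[[j]] <- data.frame(
      child_id = attr(run, "builder"),
      position = j,
      transition_stage = stages[j],
      original_block_id = rep(seq_len(8L), 2L),
      feature = rep(c("shape", "color"), each = 8L),
      transmitted = as.integer(c(tr_shape, tr_color)),
      stringsAsFactors = FALSE
    )
    alive_shape <- tr_shape
    alive_color <- tr_color
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Valid exclusion reason codes
#'
#' Behavioural reasons remove a child from every analysis; the two positional
#' codes are analysis-specific: first-position children cannot be scored as
#' copying a peer (individual analysis only), and successors accidentally
#' shown the experimenter run instead of their predecessor's run break the
#' chain (chain analysis only).
#'
#' @export
exclusion_reasons <- function() {
  c("none", "built_nothing", "dismantled_runs", "no_orientation",
    "too_few_bricks", "participated_twice", "camera_error",
    "first_position_drop", "wrong_model_successor")
}

behavioural_reasons <- function() {
  c("built_nothing", "dismantled_runs", "no_orientation",
    "too_few_bricks", "participated_twice", "camera_error")
}

#' Apply the exclusion cascade
#'
#' Behavioural exclusions are applied first and remove a child from both
#' analyses. The individual (dyadic copying) analysis additionally drops
#' first-position children; the chain analysis additionally drops children
#' downstream of a wrong-model event.
#'
#' @param ledger data frame with one row per enrolled child, columns
#'   `child_id` and `reason` (one of [exclusion_reasons()]); an optional `sex`
#'   column (`"male"`/`"female"`) enables the boy tally.
#' @param analysis `"individual"` or `"chain"`.
#' @return A list: `retained` (child ids), `n_enrolled`, `n_excluded`
#'   (behavioural), `n_retained`, `n_boys` (NA without a sex column), and
#'   `tally`, a named integer vector of reason counts.
#' @export
apply_exclusions <- function(ledger, analysis = c("individual", "chain")) {
  analysis <- match.arg(analysis)
  stopifnot(is.data.frame(ledger), all(c("child_id", "reason") %in% names(ledger)))
  bad <- setdiff(unique(ledger$reason), exclusion_reasons())
  if (length(bad)) stop("unknown exclusion reason: ", paste(bad, collapse = ", "))
  keep_codes <- switch(analysis,
    individual = c("none", "wrong_model_successor"),
    chain = c("none", "first_position_drop")
  )
  kept <- ledger$reason %in% keep_codes
  tally <- table(factor(ledger$reason, levels = exclusion_reasons()))
  n_boys <- NA_integer_
  if ("sex" %in% names(ledger)) n_boys <- sum(ledger$sex[kept] == "male")
  list(
    retained = ledger$child_id[kept],
    n_enrolled = nrow(ledger),
    n_excluded = sum(ledger$reason %in% behavioural_reasons()),
    n_retained = sum(kept),
    n_boys = n_boys,
    tally = c(tally)
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two categorical codings of the same
#' cases: kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and
#' chance agreement p_e from the product of the raters' marginal frequencies.
#'
#' @param labels_a,labels_b equal-length vectors of category labels.
#' @return Kappa in \[-1, 1\]; `NA` (with a warning) when chance agreement is
#'   1, i.e. both raters are constant with identical margins, where kappa is
#'   undefined.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 1L) {
    stop("`labels_a` and `labels_b` must have equal length >= 1")
  }
  n <- length(labels_a)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (isTRUE(all.equal(p_e, 1))) {
    warning("kappa undefined: chance agreement is 1")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}
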