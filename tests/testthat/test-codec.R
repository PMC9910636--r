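test_that("unit decomposition expands DOUBLE blocks in place", {
  r <- marble_run(c("CUBE", "CUBE"), c("red", "red"))
  u <- decompose_to_units(r)
  expect_equal(nrow(u), 2L)
  expect_true(all(u$unit_tag == "CUBE" & u$color == "red"))

  r <- marble_run(c("RAMP", "DOUBLE", "CUBE"), c("blue", "yellow", "green"))
  u <- decompose_to_units(r)
  expect_equal(u$unit_tag, c("RAMP", "DOUBLE", "DOUBLE", "CUBE"))
  expect_equal(u$color, c("blue", "yellow", "yellow", "green"))

  r <- mono_run("DOUBLE", "red", 5)
  expect_equal(nrow(decompose_to_units(r)), 10L)

  expect_error(decompose_to_units(marble_run(character(0), character(0))),
               "empty")
})

test_that("unit decomposition is a homomorphism under run concatenation", {
  set.seed(101)
  for (rep in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    s1 <- sample(shape_classes(), n1, TRUE); c1 <- sample(default_palette(), n1, TRUE)
    s2 <- sample(shape_classes(), n2, TRUE); c2 <- sample(default_palette(), n2, TRUE)
    joint <- decompose_to_units(marble_run(c(s1, s2), c(c1, c2)))
    parts <- rbind(decompose_to_units(marble_run(s1, c1)),
                   decompose_to_units(marble_run(s2, c2)))
    rownames(parts) <- NULL
    expect_equal(joint, parts)
  }
})

test_that("dyad coding counts positional matches against the longer run", {
  r <- marble_run(c("RAMP", "CUBE", "DOUBLE", "CUBE", "RAMP", "CUBE"),
                  c("red", "blue", "green", "red", "yellow", "blue"))
  d <- code_dyad(r, r)
  expect_equal(d, list(max_units = 7, shape_matches = 7, color_matches = 7))

  child <- mono_run("CUBE", "red", 6)
  model <- mono_run("CUBE", "blue", 6)
  d <- code_dyad(child, model)
  expect_equal(d$max_units, 6)
  expect_equal(d$shape_matches, 6)
  expect_equal(d$color_matches, 0)

  child <- marble_run(c("RAMP", "CUBE"), c("red", "blue"))
  model <- marble_run(c("RAMP", "DOUBLE"), c("red", "blue"))
  d <- code_dyad(child, model)
  expect_equal(d$max_units, 3)
  expect_equal(d$shape_matches, 1)  # only the leading ramp
  expect_equal(d$color_matches, 2)  # red and blue at positions 1-2
})

test_that("dyad match counts never exceed the unit maximum", {
  set.seed(102)
  for (rep in 1:50) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    a <- marble_run(sample(shape_classes(), n1, TRUE),
                    sample(default_palette(), n1, TRUE))
    b <- marble_run(sample(shape_classes(), n2, TRUE),
                    sample(default_palette(), n2, TRUE))
    d <- code_dyad(a, b)
    expect_lte(d$shape_matches, d$max_units)
    expect_lte(d$color_matches, d$max_units)
    expect_gte(d$shape_matches, 0)
    expect_gte(d$color_matches, 0)
  }
})

test_that("dismantle rule keeps runs of five to eleven bricks", {
  expect_false(apply_dismantle_rule(mono_run("CUBE", "red", 4)))
  expect_true(apply_dismantle_rule(mono_run("CUBE", "red", 5)))
  expect_true(apply_dismantle_rule(mono_run("CUBE", "red", 11)))
  expect_false(apply_dismantle_rule(mono_run("CUBE", "red", 12)))
})

test_that("stage assignment counts accepted predecessor builds", {
  expect_equal(assign_stages(rep(TRUE, 6)), 1:6)
  # build at position 3 dismantled: position 4 copies the position-2 run
  expect_equal(assign_stages(c(TRUE, TRUE, FALSE, TRUE)), c(1, 2, 3, 3))
  # first two builds dismantled: position 3 copies the initial run
  expect_equal(assign_stages(c(FALSE, FALSE, TRUE)), c(1, 1, 1))
  expect_equal(assign_stages(logical(0)), integer(0))
})

test_that("transition stage never exceeds position, equal iff no dismantles", {
  set.seed(103)
  for (rep in 1:30) {
    acc <- runif(6) < 0.8
    st <- assign_stages(acc)
    expect_true(all(st <= seq_along(acc)))
    for (j in seq_along(acc)) {
      expect_equal(st[j] == j, all(acc[seq_len(j - 1)]) || j == 1L)
    }
  }
})

test_that("chain binarisation scores perfect chains as full transmission", {
  init <- initial_run()
  runs <- lapply(1:5, function(j) {
    r <- init; attr(r, "builder") <- paste0("kid", j); r
  })
  rec <- binarize_chain(runs, init)
  expect_equal(nrow(rec), 5 * 8 * 2)
  expect_true(all(rec$transmitted == 1))
  expect_equal(sort(unique(rec$transition_stage)), 1:5)
})

test_that("a colour change is scored for that block only and is irreversible", {
  init <- initial_run()
  flip <- init
  flip$color[3] <- "red"   # block 3 original colour is blue
  runs <- list(init, flip, init)  # child 3 switches back
  for (j in 1:3) attr(runs[[j]], "builder") <- paste0("kid", j)
  rec <- binarize_chain(runs, init)
  b3c <- rec[rec$original_block_id == 3 & rec$feature == "color", ]
  expect_equal(b3c$transmitted[order(b3c$position)], c(1, 0, 0))
  b3s <- rec[rec$original_block_id == 3 & rec$feature == "shape", ]
  expect_true(all(b3s$transmitted == 1))
  other <- rec[rec$original_block_id != 3, ]
  expect_true(all(other$transmitted == 1))
})

test_that("an omitted block loses both its features for good", {
  init <- initial_run()
  drop5 <- marble_run(init$shape_class[-5], init$color[-5], builder = "kid1")
  back <- init; attr(back, "builder") <- "kid2"
  rec <- binarize_chain(list(drop5, back), init)
  b5 <- rec[rec$original_block_id == 5, ]
  expect_true(all(b5$transmitted == 0))
})

test_that("chain records are non-increasing within every series", {
  set.seed(104)
  init <- initial_run()
  for (rep in 1:15) {
    runs <- lapply(1:6, function(j) {
      n <- sample(4:9, 1)
      marble_run(sample(shape_classes(), n, TRUE),
                 sample(default_palette(), n, TRUE),
                 builder = paste0("kid", j))
    })
    rec <- binarize_chain(runs, init)
    if (is.null(rec)) next
    for (bl in 1:8) for (f in c("shape", "color")) {
      tr <- rec$transmitted[rec$original_block_id == bl & rec$feature == f]
      expect_true(all(diff(tr) <= 0))
    }
  }
  expect_error(binarize_chain(list(), mono_run("CUBE", "red", 7)), "8 blocks")
})

test_that("the exclusion cascade reproduces the published sample counts", {
  led <- study_sample_ledger()
  expect_equal(nrow(led), 394L)
  ind <- apply_exclusions(led, "individual")
  expect_equal(ind$n_excluded, 60L)
  expect_equal(ind$n_retained, 263L)
  expect_equal(ind$n_boys, 144L)
  ch <- apply_exclusions(led, "chain")
  expect_equal(ch$n_retained, 324L)
  expect_equal(ch$n_boys, 178L)
  expect_equal(unname(ind$tally["first_position_drop"]), 71L)
  expect_equal(unname(ind$tally["wrong_model_successor"]), 10L)
  expect_equal(unname(ind$tally["built_nothing"]), 44L)
})

test_that("the exclusion cascade handles empty ledgers and bad codes", {
  empty <- data.frame(child_id = character(0), reason = character(0))
  res <- apply_exclusions(empty, "individual")
  expect_length(res$retained, 0)
  expect_true(all(res$tally == 0))
  bad <- data.frame(child_id = "a", reason = "vanished")
  expect_error(apply_exclusions(bad, "chain"), "unknown exclusion reason")
})

test_that("Cohen's kappa matches hand and brute-force computation", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  a <- c(1, 1, 1, 0); b <- c(1, 1, 0, 0)
  expect_equal(cohens_kappa(a, b), kappa_brute(a, b))
  set.seed(105)
  for (rep in 1:20) {
    x <- sample(c("p", "q", "r"), 30, TRUE)
    y <- sample(c("p", "q", "r"), 30, TRUE)
    expect_equal(cohens_kappa(x, y), kappa_brute(x, y))
    expect_equal(cohens_kappa(x, y), cohens_kappa(y, x))
  }
  expect_warning(k <- cohens_kappa(rep("a", 5), rep("a", 5)), "undefined")
  expect_true(is.na(k))
})
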