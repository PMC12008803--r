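test_that("pseudocounted frequencies follow the forced formula", {
  expect_equal(pegrna_frequencies(c(0, 1, 3)), c(1/7, 2/7, 4/7))
  expect_equal(pegrna_frequencies(rep(0, 8)), rep(1/8, 8))
  # doubling counts does NOT preserve pseudocounted frequencies
  c1 <- c(0, 1, 3)
  f1 <- pegrna_frequencies(c1)
  f2 <- pegrna_frequencies(2 * c1)
  oracle <- (2 * c1 + 1) / sum(2 * c1 + 1)
  expect_equal(f2, oracle)
  expect_false(isTRUE(all.equal(f1, f2)))
  expect_error(pegrna_frequencies(integer(0)), "Empty")
})

test_that("pegRNA scores are log2 frequency ratios", {
  expect_equal(pegrna_scores(c(0.2, 0.3), c(0.2, 0.3)), c(0, 0))
  expect_equal(pegrna_scores(0.1, 0.2), 1.0)
  # 99 -> 0 counts against a filler pegRNA keeping totals at 1e4
  pre <- c(99, 10000 - 99)
  post <- c(0, 10000)
  f_pre <- (pre + 1) / sum(pre + 1)
  f_post <- (post + 1) / sum(post + 1)
  oracle <- log2(f_post[1] / f_pre[1])
  got <- pegrna_scores(pegrna_frequencies(pre), pegrna_frequencies(post))
  expect_equal(got[1], oracle)
  expect_true(is.finite(got[1]))
})

test_that("frequency and activity filters use inclusive thresholds", {
  cfg <- screen_config(freq_min = 6e-5, st_activity_min_pct = 75)
  tab <- tibble::tibble(
    pegrna_id = paste0("p", 1:4),
    freq_pre = c(5.9e-5, 6e-5, 1e-3, 1e-3),
    st_editing_pre_pct = c(90, 75, NA, 74.9)
  )
  out <- apply_filters(tab, cfg)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$passed_freq_filter, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$passed_activity_filter, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("neutral-median normalisation centres the neutral set", {
  scores <- c(2.4, 0.4, 0.4, 0.4, 0.3, 0.5)
  neut <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  out <- normalize_to_neutral(scores, neut)
  expect_equal(out[1], 2.0)
  all_neut <- normalize_to_neutral(scores, rep(TRUE, 6), min_neutral = 5)
  expect_equal(median(all_neut), 0)
  # even neutral count: median is the mean of the central pair
  x <- c(5, 1, 2, 3, 4, 1, 2, 3, 4, 9)
  nt <- c(FALSE, rep(TRUE, 8), FALSE)
  sorted <- sort(x[nt])
  oracle_med <- mean(sorted[c(4, 5)])
  expect_equal(normalize_to_neutral(x, nt)[1], 5 - oracle_med)
  expect_error(normalize_to_neutral(1:10, c(TRUE, rep(FALSE, 9))),
               "neutral")
})

test_that("multi-condition function scores match a step-by-step oracle", {
  lib <- toy_multi_screen()
  ids <- lib$designs$pegrna_id
  vmap <- setNames(lib$designs$variant_id, ids)
  set.seed(5)
  sc1 <- round(rnorm(length(ids), 0, 1), 3)
  sc2 <- round(rnorm(length(ids), 0.5, 1), 3)
  cfg <- screen_config(scoring_mode = "multi")
  tab <- toy_score_table(lib, sc1, sc2)
  got <- function_scores(tab, lib, cfg, min_conditions = 2)

  # independent spreadsheet-style oracle in base R
  neut <- paste0("v0", 2:6)
  oracle <- local({
    per_cond <- lapply(list(c1 = sc1, c2 = sc2), function(sc) {
      means <- tapply(sc, vmap[ids], mean)
      means - median(means[neut])
    })
    common <- names(per_cond$c1)
    avg <- (per_cond$c1[common] + per_cond$c2[common]) / 2
    avg - median(avg[neut])
  })
  expect_equal(got$function_score[match(names(oracle), got$variant_id)],
               as.numeric(oracle))
  expect_true(all(got$n_conditions == 2))

  # a variant scored in only one condition is dropped
  sc2_missing <- sc2
  sc2_missing[vmap[ids] == "v08"] <- NA
  tab2 <- toy_score_table(lib, sc1, sc2_missing)
  got2 <- function_scores(tab2, lib, cfg, min_conditions = 2)
  expect_false("v08" %in% got2$variant_id)
  expect_true("v08" %in% got$variant_id)
})

test_that("the trivial two-condition example gives a score of 2", {
  lib <- toy_multi_screen()
  ids <- lib$designs$pegrna_id
  vmap <- lib$designs$variant_id
  # target v01: pegRNA scores {c1: 1, 3; c2: 2}; neutrals symmetric so all
  # medians are zero at every step
  sc1 <- rep(NA_real_, length(ids))
  sc2 <- rep(NA_real_, length(ids))
  sc1[vmap == "v01"] <- c(1, 3, NA)
  sc2[vmap == "v01"] <- c(2, NA, NA)
  neutral_scores <- c(-2, -1, 0, 1, 2)
  sc1[vmap %in% paste0("v0", 2:6)] <- neutral_scores
  sc2[vmap %in% paste0("v0", 2:6)] <- neutral_scores
  tab <- toy_score_table(lib, sc1, sc2)
  got <- function_scores(tab, lib, screen_config(scoring_mode = "multi"),
                         min_conditions = 2)
  expect_equal(got$function_score[got$variant_id == "v01"], 2.0)
})

test_that("single-screen mode averages normalised pegRNA scores", {
  lib <- toy_multi_screen()
  ids <- lib$designs$pegrna_id
  vmap <- setNames(lib$designs$variant_id, ids)
  set.seed(8)
  sc <- round(rnorm(length(ids)), 3)
  tab <- toy_score_table(lib, sc, NA * sc) |>
    dplyr::filter(condition == "c1")
  cfg <- screen_config(scoring_mode = "single")
  got <- function_scores(tab, lib, cfg, min_conditions = 1)
  neut_peg <- vmap[ids] %in% paste0("v0", 2:6)
  norm <- sc - median(sc[neut_peg])
  oracle <- tapply(norm, vmap[ids], mean)
  expect_equal(got$function_score[match(names(oracle), got$variant_id)],
               as.numeric(oracle))
})

test_that("cell-line scores restrict to each line's conditions", {
  fx <- sim_screen_fixture(seed = 77,
                           params = sim_params(n_variants = 40,
                                               pegrnas_per_variant = 3,
                                               depth_per_sample = 1e5,
                                               s_lof = 2, seed = 77),
                           mode = "multi",
                           config = screen_config(
                             scoring_mode = "multi",
                             selection_direction = "enrichment",
                             freq_min = 1e-4, st_activity_min_pct = 5))
  excl <- suppressMessages(
    negative_control_filter(fx$obs, fx$samples, fx$config))
  st <- build_score_table(fx$obs, fx$samples, fx$sim$library, fx$config,
                          excl)
  cl <- cellline_scores(st, fx$sim$library, fx$config, fx$samples)
  expect_setequal(unique(cl$cell_line), c("HAP1_PEmax", "HAP1_PEmaxdn"))
  # per line, the result equals function_scores on that line's conditions
  conds <- fx$samples |>
    dplyr::filter(cell_line == "HAP1_PEmax", role == "pre") |>
    dplyr::pull(condition) |> unique()
  direct <- function_scores(st, fx$sim$library, fx$config,
                            min_conditions = 2, conditions = conds)
  sub <- cl[cl$cell_line == "HAP1_PEmax", ]
  expect_equal(sub$function_score[match(direct$variant_id, sub$variant_id)],
               direct$function_score)
})

test_that("per-variant mean ST editing averages across pegRNAs", {
  lib <- toy_multi_screen()
  tab <- tibble::tibble(
    condition = "c1",
    pegrna_id = c("pg01_1", "pg01_2", "pg02_1"),
    freq_pre = 1e-3, freq_post = 1e-3, pegrna_score = 0,
    st_editing_pre_pct = c(10, 30, 50),
    passed_freq_filter = TRUE, passed_activity_filter = TRUE,
    retained = TRUE
  )
  got <- mean_variant_st_editing(tab, lib)
  expect_equal(got$mean_st_editing_pct[got$variant_id == "v01"], 20)
  expect_equal(got$mean_st_editing_pct[got$variant_id == "v02"], 50)
})

test_that("feature correlations are Spearman with mid-ranked ties", {
  lib <- tiny_library()
  designs <- lib$designs
  designs$pbs_length <- c(8, 10, 12)
  designs$rtt_length <- c(15, 15, 15)
  ed <- tibble::tibble(pegrna_id = designs$pegrna_id,
                       st_editing_pct = c(10, 40, 80))
  got <- compute_feature_correlations(ed, designs,
                                      features = c("pbs_length",
                                                   "rtt_length"))
  expect_equal(got$rho[got$feature == "pbs_length"], 1)
  expect_true(is.na(got$rho[got$feature == "rtt_length"]))

  # 10-point fixture against the explicit rank-based oracle
  set.seed(2)
  d10 <- tibble::tibble(
    pegrna_id = sprintf("p%02d", 1:10),
    pbs_length = sample(c(8, 9, 9, 10, 11, 12, 12, 13, 14, 15)),
    spacer_ontarget_score = runif(10)
  )
  ed10 <- tibble::tibble(pegrna_id = d10$pegrna_id,
                         st_editing_pct = runif(10, 0, 100))
  got10 <- compute_feature_correlations(ed10, d10,
                                        features = "pbs_length")
  expect_equal(got10$rho,
               oracle_spearman(d10$pbs_length, ed10$st_editing_pct))
})

test_that("raising the activity threshold never gains scored variants", {
  fx <- sim_screen_fixture(seed = 19,
                           params = sim_params(n_variants = 60,
                                               pegrnas_per_variant = 3,
                                               depth_per_sample = 1e5,
                                               seed = 19))
  excl <- suppressMessages(
    negative_control_filter(fx$obs, fx$samples, fx$config))
  st <- build_score_table(fx$obs, fx$samples, fx$sim$library, fx$config,
                          excl)
  prev <- Inf
  for (t in c(0, 10, 30, 50, 75, 90)) {
    cfg <- fx$config
    cfg$st_activity_min_pct <- t
    tab <- apply_filters(st, cfg)
    n <- tryCatch(nrow(function_scores(tab, fx$sim$library, cfg,
                                       min_conditions = 1)),
                  error = function(e) 0L)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("neutral function scores centre at zero after final normalisation", {
  fx <- sim_screen_fixture(seed = 37,
                           params = sim_params(n_variants = 50,
                                               pegrnas_per_variant = 3,
                                               depth_per_sample = 1e5,
                                               s_lof = 2, seed = 37),
                           mode = "multi",
                           config = screen_config(
                             scoring_mode = "multi",
                             selection_direction = "enrichment",
                             freq_min = 1e-4, st_activity_min_pct = 5))
  excl <- suppressMessages(
    negative_control_filter(fx$obs, fx$samples, fx$config))
  st <- build_score_table(fx$obs, fx$samples, fx$sim$library, fx$config,
                          excl)
  fs <- function_scores(st, fx$sim$library, fx$config, min_conditions = 2)
  expect_equal(median(fs$function_score[fs$neutral_set]), 0)
})
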