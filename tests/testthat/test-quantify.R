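mk_table <- function(animals, counts_per_animal, group = "control",
                     cell_class = "hepatocyte", tissue = "liver") {
  rows <- do.call(rbind, lapply(seq_along(animals), function(i) {
    data.frame(animal_id = animals[i], n_foci = counts_per_animal[[i]])
  }))
  foci_count_table(rows$animal_id, group, tissue, cell_class,
                   nucleus_id = stats::ave(seq_len(nrow(rows)), rows$animal_id,
                                           FUN = seq_along),
                   n_foci = rows$n_foci)
}

test_that("group summaries use the animal as the experimental unit", {
  tb <- mk_table("a1", list(c(2, 4)))
  s <- summarize_groups(tb)
  expect_equal(s$mean_foci, 3)
  expect_true(is.na(s$sd_foci)); expect_false(s$sd_defined)
  tb2 <- mk_table(c("a1", "a2"), list(c(1, 3), c(4, 4)))  # animal means 2, 4
  s2 <- summarize_groups(tb2)
  expect_equal(s2$mean_foci, 3)
  expect_equal(s2$sd_foci, sqrt(2))
  expect_equal(s2$n_animals, 2); expect_equal(s2$n_nuclei, 4)
  # nucleus unit pools all nuclei: {2,4} and {4} -> 10/3
  tb3 <- mk_table(c("a1", "a2"), list(c(2, 4), 4))
  expect_equal(summarize_groups(tb3, unit = "nucleus")$mean_foci, 10 / 3)
  # duplicating every nucleus of one animal leaves the animal-unit mean alone
  dup <- tb2
  extra <- dup[dup$animal_id == "a1", ]
  extra$nucleus_id <- extra$nucleus_id + 100L
  dup2 <- dplyr::bind_rows(dup, extra)
  class(dup2) <- class(tb2)
  expect_equal(summarize_groups(dup2)$mean_foci, s2$mean_foci)
})

test_that("zero-foci fractions and histograms are exact on small fixtures", {
  tb <- mk_table("a1", list(c(0, 0, 1, 2)))
  expect_equal(zero_foci_fraction(tb)$zero_fraction, 0.5)
  tbz <- mk_table("a1", list(c(0, 0, 0)))
  expect_equal(zero_foci_fraction(tbz)$zero_fraction, 1)
  h <- count_histogram(tb)
  expect_equal(h$fraction[h$n_foci == 0], 0.5)
  expect_equal(h$fraction[h$n_foci == 1], 0.25)
  expect_equal(h$fraction[h$n_foci == 2], 0.25)
  hz <- count_histogram(mk_table("a1", list(c(7, 7))))
  expect_equal(hz$fraction, 1)
  # histograms: fractions sum to 1 and reproduce the mean, on random tables
  for (seed in 1:3) {
    set.seed(seed)
    cnt <- stats::rpois(50, 4)
    tbr <- mk_table("a1", list(cnt))
    hr <- count_histogram(tbr)
    expect_equal(sum(hr$fraction), 1, tolerance = 1e-12)
    expect_equal(sum(hr$fraction * hr$n_foci), mean(cnt), tolerance = 1e-12)
  }
})

test_that("zero fraction of a ZIP sample falls in the 99% binomial interval", {
  set.seed(5)
  pi0 <- zip_pi0_for_zero_fraction(0.26, 5)
  cnt <- ifelse(stats::runif(200) < pi0, 0, stats::rpois(200, 5))
  tb <- mk_table("a1", list(cnt))
  zf <- zero_foci_fraction(tb)$zero_fraction
  half <- stats::qnorm(0.995) * sqrt(0.26 * 0.74 / 200)
  expect_lt(abs(zf - 0.26), half)
})

test_that("one-way ANOVA reproduces hand computations and identities", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))$F, 0)
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$F, 3, tolerance = 1e-10)
  expect_equal(a$df_between, 2); expect_equal(a$df_within, 6)
  expect_equal(a$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # k = 2: F equals the squared pooled-variance t statistic
  set.seed(7)
  g1 <- rnorm(8); g2 <- rnorm(5, 1)
  f2 <- one_way_anova(list(g1, g2))$F
  t2 <- stats::t.test(g1, g2, var.equal = TRUE)$statistic^2
  expect_equal(f2, unname(t2), tolerance = 1e-10)
  # shift and scale invariance
  gs <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  f0 <- one_way_anova(gs)$F
  expect_equal(one_way_anova(lapply(gs, `+`, 100))$F, f0, tolerance = 1e-10)
  expect_equal(one_way_anova(lapply(gs, `*`, 3.5))$F, f0, tolerance = 1e-10)
  # zero within-group variance with nonzero between
  az <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(is.infinite(az$F)); expect_equal(az$p, 0)
  expect_true(az$degenerate)
})

test_that("Tukey HSD matches hand values and stats::TukeyHSD", {
  gs <- list(c(1, 2, 3), c(3, 4, 5), c(2, 3, 4))
  tk <- tukey_hsd(gs)
  q_extreme <- tk$q[tk$group_i == 1 & tk$group_j == 2]
  expect_equal(q_extreme, 2 / sqrt(1 / 3), tolerance = 1e-10)
  # identical groups: all adjusted p = 1
  tk0 <- tukey_hsd(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(abs(tk0$p_adj - 1) < 1e-12))
  # cross-check adjusted p against stats::TukeyHSD on an unbalanced fixture
  set.seed(11)
  gu <- list(rnorm(6), rnorm(4, 0.8), rnorm(7, -0.4))
  tku <- tukey_hsd(gu)
  values <- unlist(gu)
  fac <- factor(rep(1:3, times = lengths(gu)))
  ref <- stats::TukeyHSD(stats::aov(values ~ fac))$fac
  # same pair order: 2-1, 3-1, 3-2
  expect_equal(tku$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_equal(tku$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  # adjusted p decreases with |mean difference| at fixed spread
  base <- list(c(1, 2, 3), c(1, 2, 3) + 0.5, c(1, 2, 3) + 3)
  tkm <- tukey_hsd(base)
  expect_true(tkm$p_adj[tkm$group_j == 3 & tkm$group_i == 1] <
              tkm$p_adj[tkm$group_j == 2 & tkm$group_i == 1])
})

test_that("a 3-group x 4-animal design gives ANOVA df (2, 9)", {
  set.seed(13)
  rows <- expand.grid(animal = 1:12)
  groups <- rep(c("control", "4h", "25h"), each = 4)
  per_animal_means <- lapply(1:12, function(i)
    mean(stats::rpois(40, c(0.5, 5, 7)[(i - 1) %/% 4 + 1])))
  gl <- split(unlist(per_animal_means), groups)
  a <- one_way_anova(gl)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 9)
})

test_that("count table validation catches duplicates and bad groups", {
  expect_error(foci_count_table("a", "x", "liver", "hepatocyte", 1, 1),
               "declared set")
  expect_error(foci_count_table(c("a", "a"), "control", "liver", "hepatocyte",
                                c(1, 1), c(1, 2)), "unique")
})
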