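test_that("interaction classifier reproduces the hand-written truth table", {
  tt <- utils::read.csv(test_path("fixtures", "interaction-truth-table.csv"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tt))) {
    row <- tt[i, ]
    cl <- classify_interaction(
      rec(row$a_est, row$a_lo, row$a_hi),
      rec(row$b_est, row$b_lo, row$b_hi),
      rec(row$ab_est, row$ab_lo, row$ab_hi),
      rec(0, row$di_lo, row$di_hi))
    expect_identical(cl$type, row$type, label = row$case)
    expect_identical(cl$audit_flag, row$audit, label = row$case)
    expect_identical(cl$intensity, intensity_score(row$type))
  }
})

test_that("classifier is total and rule-consistent over the exhaustive grid", {
  # every combination of dI CI position, single-effect sign/significance
  # pattern, combined significance, and combined-magnitude class
  di_pos <- list(contains = c(-0.4, 0.4), below = c(-0.9, -0.3),
                 above = c(0.3, 0.9))
  sgl <- function(est, sig)
    if (sig) rec(est, est - 0.1, est + 0.1) else rec(est, -abs(est) - 1, abs(est) + 1)
  grid <- expand.grid(di = names(di_pos), sa = c(1, -1), sb = c(1, -1),
                      siga = c(TRUE, FALSE), sigb = c(TRUE, FALSE),
                      sigab = c(TRUE, FALSE),
                      mag = c("below_min", "between", "above_sum"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    a <- sgl(0.9 * gr$sa, gr$siga)
    b <- sgl(0.6 * gr$sb, gr$sigb)
    ab_mag <- switch(gr$mag, below_min = 0.3, between = 1.0,
                     above_sum = 2.0)
    ab <- sgl(-ab_mag, gr$sigab)
    di <- rec(mean(di_pos[[gr$di]]), di_pos[[gr$di]][1],
              di_pos[[gr$di]][2])
    cl <- classify_interaction(a, b, ab, di)
    expect_true(cl$type %in% c("synergistic", "additive",
                               "weak_antagonistic",
                               "strong_antagonistic", "neutralizing"))
    expect_identical(cl$intensity, intensity_score(cl$type))
    if (gr$di == "contains") expect_identical(cl$type, "additive")
    if (cl$type == "neutralizing") expect_false(isTRUE(ab$significant))
    if (cl$type == "strong_antagonistic" && !cl$audit_flag)
      expect_true(ab$significant &&
                  abs(ab$estimate) < min(abs(a$estimate), abs(b$estimate)))
  }
})

test_that("intensity scale maps the five types onto -1..3", {
  expect_identical(intensity_score(c("synergistic", "additive",
                                     "weak_antagonistic",
                                     "strong_antagonistic",
                                     "neutralizing")),
                   c(-1L, 0L, 1L, 2L, 3L))
  expect_error(intensity_score("mutualistic"), "unknown")
})

test_that("community antagonism is a proportion-weighted intensity", {
  expect_equal(community_antagonism(c(rep("weak_antagonistic", 5),
                                      rep("neutralizing", 5))), 2.0)
  expect_equal(community_antagonism(rep("additive", 7)), 0)
  expect_equal(community_antagonism(rep("synergistic", 3)), -1)
  expect_error(community_antagonism(character(0)), "no interaction calls")
  # bounded in [-1, 3] under fuzzing
  set.seed(1)
  for (i in 1:50) {
    tys <- sample(c("synergistic", "additive", "weak_antagonistic",
                    "strong_antagonistic", "neutralizing"),
                  sample(1:30, 1), replace = TRUE)
    v <- community_antagonism(tys)
    expect_true(v >= -1 && v <= 3)
    if (length(unique(tys)) == 1)
      expect_equal(v, intensity_score(tys[1]))
  }
})

test_that("response directions partition taxa, ties counting positive", {
  ctrl <- c(a = 2, b = 3, c = 4)
  worse <- c(a = 1, b = 2, c = 3)
  r <- summarize_response_directions(ctrl, worse)
  expect_equal(r$prop_negative, 1)
  tie <- c(a = 2, b = 3, c = 5)
  r2 <- summarize_response_directions(ctrl, tie)
  expect_equal(r2$prop_positive, 1)  # equal rates count positive
  mix <- c(a = 1, b = 4, c = 4)
  r3 <- summarize_response_directions(ctrl, mix)
  expect_equal(r3$prop_negative + r3$prop_positive, 1)
  expect_error(summarize_response_directions(c(x = 1), c(y = 2)),
               "no taxa shared")
})

test_that("scenario comparison: overlap, intensity shifts, cross-tab", {
  mk <- function(taxa, types) data.frame(taxon = taxa, type = types,
                                         intensity = intensity_score(types),
                                         stringsAsFactors = FALSE)
  a <- mk(c("t1", "t2"), c("additive", "additive"))
  b <- mk(c("t3", "t4"), c("additive", "additive"))
  expect_equal(compare_scenarios(a, b)$n_shared, 0)

  same <- mk(c("t1", "t2", "t3"),
             c("weak_antagonistic", "additive", "synergistic"))
  cs <- compare_scenarios(same, same)
  expect_true(all(cs$intensity_shift == 0))
  expect_equal(cs$n_higher_in_ww, 0)

  wd <- mk(c("t1", "t2", "t3", "t4"),
           c("weak_antagonistic", "weak_antagonistic", "additive",
             "synergistic"))
  ww <- mk(c("t1", "t2", "t3", "t5"),
           c("neutralizing", "weak_antagonistic", "strong_antagonistic",
             "additive"))
  cs2 <- compare_scenarios(wd, ww)
  expect_equal(cs2$n_shared, 3)
  expect_setequal(cs2$shared_taxa, c("t1", "t2", "t3"))
  expect_equal(cs2$n_higher_in_ww, 2)  # t1 (1 -> 3) and t3 (0 -> 2)
  expect_equal(cs2$cross_tab["weak_antagonistic", "neutralizing"], 1,
               ignore_attr = TRUE)
  expect_equal(cs2$cross_tab["weak_antagonistic", "weak_antagonistic"], 1,
               ignore_attr = TRUE)
  expect_equal(sum(cs2$cross_tab), 3)
})
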