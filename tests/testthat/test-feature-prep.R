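test_that("feature assembly yields one complete row per mouse-session", {
  sf <- small_features()
  feats <- sf$features
  expect_equal(nrow(feats), length(small_cohort()$traces))
  expect_equal(names(feats)[-(1:5)],
               c("AUC_H", "AUC_SB", "AUC_SN", "s_H_SB", "s_H_SN", "s_SB_SN",
                 "Lg_H", "Lg_SB", "Lg_SN", "Cl_H", "Cl_SB", "Cl_SN",
                 "Cg_H", "Cg_SB", "Cg_SN"))
  expect_false(anyNA(feats))
  expect_true(all(feats[, c("s_H_SB", "s_H_SN", "s_SB_SN")] >= 0))
  # a missing stage row is an error that names the key
  broken <- sf$indices[-1, ]
  expect_error(assemble_features(broken, sf$spectral, sf$activity,
                                 sf$behavior),
               sf$indices$mouse_id[1])
})

test_that("variance-stabilizing transforms hit the right columns", {
  tab <- data.frame(mouse_id = "m", AUC_H = 5, s_H_SB = 0, Cl_SB = 1,
                    Cg_H = 0.5, Lg_SB = 2, S_avg = 50)
  tr <- transform_features(tab, eps = 1e-6)
  expect_equal(tr$s_H_SB, log(1e-6))           # s = 0 stays finite
  expect_equal(tr$Cl_SB, log(1 + 1e-6))
  expect_equal(tr$Cg_H, 1 / (0.5 + 1e-6))
  expect_equal(tr$AUC_H, 5)                    # untouched
  expect_equal(tr$Lg_SB, 2)
  expect_equal(tr$S_avg, 50)                   # id columns untouched
  # log preserves order; inverse reverses it
  x <- c(0.1, 0.5, 2)
  t2 <- transform_features(data.frame(s_H_SN = x, Cg_SB = x))
  expect_equal(order(t2$s_H_SN), order(x))
  expect_equal(order(t2$Cg_SB), rev(order(x)))
})

test_that("winsorization clips at 3 unscaled MADs", {
  expect_equal(winsorize_mad(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4, 6))
  x <- c(2, 3, 4, 5)
  expect_equal(winsorize_mad(x), x)            # all within bounds
  expect_warning(w <- winsorize_mad(rep(7, 5)), "MAD is zero")
  expect_equal(w, rep(7, 5))
})

test_that("the Mahalanobis screen flags the chi-square tail", {
  # univariate: value at the mean has D2 = 0 and is kept
  tab <- data.frame(AUC_H = c(0, 1, -1, 0.5, -0.5))
  scr <- mahalanobis_screen(tab, columns = "AUC_H")
  expect_equal(scr$d2[1], 0)
  expect_true(nrow(scr$flagged) == 0)
  # Monte-Carlo: ~2.5% of standard normals exceed chi2_{1,0.975}
  withr::with_seed(33, {
    tabn <- data.frame(AUC_H = stats::rnorm(4000))
    scr <- mahalanobis_screen(tabn, columns = "AUC_H")
    expect_equal(mean(scr$d2 > scr$cutoff), 0.025, tolerance = 0.3)
    expect_equal(scr$cutoff, stats::qchisq(0.975, 1))
  })
  # identical rows exercise the singular-covariance path
  same <- data.frame(AUC_H = rep(1, 6), AUC_SB = rep(2, 6))
  expect_warning(mahalanobis_screen(same, columns = c("AUC_H", "AUC_SB")),
                 "singular")
  # flag-only mode keeps every row
  scr <- mahalanobis_screen(tabn, columns = "AUC_H", action = "flag")
  expect_equal(nrow(scr$kept), nrow(tabn))
})

test_that("correlation pruning follows the mean-absolute-correlation rule", {
  withr::with_seed(44, {
    z <- stats::rnorm(40)
    tab <- data.frame(AUC_H = z, AUC_SB = z, AUC_SN = stats::rnorm(40))
    pruned <- prune_correlated(tab, cutoff = 0.8,
                               columns = c("AUC_H", "AUC_SB", "AUC_SN"))
    expect_length(attr(pruned, "pruned"), 1)     # one of the twins removed
    # A-B 0.9, A-C 0.85, B-C 0.1: A has the largest mean |r| and goes first
    n <- 200
    a <- stats::rnorm(n)
    b <- 0.9 * a + sqrt(1 - 0.81) * stats::rnorm(n)
    cvec <- 0.85 * a + sqrt(1 - 0.7225) * stats::rnorm(n)
    tab2 <- data.frame(A = a, B = b, C = cvec)
    p2 <- prune_correlated(tab2, cutoff = 0.8, columns = c("A", "B", "C"))
    expect_equal(attr(p2, "pruned"), "A")
    # below-cutoff tables pass through unchanged
    tab3 <- data.frame(A = a, C = stats::rnorm(n))
    p3 <- prune_correlated(tab3, cutoff = 0.8, columns = c("A", "C"))
    expect_length(attr(p3, "pruned"), 0)
  })
})

test_that("the fixed candidate subset keeps exactly the 11 model predictors", {
  feats <- small_features()$features
  sub <- candidate_subset(feats)
  pred_cols <- setdiff(names(sub),
                       c("mouse_id", "session", "genotype",
                         "motivation_label", "S_avg"))
  expect_length(pred_cols, 11)
  expect_false("s_SB_SN" %in% pred_cols)
  expect_setequal(pred_cols,
                  c("AUC_H", "AUC_SB", "AUC_SN", "s_H_SB", "s_H_SN",
                    "Lg_SB", "Cl_SB", "Cl_SN", "Cg_H", "Cg_SB", "Cg_SN"))
  expect_error(candidate_subset(feats[, -match("Cg_H", names(feats))]),
               "Cg_H")
})

test_that("the default preprocessing ledger runs end to end", {
  pre <- small_preprocessed()
  expect_lte(nrow(pre), nrow(small_features()$features))
  expect_length(setdiff(names(pre), c("mouse_id", "session", "genotype",
                                      "motivation_label", "S_avg")), 11)
  expect_false(anyNA(pre))
})
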