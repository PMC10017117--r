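test_that("node-to-tip distances are path-length sums", {
  tr <- tree_from_text(TOY_NEWICK)
  expect_equal(node_to_tip_distances(tr, 1),
               c(A_2000 = 0.15, B_2001 = 0.25, C_2002 = 0.3))
  expect_equal(node_to_tip_distances(tr, 2), c(A_2000 = 0.1, B_2001 = 0.2))
  expect_error(node_to_tip_distances(tr, 3), "tip")
})

test_that("distances agree with brute-force path walking and are additive", {
  set.seed(42)
  for (seed in 1:5) {
    sim <- simulate_clock_tree(n_tips = 15, noise = "gaussian",
                               noise_sd_frac = 0.3, seed = seed)
    tr <- sim$tree
    for (id in internal_nodes(tr)) {
      expect_equal(node_to_tip_distances(tr, id), brute_distances(tr, id),
                   tolerance = 1e-12)
    }
    # additivity: d(root, tip) = d(root, v) + d(v, tip) for v on the path
    droot <- node_to_tip_distances(tr, 1)
    for (id in setdiff(internal_nodes(tr), 1)) {
      v <- tr$preorder[id]
      d_root_v <- tr$depths[v]                 # root is at depth 0
      dv <- node_to_tip_distances(tr, id)
      expect_equal(droot[names(dv)], d_root_v + dv, tolerance = 1e-12)
    }
  }
})

test_that("eligibility enforces the three conditions in order", {
  cfg <- scan_config()
  expect_equal(check_eligibility(c(2000, 2001), c(0.1, 0.2), cfg),
               list(eligible = FALSE, reason = "too-few-tips"))
  # 3 distinct pairs but only one date -> the combos rule passes first,
  # dates rule fails
  expect_equal(
    check_eligibility(c(2000, 2000, 2000), c(0.1, 0.2, 0.3), cfg),
    list(eligible = FALSE, reason = "too-few-distinct-dates"))
  expect_equal(
    check_eligibility(c(2000, 2000, 2001), c(0.1, 0.1, 0.2), cfg),
    list(eligible = FALSE, reason = "too-few-distinct-combinations"))
  expect_equal(check_eligibility(c(2000, 2000, 2001), c(0.1, 0.2, 0.2), cfg),
               list(eligible = TRUE, reason = "none"))
  expect_error(check_eligibility(1:3, 1:2, cfg), "length")
  # tolerance merges near-identical pairs
  tol_cfg <- scan_config(combo_tolerance = 1e-6)
  expect_false(check_eligibility(c(2000, 2000 + 1e-9, 2001),
                                 c(0.1, 0.1 + 1e-9, 0.2), tol_cfg)$eligible)
})

test_that("regression matches hand-worked and closed-form values", {
  # perfect line
  f <- fit_rtt_regression(c(2000, 2001, 2002), c(0.1, 0.2, 0.3))
  expect_equal(f$slope, 0.1)
  expect_equal(f$intercept, -199.9)
  expect_equal(f$adj_r2, 1)
  expect_equal(f$x_intercept, 1999)
  expect_equal(f$p_value, 0)

  # hand-worked: Sxy = 3, Sxx = 5, SSE = 0.2, SStot = 2, df = 2
  f2 <- fit_rtt_regression(c(0, 1, 2, 3), c(0, 1, 1, 2))
  expect_equal(f2$slope, 0.6)
  expect_equal(f2$intercept, 0.1)
  expect_equal(f2$r2, 0.9)
  expect_equal(f2$adj_r2, 0.85)
  expect_equal(f2$x_intercept, -1 / 6)
  # closed-form t CDF for df = 2: F(t) = 1/2 + t/(2*sqrt(t^2+2))
  t <- 0.6 / sqrt(0.02)
  expect_equal(f2$p_value, 2 * (1 - (0.5 + t / (2 * sqrt(t^2 + 2)))),
               tolerance = 1e-12)
  expect_equal(f2$p_value, 1 - sqrt(0.9), tolerance = 1e-12)

  # constant distances convention
  f3 <- fit_rtt_regression(c(2000, 2001, 2002), c(0.2, 0.2, 0.2))
  expect_equal(f3$slope, 0)
  expect_equal(f3$p_value, 1)
  expect_equal(f3$adj_r2, 0)
  expect_true(is.na(f3$x_intercept))

  # all dates equal is a defensive error
  expect_error(fit_rtt_regression(c(2000, 2000, 2000), c(0.1, 0.2, 0.3)),
               "Sxx")
})

test_that("fit agrees with lm()/summary.lm() on random data", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    x <- runif(n, 1980, 2020)
    y <- 1e-3 * x + rnorm(n, 0, 0.01)
    f <- fit_rtt_regression(x, y)
    m <- summary(lm(y ~ x))
    expect_equal(f$slope, unname(m$coefficients["x", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(f$intercept, unname(m$coefficients["(Intercept)", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(f$p_value, unname(m$coefficients["x", "Pr(>|t|)"]),
                 tolerance = 1e-10)
    expect_equal(f$r2, m$r.squared, tolerance = 1e-10)
    expect_equal(f$adj_r2, m$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("the toy tree scan yields one eligible node with the expected fit", {
  tr <- dated_tree_from_text(TOY_NEWICK)
  scan <- scan_tree(tr)
  expect_length(scan$reports, 2)
  eligible <- Filter(function(r) r$eligible, scan$reports)
  expect_length(eligible, 1)
  root <- eligible[[1]]
  expect_equal(root$node_id, 1)
  expect_equal(root$n_tips, 3)
  # oracle on distances {0.15, 0.25, 0.30} vs dates {2000, 2001, 2002}
  orc <- ols_oracle(c(2000, 2001, 2002), c(0.15, 0.25, 0.30))
  expect_equal(root$fit$slope, orc$slope, tolerance = 1e-10)
  expect_equal(root$fit$slope, 0.075)
  expect_equal(root$fit$p_value, orc$p_value, tolerance = 1e-10)
  # p ~ 0.121 > alpha: eligible but no temporal signal
  expect_false(root$significant)
  # the 2-tip cherry is ineligible
  cherry <- Filter(function(r) !r$eligible, scan$reports)[[1]]
  expect_equal(cherry$ineligibility_reason, "too-few-tips")
  expect_null(cherry$fit)
})

test_that("scan statistics are invariant to the order of children in the file", {
  a <- dated_tree_from_text("((A_2000:0.1,B_2001:0.2):0.05,(C_2002:0.3,(D_2003:0.1,E_2004:0.2):0.1):0.02);")
  b <- dated_tree_from_text("(((E_2004:0.2,D_2003:0.1):0.1,C_2002:0.3):0.02,(B_2001:0.2,A_2000:0.1):0.05);")
  sa <- scan_tree(a); sb <- scan_tree(b)
  for (ra in sa$reports) {
    tips <- descendant_tips(a, ra$node_id)
    rb <- report_for_tips(sb, b, tips)
    expect_false(is.null(rb))
    expect_equal(ra$eligible, rb$eligible)
    expect_equal(ra$significant, rb$significant)
    if (ra$eligible) {
      expect_equal(ra$fit$slope, rb$fit$slope)
      expect_equal(ra$fit$p_value, rb$fit$p_value)
      expect_equal(ra$fit$adj_r2, rb$fit$adj_r2)
    }
  }
})

test_that("scan respects alpha, sidedness and Benjamini-Hochberg correction", {
  sim <- simulate_clock_tree(n_tips = 30, noise = "gaussian",
                             noise_sd_frac = 0.4, seed = 13)
  tr <- sim$tree
  s_raw <- scan_tree(tr)
  s_bh <- scan_tree(tr, scan_config(correction = "benjamini-hochberg"))
  raw_sig <- vapply(s_raw$reports, `[[`, TRUE, "significant")
  bh_sig <- vapply(s_bh$reports, `[[`, TRUE, "significant")
  # BH can only demote, never promote
  expect_true(all(bh_sig <= raw_sig))
  # adjusted p-values recorded and match p.adjust
  elig <- Filter(function(r) r$eligible, s_bh$reports)
  p_raw <- vapply(elig, function(r) r$fit$p_value, numeric(1))
  p_adj <- vapply(elig, `[[`, numeric(1), "p_adj")
  expect_equal(p_adj, p.adjust(p_raw, "BH"))

  # one-sided halves the two-sided p for positive slopes
  s_one <- scan_tree(tr, scan_config(sided = "one"))
  for (i in seq_along(s_raw$reports)) {
    r2s <- s_raw$reports[[i]]; r1s <- s_one$reports[[i]]
    if (r2s$eligible && r2s$fit$slope > 0 && r2s$fit$sse > 0) {
      expect_equal(r1s$fit$p_value, r2s$fit$p_value / 2, tolerance = 1e-12)
    }
  }
  # a tiny tree is rejected
  expect_error(scan_tree(dated_tree_from_text("(A_2000:0.1,B_2001:0.2);")),
               "fewer than 3")
})

test_that("significance always implies eligible, positive slope, p <= alpha", {
  set.seed(3)
  for (seed in 1:6) {
    sim <- simulate_clock_tree(n_tips = 20, noise = "gaussian",
                               noise_sd_frac = 0.5, seed = seed)
    scan <- scan_tree(sim$tree)
    for (r in scan$reports) {
      expect_identical(r$eligible, r$ineligibility_reason == "none")
      if (r$significant) {
        expect_true(r$eligible)
        expect_gt(r$fit$slope, 0)
        expect_lte(r$fit$p_value, scan$config$alpha)
      }
      if (r$eligible) {
        expect_gte(r$fit$p_value, 0)
        expect_lte(r$fit$p_value, 1)
        expect_lte(r$fit$adj_r2, r$fit$r2 + 1e-15)
        if (r$fit$slope != 0) {
          expect_equal(r$fit$x_intercept,
                       -r$fit$intercept / r$fit$slope)
        }
      }
    }
  }
})

test_that("outlier tips are flagged by externally studentized residuals", {
  # perfect line: nothing to flag
  x <- c(2000, 2001, 2002, 2003)
  y <- 1e-3 * (x - 1990)
  f <- fit_rtt_regression(x, y)
  expect_identical(residual_outliers(f, x, y), character(0))

  # gross outlier in the last tip
  x2 <- c(0, 1, 2, 3, 4)
  y2 <- c(0, 0.1, 0.2, 0.3, 5.0)
  names(y2) <- paste0("tip", 1:5)
  f2 <- fit_rtt_regression(x2, y2)
  expect_identical(residual_outliers(f2, x2, y2), "tip5")
  # cross-check the full studentized-residual vector against stats::rstudent
  m <- lm(unname(y2) ~ x2)
  expect_true(abs(rstudent(m)[5]) > 3)
  expect_true(all(abs(rstudent(m)[-5]) <= 3))

  # invariant under relabeling
  names(y2) <- paste0("z", 5:1)
  expect_identical(residual_outliers(f2, x2, y2), "z1")

  # too few points: warn, flag nothing
  f3 <- fit_rtt_regression(c(0, 1, 2), c(0, 1, 5))
  expect_warning(out <- residual_outliers(f3, c(0, 1, 2), c(0, 1, 5)),
                 "fewer than 4")
  expect_identical(out, character(0))
})

test_that("permuting dates against distances keeps false positives near alpha", {
  # smoke test: regression non-independence inflates the rate mildly, so the
  # bound is alpha + 0.03, not a calibration claim
  sim <- simulate_clock_tree(n_tips = 20, noise = "gaussian",
                             noise_sd_frac = 0.2, seed = 21)
  d <- node_to_tip_distances(sim$tree, 1)
  dates <- sim$tree$dates[names(d)]
  set.seed(22)
  hits <- 0L
  n_rep <- 1000L
  for (i in seq_len(n_rep)) {
    f <- fit_rtt_regression(sample(dates), d)
    if (f$slope > 0 && f$p_value <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits / n_rep, 0.08)
})
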