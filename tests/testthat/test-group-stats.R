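mk_profile <- function(id, exv) {
  structure(list(vessel_id = id, extravasated = exv), class = "vessel_profile")
}

test_that("contingency tables count extravasated flags per side", {
  ctrl <- lapply(1:4, mk_profile, exv = FALSE)
  trt <- lapply(1:6, mk_profile, exv = TRUE)
  tab <- tabulate_extravasation(ctrl, trt)
  expect_equal(unlist(tab[c("control_exv", "control_not",
                            "treated_exv", "treated_not")]),
               c(control_exv = 0L, control_not = 4L,
                 treated_exv = 6L, treated_not = 0L))
  # conservation of totals
  expect_equal(tab$control_exv + tab$control_not, 4L)
  expect_equal(tab$treated_exv + tab$treated_not, 6L)

  # hand-counted 10-vessel fixture
  flags_c <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  flags_t <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  tab2 <- tabulate_extravasation(flags_c, flags_t)
  expect_equal(tab2$control_exv, 2L)
  expect_equal(tab2$control_not, 3L)
  expect_equal(tab2$treated_exv, 4L)
  expect_equal(tab2$treated_not, 1L)
  expect_equal(percent_extravasated(tab2), c(control = 40, treated = 80))

  # swapping the sides transposes the table rows
  tab3 <- tabulate_extravasation(flags_t, flags_c)
  expect_equal(tab3$control_exv, tab2$treated_exv)
  expect_equal(tab3$treated_not, tab2$control_not)
})

test_that("Fisher exact test matches enumeration and handles degenerate margins", {
  # published count fixture: p printed as 0.003
  expect_lt(abs(fisher_exact_2x2(contingency_table(27, 32, 46, 18)) - 0.003),
            0.002)
  # identical proportions carry no association
  expect_equal(fisher_exact_2x2(contingency_table(8, 5, 8, 5)), 1)
  # zero margin convention
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 4, 0, 5), 2, 2, byrow = TRUE)), 1)

  set.seed(23)
  for (i in 1:25) {
    m <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m),
                 oracle_fisher(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-10)
    # symmetry under simultaneous row and column swaps
    expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(m[2:1, 2:1]),
                 tolerance = 1e-12)
  }
})

test_that("two-way ANOVA recovers the balanced closed form and its invariances", {
  # identical observed cell means (symmetric within-cell noise): F = 0, p = 1
  d0 <- expand.grid(side = c("control", "treated"),
                    pulse = c("long", "mid", "short"), rep = 1:2)
  d0$value <- 10 + ifelse(d0$rep == 1, -1, 1)
  a0 <- two_way_anova(d0, "value", "side", "pulse")
  eff <- a0$table[a0$table$term != "Residuals", ]
  expect_true(all(abs(eff$statistic) < 1e-20))
  expect_true(all(eff$p_value > 0.999))

  # balanced 2x3 fixture vs textbook decomposition
  set.seed(24)
  d <- expand.grid(side = c("control", "treated"),
                   pulse = c("long", "mid", "short"), rep = 1:4)
  d$value <- 5 + 2 * (d$side == "treated") + 1.5 * as.integer(d$pulse) +
    0.8 * (d$side == "treated") * (d$pulse == "mid") + rnorm(nrow(d))
  a <- two_way_anova(d, "value", "side", "pulse")
  ref <- oracle_anova_balanced(d, "value", "side", "pulse")
  tab <- a$table
  expect_equal(tab$statistic[tab$term == "side"], ref$F_a, tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "pulse"], ref$F_b, tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "side:pulse"], ref$F_ab,
               tolerance = 1e-8)
  expect_equal(a$mse, ref$mse, tolerance = 1e-10)

  # location invariance
  d2 <- d
  d2$value <- d$value + 100
  a2 <- two_way_anova(d2, "value", "side", "pulse")
  expect_equal(a2$table$statistic, a$table$statistic, tolerance = 1e-8)

  # single-level factor is rejected
  d3 <- d[d$side == "control", ]
  expect_error(two_way_anova(d3, "value", "side", "pulse"), "single level")
})

test_that("post-hoc comparisons use the pooled error and adjust correctly", {
  set.seed(25)
  x <- c(rnorm(8, 0), rnorm(8, 1.2))
  g <- rep(c("a", "b"), each = 8)

  # two groups: one comparison, Sidak with m = 1 equals the raw p,
  # and LSD equals the pooled-variance t test
  lsd <- posthoc_pairwise(x, g, method = "fisher_lsd")
  sid <- posthoc_pairwise(x, g, method = "sidak")
  expect_equal(sid$p_adjusted, sid$p_value)
  expect_equal(lsd$p_value,
               t.test(x ~ g, var.equal = TRUE)$p.value, tolerance = 1e-12)

  # several groups: Sidak-adjusted p >= raw p, all p in [0, 1]
  y <- rnorm(30)
  h <- rep(letters[1:5], each = 6)
  res <- posthoc_pairwise(y, h, method = "sidak")
  expect_equal(nrow(res), choose(5, 2))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_true(all(res$p_adjusted <= 1 & res$p_value >= 0))
  # Sidak formula, explicitly
  expect_equal(res$p_adjusted, pmin(1 - (1 - res$p_value)^nrow(res), 1))
  expect_error(posthoc_pairwise(y, rep("a", 30)), "two groups")
})

test_that("LSD from a fitted two-way model agrees with emmeans", {
  skip_if_not_installed("emmeans")
  set.seed(26)
  d <- expand.grid(side = c("control", "treated"),
                   pulse = c("long", "mid", "short"), rep = 1:4)
  d$value <- 5 + 2 * (d$side == "treated") + rnorm(nrow(d))
  a <- two_way_anova(d, "value", "side", "pulse")
  cell <- interaction(d$side, d$pulse)
  got <- posthoc_pairwise(d$value, cell, method = "fisher_lsd",
                          mse = a$mse, df_error = a$df_error)
  em <- summary(emmeans::emmeans(a$fit, pairwise ~ side * pulse,
                                 adjust = "none")$contrasts)
  # same set of |t| statistics and raw p-values
  expect_equal(sort(abs(got$statistic)), sort(abs(em$t.ratio)),
               tolerance = 1e-8)
  expect_equal(sort(got$p_value), sort(em$p.value), tolerance = 1e-8)
})

test_that("paired biofluorescence deltas and normalization behave", {
  rec <- expand.grid(animal_id = 1:3, side = c("control", "treated"),
                     time_h = c(0, 4), stringsAsFactors = FALSE)
  rec$mean_intensity <- 1000
  out <- paired_delta_and_normalize(rec)
  expect_true(all(out$delta == 0))
  expect_true(all(out$norm_control == out$norm_treated))

  # control side at the reference time normalizes to mean 1
  set.seed(27)
  rec2 <- rec
  rec2$mean_intensity <- 1000 + rnorm(nrow(rec2), 0, 50)
  out2 <- paired_delta_and_normalize(rec2)
  expect_equal(mean(out2$norm_control[out2$time_h == 0]), 1)

  # treated = 1.4 x control at t 0: normalized treated 1.4, delta 0.4 x control
  rec3 <- expand.grid(animal_id = 1:3, side = c("control", "treated"),
                      time_h = 0, stringsAsFactors = FALSE)
  ctrl_val <- c(900, 1000, 1100)
  rec3$mean_intensity <- ifelse(rec3$side == "control",
                                ctrl_val[rec3$animal_id],
                                1.4 * ctrl_val[rec3$animal_id])
  out3 <- paired_delta_and_normalize(rec3)
  expect_equal(mean(out3$norm_treated), 1.4)
  expect_equal(out3$delta, 0.4 * ctrl_val)

  # missing pair member errors
  expect_error(paired_delta_and_normalize(rec[-1, ]), "missing pair")
})
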