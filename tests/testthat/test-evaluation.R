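test_that("batch evaluation yields one scored record per pair", {
  pairs <- gen_pairs(2, seed = 1)
  rec <- evaluate_batch(pairs)
  expect_s3_class(rec, "eims_eval")
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$dot >= 0 & rec$dot <= 1000))
  # identical pair scores 1000/1000
  s <- gen_reference(seed = 2)
  same <- evaluate_batch(list(list(id = "x", ref = s, pred = s)))
  expect_equal(same$dot, 1000L)
  expect_equal(same$cos, 1000L)
})

test_that("batch scores agree with per-pair scoring", {
  pairs <- gen_pairs(100, seed = 3)
  rec <- evaluate_batch(pairs)
  for (k in seq_along(pairs)) {
    sc <- score_pair(pairs[[k]]$pred, pairs[[k]]$ref)
    expect_identical(rec$dot[k], sc[["dot"]])
    expect_identical(rec$cos[k], sc[["cos"]])
  }
})

test_that("metadata joins by id and reports unmatched ids", {
  pairs <- gen_pairs(3, seed = 4)
  md <- data.frame(id = vapply(pairs, `[[`, "", "id"),
                   class = c("A", "A", "B"), mw = c(130, 130, 130),
                   rbn = 1:3, phi = c(2, 3, 4))
  rec <- evaluate_batch(pairs, metadata = md)
  expect_equal(rec$class_label, c("A", "A", "B"))
  expect_equal(rec$rbn, 1:3)
  expect_error(evaluate_batch(pairs, metadata = md[1:2, ]),
               "missing from metadata")
})

test_that("summaries match brute-force recomputation", {
  rec <- data.frame(dot = c(999, 800, 400), cos = c(999, 800, 400))
  s <- summarize_scores(rec)
  expect_equal(s$frac_gt700, c(2 / 3, 2 / 3))
  expect_equal(s$frac_lt500, c(1 / 3, 1 / 3))
  expect_equal(s$frac_gt850, c(1 / 3, 1 / 3))
  # single record: sd is absent
  expect_true(is.na(summarize_scores(rec[1, ])$sd[1]))
  # 1000 random records vs independent formulas
  set.seed(11)
  x <- data.frame(dot = sample(0:1000, 1000, TRUE),
                  cos = sample(0:1000, 1000, TRUE))
  s <- summarize_scores(x)
  d <- s[s$score == "dot", ]
  expect_equal(d$mean, sum(x$dot) / 1000)
  expect_equal(d$sd, sqrt(sum((x$dot - mean(x$dot))^2) / 999))
  expect_equal(d$median, sort(x$dot)[500:501] |> mean())
  expect_equal(d$frac_gt700, sum(x$dot > 700) / 1000)
  # threshold fractions are monotone; permutation invariance
  expect_lte(d$frac_gt850, d$frac_gt700)
  expect_equal(summarize_scores(x[sample(1000), ]), s)
})

test_that("Welch class comparison detects a simulated shift", {
  hits <- 0L
  for (r in 1:200) {
    set.seed(2000 + r)
    rec <- data.frame(
      dot = c(rnorm(75, 520, 200), rnorm(75, 650, 200)),
      cos = 0,
      class_label = rep(c("oxy", "het"), each = 75))
    cmp <- compare_classes(rec, "dot")
    hits <- hits + (cmp$p_value < 0.05)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Welch comparison holds its type-I error under the null", {
  pvals <- vapply(1:200, function(r) {
    set.seed(4000 + r)
    rec <- data.frame(dot = rnorm(150, 600, 200), cos = 0,
                      class_label = rep(c("A", "B"), each = 75))
    compare_classes(rec, "dot")$p_value
  }, numeric(1))
  expect_lte(abs(mean(pvals < 0.05) - 0.05), 0.02 + 1e-12)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("small classes are excluded and degenerate cases warn", {
  rec <- data.frame(dot = rnorm(149, 600, 100), cos = 0,
                    class_label = c(rep("A", 50), rep("B", 50),
                                    rep("C", 49)))
  cmp <- compare_classes(rec, "dot")
  expect_false("C" %in% c(cmp$class_a, cmp$class_b))
  rec2 <- data.frame(dot = rnorm(60), cos = 0,
                     class_label = rep(c("A", "B"), c(50, 10)))
  expect_warning(out <- compare_classes(rec2, "dot"), "fewer than two")
  expect_equal(nrow(out), 0L)
})

test_that("flexibility correlation behaves at the extremes", {
  rec <- data.frame(phi = 1:20, rbn = 1:20,
                    dot = (1:20) * 50, cos = (1:20) * 40)
  ct <- correlate_flexibility(rec)
  expect_equal(ct$rho, rep(1, 4))
  # independent draws: small rho, rarely significant
  sig <- 0L
  for (r in 1:100) {
    set.seed(6000 + r)
    rec <- data.frame(phi = runif(80, 1, 10), rbn = sample(0:10, 80, TRUE),
                      dot = sample(0:1000, 80), cos = sample(0:1000, 80))
    ct <- correlate_flexibility(rec)
    sig <- sig + (ct$p_value[ct$descriptor == "phi" &
                               ct$score == "dot"] < 0.05)
  }
  expect_lt(sig / 100, 0.2)
  # constant descriptor: reported absent
  recc <- data.frame(phi = rep(2, 10), rbn = 1:10,
                     dot = sample(0:1000, 10), cos = sample(0:1000, 10))
  expect_true(is.na(correlate_flexibility(recc)$rho[1]))
})

test_that("parameter sweeps aggregate per-setting summaries", {
  sets <- lapply(c(a = 100, b = 400, c = 250), function(ntraj) {
    evaluate_batch(gen_pairs(5, seed = ntraj))
  })
  names(sets) <- c("100", "400", "250")
  tab <- sweep_summarize(sets, parameter = "ntraj")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$value, c("100", "250", "400"))  # numerically sorted
  # equals summarize() applied per group
  s <- summarize_scores(sets[["250"]])
  expect_equal(tab$mean_dot[tab$value == "250"],
               s$mean[s$score == "dot"])
  expect_error(sweep_summarize(list()), "no record sets")
})
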