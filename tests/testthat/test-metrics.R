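# NRMSE, ranges, summaries, envelope, comparison report

test_that("nrmse: identity, constant offset, direct evaluation", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3))$nrmse, 0)
  # constant offset d over observed range R gives exactly d/R
  o <- c(0, 2, 5, 9)
  expect_equal(nrmse(o, o + 1.8)$nrmse, 1.8 / 9)
  r <- nrmse(c(0, 1, 2), c(1, 1, 1))
  expect_equal(r$nrmse, sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_equal(r$percent, 40.82, tolerance = 1e-2)
  expect_false(r$accepted)
  expect_true(nrmse(o, o + 0.5)$accepted)
})

test_that("nrmse errors on malformed input", {
  expect_error(nrmse(c(1, 1, 1), c(1, 2, 1)), "range")
  expect_error(nrmse(1, 1), "at least 2")
  expect_error(nrmse(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("nrmse is invariant to common scaling and shifting", {
  set.seed(7)
  for (i in 1:20) {
    o <- rnorm(50); p <- o + rnorm(50, sd = 0.3)
    base <- nrmse(o, p)$nrmse
    c_ <- runif(1, 0.1, 10); d_ <- runif(1, -5, 5)
    expect_equal(nrmse(c_ * o, c_ * p)$nrmse, base, tolerance = 1e-12)
    expect_equal(nrmse(o + d_, p + d_)$nrmse, base, tolerance = 1e-12)
  }
})

test_that("motion_range reproduces the published endpoint arithmetic", {
  expect_equal(unname(motion_range(c(2.7, 12.5))["range"]), 9.8)
  expect_equal(unname(motion_range(c(-2.6, 14))["range"]), 16.6)
  expect_equal(unname(motion_range(rep(4, 5))["range"]), 0)
  expect_error(motion_range(numeric(0)), "empty")
})

test_that("summarize_ranges matches the published means and sample SDs", {
  fd <- c(9.5, 8.9, 7.6, 6.9, 6.6, 8.1, 9.2)
  s <- summarize_ranges(fd)
  expect_equal(round(s[["mean"]], 1), 8.1)
  expect_equal(round(s[["sd"]], 1), 1.1)
  exp_ <- c(12.1, 11.5, 10.2, 11.6, 11.1, 12.3, 11.7)
  s2 <- summarize_ranges(exp_)
  expect_equal(round(s2[["mean"]], 1), 11.5)
  expect_equal(round(s2[["sd"]], 1), 0.7)
  expect_equal(summarize_ranges(c(3, 3, 3))[["sd"]], 0)
  expect_error(summarize_ranges(5), "at least 2")
})

test_that("summarize_ranges agrees with a brute-force two-pass oracle", {
  set.seed(11)
  x <- runif(9, 5, 15)
  mu <- sum(x) / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - mu)^2
  s <- summarize_ranges(x)
  expect_equal(s[["mean"]], mu, tolerance = 1e-12)
  expect_equal(s[["sd"]], sqrt(ss / (length(x) - 1)), tolerance = 1e-12)
})

test_that("rotation envelope: zero width on identical results, grid checks", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 20, step = 10, direction = "ir")
  r <- run_flexion_sweep(m, prot)
  env0 <- rotation_envelope(r, r)
  expect_true(all(env0$width_deg == 0))
  prot_er <- simulation_protocol(flexion_max = 20, step = 10,
                                 direction = "er")
  re <- run_flexion_sweep(m, prot_er)
  env <- rotation_envelope(r, re)
  expect_true(all(env$width_deg > 0))
  bad <- re
  bad$kinematics <- bad$kinematics[1:2, ]
  expect_error(rotation_envelope(r, bad), "grids differ")
})

test_that("comparison report is internally consistent and ranks by IR NRMSE", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 30, step = 10, direction = "ir")
  res <- list()
  for (st in c("INTACT", "ACL_SECTIONED", "ACLR"))
    res[[st]] <- run_flexion_sweep(apply_state(m, st), prot)
  rep <- compare_states(res)
  # report rows reproduce motion_range for every state/DoF cell
  for (i in seq_len(nrow(rep$dof_table))) {
    row <- rep$dof_table[i, ]
    mr <- motion_range(res[[row$state]]$kinematics[[row$dof]])
    expect_equal(c(row$min, row$max, row$range), unname(mr))
  }
  expect_setequal(rep$ranking$state, "ACLR")
  expect_equal(rep$ranking$nrmse_vs_intact_pct[1],
               nrmse(res$INTACT$kinematics$ir_deg,
                     res$ACLR$kinematics$ir_deg)$percent)
  expect_true(all(c("ACLR_ALLR", "ACLR_MAC") %in% rep$missing))
  expect_error(compare_states(res["ACLR"]), "intact")
})

test_that("comparison report serialises to JSON and Markdown", {
  m <- intact_model()
  prot <- simulation_protocol(flexion_max = 20, step = 10, direction = "ir")
  res <- list(INTACT = run_flexion_sweep(m, prot),
              ACLR = run_flexion_sweep(apply_state(m, "ACLR"), prot))
  rep <- compare_states(res)
  jf <- tempfile(fileext = ".json"); mf <- tempfile(fileext = ".md")
  write_comparison_report(rep, jf, mf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(names(parsed$ir_ranges), c("INTACT", "ACLR"))
  md <- readLines(mf)
  expect_true(any(grepl("Ranking of reconstructions", md)))
})
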