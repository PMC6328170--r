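test_that("equal-volume pilot plan dispenses the same quantized volume", {
  ids <- sprintf("L%03d", 1:265)
  plan <- plan_equal_volume(ids, pool_constraints())
  expect_equal(nrow(plan), 265)
  expect_true(all(plan$volume == 500))
  expect_equal(total_volume(plan), 132500)
  expect_false(any(plan$clipped_low | plan$clipped_high))

  single <- plan_equal_volume("only", pool_constraints())
  expect_equal(nrow(single), 1)
  expect_equal(total_volume(single), 500)

  # 510 nL requested with a 25 nL droplet rounds to 500, recording the request
  odd <- plan_equal_volume(
    ids[1:3], pool_constraints(pilot_volume = 510, quantum = 25))
  expect_true(all(odd$volume == 500))
  expect_true(all(odd$quantized_from == 510))

  expect_error(plan_equal_volume(character(0)), "empty")
})

test_that("pilot fractions are read shares summing to one", {
  equal <- compute_fractions(stats::setNames(rep(1000, 265),
                                             sprintf("L%03d", 1:265)))
  expect_equal(sum(equal$per_library), 1)
  expect_equal(unname(equal$per_library[1]), 1 / 265)
  expect_equal(round(mean(equal$per_library) * 100, 3), 0.377)

  two <- compute_fractions(c(A = 10, B = 30))
  expect_equal(unname(two$per_library), c(0.25, 0.75))
  expect_equal(two$assigned_total, 40)

  expect_error(compute_fractions(c(A = 0, B = 0)), "zero")
  expect_error(compute_fractions(c(5, 5)), "named")
})

test_that("equimolar volumes are inverse to fractions, anchored at the minimum", {
  fr <- compute_fractions(c(A = 2, B = 1, C = 1))  # fractions .5/.25/.25
  cons <- pool_constraints(v_min = 160, v_max = 3800, quantum = 1)
  plan <- plan_equimolar(fr, cons)
  vols <- stats::setNames(plan$volume, plan$library_id)
  expect_equal(unname(vols[c("A", "B", "C")]), c(160, 320, 320))
  expect_false(any(plan$clipped_low | plan$clipped_high))

  # uniform fractions collapse to the minimum attainable volume, no flags
  uni <- compute_fractions(stats::setNames(rep(7, 20), sprintf("L%02d", 1:20)))
  plan_u <- plan_equimolar(uni, pool_constraints(v_min = 150, quantum = 25))
  expect_true(all(plan_u$volume == 150))
  expect_false(any(plan_u$clipped_low | plan_u$clipped_high))

  # a zero-fraction library gets the maximum volume, flagged
  fz <- compute_fractions(c(A = 10, B = 10, C = 0))
  plan_z <- plan_equimolar(fz, pool_constraints())
  zrow <- plan_z[plan_z$library_id == "C", ]
  expect_equal(zrow$volume, 3800)
  expect_true(zrow$clipped_high)
})

test_that("fixed-total strategy hits the requested pool volume before clipping", {
  fr <- compute_fractions(c(A = 1, B = 1, C = 2))
  cons <- pool_constraints(v_min = 100, v_max = 5000, quantum = 1)
  plan <- plan_equimolar(fr, cons, strategy = "fixed_total",
                         target_total = 1000)
  expect_equal(sum(plan$quantized_from), 1000)
  expect_equal(total_volume(plan), sum(plan$volume))
  expect_error(plan_equimolar(fr, cons, strategy = "fixed_total"),
               "target_total")
})

test_that("planned volumes respect dispenser constraints for arbitrary fractions", {
  cons <- pool_constraints(v_min = 160, v_max = 3800, quantum = 25)
  for (case in 1:25) {
    n <- withr::with_seed(case, sample(3:300, 1))
    f <- random_fractions(n, seed = 100 + case, cv = 1.0)
    plan <- plan_equimolar(compute_fractions(f * 1e6), cons)
    # range and droplet-multiple constraints
    expect_true(all(plan$volume >= cons$v_min & plan$volume <= cons$v_max))
    expect_true(all(abs(plan$volume / cons$quantum -
                          round(plan$volume / cons$quantum)) < 1e-9))
    # conservation
    expect_equal(total_volume(plan), sum(plan$volume))
    # monotonicity: larger fraction never gets a larger volume
    v <- plan$volume[match(names(f), plan$library_id)]
    ord <- order(f)
    expect_true(all(diff(v[ord]) <= 0 + 1e-9))
  }
})

test_that("predicted deep-run fractions behave as the algebra dictates", {
  ids <- sprintf("L%03d", 1:50)
  f <- random_fractions(50, seed = 5, cv = 0.3)
  fr <- compute_fractions(stats::setNames(f * 1e6, ids))
  cons <- pool_constraints(quantum = 25)

  # identity: re-dispensing equal volumes reproduces the input fractions
  eq_plan <- plan_equal_volume(ids, cons)
  pred_eq <- predict_fractions(fr, eq_plan, cons)
  expect_equal(pred_eq$per_library, fr$per_library, tolerance = 1e-12)

  # equimolar plan without clipping: uniform within the quantization bound
  plan <- plan_equimolar(fr, cons)
  expect_false(any(plan$clipped_low | plan$clipped_high))
  pred <- predict_fractions(fr, plan, cons)
  expect_equal(sum(pred$per_library), 1, tolerance = 1e-12)
  bound <- length(ids) * cons$quantum / total_volume(plan)
  expect_lt(max(abs(pred$per_library - 1 / length(ids))), bound)

  # hand-computed renormalization with one clipped volume
  fr3 <- compute_fractions(c(A = 80, B = 15, C = 5))
  cons3 <- pool_constraints(v_min = 100, v_max = 400, quantum = 1,
                            pilot_volume = 400)
  plan3 <- plan_equimolar(fr3, cons3)
  v3 <- stats::setNames(plan3$volume, plan3$library_id)
  expect_equal(unname(v3), c(100, 400, 400))  # C clipped at v_max
  expect_true(plan3[plan3$library_id == "C", "clipped_high"])
  contrib <- c(0.80 * 100, 0.15 * 400, 0.05 * 400)
  pred3 <- predict_fractions(fr3, plan3, cons3)
  expect_equal(unname(pred3$per_library[c("A", "B", "C")]),
               contrib / sum(contrib), tolerance = 1e-12)

  expect_error(predict_fractions(fr3, plan, cons), "different library sets")
})

test_that("variance-ratio test reproduces the published tightening", {
  cmp <- compare_variance(list(sd = 0.125, n = 265),
                          list(sd = 0.087, n = 265))
  expect_equal(cmp$f_statistic, 0.125^2 / 0.087^2, tolerance = 1e-12)
  expect_equal(cmp$f_statistic, 2.0645, tolerance = 1e-4)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$df, c(264L, 264L))

  null <- compare_variance(list(sd = 0.3, n = 50), list(sd = 0.3, n = 50))
  expect_equal(null$f_statistic, 1)
  expect_equal(null$p_value, 1)

  expect_error(compare_variance(list(sd = 1, n = 1), list(sd = 1, n = 9)),
               "n >= 2")
  expect_error(compare_variance(c(1, 2, 3), c(5, 5, 5)), "zero variance")
})

test_that("sample-based variance test agrees with independent references", {
  for (s in 1:10) {
    ab <- withr::with_seed(s, list(a = stats::rnorm(30, sd = 1.3),
                                   b = stats::rnorm(45, sd = 0.9)))
    cmp <- compare_variance(ab$a, ab$b)
    # direct distribution-function oracle
    f <- stats::var(ab$a) / stats::var(ab$b)
    p_oracle <- 2 * min(stats::pf(f, 29, 44), 1 - stats::pf(f, 29, 44))
    expect_equal(cmp$f_statistic, f, tolerance = 1e-12)
    expect_equal(cmp$p_value, p_oracle, tolerance = 1e-10)
    # and the standard F test as an independent cross-check
    vt <- stats::var.test(ab$a, ab$b)
    expect_equal(cmp$f_statistic, unname(vt$statistic), tolerance = 1e-12)
    expect_equal(cmp$p_value, vt$p.value, tolerance = 1e-10)
  }
})

test_that("transfer lists are bit-exact instrument input", {
  plan <- plan_equimolar(
    compute_fractions(c(B = 1, A = 1)),
    pool_constraints(v_min = 150, quantum = 25))
  layout <- data.frame(library_id = c("A", "B"),
                       plate = "Plate1", well = c("A1", "B7"))
  lines <- write_transfer_list(plan, layout, destination_well = "D4")
  expect_equal(lines[1],
               "Source Plate Name,Source Well,Destination Well,Transfer Volume")
  expect_equal(lines[2], "Plate1,A1,D4,150")
  expect_equal(lines[3], "Plate1,B7,D4,150")

  # conservation over the 265-library pilot plan
  big <- plan_equal_volume(sprintf("L%03d", 1:265), pool_constraints())
  big_layout <- data.frame(library_id = big$library_id, plate = "P",
                           well = sprintf("W%d", 1:265))
  txt <- write_transfer_list(big, big_layout)
  vols <- as.numeric(vapply(strsplit(txt[-1], ","), `[`, "", 4L))
  expect_equal(sum(vols), 132500)

  # written file has LF endings and round-trips
  path <- withr::local_tempfile(fileext = ".csv")
  write_transfer_list(plan, layout, destination_well = "D4", path = path)
  raw <- readBin(path, "raw", file.size(path))
  expect_false(any(raw == charToRaw("\r")))
  expect_equal(readLines(path), lines)

  expect_error(write_transfer_list(plan, layout[1, , drop = FALSE]),
               "no source well")
})
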