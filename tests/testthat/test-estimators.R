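# Nelson-Aalen, Aalen-Johansen, the Kaplan-Meier components and the CGRFS
# estimators.

test_that("Nelson-Aalen increments match hand counts on the example data", {
  ch <- nelson_aalen(build_counting(toy_table1()))
  expect_equal(cumhaz_entry(ch, 0, 1, 1), 1 / 3)
  expect_equal(cumhaz_entry(ch, 0, 1, 4), 1 / 3 + 1)
  expect_equal(cumhaz_entry(ch, 1, 2, 3), 1)
  # rows of the increment matrices sum to zero
  expect_lt(max(abs(apply(ch$dA, 3, rowSums))), 1e-14)
  # no events: zero matrix function on an empty grid
  solo <- msm_dataset(data.frame(id = 1, from = 0, to = NA, time = 2),
                      model_prog6())
  expect_equal(dim(nelson_aalen(build_counting(solo))$dA), c(6L, 6L, 0L))
})

test_that("Aalen-Johansen transition matrices behave as product integrals", {
  # single path absorbed at t = 2
  solo <- msm_dataset(data.frame(id = 1, from = 0, to = 5, time = 2),
                      model_prog6())
  P <- aalen_johansen(nelson_aalen(build_counting(solo)))
  expect_equal(aje_matrix(P, 1)[1, 1], 1)
  expect_equal(aje_matrix(P, 2)[1, 1], 0)
  expect_equal(aje_matrix(P, 2)[1, 6], 1)

  # example data at t = 3: hand product integral over jumps at 1 and 3
  P <- aalen_johansen(nelson_aalen(build_counting(toy_table1())))
  M <- aje_matrix(P, 3)
  expect_equal(M[1, 1], 2 / 3)
  expect_equal(M[1, 3], 1 / 3)
  expect_equal(M[1, 5], 0)

  # rows sum to one and entries stay in [0, 1] on random data
  for (seed in c(2, 9)) {
    cnt <- build_counting(random_prog6(60, seed = seed))
    P <- aalen_johansen(nelson_aalen(cnt))
    expect_lt(max(abs(apply(P$P, 3, rowSums) - 1)), 1e-12)
    expect_true(all(P$P >= -1e-14 & P$P <= 1 + 1e-14))
  }

  # an off-diagonal increment above one is rejected
  bad <- nelson_aalen(build_counting(toy_table1()))
  bad$dA[1, 2, 1] <- 1.5
  expect_error(aalen_johansen(bad), "increment")
})

test_that("Kaplan-Meier components reproduce the example table", {
  cnt <- build_counting(toy_table1())
  S1 <- km_component(cnt, km_spec(1))
  expect_equal(eval_stepfn(S1, 1), 2 / 3)
  expect_equal(eval_stepfn(S1, 4), 0)
  S3 <- km_component(cnt, km_spec(3))
  expect_equal(eval_stepfn(S3, 3), 0.5)
  expect_equal(eval_stepfn(S3, 7), 0.5)   # constant thereafter
  S2 <- km_component(cnt, km_spec(2))
  expect_equal(eval_stepfn(S2, 6), 0)
  # full table, rounded to two decimals as printed
  comps <- lapply(1:5, function(j) km_component(cnt, km_spec(j)))
  tab <- sapply(comps, function(f) round(eval_stepfn(f, 0:7), 2))
  expected <- cbind(
    S1 = c(1, 0.67, 0.67, 0.67, 0, 0, 0, 0),
    S2 = c(1, 1, 1, 1, 1, 1, 0, 0),
    S3 = c(1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5),
    S4 = c(1, 1, 1, 1, 1, 1, 1, 0),
    S5 = c(1, 1, 1, 1, 1, 1, 1, 0))
  expect_equal(unname(tab), unname(expected))
  # dataset without any component event: curve identically one
  solo <- msm_dataset(data.frame(id = c(1, 1), from = c(0, 1),
                                 to = c(1, NA), time = c(1, 4)),
                      model_prog6())
  S4 <- km_component(build_counting(solo), km_spec(4))
  expect_true(all(S4$values == 1))
})

test_that("the Kaplan-Meier combination can leave the unit interval", {
  f <- cgrfs_km(toy_table1())
  expect_equal(eval_stepfn(f, 0), 1)
  expect_equal(eval_stepfn(f, 3), 7 / 6)
  expect_equal(eval_stepfn(f, 6), -0.5)
  g <- clip_unit(f)
  expect_equal(eval_stepfn(g, 3), 1)
  expect_equal(eval_stepfn(g, 6), 0)
  expect_equal(clip_unit(g), g)                        # idempotent
  h <- step_function(c(1, 2), c(0.4, 0.2), 1)
  expect_equal(clip_unit(h), h)                        # identity inside [0,1]
})

test_that("each KM component equals the product integral of its bilinear hazard", {
  for (seed in 1:20) {
    cnt <- build_counting(random_prog6(15, seed = 100 + seed))
    if (length(cnt$times) == 0L) next
    dA <- nelson_aalen(cnt)$dA
    for (j in 1:5) {
      sp <- km_spec(j)
      YR <- rowSums(cnt$Y[, sp$risk + 1L, drop = FALSE])
      dF <- vapply(seq_along(cnt$times), function(k) {
        u <- if (YR[k] > 0) cnt$Y[k, sp$risk + 1L] / YR[k]
             else numeric(length(sp$risk))
        dAk <- dA[, , k][sp$risk + 1L, sp$targets + 1L, drop = FALSE]
        sum(u * rowSums(dAk))
      }, numeric(1))
      oracle <- cumprod(1 - dF)
      expect_equal(km_component(cnt, sp)$values, oracle, tolerance = 1e-12)
    }
  }
})

test_that("KM components agree with survfit on composite first-exit data", {
  skip_if_not_installed("survival")
  # component 1 on the example data plus a larger simulated dataset
  for (ds in list(toy_table1(), random_prog6(120, seed = 55))) {
    ev <- ds$events
    exit <- do.call(rbind, lapply(split(ev, ev$id), function(e) {
      # first time the individual leaves state 0 (risk set of component 1)
      data.frame(time = e$time[1],
                 status = as.integer(!is.na(e$to[1])))
    }))
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = exit)
    S1 <- km_component(build_counting(ds), km_spec(1))
    expect_equal(eval_stepfn(S1, fit$time), fit$surv, tolerance = 1e-12)
  }
})

test_that("all three CGRFS estimators equal the empirical proportion when uncensored", {
  ds <- random_prog6(80, seed = 21, censoring = FALSE)
  km <- cgrfs_km(ds)
  ajp <- cgrfs_aje(ds)
  aji <- cgrfs_aje(map_prog6_to_idm3(ds))
  tt <- c(0, 100, 400, 800, 1500, 3000, 6000)
  emp <- vapply(tt, function(t) occupancy_proportion(ds, c(0, 2, 4), t),
                numeric(1))
  expect_equal(eval_stepfn(km, tt), emp, tolerance = 1e-12)
  expect_equal(eval_stepfn(ajp, tt), emp, tolerance = 1e-12)
  expect_equal(eval_stepfn(aji, tt), emp, tolerance = 1e-12)
})

test_that("in a pure-survival reduction every component is the ordinary Kaplan-Meier", {
  skip_if_not_installed("survival")
  ds <- pure_survival_dataset(100, seed = 4)
  cnt <- build_counting(ds)
  ev <- ds$events
  fit <- survival::survfit(
    survival::Surv(ev$time, !is.na(ev$to)) ~ 1)
  km_ref <- eval_stepfn(step_function(fit$time, fit$surv, 1), cnt$times)
  for (j in 1:5)
    expect_equal(km_component(cnt, km_spec(j))$values, km_ref,
                 tolerance = 1e-12)
  expect_equal(cgrfs_km(ds)$values, km_ref, tolerance = 1e-12)
  expect_equal(cgrfs_aje(ds)$values, km_ref, tolerance = 1e-12)
})

test_that("the Aalen-Johansen CGRFS stays in the unit interval", {
  for (seed in c(5, 6)) {
    ds <- random_prog6(100, seed = seed)
    f <- cgrfs_aje(ds)
    expect_true(all(f$values >= -1e-14 & f$values <= 1 + 1e-14))
  }
  # while the KM combination demonstrably exits it on the example data
  f <- cgrfs_km(toy_table1())
  expect_gt(max(f$values), 1)
  expect_lt(min(f$values), 0)
})
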