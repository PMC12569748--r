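# Wild bootstrap (multipliers, xi process, Hadamard-derivative
# realizations) and Efron's bootstrap.

test_that("one multiplier is drawn per individual jump, reproducibly", {
  cnt <- build_counting(toy_table1())
  G <- draw_multipliers(cnt, B = 1, seed = 3)
  expect_equal(ncol(G), 5L)                     # five observed transitions
  expect_equal(draw_multipliers(cnt, B = 1, seed = 3), G)
  # mapped illness-death paths: individual 2 contributes two separate
  # 0 -> 1 draws, still five in total
  cnt_idm <- build_counting(map_prog6_to_idm3(toy_table1()))
  expect_equal(ncol(draw_multipliers(cnt_idm, B = 1, seed = 3)), 5L)
  expect_equal(sum(cnt_idm$jumps$from == 0 & cnt_idm$jumps$to == 1 &
                     cnt_idm$jumps$id == "2"), 2L)
})

test_that("the xi process follows its closed form", {
  cnt <- build_counting(toy_table1())
  # all multipliers zero: xi vanishes
  xi0 <- xi_process(cnt, rep(0, 5))
  expect_true(all(xi0$dA == 0))
  # a single 0->5 jump with everyone at risk: xi_05 = G / sqrt(n)
  n <- 8
  ds <- msm_dataset(data.frame(id = 1:n, from = 0L,
                               to = c(5L, rep(NA_integer_, n - 1)),
                               time = c(1, rep(2, n - 1))), model_prog6())
  cs <- build_counting(ds)
  xi <- xi_process(cs, 1.7)
  expect_equal(xi$A[1, 6, 1], 1.7 / sqrt(n))
  # rows sum to zero at every time, jumps only at observed transition times
  cnt2 <- build_counting(random_prog6(50, seed = 8))
  xi2 <- xi_process(cnt2, draw_multipliers(cnt2, seed = 1)[1, ])
  expect_lt(max(abs(apply(xi2$dA, 3, rowSums))), 1e-12)
  expect_equal(xi2$times, cnt2$times)
})

test_that("the Monte Carlo variance of xi matches the closed form", {
  cnt <- build_counting(random_prog6(40, seed = 19))
  t0 <- stats::median(cnt$times)
  B <- 4000
  G <- draw_multipliers(cnt, B = B, seed = 77)
  # xi_01(t0) is linear in the multipliers of 0->1 jumps at or before t0
  sel <- cnt$jumps$from == 0 & cnt$jumps$to == 1 & cnt$jumps$time <= t0
  vals <- G[, sel, drop = FALSE] %*%
    (sqrt(cnt$n) / cnt$jumps$Yfrom[sel])
  theo <- cnt$n * sum(1 / cnt$jumps$Yfrom[sel]^2)
  expect_gt(sum(sel), 3)
  expect_lt(abs(stats::var(as.numeric(vals)) / theo - 1), 0.1)
  # and the linear form is exactly xi_01(t0) for one draw
  xi <- xi_process(cnt, G[1, ])
  k <- findInterval(t0, cnt$times)
  expect_equal(xi$A[1, 2, k], as.numeric(vals[1]), tolerance = 1e-12)
})

test_that("wild KM realizations collapse to the classical form under pure survival", {
  ds <- pure_survival_dataset(150, seed = 9)
  cnt <- build_counting(ds)
  # all multipliers zero: realization identically zero
  z <- wild_km_realization(cnt, xi_process(cnt, rep(0, nrow(cnt$jumps))))
  expect_true(all(z$values == 0))
  # per draw: B(t) = -S(t) * xi_05(t) exactly
  S <- cgrfs_km(cnt)
  for (b in 1:3) {
    G <- draw_multipliers(cnt, seed = 40 + b)[1, ]
    xi <- xi_process(cnt, G)
    r <- wild_km_realization(cnt, xi)
    xi05 <- vapply(seq_along(cnt$times), function(k) xi$A[1, 6, k],
                   numeric(1))
    expect_equal(r$values, -S$values * xi05, tolerance = 1e-12)
  }
})

test_that("wild KM realizations are linear in the multipliers with enumerable coefficients", {
  cnt <- build_counting(toy_table1())
  E <- nrow(cnt$jumps)
  # coefficient of each jump obtained by feeding unit multiplier vectors
  unit_real <- sapply(seq_len(E), function(e) {
    g <- rep(0, E); g[e] <- 1
    wild_km_realization(cnt, xi_process(cnt, g))$values
  })                                            # m x E
  g1 <- rnorm(E); g2 <- rnorm(E)
  r1 <- wild_km_realization(cnt, xi_process(cnt, g1))$values
  r2 <- wild_km_realization(cnt, xi_process(cnt, g2))$values
  r12 <- wild_km_realization(cnt, xi_process(cnt, g1 + g2))$values
  expect_equal(r12, r1 + r2, tolerance = 1e-12)
  expect_equal(r1, as.numeric(unit_real %*% g1), tolerance = 1e-12)
  # the ensemble fast path realizes exactly G %*% W with those coefficients
  ens <- bootstrap_ensemble(toy_table1(), "km_comb", "wild", B = 7,
                            seed = 2, details = TRUE)
  G <- attr(ens$real, "multipliers")
  expect_equal(unname(ens$real), unname(G %*% t(unit_real)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("wild Aalen-Johansen realizations have zero row sums and the two-state form", {
  cnt <- build_counting(random_prog6(40, seed = 23))
  xi <- xi_process(cnt, draw_multipliers(cnt, seed = 5)[1, ])
  r <- wild_aje_realization(cnt, xi, full = TRUE)
  D <- attr(r, "D")
  expect_lt(max(abs(apply(D, 3, rowSums))), 1e-10)
  z <- wild_aje_realization(cnt, xi_process(cnt, rep(0, nrow(cnt$jumps))))
  expect_true(all(z$values == 0))

  # two-state pure survival: D_00(t) = -S(t) sum_{s<=t} {S(s-)/S(s)} dxi(s)
  ds <- pure_survival_dataset(60, seed = 10, cens_rate = 0.02)
  cs <- build_counting(ds)
  S <- cgrfs_km(cs)$values
  stopifnot(min(S) > 0)   # no zero survival, ratio well defined
  xi <- xi_process(cs, draw_multipliers(cs, seed = 6)[1, ])
  dxi <- vapply(seq_along(cs$times), function(k) xi$dA[1, 6, k], numeric(1))
  Sm <- c(1, S[-length(S)])
  ref <- -S * cumsum(Sm / S * dxi)
  r <- wild_aje_realization(cs, xi, states = c(0L, 2L, 4L))
  expect_equal(r$values, ref, tolerance = 1e-10)

  # the vectorized coefficient path agrees with the recursion
  cnts <- build_counting(random_prog6(30, seed = 44))
  G <- draw_multipliers(cnts, B = 3, seed = 9)
  W <- cgrfs:::wild_aje_coef(cnts, c(0L, 2L, 4L))
  for (b in 1:3) {
    direct <- wild_aje_realization(cnts, xi_process(cnts, G[b, ]))
    expect_equal(as.numeric(G[b, , drop = FALSE] %*% W), direct$values,
                 tolerance = 1e-10)
  }
})

test_that("Efron resampling copies whole paths with replacement", {
  toy <- toy_table1()
  rs <- efron_resample(toy, seed = 1)
  expect_equal(rs$n, 3L)
  # every resampled path equals one of the three originals
  orig <- lapply(split(toy$events[-1], toy$events$id), function(d)
    `rownames<-`(d, NULL))
  for (d in split(rs$events[-1], rs$events$id)) {
    d <- `rownames<-`(d, NULL)
    expect_true(any(vapply(orig, identical, logical(1), y = d)))
  }
  expect_equal(efron_resample(toy, seed = 1)$events,
               rs$events)
  expect_error(efron_resample(msm_dataset(
    data.frame(id = character(), from = integer(), to = integer(),
               time = numeric()), model_prog6())), "empty")
})

test_that("Efron omission frequency matches the binomial computation", {
  # a fixed individual is left out of a resample with prob (1 - 1/n)^n
  ds <- random_prog6(200, seed = 3)
  target <- ds$events[ds$events$id == ds$events$id[1], "time"]
  set.seed(10)
  omitted <- mean(replicate(300, {
    r <- efron_resample(ds)
    !any(tapply(r$events$time, r$events$id,
                function(tt) identical(tt, target)))
  }))
  expect_lt(abs(omitted - (1 - 1 / 200)^200), 0.09)
})

test_that("bootstrap ensembles are centered and finite", {
  toy <- toy_table1()
  cnt <- build_counting(toy)
  # wild with injected zero multipliers: a single zero realization
  ens0 <- bootstrap_ensemble(toy, "km_comb", "wild", B = 1,
                             multipliers = matrix(0, 1, nrow(cnt$jumps)))
  expect_true(all(ens0$real == 0))
  # Efron smoke contract on the example data
  ense <- bootstrap_ensemble(toy, "km_comb", "efron", B = 25, seed = 4)
  expect_equal(dim(ense$real), c(25L, length(cnt$times)))
  expect_true(all(is.finite(ense$real)))
  # ensemble means tend to zero at the CLT rate
  ens <- bootstrap_ensemble(random_prog6(60, seed = 13), "km_comb", "wild",
                            B = 2000, seed = 21)
  sds <- apply(ens$real, 2, sd)
  ok <- sds > 0
  expect_true(all(abs(colMeans(ens$real))[ok] <= 4 * sds[ok] / sqrt(2000)))
  # invalid requests
  expect_error(bootstrap_ensemble(map_prog6_to_idm3(toy), "km_comb",
                                  "wild", B = 2), "progressive")
  expect_error(bootstrap_ensemble(toy, "km_comb", "wild", B = 0))
})

test_that("wild and Efron variances agree for the Aalen-Johansen estimators", {
  ds <- random_prog6(400, seed = 101)
  for (est in c("aje_prog6", "aje_idm3")) {
    vw <- bootstrap_variance(
      bootstrap_ensemble(ds, est, "wild", B = 600, seed = 1, times = 500))
    ve <- bootstrap_variance(
      bootstrap_ensemble(ds, est, "efron", B = 600, seed = 2, times = 500))
    expect_lt(abs(eval_stepfn(vw, 500) / eval_stepfn(ve, 500) - 1), 0.3)
  }
})
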