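p <- default_parameters()

test_that("metabolic weight and fittest-trait maps hit their closed-form values", {
  # branch values at the thresholds and linear midpoints
  expect_identical(oxygen_weight(p$O_M, p), 1)
  expect_identical(oxygen_weight(p$O_m, p), 0)
  expect_equal(oxygen_weight((p$O_m + p$O_M) / 2, p), 0.5)

  expect_identical(fittest_hypoxia_level(p$O_M, p), 0)
  expect_identical(fittest_hypoxia_level(2 * p$O_M, p), 0)
  expect_identical(fittest_hypoxia_level(p$O_m / 2, p), 1)
  expect_equal(fittest_hypoxia_level(2.191e-7, p), 0.5, tolerance = 1e-3)

  expect_identical(fittest_acidity_level(p$L_m, p), 0)
  expect_identical(fittest_acidity_level(p$L_M, p), 1)
  expect_equal(fittest_acidity_level(4.575e-5, p), 0.5)
})

test_that("weight and trait maps are continuous at the thresholds and complementary", {
  eps <- 1e-20
  for (thr in c(p$O_m, p$O_M)) {
    expect_equal(oxygen_weight(thr - eps, p), oxygen_weight(thr + eps, p),
                 tolerance = 1e-10)
  }
  for (thr in c(p$L_m, p$L_M)) {
    expect_equal(fittest_acidity_level(thr - eps, p),
                 fittest_acidity_level(thr + eps, p), tolerance = 1e-10)
  }
  S <- seq(0, 3 * p$O_M, length.out = 1000)
  expect_equal(1 - oxygen_weight(S, p), fittest_hypoxia_level(S, p))
})

test_that("metabolic rates match hand-evaluated values and stay in range", {
  expect_identical(oxphos_rate(0, p), 0)
  expect_identical(oxphos_rate(p$O_m / 2, p), 0)          # gated off in hypoxia
  expect_equal(oxphos_rate(2.08e-6, p),
               3.65e-7 * 2.08e-6 / (6.4e-9 + 2.08e-6), tolerance = 1e-12)

  expect_identical(glycolysis_rate(p$O_M, 1e-4, p), 0)     # gated off in normoxia
  expect_equal(glycolysis_rate(0, 9e-6, p), 3.42e-7 / 2)   # half-saturation
  expect_equal(glycolysis_rate(0, 1.35e-4, p),
               3.42e-7 * 1.35e-4 / (9e-6 + 1.35e-4), tolerance = 1e-12)

  S <- seq(0, 5e-6, length.out = 1000)
  po <- oxphos_rate(S, p)
  expect_true(all(po >= 0 & po <= p$gamma_o))
  expect_true(all(diff(po) >= 0))
  Sg <- seq(0, 2e-4, length.out = 1000)
  pg <- glycolysis_rate(0, Sg, p)
  expect_true(all(pg >= 0 & pg <= p$gamma_g))
  expect_true(all(diff(pg) >= 0))
  pg_in_So <- glycolysis_rate(S, 1e-4, p)
  expect_true(all(diff(pg_in_So) <= 0))
  expect_true(all(diff(fittest_hypoxia_level(S, p)) <= 0))
  Sl <- seq(0, 1e-4, length.out = 1000)
  expect_true(all(diff(fittest_acidity_level(Sl, p)) >= 0))
})

test_that("selection penalties and crowding death evaluate exactly", {
  # net proliferation: penalty vanishes at the fittest trait
  expect_equal(net_proliferation(2.08e-6, 0, 0, p), oxphos_rate(2.08e-6, p))
  expect_equal(net_proliferation(2.08e-6, 0, 1, p),
               oxphos_rate(2.08e-6, p) - 3.65e-2, tolerance = 1e-12)
  expect_equal(net_proliferation(0, 9e-6, 1, p), 3.42e-7 / 2)

  expect_identical(acid_death(1e-8, 0, p), 0)       # fittest trait, mild acid
  expect_equal(acid_death(1e-8, 1, p), 1e-2)        # full penalty
  expect_equal(acid_death(4.575e-5, 0, p), 2.5e-3)  # eta_l * 0.5^2
  Sl <- seq(0, 2e-4, length.out = 100)
  D <- acid_death(Sl, 0.3, p)
  expect_true(all(D >= 0 & D <= p$eta_l))

  expect_identical(crowding_death(0, p), 0)
  expect_equal(crowding_death(1, p), 2e-10)
  expect_equal(crowding_death(3.65e-7 / 2e-10, p), 3.65e-7)  # balances max oxphos
})

test_that("full landscape assembles and is maximised at the fittest state", {
  expect_equal(fitness(2.08e-6, 0, 1e-8, 0, 0, 0, p), oxphos_rate(2.08e-6, p))
  expect_equal(fitness(2.08e-6, 0, 1e-8, 0, 1, 1, p),
               oxphos_rate(2.08e-6, p) - 3.65e-2 - 1e-2, tolerance = 1e-12)
  # crowding exactly balances proliferation at the fittest trait
  po_pg <- oxphos_rate(1e-7, p) + glycolysis_rate(1e-7, 5e-5, p)
  y1s <- fittest_acidity_level(3e-5, p); y2s <- fittest_hypoxia_level(1e-7, p)
  expect_equal(fitness(1e-7, 5e-5, 3e-5, po_pg / p$kappa, y1s, y2s, p), 0,
               tolerance = 1e-20)

  # argmax over a fine trait grid sits at the node nearest (phi_l, phi_o)
  yg <- seq(0, 1, length.out = 201)
  set.seed(42)
  for (rep in 1:100) {
    So <- runif(1, 0, 3 * p$O_M); Sg <- runif(1, 0, 2e-4)
    Sl <- runif(1, 0, 1.5e-4); rho <- runif(1, 0, 2e3)
    Rg <- outer(yg, yg, function(a, b) fitness(So, Sg, Sl, rho, a, b, p))
    am <- arrayInd(which.max(Rg), dim(Rg))
    expect_identical(am[1], which.min(abs(yg - fittest_acidity_level(Sl, p))))
    expect_identical(am[2], which.min(abs(yg - fittest_hypoxia_level(So, p))))
  }
})
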