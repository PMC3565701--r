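test_that("branch values match their closed forms at preset anchor points", {
  p <- load_preset("fig2a")
  # saturated B1: O at its maximum, P fully repressed by O
  expect_equal(unname(branch_value("B1", 1e12, p)),
               c(5 / 26, 5, 0), tolerance = 1e-9)
  # B2 at S = 5: N = 5 * 5/6, P = 5 / (1 + (N / 0.9)^2)
  N <- 5 * 5 / 6
  expect_equal(unname(branch_value("B2", 5, p)),
               c(5 / (1 + (N / 0.9)^2), 0, N), tolerance = 1e-12)
  # zero drive: every preset rests at (P_max, 0, 0) on B1
  for (nm in c("fig2a", "fig2b", "fig3a", "fig3b")) {
    q <- load_preset(nm)
    expect_equal(unname(branch_value("B1", 0, q)),
                 c(unname(param_maxima(q))[1], 0, 0))
  }
  expect_error(branch_value("B4", 1, p), "unknown")
})

test_that("every existing branch is an exact zero of the right-hand side", {
  pool <- valid_pool()
  set.seed(31)
  checked <- 0
  for (p in pool) {
    for (d in runif(12, 0.01, 0.99)) {
      S <- s_from_drive(d)
      for (lab in c("B1", "B2", "B3")) {
        if (branch_exists(lab, S, p)) {
          res <- max(abs(circuit_rhs(branch_value(lab, S, p), S, p)))
          expect_lt(res, 1e-10)
          checked <- checked + 1
        }
      }
    }
  }
  expect_gt(checked, 300)
})

test_that("branch existence matches the preset worked examples", {
  p <- load_preset("fig2a")
  expect_true(branch_exists("B1", 1, p))   # O = 2.5 below the loss point
  expect_false(branch_exists("B1", 2, p))  # O = 10/3 beyond it
  expect_true(branch_exists("B2", 5, p))
})

test_that("B2 and B3 never coexist, and B2 persists once attained", {
  pool <- valid_pool()
  set.seed(41)
  for (p in pool) {
    d <- sort(runif(40, 0.01, 0.99))
    S <- s_from_drive(d)
    e2 <- vapply(S, branch_exists, logical(1), label = "B2", params = p)
    e3 <- vapply(S, branch_exists, logical(1), label = "B3", params = p)
    expect_false(any(e2 & e3))
    if (any(e2)) expect_true(all(e2[min(which(e2)):length(e2)]))
  }
})

test_that("validity conditions pass for presets and fail for weak constitutive production", {
  expect_true(attr(validity_conditions(load_preset("fig2a")), "valid"))
  expect_true(attr(validity_conditions(load_preset("fig3b")), "valid"))
  weak <- circuit_params(alpha = 0.4, P_crit1 = 0.5)
  v <- validity_conditions(weak)
  expect_false(v$pass[v$id == "n_silent_at_zero"])
  expect_false(attr(v, "valid"))
})

test_that("routes and transition points match the closed-form analysis", {
  expect_equal(classify_route(load_preset("fig2a")), "route1")
  expect_equal(classify_route(load_preset("fig2b")), "route1")
  expect_equal(classify_route(load_preset("fig3a")), "route2")
  p3b <- load_preset("fig3b")
  expect_equal(classify_route(p3b), "route2")
  # B1 is lost where O reaches O_crit (P_max/P_crit1 - 1)^(1/h2) = sqrt(2)
  r <- classify_regime(p3b)
  expect_equal(r$transitions$S[r$transitions$event == "B1_lost"],
               s_from_drive(sqrt(2) / 5), tolerance = 1e-9)
  expect_equal(classify_route(circuit_params(alpha = 0.4)), "invalid")
})

test_that("oscillation gaps and bistable overlaps match the worked intervals", {
  g2a <- oscillation_gap(load_preset("fig2a"))
  expect_false(g2a$gap)
  r2a <- classify_regime(load_preset("fig2a"))
  ov <- r2a$annotations[r2a$annotations$kind == "overlap", ]
  expect_equal(c(ov$S_lo, ov$S_hi), c(27 / 23, 1.5), tolerance = 1e-9)

  g2b <- oscillation_gap(load_preset("fig2b"))
  expect_true(g2b$gap)
  expect_equal(c(g2b$S_lo, g2b$S_hi), c(1.5, 33 / 17), tolerance = 1e-9)

  g3b <- oscillation_gap(load_preset("fig3b"))
  expect_true(g3b$gap)
  expect_equal(c(g3b$S_lo, g3b$S_hi), c(1, 1 + sqrt(2)), tolerance = 1e-9)

  expect_false(oscillation_gap(load_preset("fig3a"))$gap)
})

test_that("the equal-exponent simplification decides route-1 gaps exactly", {
  # with h1 = h2, a route-1 gap occurs iff N_max/N_crit < O_max/O_crit,
  # i.e. repression of P by O stronger than by N
  pool <- valid_pool()
  for (p in pool) {
    if (classify_route(p) != "route1") next
    m <- param_maxima(p)
    simplified <- m[["N_max"]] / p$N_crit < m[["O_max"]] / p$O_crit
    expect_identical(oscillation_gap(p)$gap, unname(simplified))
  }
})

test_that("route-2 gaps follow the P-gate inequality", {
  pool <- valid_pool()
  for (p in pool) {
    if (classify_route(p) != "route2") next
    m <- param_maxima(p)
    gate <- m[["P_max"]] / p$P_crit1 > 1 + (p$N_crit1 / p$N_crit)^p$h1
    expect_identical(oscillation_gap(p)$gap, unname(gate))
  }
})

test_that("regime labels pair route and gap as documented", {
  expect_equal(classify_regime(load_preset("fig2a"))$possibility, 1L)
  expect_equal(classify_regime(load_preset("fig2b"))$possibility, 3L)
  expect_equal(classify_regime(load_preset("fig3a"))$possibility, 2L)
  expect_equal(classify_regime(load_preset("fig3b"))$possibility, 4L)
  for (p in valid_pool()) {
    r <- classify_regime(p)
    expect_identical(r$possibility %in% c(1L, 3L), r$route == "route1")
    expect_identical(r$possibility %in% c(3L, 4L),
                     any(r$annotations$kind == "gap"))
  }
})

test_that("removing the O-on-N repression never changes the regime", {
  for (p in valid_pool()) {
    reduced <- modify_params(p, O_crit1 = 1e9)
    expect_identical(classify_regime(reduced)$possibility,
                     classify_regime(p)$possibility)
    expect_identical(classify_route(reduced), classify_route(p))
  }
})

test_that("branches are stable nodes: Jacobian eigenvalues are the decay rates", {
  pool <- valid_pool()
  set.seed(51)
  for (p in pool[1:8]) {
    for (lab in c("B1", "B2", "B3")) {
      ds <- drives_where_exists(lab, p)
      if (length(ds) < 3) next
      d <- ds[ceiling(length(ds) / 2)]   # interior of the existence range
      S <- s_from_drive(d)
      y0 <- branch_value(lab, S, p)
      # finite-difference Jacobian of the smooth piece around the branch;
      # one-sided at coordinates sitting on the zero boundary
      h <- 1e-6
      J <- matrix(0, 3, 3)
      for (j in 1:3) {
        e <- numeric(3); e[j] <- h
        J[, j] <- if (y0[j] < h) {
          (circuit_rhs(y0 + e, S, p) - circuit_rhs(y0, S, p)) / h
        } else {
          (circuit_rhs(y0 + e, S, p) - circuit_rhs(y0 - e, S, p)) / (2 * h)
        }
      }
      ev <- sort(Re(eigen(J, only.values = TRUE)$values))
      expect_equal(ev, sort(-c(p$k1, p$k2, p$k3)), tolerance = 1e-5)
    }
  }
})

test_that("regime reports flatten to a serializable table", {
  tab <- as.data.frame(classify_regime(load_preset("fig3b")))
  expect_true(all(c("route", "possibility", "event", "S_lo") %in% names(tab)))
  expect_true(any(tab$event == "gap"))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$S_lo, tab$S_lo, tolerance = 1e-12)
  unlink(f)
})
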