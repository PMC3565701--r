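test_that("gradient profiles are monotone and reject bad specifications", {
  g <- gradient_profile(50, S_max = 10, S_min = 0.01)
  expect_equal(nrow(g), 50)
  expect_true(all(diff(g$S) < 0))
  expect_equal(g$S[1], 10)
  expect_equal(g$S[50], 0.01, tolerance = 1e-12)
  gl <- gradient_profile(10, type = "linear", S_max = 4, S_min = 1)
  expect_equal(gl$S, seq(4, 1, length.out = 10))
  expect_error(gradient_profile(1), "2 cells")
  expect_error(gradient_profile(10, S_min = 20, S_max = 10), "S_min")
  bad <- data.frame(cell = 0:2, x = 0:2, S = c(1, 3, 2))
  expect_error(simulate_gradient(load_preset("fig2a"), bad), "monotone")
})

test_that("the switch preset patterns a gradient into three ordered domains", {
  pat <- label_domains(simulate_gradient(load_preset("fig2a")))
  expect_equal(attr(pat, "n_stripes"), 3L)
  expect_equal(attr(pat, "n_gene_domains"), 3L)
  expect_equal(rle(pat$label)$values, c("N", "O", "P"))  # high-S end first
  # boundary positions match the analytic transition signals within one cell
  b <- attr(pat, "boundaries")
  no_b <- b[b$from == "N", ]
  cells <- pat$S
  spacing <- abs(diff(log(cells[1:2])))
  expect_lt(abs(log(no_b$S_mid) - log(1.5)), 1.5 * spacing)
  # O/P boundary: the crossover of O and P along B1
  p <- load_preset("fig2a")
  cross <- stats::uniroot(function(S) {
    v <- branch_value("B1", S, p); v[["O"]] - v[["P"]]
  }, c(0.05, 2))$root
  op_b <- b[b$from == "O", ]
  expect_lt(abs(log(op_b$S_mid) - log(cross)), 1.5 * spacing)
})

test_that("the oscillatory preset shows an oscillating band between N and P domains", {
  pat <- label_domains(simulate_gradient(load_preset("fig2b"), t_end = 150))
  labs <- rle(pat$label)$values
  expect_true("oscillatory" %in% labs)
  expect_lt(which(labs == "N")[1], which(labs == "oscillatory")[1])
  expect_gt(which(labs == "P")[1], which(labs == "oscillatory")[1])
})

test_that("two- and four-gene canonical circuits give two and four stripes", {
  pat2 <- label_domains(simulate_gradient(multigene_circuit(2), t_end = 60))
  expect_equal(attr(pat2, "n_stripes"), 2L)
  expect_equal(rle(pat2$label)$values, c("O", "P"))

  pat4 <- label_domains(simulate_gradient(
    multigene_circuit(4), gradient_profile(80, S_max = 20, S_min = 0.01),
    t_end = 120))
  expect_equal(attr(pat4, "n_stripes"), 4L)
  expect_equal(rle(pat4$label)$values, c("Q", "N", "O", "P"))
})

test_that("a zero-signal field is a single constitutive domain", {
  flat <- data.frame(cell = 0:9, x = 0:9, S = rep(0, 10))
  pat <- label_domains(simulate_gradient(load_preset("fig2a"), flat,
                                         t_end = 30))
  expect_equal(attr(pat, "n_stripes"), 1L)
  expect_true(all(pat$label == "P"))
})

test_that("domain order along the signal axis is always P, middle, N", {
  pool <- valid_pool()
  grad <- gradient_profile(25, S_max = 20, S_min = 0.02)
  for (p in pool[1:8]) {
    # precondition: once the O-silent state is entered, N dominates P on the
    # normalized scale (guaranteed for increasing signal by monotonicity);
    # otherwise a residual constitutive domain legitimately caps the pattern
    r <- classify_regime(p)
    d2 <- max(r$transitions$d)
    v2 <- branch_value("B2", s_from_drive(min(d2 * 1.01, 0.99)), p)
    m <- param_maxima(p)
    if (v2[["N"]] / m[["N_max"]] < v2[["P"]] / m[["P_max"]]) next
    circ <- multigene_circuit(3, params = p)
    pat <- label_domains(simulate_gradient(circ, grad, t_end = 60,
                                           rtol = 1e-7, atol = 1e-9))
    labs <- rle(pat$label)$values
    # from the high-signal end: N first, P last, singles never out of order
    expect_equal(labs[length(labs)], "P")
    expect_false("P" %in% labs[-length(labs)])
    if ("N" %in% labs) expect_equal(which(labs == "N"), 1L)
    if ("O" %in% labs)
      expect_true(all(which(labs == "O") > max(0, which(labs == "N"))))
  }
})

test_that("topology comparison is deterministic and the symmetric circuit caps at two gene domains", {
  a <- compare_topologies(n_draws = 4, seed = 9,
                          gradient = gradient_profile(15, S_max = 20,
                                                      S_min = 0.05))
  b <- compare_topologies(n_draws = 4, seed = 9,
                          gradient = gradient_profile(15, S_max = 20,
                                                      S_min = 0.05))
  expect_identical(a, b)
  s7 <- a[a$topology == "fig7bi", ]
  expect_true(all(s7$n_gene_domains <= 2))
  acdc <- a[a$topology == "acdc", ]
  expect_true(all(acdc$n_gene_domains <= 3))
  # draws without a gap whose transitions all fall inside the gradient and
  # whose O domain exists (O exceeds P before B1 is lost) must show all three
  draws <- sample_parameters(4, seed = 9)
  for (i in seq_along(draws)) {
    p <- draws[[i]]
    r <- classify_regime(p)
    if (r$possibility %in% c(3, 4)) next
    m <- param_maxima(p)
    d1 <- r$transitions$d[r$transitions$event == "B1_lost"]
    d2 <- max(r$transitions$d)
    v2 <- branch_value("B2", s_from_drive(min(d2 * 1.01, 0.99)), p)
    lowS <- branch_value("B1", 0.05, p)
    inside <- all(r$transitions$d < 0.9) &&
      d1 > p$P_crit1 / m[["P_max"]] &&                        # O domain exists
      v2[["N"]] / m[["N_max"]] > v2[["P"]] / m[["P_max"]] &&  # N domain exists
      lowS[["P"]] / m[["P_max"]] > lowS[["O"]] / m[["O_max"]] # P domain exists
    if (inside)
      expect_equal(acdc$n_gene_domains[acdc$draw == i], 3L)
  }
})
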