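toy <- nested_table(array(c(1, 5, 3, 7), dim = c(2, 1, 2)))

test_that("the two-clone toy design reproduces the hand-computed partition", {
  ss <- nested_ss(toy)
  expect_equal(ss$ssa, 16)
  expect_equal(ss$ss_b_a, 0)
  expect_equal(ss$ss_c_b, 4)
  expect_equal(ss$sst, 20)
  expect_equal(particle_H2(ss)$h2, 0.8)
  expect_equal(collective_H2(ss)$h2, 1.0)  # b = 1: no within-clone term
  expect_equal(heritability_ratio(ss), 1.25)

  z <- matrix(c(2, 6), nrow = 2)  # within-collective means
  css <- collective_ss(z)
  expect_equal(css$ss_alpha, 8)
  expect_equal(css$ss_beta_alpha, 0)
  expect_equal(collective_H2(css)$h2, 1.0)
})

test_that("nested_ss agrees with a brute-force deviation-sum oracle", {
  set.seed(42)
  for (rep in 1:25) {
    a <- sample(2:4, 1); b <- sample(1:4, 1); c_ <- sample(2:4, 1)
    y <- array(rnorm(a * b * c_, 5, 2), dim = c(a, b, c_))
    ss <- nested_ss(nested_table(y))
    oracle <- brute_nested_ss(y)
    expect_equal(ss$ssa, oracle$ssa)
    expect_equal(ss$ss_b_a, oracle$ss_b_a)
    expect_equal(ss$ss_c_b, oracle$ss_c_b)
    # additivity: partition reconstructs the naive total exactly
    expect_equal(ss$sst, oracle$sst)
    expect_equal(ss$ssa + ss$ss_b_a + ss$ss_c_b, ss$sst)
  }
})

test_that("identical phenotypes give a null partition and undefined estimates", {
  flat <- nested_table(array(2.5, dim = c(3, 2, 4)))
  ss <- nested_ss(flat)
  expect_equal(ss$ssa, 0)
  expect_equal(ss$ss_b_a, 0)
  expect_equal(ss$ss_c_b, 0)
  expect_error(particle_H2(ss), "undefined")
  expect_error(heritability_ratio(ss), "undefined")
  expect_error(collective_ss(matrix(NA_real_, 2, 2)), "finite")
})

test_that("collective-level SS from within-collective means matches the particle shortcut", {
  set.seed(7)
  for (rep in 1:10) {
    a <- sample(2:5, 1); b <- sample(2:4, 1); c_ <- sample(2:5, 1)
    tab <- simulate_nested_table(a, b, c_, 1, 0.5, 2)
    ss <- nested_ss(tab)
    z <- apply(tab$y, c(1, 2), mean)
    css <- collective_ss(z)
    # common scale factor 1/c between the two levels
    expect_equal(css$ss_alpha, ss$ssa / c_)
    expect_equal(css$ss_beta_alpha, ss$ss_b_a / c_)
    # the scale cancels from the heritability
    expect_equal(collective_H2(css)$h2, collective_H2(ss)$h2)
    # ratio identity: H_z2 / H_y2 computed from the two estimates equals
    # the sums-of-squares ratio formula
    expect_equal(collective_H2(css)$h2 / particle_H2(ss)$h2,
                 heritability_ratio(ss))
  }
})

test_that("any linear collective trait gives the same heritability and ratio", {
  set.seed(8)
  tab <- simulate_nested_table(5, 4, 6, 1, 0.3, 1.5)
  ss <- nested_ss(tab)
  z_mean <- apply(tab$y, c(1, 2), mean)
  h_ref <- collective_H2(collective_ss(z_mean))$h2
  for (p in c(-2, 0.5, 6)) {
    for (q in c(-1, 0, 10)) {
      z_lin <- p * apply(tab$y, c(1, 2), sum) + q
      expect_equal(collective_H2(collective_ss(z_lin))$h2, h_ref)
    }
  }
})

test_that("all estimates are invariant to a common rescaling of phenotypes", {
  set.seed(9)
  tab <- simulate_nested_table(6, 3, 5, 1, 0.5, 2, mean = 4)
  ss <- nested_ss(tab)
  for (k in c(0.2, 3)) {
    ssk <- nested_ss(nested_table(k * tab$y))
    expect_equal(particle_H2(ssk)$h2, particle_H2(ss)$h2)
    expect_equal(collective_H2(ssk)$h2, collective_H2(ss)$h2)
    expect_equal(heritability_ratio(ssk), heritability_ratio(ss))
  }
  pairs <- data.frame(p = rnorm(50, 2), o = rnorm(50, 2))
  expect_equal(po_slope(data.frame(3 * pairs$p, 3 * pairs$o)), po_slope(pairs))
})

test_that("parent-offspring regression matches hand and lm() oracles", {
  expect_equal(po_slope(data.frame(p = 1:3, o = 1:3)), 1)
  expect_equal(po_slope(data.frame(p = 1:3, o = c(5, 5, 5))), 0)
  expect_equal(po_slope(data.frame(p = 1:3, o = c(2, 2.5, 4))), 1)  # Sxy/Sxx = 2/2
  set.seed(10)
  pairs <- data.frame(p = rnorm(200), o = rnorm(200))
  expect_equal(po_slope(pairs), lm_slope(pairs))
  expect_error(po_slope(data.frame(p = c(2, 2, 2), o = 1:3)), "zero variance")
  expect_error(po_slope(data.frame(p = 1, o = 1)), "at least two")
})

test_that("long-format input round-trips and unbalanced designs are rejected", {
  set.seed(11)
  tab <- simulate_nested_table(3, 2, 4, 1, 0.5, 1)
  long <- expand.grid(particle = 1:4, collective = 1:2, clone = 1:3)
  long$value <- as.vector(aperm(tab$y, c(3, 2, 1)))
  tab2 <- nested_table(long[c("clone", "collective", "particle", "value")])
  expect_equal(tab2$y, tab$y)
  tmp <- tempfile(fileext = ".csv")
  write.csv(long, tmp, row.names = FALSE)
  tab3 <- read_nested_csv(tmp)
  expect_equal(nested_ss(tab3)$sst, nested_ss(tab)$sst)
  unlink(tmp)

  expect_error(nested_table(long[-1, c("clone", "collective", "particle", "value")]),
               "unbalanced")
  expect_error(nested_table(data.frame(clone = 1, value = 2)), "columns")
  expect_error(collective_ss(list(c(1, 2), c(1, 2, 3))), "unbalanced")
})

test_that("mean squares recover known variance components on large designs", {
  tab <- simulate_nested_table(200, 20, 5, var_a = 1, var_b = 0.5, var_c = 2,
                               mean = 10, seed = 123)
  ss <- nested_ss(tab)
  a <- tab$a; b <- tab$b; c_ <- tab$c
  msa <- ss$ssa / (a - 1)
  msb <- ss$ss_b_a / (a * (b - 1))
  msc <- ss$ss_c_b / (a * b * (c_ - 1))
  expect_equal(msc, 2, tolerance = 0.05)
  expect_equal((msb - msc) / c_, 0.5, tolerance = 0.1)
  expect_equal((msa - msb) / (b * c_), 1, tolerance = 0.25)
})

test_that("simulation runs convert to balanced nested tables", {
  run <- grow_population(tiny_params(n_genotypes = 3, generations = 3, n_bar = 8))
  tab <- as_nested_table(run)
  expect_equal(c(tab$a, tab$b, tab$c), c(3, 8, 8))
  ids <- run$collectives$id[run$collectives$generation == 3 &
                              run$collectives$genotype_id == 1]
  expect_equal(sort(as.vector(tab$y[1, , ])), sort(unlist(run$cells[ids])))
  run_cv <- grow_population(tiny_params(cv_n = 0.3))
  expect_error(as_nested_table(run_cv), "unbalanced")
})

test_that("relative heritability of a linear trait is exactly 1 without cell noise", {
  # sigma = 0, fixed N: collective volume is N x (a common per-collective value),
  # and both regressions see the same genotype signal
  run <- grow_population(sim_params(sigma = 0, sigma_env = 0.2, n_bar = 8,
                                    generations = 4, n_genotypes = 5, seed = 21))
  rh <- relative_heritability(run, "volume")
  expect_equal(rh$ratio, 1.0, tolerance = 1e-10)
  # fully degenerate population: no parent variance at all
  run0 <- grow_population(sim_params(sigma = 0, sigma_env = 0, n_bar = 8,
                                     generations = 3, n_genotypes = 1, seed = 1))
  expect_error(relative_heritability(run0, "volume"), "zero variance")
})

test_that("the sums-of-squares approximation error behaves as the closed forms say", {
  expect_equal(ss_vs_variance_error(1, 0, 0, 10, 10, 32), 0)
  expect_gt(ss_vs_variance_error(1, 0.5, 2, 2, 2, 32),
            ss_vs_variance_error(1, 0.5, 2, 100, 100, 32))
  expect_error(ss_vs_variance_error(0, 0, 0, 10, 10, 32), "zero")
})
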