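test_that("cell-size draws follow the stated distribution and stay positive", {
  expect_identical(draw_cell_size(1.5, 0), 1.5)
  expect_identical(draw_cell_size(1.5, 0, n = 3), rep(1.5, 3))

  set.seed(1)
  x <- draw_cell_size(1.5, 0.25, n = 1e5)
  expect_equal(mean(x), 1.5, tolerance = 0.005)
  expect_equal(sd(x), 0.25, tolerance = 0.005)

  set.seed(2)
  y <- draw_cell_size(0.1, 0.25, n = 1e4)  # heavy truncation regime
  expect_true(all(y > 0))

  expect_error(draw_cell_size(-1, 0.1), "positive")
  expect_error(draw_cell_size(1, -0.1), "non-negative")
})

test_that("environmental modifiers are centred on 1 and applied multiplicatively", {
  expect_identical(draw_env_modifier(0), 1)
  set.seed(3)
  m <- draw_env_modifier(0.25, n = 1e5)
  expect_equal(mean(m), 1, tolerance = 0.005)
  expect_equal(sd(m), 0.25, tolerance = 0.005)
  expect_true(all(m > 0))
  expect_error(draw_env_modifier(-0.1), "non-negative")

  # one modifier scales every member cell by the same factor
  cells <- c(1, 2)
  mod <- 1.3
  expect_equal((cells * mod) / cells, rep(mod, 2))
})

test_that("cell-count draws have SD = CV * mean, are integer and floored at 1", {
  expect_identical(draw_cell_count(32, 0), 32L)
  set.seed(4)
  n <- draw_cell_count(32, 0.25, n = 1e5)
  expect_true(is.integer(n))
  expect_equal(mean(n), 32, tolerance = 0.1)
  expect_equal(sd(n), 8, tolerance = 0.1)

  set.seed(5)
  expect_true(all(draw_cell_count(2, 1.0, n = 1e4) >= 1L))
  expect_error(draw_cell_count(0.5, 0), ">= 1")
  expect_error(draw_cell_count(32, -0.1), "non-negative")
})

test_that("founders get evenly spaced genetic means and full noise structure", {
  p <- sim_params(n_genotypes = 10, genetic_mean_range = c(1, 2), seed = 1)
  founders <- init_population(p)
  expect_length(founders, 10)
  expect_equal(vapply(founders, `[[`, numeric(1), "genetic_mean"),
               seq(1, 2, length.out = 10))

  p3 <- sim_params(n_genotypes = 3, genetic_mean_range = c(0.5, 1), seed = 1)
  expect_equal(vapply(init_population(p3), `[[`, numeric(1), "genetic_mean"),
               c(0.5, 0.75, 1))

  # degenerate single genotype: lower bound
  p1 <- sim_params(n_genotypes = 1, seed = 1)
  expect_equal(init_population(p1)[[1]]$genetic_mean, 1)

  # founder cells carry an environmental modifier like any later collective
  pz <- sim_params(sigma = 0, sigma_env = 0.25, n_genotypes = 2, seed = 9)
  f <- init_population(pz)[[1]]
  expect_equal(unique(f$cells / f$env_modifier), f$genetic_mean)
})

test_that("collective reproduction doubles, pairs cells, and assigns fresh modifiers", {
  p <- tiny_params(sigma = 0.1, sigma_env = 0.1, n_bar = 32, n_genotypes = 1)
  set.seed(20)
  parent <- init_population(p)[[1]]
  rep1 <- reproduce_collective(parent, p)
  expect_length(rep1$offspring, 2)
  expect_equal(vapply(rep1$offspring, function(o) length(o$cells), integer(1)),
               c(32L, 32L))
  # 2N cell pairs, 2 collective pairs per event
  expect_equal(nrow(rep1$cell_pairs), 64)
  expect_equal(nrow(rep1$collective_pairs), 2)
  expect_equal(rep1$collective_pairs$parent_id, rep(parent$id, 2))
  # every parent cell appears exactly twice among the pair parents
  expect_equal(sort(tabulate(match(rep1$cell_pairs$parent, parent$cells))),
               rep(2L, 32))

  # zero noise: daughters equal the genetic mean exactly
  p0 <- tiny_params(sigma = 0, sigma_env = 0, n_genotypes = 1)
  parent0 <- init_population(p0)[[1]]
  rep0 <- reproduce_collective(parent0, p0)
  for (o in rep0$offspring) expect_true(all(o$cells == parent0$genetic_mean))

  expect_error(reproduce_collective(structure(list(cells = numeric(0)),
                                              class = "collective_record"), p),
               "no cells")
})

test_that("population growth satisfies the event-count identities", {
  p <- tiny_params(sigma = 0.1, n_genotypes = 3, generations = 4, n_bar = 8)
  run <- grow_population(p)
  g <- p$generations
  # per founder: 2^g leaves and 2^g - 1 collective events
  expect_equal(sum(run$collectives$generation == g), 3 * 2^g)
  expect_equal(run$pedigree$n_collective_events, 3 * (2^g - 1))
  # fixed N: cell events = N x collective events, cell pairs = 2 N x events
  expect_equal(run$pedigree$n_cell_events, 8 * 3 * (2^g - 1))
  expect_equal(nrow(run$pedigree$cell_pairs), 2 * 8 * 3 * (2^g - 1))
  expect_equal(nrow(run$pedigree$collective_pairs), 2 * 3 * (2^g - 1))
  # with cv_n = 0 every collective has exactly n_bar cells
  expect_true(all(run$collectives$n_cells == 8))
  expect_true(all(lengths(run$cells) == 8))

  # zero generations: founders only, empty pedigree
  run0 <- grow_population(tiny_params(generations = 0))
  expect_equal(nrow(run0$collectives), 4)
  expect_equal(run0$pedigree$n_collective_events, 0)
  expect_equal(nrow(run0$pedigree$cell_pairs), 0)
})

test_that("genetic means are constant over a run and zero noise is fully heritable", {
  p <- tiny_params(sigma = 0, sigma_env = 0, n_genotypes = 3, generations = 4)
  run <- grow_population(p)
  means <- seq(1, 2, length.out = 3)
  for (i in 1:3) {
    rows <- run$collectives$genotype_id == i
    expect_identical(unique(run$collectives$genetic_mean[rows]), means[i])
    cells_i <- unlist(run$cells[run$collectives$id[rows]])
    expect_true(all(cells_i == means[i]))
  }
})

test_that("within a collective the environmental modifier is one shared constant", {
  p <- tiny_params(sigma = 0, sigma_env = 0.25, n_genotypes = 2, generations = 3)
  run <- grow_population(p)
  for (i in seq_len(nrow(run$collectives))) {
    pre <- run$cells[[i]] / run$collectives$env_modifier[i]
    expect_equal(unique(pre), run$collectives$genetic_mean[i])
  }
})

test_that("a fixed seed reproduces the entire pedigree bit-for-bit", {
  p <- tiny_params(sigma = 0.2, sigma_env = 0.1, cv_n = 0.2, seed = 77L)
  r1 <- grow_population(p)
  r2 <- grow_population(p)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$pedigree$cell_pairs, r2$pedigree$cell_pairs)
  expect_identical(r1$collectives, r2$collectives)
  r3 <- grow_population(tiny_params(sigma = 0.2, sigma_env = 0.1, cv_n = 0.2,
                                    seed = 78L))
  expect_false(identical(r1$cells, r3$cells))
})

test_that("variable cell number keeps counts positive and near the genetic mean", {
  p <- tiny_params(cv_n = 0.25, n_bar = 16, generations = 5, n_genotypes = 2)
  run <- grow_population(p)
  expect_true(all(run$collectives$n_cells >= 1))
  expect_equal(mean(run$collectives$n_cells), 16, tolerance = 0.5)
  expect_identical(run$collectives$n_cells, lengths(run$cells))
})

test_that("long-format export has the documented columns and row counts", {
  p <- tiny_params(generations = 2, n_genotypes = 2, n_bar = 4)
  run <- grow_population(p)
  long <- population_long(run)
  expect_identical(names(long),
                   c("level", "id", "parent_id", "genotype", "generation", "value"))
  expect_equal(sum(long$level == "collective"), nrow(run$collectives))
  expect_equal(sum(long$level == "cell"), sum(run$collectives$n_cells))
  tmp <- tempfile(fileext = ".csv")
  population_long(run, tmp)
  back <- read.csv(tmp)
  expect_equal(nrow(back), nrow(long))
  expect_equal(back$value, long$value)
  unlink(tmp)
})
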