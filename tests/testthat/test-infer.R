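test_that("first approximation applies the copy-number/purity correction", {
  ds <- make_dataset(
    tibble::tibble(
      mutation_id = c("M1", "M2", "M3"),
      biopsy_id = "B1",
      alt_reads = c(30L, 90L, 40L),
      ref_reads = c(70L, 10L, 60L),
      c_obs = c(2, 2, 3)),
    purity = tibble::tibble(biopsy_id = "B1", purity = c(0.8)))
  # purity 0.8: M1 2*0.3*2/(2-0.4); M2 clamps at 1; M3 2*0.4*3/(3-0.4)
  fa <- first_approximation(ds)
  expect_equal(fa$phi_tilde[fa$mutation_id == "M3"], 2.4 / 2.6,
               tolerance = 1e-12)
  ds1 <- make_dataset(tibble::tibble(
    mutation_id = c("M1", "M2"), biopsy_id = "B1",
    alt_reads = c(30L, 90L), ref_reads = c(70L, 10L), c_obs = 2))
  fa1 <- first_approximation(ds1)
  expect_equal(fa1$phi_tilde, c(0.6, 1))  # pure diploid: min(2f, 1)
})

test_that("pure diploid reduction holds across the whole f range", {
  f_grid <- seq(0, 1, by = 0.01)
  n <- length(f_grid)
  ds <- make_dataset(tibble::tibble(
    mutation_id = sprintf("M%03d", seq_len(n)),
    biopsy_id = "B1",
    alt_reads = as.integer(round(1e6 * f_grid)),
    ref_reads = as.integer(1e6 - round(1e6 * f_grid)),
    c_obs = 2))
  fa <- first_approximation(ds)
  expect_equal(fa$phi_tilde, pmin(2 * f_grid, 1), tolerance = 1e-12)
})

test_that("non-positive correction denominators route mutations aside", {
  # c_obs = 0.3 <= 2(1-0.9): tumor DNA absent at the locus
  rows <- tibble::tibble(
    mutation_id = rep(c(sprintf("M%02d", 1:6), "Mbad"), each = 2),
    biopsy_id = rep(c("B1", "B2"), 7),
    alt_reads = 30L, ref_reads = 70L,
    c_obs = c(rep(2, 12), 0.15, 0.15))
  ds <- make_dataset(rows, purity = tibble::tibble(
    biopsy_id = c("B1", "B2"), purity = 0.9))
  fit <- infer_subclones(ds, seed = 1)
  bad <- tidy(fit) %>% dplyr::filter(mutation_id == "Mbad")
  expect_true(is.na(bad$cluster))
  expect_match(bad$reason, "undefined first approximation")
  expect_true(all(!is.na(tidy(fit)$cluster[tidy(fit)$mutation_id != "Mbad"])))
})

test_that("inference requires at least two biopsies", {
  ds <- make_dataset(tibble::tibble(
    mutation_id = sprintf("M%02d", 1:10), biopsy_id = "B1",
    alt_reads = 30L, ref_reads = 70L, c_obs = 2))
  expect_error(infer_subclones(ds), class = "clonefreq_few_biopsies")
})

test_that("noiseless simulations recover the simulated subclones", {
  st <- sim_tumor(n_subclones = 6, n_biopsies = 6, mu = 1, sigma = 0,
                  dup_loss_max = 0, seed = 42)
  fit <- infer_subclones(st$dataset, seed = 1)
  truth_vectors <- unique(round(truth_subclone_phi(st), 10))
  expect_equal(nrow(subclone_phi(fit)), nrow(truth_vectors))
  # refined frequencies close to truth for every assigned mutation
  expect_lt(evaluate_fit(fit, st)$mean_error, 0.02)
})

test_that("inference is deterministic given dataset and seed", {
  st <- sim_tumor(n_subclones = 4, n_biopsies = 4, mu = 2, sigma = 1,
                  seed = 17)
  f1 <- infer_subclones(st$dataset, seed = 7)
  f2 <- infer_subclones(st$dataset, seed = 7)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$frequencies, f2$frequencies)
})

test_that("assigned and unassigned mutations partition the dataset", {
  st <- sim_tumor(n_subclones = 6, n_biopsies = 6, mu = 3, sigma = 3,
                  seed = 23)
  fit <- infer_subclones(st$dataset, seed = 2)
  a <- tidy(fit)
  expect_setequal(a$mutation_id, st$dataset$mutations)
  expect_equal(anyDuplicated(a$mutation_id), 0L)
  est <- mutation_phi(fit)
  expect_setequal(unique(est$mutation_id),
                  a$mutation_id[!is.na(a$cluster)])
  g <- glance(fit)
  expect_equal(g$assigned_fraction,
               mean(!is.na(a$cluster)))
})
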