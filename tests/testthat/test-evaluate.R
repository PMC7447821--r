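test_that("mean L1 error is biopsy-normalized and metric-like", {
  t1 <- rbind(m1 = c(0.5, 0.5)); e1 <- rbind(m1 = c(0.6, 0.4))
  expect_equal(mean_l1_error(t1, e1), 0.1)
  expect_equal(mean_l1_error(t1, t1), 0)
  # constant per-biopsy error e gives mean error e regardless of |S|
  for (S in c(2, 4, 8)) {
    tt <- matrix(0.5, 3, S, dimnames = list(paste0("m", 1:3), NULL))
    ee <- tt + 0.07
    expect_equal(mean_l1_error(tt, ee), 0.07, tolerance = 1e-12)
  }
  # symmetry and empty assigned set
  expect_equal(mean_l1_error(t1, e1), mean_l1_error(e1, t1))
  expect_true(is.na(mean_l1_error(t1, e1, assigned_ids = character(0))))
})

test_that("assigned fraction is the clustered share of all mutations", {
  fake <- function(cl) {
    structure(list(assignments = tibble::tibble(
      mutation_id = sprintf("M%d", seq_along(cl)), cluster = cl)),
      class = "subclone_fit")
  }
  expect_equal(assigned_fraction(fake(c(1, 1, 2, 2))), 1)
  expect_equal(assigned_fraction(fake(c(NA, NA))), 0)
  expect_equal(assigned_fraction(fake(c(rep(1L, 80), rep(NA, 20)))), 0.8)
})

test_that("ancestry error combines false positives and negatives", {
  tp <- tibble::tibble(ancestor = c("a", "a"), descendant = c("b", "c"))
  expect_equal(ancestry_error(tp, tp, universe = 10), 0)
  empty <- tp[0, ]
  expect_equal(ancestry_error(tp, empty, universe = 10), 0.2)
  ip <- tibble::tibble(ancestor = c("b", "c"), descendant = c("d", "d"))
  expect_equal(ancestry_error(tp, ip, universe = 10), 0.4)
  expect_true(is.na(ancestry_error(tp, tp, universe = 0)))
  # character universe restricts both sides
  expect_equal(ancestry_error(tp, empty, universe = c("a", "b")),
               1 / 2)  # only (a,b) evaluable among 2 ordered pairs
})

test_that("instability CV is scale-invariant population sd over mean", {
  expect_equal(instability_cv(rbind(m1 = c(2, 2, 2)))$cv, 0)
  expect_equal(instability_cv(rbind(m1 = c(1, 3)))$cv, 0.5)
  v <- c(0.5, 1.5, 4, 2)
  expect_equal(instability_cv(rbind(m = v))$cv,
               instability_cv(rbind(m = 10 * v))$cv)
  expect_true(is.na(instability_cv(rbind(m = c(0, 0)))$cv))
})

test_that("evaluation ties fits to their own simulation", {
  st <- sim_tumor(n_subclones = 3, n_biopsies = 3, seed = 2,
                  tumor_id = "A")
  st2 <- sim_tumor(n_subclones = 3, n_biopsies = 3, seed = 2,
                   tumor_id = "B")
  fit <- infer_subclones(st$dataset, seed = 1)
  expect_error(evaluate_fit(fit, st2), class = "clonefreq_id_mismatch")
  rep <- evaluate_fit(fit, st)
  expect_true(rep$assigned_fraction >= 0 && rep$assigned_fraction <= 1)
  expect_true(is.na(rep$ancestry_error) ||
                (rep$ancestry_error >= 0 && rep$ancestry_error <= 1))
})

test_that("region subsets are enumerated per size with a cap", {
  st <- sim_tumor(n_subclones = 3, n_biopsies = 5, mu = 1, sigma = 0,
                  dup_loss_max = 0, seed = 19)
  conv <- region_convergence(st$dataset, k_range = c(4, 5), seed = 3)
  expect_equal(sum(conv$k == 4), choose(5, 4))
  expect_equal(sum(conv$k == 5), 1)
  # the full-region subset equals a direct run on all data
  full_fit <- infer_subclones(st$dataset,
                              seed = clonefreq:::derive_seeds(3, 3)[3])
  expect_equal(conv$n_clusters[conv$k == 5],
               nrow(subclone_phi(full_fit)))
  expect_error(region_convergence(st$dataset, k_range = 6),
               class = "clonefreq_range_error")
  capped <- region_convergence(st$dataset, k_range = 3, max_subsets = 4,
                               seed = 3)
  expect_equal(nrow(capped), 4)
})
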