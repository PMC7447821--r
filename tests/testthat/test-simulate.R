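test_that("phylogeny generator respects sizes, tree shape and determinism", {
  ph <- sim_phylogeny(3, c(20, 20), seed = 1)
  expect_equal(nrow(ph$mutations), 60)
  expect_equal(sum(ph$mutations$subclone == "S1"), 20)
  expect_true(is.na(ph$parent["S1"]))
  # every non-root parent precedes its child (acyclic by construction)
  for (k in 2:3) {
    expect_lt(match(ph$parent[[paste0("S", k)]], ph$subclones), k)
  }
  expect_error(sim_phylogeny(1), class = "clonefreq_range_error")
  expect_error(sim_phylogeny(13), class = "clonefreq_range_error")
  expect_error(sim_phylogeny(5, c(5, 10)), class = "clonefreq_range_error")
  expect_identical(sim_phylogeny(8, seed = 7), sim_phylogeny(8, seed = 7))
})

test_that("composition columns are simplexes with bounded contamination", {
  ph <- sim_phylogeny(5, seed = 2)
  rho <- sim_composition(ph, 6, wt_max = 0.10, seed = 3)
  expect_equal(unname(colSums(rho)), rep(1, 6))
  expect_true(all(rho["WT", ] <= 0.10))
  expect_true(all(rho >= 0))
  expect_false(anyDuplicated(t(rho)) > 0)
  rho0 <- sim_composition(ph, 4, wt_max = 0, seed = 3)
  expect_equal(unname(rho0["WT", ]), rep(0, 4))
  expect_identical(sim_composition(ph, 6, seed = 5),
                   sim_composition(ph, 6, seed = 5))
  expect_error(sim_composition(ph, 1), class = "clonefreq_range_error")
})

test_that("copy-number trios follow the truncated normal on [0, cn_max]", {
  tr <- sim_trios(paste0("M", 1:5), c("B1", "B2"), mu = 1, sigma = 0, seed = 1)
  expect_true(all(tr$delta == 1 & tr$delta_w == 1 & tr$delta_m == 1))
  expect_error(sim_trios("M1", "B1", mu = 2, sigma = 0),
               class = "clonefreq_range_error")
  expect_error(sim_trios("M1", "B1", mu = 4, sigma = 1),
               class = "clonefreq_range_error")

  # moment check against the closed-form truncated-normal mean
  set.seed(10)
  draws <- rtrunc_norm(1e5, mu = 3, sigma = 2, lo = 0, hi = 15)
  expect_true(all(draws >= 0 & draws <= 15))
  m_oracle <- trunc_norm_mean(3, 2, 0, 15)
  se <- sqrt(trunc_norm_var(3, 2, 0, 15) / 1e5)
  expect_lt(abs(mean(draws) - m_oracle), 3 * se)
})

test_that("idealized read counts follow the forward model exactly", {
  phi <- matrix(0.5, 1, 2, dimnames = list("M1", c("B1", "B2")))
  trios <- sim_trios("M1", c("B1", "B2"), mu = 1, sigma = 0)
  ds <- sim_reads(phi, trios, purity = c(B1 = 1, B2 = 1),
                  coverage_fn = function(n) rep(1000L, n),
                  dup_loss_max = 0, seed = 1)
  # f* = 0.5/2 = 0.25 at 1000x
  expect_equal(ds$observations$alt_reads, c(250L, 250L))
  expect_equal(ds$observations$ref_reads, c(750L, 750L))
  phi0 <- matrix(0, 1, 2, dimnames = dimnames(phi))
  ds0 <- sim_reads(phi0, trios, purity = c(B1 = 1, B2 = 1),
                   coverage_fn = function(n) rep(100L, n),
                   dup_loss_max = 0, seed = 1)
  expect_true(all(ds0$observations$alt_reads == 0))
})

test_that("simulated tumors are reproducible and internally consistent", {
  a <- sim_tumor(n_subclones = 4, n_biopsies = 4, seed = 9)
  b <- sim_tumor(n_subclones = 4, n_biopsies = 4, seed = 9)
  expect_identical(a$dataset$observations, b$dataset$observations)
  expect_identical(a$phi, b$phi)

  st <- sim_tumor(n_subclones = 5, n_biopsies = 5, mu = 2, sigma = 1,
                  dup_loss_max = 0, seed = 13)
  # purity equals the tumor fraction
  expect_equal(purity <- setNames(st$dataset$purity$purity,
                                  st$dataset$purity$biopsy_id),
               1 - st$composition["WT", names(purity)])
  # emitted c_obs equals the purity-mixed expected total copy number
  obs <- st$dataset$observations
  tr <- st$trios
  key <- paste(tr$mutation_id, tr$biopsy_id)
  obs_key <- paste(obs$mutation_id, obs$biopsy_id)
  tr <- tr[match(obs_key, key), ]
  p <- purity[obs$biopsy_id]
  phi <- st$phi[cbind(obs$mutation_id, obs$biopsy_id)]
  C <- expected_total_copy_number(phi, tr$delta, tr$delta_w, tr$delta_m)
  expect_equal(obs$c_obs, unname(observed_copy_number(C, p)),
               tolerance = 1e-12)
  # truth consistency: recomputed b entries match phi*delta_m within count
  # rounding (half a read each way, scaled by c_obs/p)
  N <- obs$alt_reads + obs$ref_reads
  b <- b_entry(obs$alt_reads / N, obs$c_obs, p)
  bound <- 0.5 / N * obs$c_obs / p + 1e-9
  expect_true(all(abs(b - phi * tr$delta_m) <= bound))
})

test_that("frequencies are inherited monotonically along the phylogeny", {
  st <- sim_tumor(n_subclones = 7, n_biopsies = 6, seed = 31)
  sub_phi <- truth_subclone_phi(st)
  for (child in names(st$phylogeny$parent)) {
    par <- st$phylogeny$parent[[child]]
    if (is.na(par)) next
    expect_true(all(sub_phi[par, ] >= sub_phi[child, ]))
  }
})

test_that("trio instability (CV) increases with sigma on matched seeds", {
  tr1 <- sim_trios(sprintf("M%03d", 1:120), paste0("B", 1:6),
                   mu = 1, sigma = 1, seed = 77)
  tr3 <- sim_trios(sprintf("M%03d", 1:120), paste0("B", 1:6),
                   mu = 1, sigma = 3, seed = 77)
  cv_of <- function(tr) {
    median(instability_cv(dplyr::select(tr, mutation_id,
                                        value = delta_m))$cv, na.rm = TRUE)
  }
  expect_gt(cv_of(tr3), cv_of(tr1))
})

test_that("cohorts expand the config grid reproducibly", {
  cfg <- tibble::tibble(mu = c(1, 1, 2), sigma = c(0, 1, 1),
                        n_subclones = 3, n_biopsies = 3, replicates = 2L)
  co <- sim_cohort(cfg, seed = 5)
  expect_length(co, 6)
  co2 <- sim_cohort(cfg, seed = 5)
  expect_identical(lapply(co, function(s) s$dataset$observations),
                   lapply(co2, function(s) s$dataset$observations))
  sigma0 <- co[[1]]
  expect_true(all(sigma0$trios$delta_m == 1))
})
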