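test_that("dominance classifies strict, crossing and tied vectors", {
  expect_equal(dominance(c(0.9, 0.8), c(0.4, 0.1)), "ancestral")
  expect_equal(dominance(c(0.4, 0.1), c(0.9, 0.8)), "descendant")
  expect_equal(dominance(c(0.6, 0.2), c(0.2, 0.6)), "incomparable")
  expect_equal(dominance(c(0.5, 0.5), c(0.5, 0.5)), "tied")
  expect_equal(dominance(c(0.5, 0.5), c(0.5, 0.5), epsilon = 0.2), "tied")
  expect_error(dominance(c(0.5), c(0.5, 0.5)))
})

test_that("a dominance chain assembles into a linear tree", {
  phi <- rbind(A = c(0.9, 0.9), B = c(0.6, 0.5), C = c(0.2, 0.1))
  tr <- clone_tree(phi, epsilon = 0)
  expect_equal(tr$edges,
               tibble::tibble(parent = c("A", "B", "germline"),
                              child = c("B", "C", "A")) |>
                 dplyr::arrange(parent, child))
})

test_that("incomparable subclones branch from the germline root", {
  phi <- rbind(A = c(0.6, 0.1), B = c(0.1, 0.6))
  tr <- clone_tree(phi, epsilon = 0)
  expect_equal(tr$edges$parent, c("germline", "germline"))
  single <- clone_tree(rbind(A = c(0.5, 0.5)), epsilon = 0)
  expect_equal(single$edges,
               tibble::tibble(parent = "germline", child = "A"))
})

test_that("tied subclones are merged with a warning", {
  phi <- rbind(A = c(0.9, 0.9), B = c(0.9, 0.9), C = c(0.2, 0.2))
  expect_warning(tr <- clone_tree(phi, epsilon = 0.05), "tied")
  expect_equal(nrow(tr$phi), 2)
  expect_setequal(tr$members$A, c("A", "B"))
})

test_that("ancestral pairs expand tree closure to member mutations", {
  phi <- rbind(A = c(0.9, 0.9), B = c(0.6, 0.5), C = c(0.2, 0.1))
  rownames(phi) <- c("C1", "C2", "C3")
  tr <- clone_tree(phi, epsilon = 0)
  asg <- tibble::tibble(mutation_id = sprintf("M%d", 1:6),
                        cluster = rep(1:3, each = 2))
  pairs <- ancestral_pairs(tr, asg)
  # 3 ancestor node pairs x 2 x 2 mutations
  expect_equal(nrow(pairs), 12)
  expect_equal(anyDuplicated(pair_key(pairs)), 0L)
  # single node: no pairs
  single <- clone_tree(rbind(C1 = c(0.5, 0.5)), epsilon = 0)
  expect_equal(nrow(ancestral_pairs(single, asg[1:2, ])), 0)
  # star: siblings are not ancestrally related
  star <- clone_tree(rbind(C1 = c(0.5, 0.05), C2 = c(0.05, 0.5)), epsilon = 0)
  expect_equal(nrow(ancestral_pairs(star, asg[1:4, ])), 0)
})

test_that("tree assembly is invariant to subclone input order", {
  set.seed(3)
  phi <- matrix(runif(12), 4, 3,
                dimnames = list(paste0("C", 1:4), NULL))
  tr1 <- suppressWarnings(clone_tree(phi, epsilon = 0))
  perm <- c(3, 1, 4, 2)
  tr2 <- suppressWarnings(clone_tree(phi[perm, ], epsilon = 0))
  expect_equal(tr1$edges, tr2$edges)
})

test_that("true ancestry is recovered whenever dominance is unambiguous", {
  # the dominance relation always contains the true ancestor relation on
  # exact subtree masses; when it adds no spurious cross-branch pair the
  # assembled tree reproduces the simulated ancestor relation exactly
  seeds <- clonefreq:::derive_seeds(29, 40)
  n_exact <- 0
  for (i in seq_along(seeds)) {
    st <- sim_tumor(n_subclones = 3 + (i %% 5), n_biopsies = 6,
                    seed = seeds[i])
    sub_phi <- truth_subclone_phi(st)
    if (anyDuplicated(round(sub_phi, 10)) > 0) next
    true_pairs <- clonefreq:::phylo_ancestor_pairs(st$phylogeny)
    k <- nrow(sub_phi)
    dom_pairs <- list()
    for (a in 1:k) for (b in 1:k) {
      if (a != b &&
          dominance(sub_phi[a, ], sub_phi[b, ], 0) == "ancestral") {
        dom_pairs[[length(dom_pairs) + 1]] <-
          c(rownames(sub_phi)[a], rownames(sub_phi)[b])
      }
    }
    dom_keys <- vapply(dom_pairs, paste, character(1), collapse = " ")
    # containment always holds
    expect_true(all(pair_key(true_pairs) %in% dom_keys))
    if (setequal(dom_keys, pair_key(true_pairs))) {
      tr <- suppressWarnings(clone_tree(sub_phi, epsilon = 0))
      clos <- clonefreq:::tree_closure(tr)
      expect_setequal(pair_key(clos), pair_key(true_pairs))
      n_exact <- n_exact + 1
    }
  }
  expect_gt(n_exact, 5)  # the unambiguous regime is actually exercised
})

test_that("newick serialization round-trips through an independent parser", {
  skip_if_not_installed("ape")
  phi <- rbind(A = c(0.95, 0.9), B = c(0.6, 0.5), C = c(0.25, 0.1),
               D = c(0.05, 0.3))
  tr <- suppressWarnings(clone_tree(phi, epsilon = 0))
  nwk <- to_newick(tr)
  expect_match(nwk, ";$")
  ph <- ape::read.tree(text = nwk)
  got <- sort(c(ph$tip.label, ph$node.label))
  expect_setequal(setdiff(got, ""), c("germline", rownames(tr$phi)))
})
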