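#' Compare two subclone frequency vectors for ancestral dominance
#'
#' Under the infinite-sites model an ancestor's mutation frequency is at
#' least its descendant's in every biopsy. `phi_i` is called `"ancestral"`
#' to `phi_j` when \eqn{\phi_i^s \ge \phi_j^s - \epsilon} in all biopsies
#' and the total excess \eqn{\sum_s(\phi_i^s - \phi_j^s) > \epsilon};
#' `"descendant"` is the mirror case; `"tied"` when the vectors agree
#' within `epsilon` componentwise; `"incomparable"` when the vectors cross
#' (distinct branches).
#'
#' @param phi_i,phi_j Equal-length frequency vectors in `[0, 1]`.
#' @param epsilon Non-negative tolerance absorbing estimation noise
#'   (default 0).
#' @return One of `"ancestral"`, `"descendant"`, `"tied"`, `"incomparable"`.
#' @examples
#' dominance(c(0.9, 0.8), c(0.4, 0.1)) # "ancestral"
#' @export
dominance <- function(phi_i, phi_j, epsilon = 0) {
  check_that(length(phi_i) == length(phi_j),
             "frequency vectors must have equal length")
  check_that(epsilon >= 0, "epsilon must be non-negative")
  d <- phi_i - phi_j
  if (all(abs(d) <= epsilon)) return("tied")
  if (all(d >= -epsilon) && sum(d) > epsilon) return("ancestral")
  if (all(d <= epsilon) && sum(d) < -epsilon) return("descendant")
  "incomparable"
}

#' Build a clone tree from subclone frequency vectors
#'
#' Computes the pairwise dominance DAG over subclones, takes its transitive
#' reduction, and attaches every subclone to the dominating ancestor with
#' the smallest total frequency excess \eqn{\sum_s(\phi_{parent} -
#' \phi_{child})} (the closest ancestor; equal to the transitive-reduction
#' parent in noiseless chains). Subclones with no dominator become children
#' of the implicit germline root. Mutually-dominant (tied) subclones are
#' merged with a warning. The result is deterministic and invariant to
#' input order.
#'
#' @param x A `subclone_fit` (refined subclone frequencies are used) or a
#'   numeric matrix of frequency vectors (rows = subclones, named).
#' @param epsilon Dominance tolerance (default 0.05 for noisy estimates;
#'   use 0 on exact frequencies).
#' @return A `clone_tree`: list with `edges` tibble (`parent`, `child`;
#'   parent `"germline"` at the root), `phi` (node frequency matrix) and
#'   `members` (named list of merged node composition).
#' @export
clone_tree <- function(x, epsilon = 0.05) {
  phi <- if (inherits(x, "subclone_fit")) subclone_phi(x) else as.matrix(x)
  check_that(nrow(phi) >= 1, "at least one subclone is required",
             class = "clonefreq_no_subclones")
  if (is.null(rownames(phi))) rownames(phi) <- paste0("C", seq_len(nrow(phi)))

  # merge tied nodes (mutual ancestral calls within epsilon)
  n <- nrow(phi)
  group <- seq_len(n)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (dominance(phi[i, ], phi[j, ], epsilon) == "tied") {
        gi <- find(i); gj <- find(j)
        if (gi != gj) {
          group[max(gi, gj)] <- min(gi, gj)
          warn(paste0("merging tied subclones ", rownames(phi)[i], " and ",
                      rownames(phi)[j]))
        }
      }
    }
  }
  reps <- sort(unique(vapply(seq_len(n), find, integer(1))))
  members <- lapply(reps, function(r)
    rownames(phi)[vapply(seq_len(n), find, integer(1)) == r])
  node_phi <- t(vapply(members,
                       function(m) colMeans(phi[m, , drop = FALSE]),
                       numeric(ncol(phi))))
  node_ids <- vapply(members, `[[`, character(1), 1)
  rownames(node_phi) <- node_ids
  names(members) <- node_ids
  k <- length(node_ids)

  # dominance DAG and its transitive reduction
  dom <- matrix(FALSE, k, k, dimnames = list(node_ids, node_ids))
  if (k > 1) {
    for (i in 1:k) for (j in 1:k) {
      if (i != j &&
          dominance(node_phi[i, ], node_phi[j, ], epsilon) == "ancestral") {
        dom[i, j] <- TRUE
      }
    }
  }
  reduced <- dom
  if (k > 2) {
    for (i in 1:k) for (j in 1:k) {
      if (reduced[i, j]) {
        for (v in 1:k) {
          if (v != i && v != j && dom[i, v] && dom[v, j]) {
            reduced[i, j] <- FALSE
            break
          }
        }
      }
    }
  }

  parent <- vapply(seq_len(k), function(j) {
    doms <- which(reduced[, j])
    if (length(doms) == 0) return("germline")
    excess <- vapply(doms, function(i) sum(node_phi[i, ] - node_phi[j, ]),
                     numeric(1))
    node_ids[doms[which.min(excess)]]
  }, character(1))

  structure(
    list(edges = tibble(parent = parent, child = node_ids) %>%
           arrange(.data$parent, .data$child),
         phi = node_phi,
         members = members,
         epsilon = epsilon),
    class = "clone_tree"
  )
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", nrow(x$phi), " subclone(s) + germline root\n",
      sep = "")
  cat(to_newick(x), "\n")
  invisible(x)
}

#' Serialize a clone tree to Newick
#'
#' Labels are subclone ids; branch lengths are omitted (the model provides
#' none). The germline root is the outermost label.
#'
#' @param tree A [clone_tree()].
#' @return Single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree) {
  kids <- split(tree$edges$child, tree$edges$parent)
  rec <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) return(node)
    paste0("(", paste(vapply(sort(ch), rec, character(1)), collapse = ","),
           ")", node)
  }
  paste0(rec("germline"), ";")
}

# transitive closure of tree edges at the subclone level
tree_closure <- function(tree) {
  kids <- split(tree$edges$child, tree$edges$parent)
  out <- list()
  desc <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) return(character(0))
    unlist(c(ch, lapply(ch, desc)), use.names = FALSE)
  }
  for (nd in rownames(tree$phi)) {
    dd <- desc(nd)
    if (length(dd)) out[[nd]] <- tibble(ancestor = nd, descendant = dd)
  }
  if (!length(out)) return(tibble(ancestor = character(),
                                  descendant = character()))
  bind_rows(out)
}

#' Ordered ancestral mutation pairs implied by a clone tree
#'
#' Expands the transitive closure of the tree's subclone edges to ordered
#' (ancestor, descendant) pairs of member mutations. Mutations assigned to
#' the same subclone, and mutations on sibling branches, form no pair.
#'
#' @param tree A [clone_tree()].
#' @param assignments Tibble (`mutation_id`, `cluster`) mapping mutations to
#'   tree nodes, e.g. `fit$assignments` (clusters are matched to node ids
#'   `"C<cluster>"`); if `NULL`, subclone-level pairs are returned.
#' @return Tibble (`ancestor`, `descendant`).
#' @export
ancestral_pairs <- function(tree, assignments = NULL) {
  closure <- tree_closure(tree)
  # tied-merge members all map to their representative node
  rep_of <- unlist(lapply(names(tree$members), function(r)
    setNames(rep(r, length(tree$members[[r]])), tree$members[[r]])))
  if (is.null(assignments)) return(closure)
  asg <- assignments %>% filter(!is.na(.data$cluster)) %>%
    mutate(node = rep_of[paste0("C", .data$cluster)])
  by_node <- split(asg$mutation_id, asg$node)
  rows <- lapply(seq_len(nrow(closure)), function(i) {
    a <- by_node[[closure$ancestor[i]]]
    d <- by_node[[closure$descendant[i]]]
    if (is.null(a) || is.null(d)) return(NULL)
    tidyr::expand_grid(ancestor = a, descendant = d)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(ancestor = character(), descendant = character())
  else out
}
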