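# Independent Fitch parsimony scorer used as the search oracle.
fitch_score <- function(tree, seqs) {
  tr <- ape::reorder.phylo(tree, "postorder")
  labs <- tr$tip.label
  n <- length(labs)
  mats <- lapply(seqs[labs], function(s) strsplit(s, "")[[1]])
  L <- length(mats[[1]])
  total <- 0
  for (site in seq_len(L)) {
    sets <- vector("list", max(tr$edge))
    for (i in seq_len(n)) sets[[i]] <- mats[[i]][site]
    score <- 0
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
      if (is.null(sets[[p]])) {
        sets[[p]] <- sets[[c]]
      } else {
        inter <- intersect(sets[[p]], sets[[c]])
        if (length(inter) > 0L) {
          sets[[p]] <- inter
        } else {
          sets[[p]] <- union(sets[[p]], sets[[c]])
          score <- score + 1
        }
      }
    }
    total <- total + score
  }
  total
}

make_lineage <- function(seqs, germ, mask = NULL) {
  lineage_data(seqs, germ, mask = mask, id = "toy")
}

test_that("three distinct sequences give the unique topology, germline-rooted", {
  germ <- "AAAAAATTT"
  seqs <- c(s1 = "AAAAAATTA", s2 = "AAACAATTT", s3 = "AAACAGTTT")
  tr <- parsimony_topology(make_lineage(seqs, germ), seed = 1)
  expect_setequal(tr$tip.label, c("GERMLINE", names(seqs)))
  # rooted on the germline: the germline tip descends straight from the root
  root <- length(tr$tip.label) + 1L
  g_edge <- tr$edge[tr$edge[, 2] == match("GERMLINE", tr$tip.label), 1]
  expect_identical(as.integer(g_edge), root)
  expect_true(all(tr$edge.length >= 0))
})

test_that("the heuristic search attains the exhaustive parsimony optimum", {
  set.seed(5)
  for (k in 1:5) {
    germ <- random_codon_seq(8)
    # three sequences + germline: three possible unrooted topologies
    mutate <- function(s, n) {
      x <- strsplit(s, "")[[1]]
      i <- sample(length(x), n)
      x[i] <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      paste(x, collapse = "")
    }
    seqs <- c(s1 = mutate(germ, 3), s2 = mutate(germ, 3), s3 = mutate(germ, 4))
    all_seqs <- c(seqs, GERMLINE = germ)
    tr <- parsimony_topology(make_lineage(seqs, germ), seed = k)
    got <- fitch_score(tr, all_seqs)
    topos <- c("(GERMLINE,s1,(s2,s3));", "(GERMLINE,s2,(s1,s3));",
               "(GERMLINE,s3,(s1,s2));")
    best <- min(vapply(topos, function(t) {
      fitch_score(ape::read.tree(text = t), all_seqs)
    }, numeric(1)))
    expect_identical(got, best)
  }
})

test_that("identical sequences collapse to a zero-length star", {
  germ <- "AAATTTCCC"
  seqs <- stats::setNames(rep(germ, 4), paste0("s", 1:4))
  tr <- parsimony_topology(make_lineage(seqs, germ), seed = 1)
  expect_setequal(tr$tip.label, c("GERMLINE", names(seqs)))
  expect_equal(sum(tr$edge.length), 0)
})

test_that("duplicate sequences are re-attached so every tip survives", {
  germ <- random_codon_seq(6)
  s1 <- sub("^...", "CCC", germ)
  s2 <- sub("...$", "GGG", germ)
  seqs <- c(a1 = s1, a2 = s1, b1 = s2, c1 = germ)
  tr <- parsimony_topology(make_lineage(seqs, germ), seed = 2)
  expect_setequal(tr$tip.label, c("GERMLINE", names(seqs)))
  # the duplicate pair sits at zero distance
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["a1", "a2"], 0)
})

test_that("parsimony score is invariant under tip relabeling", {
  set.seed(9)
  germ <- random_codon_seq(10)
  mutate <- function(s, n) {
    x <- strsplit(s, "")[[1]]
    i <- sample(length(x), n)
    x[i] <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    paste(x, collapse = "")
  }
  seqs <- stats::setNames(vapply(c(2, 3, 4, 5), function(n) mutate(germ, n),
                                 character(1)), paste0("s", 1:4))
  tr1 <- parsimony_topology(make_lineage(seqs, germ), seed = 3)
  perm <- rev(seq_along(seqs))
  seqs2 <- stats::setNames(seqs[perm], names(seqs)[perm])
  tr2 <- parsimony_topology(make_lineage(seqs2, germ), seed = 3)
  all_seqs <- c(seqs, GERMLINE = germ)
  expect_identical(fitch_score(tr1, all_seqs), fitch_score(tr2, all_seqs))
})

test_that("GY94 branch refinement matches a dense grid and never hurts logL", {
  set.seed(13)
  germ <- random_codon_seq(20)
  x <- strsplit(germ, "")[[1]]
  i <- sample(length(x), 6)
  x[i] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
  s1 <- paste(x, collapse = "")
  tr <- ape::read.tree(text = "(GERMLINE:0.05,s1:0.05);")
  lin <- lineage_data(c(s1 = s1), germ, tree = tr)
  pars <- model_params(kappa = 2, omega_fwr = 0.5, omega_cdr = 0.5,
                       pi = empirical_codon_freqs(c(s1, germ),
                                                  pseudocount = 0.5))
  ref <- gy94_branch_refine(lin, params = pars)
  t_hat <- sum(ref$edge.length)  # a 2-taxon tree: only the path length is
  # identifiable, split across two pendant edges
  # dense two-stage grid oracle on the path length
  ll_of <- function(t) {
    tr2 <- ape::read.tree(text = sprintf("(GERMLINE:%g,s1:0);", t))
    lineage_loglik(lineage_data(c(s1 = s1), germ, tree = tr2), pars,
                   model = "gy94")
  }
  coarse <- seq(1e-4, 1, by = 1e-3)
  t0 <- coarse[which.max(vapply(coarse, ll_of, numeric(1)))]
  fine <- seq(max(1e-6, t0 - 2e-3), t0 + 2e-3, by = 1e-5)
  t_star <- fine[which.max(vapply(fine, ll_of, numeric(1)))]
  expect_equal(t_hat, t_star, tolerance = 2e-4)
  expect_gte(attr(ref, "loglik"),
             lineage_loglik(lin, pars, model = "gy94") - 1e-9)
})

test_that("refinement drives zero-divergence data to zero length", {
  germ <- random_codon_seq(10)
  tr <- ape::read.tree(text = "(GERMLINE:0.1,(s1:0.2,s2:0.1):0.05);")
  lin <- lineage_data(stats::setNames(c(germ, germ), c("s1", "s2")), germ,
                      tree = tr)
  ref <- gy94_branch_refine(lin, params = model_params(omega_fwr = 0.5,
                                                       omega_cdr = 0.5))
  expect_lt(sum(ref$edge.length), 1e-4)
})

test_that("NNI is not accepted when the start topology is true at high signal", {
  set.seed(17)
  germ <- random_codon_seq(40)
  p <- model_params(kappa = 2, omega_fwr = 0.5, omega_cdr = 0.5)
  true_tr <- ape::read.tree(
    text = "(GERMLINE:0.05,((s1:0.03,s2:0.03):0.25,(s3:0.03,s4:0.03):0.25):0.05);")
  tips <- evolve_hlp19_full_context(germ, true_tr, p, seed = 99)
  lin <- lineage_data(tips, germ, tree = true_tr)
  pars <- model_params(kappa = 2, omega_fwr = 0.5, omega_cdr = 0.5,
                       pi = empirical_codon_freqs(c(tips, germ),
                                                  pseudocount = 0.5))
  ref <- gy94_branch_refine(lin, params = pars, nni = TRUE)
  expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(true_tr)), 0,
               ignore_attr = TRUE)
})

test_that("add_parsimony_trees equips every lineage with a usable tree", {
  cfg <- sim_config(n_lineages = 4, clone_size_law = list(law = "fixed", n = 3),
                    n_codons = 30, seed = 5)
  rp <- generate_repertoire_fixture(cfg)
  for (i in seq_along(rp$lineages)) rp$lineages[[i]]$tree <- NULL
  rp <- add_parsimony_trees(rp, seed = 1)
  ll <- repertoire_loglik(rp, ref_params(), model = "hlp19")
  expect_true(is.finite(as.numeric(ll)))
})
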