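# Fixed lineage-tree topology inference: heuristic maximum parsimony with the
# germline as outgroup, then ML branch-length refinement under GY94 with
# repertoire-shared kappa/omega. This mirrors the two-stage protocol in which
# topologies are estimated under a cheap model and held fixed while the
# SHM-aware model is fitted.

# Nucleotide columns of the non-IGNORED codon sites.
scored_nt_sequences <- function(lineage) {
  mask <- as.character(lineage$mask)
  scored <- which(mask != "IGNORED")
  nt_idx <- as.vector(rbind(3L * scored - 2L, 3L * scored - 1L, 3L * scored))
  seqs <- c(lineage$sequences,
            stats::setNames(lineage$germline, lineage$germline_label))
  vapply(seqs, function(s) {
    paste(strsplit(s, "")[[1]][nt_idx], collapse = "")
  }, character(1))
}

#' Maximum-parsimony lineage topology
#'
#' Heuristic parsimony search (neighbour-joining start, NNI rearrangements)
#' at the nucleotide level over non-IGNORED sites, with the germline included
#' as a taxon and the returned tree rooted on it. Duplicate sequences are
#' collapsed to a single taxon during the search and re-attached as
#' zero-length children afterwards, so every sequence keeps its tip. Initial
#' branch lengths are parsimony change counts divided by the number of
#' scored codon sites (expected substitutions per codon). Ties are broken
#' deterministically under `seed`.
#'
#' @param lineage A [lineage_data()] with at least one sequence.
#' @param seed Integer seed controlling tie-breaking in the heuristic search.
#' @return A rooted `phylo` tree containing all sequence tips plus the
#'   germline tip.
#' @export
parsimony_topology <- function(lineage, seed = 1L) {
  nt <- scored_nt_sequences(lineage)
  glab <- lineage$germline_label
  seq_nt <- nt[names(nt) != glab]
  n_codons <- sum(lineage$mask != "IGNORED")

  # collapse duplicates (germline stays its own taxon)
  groups <- split(names(seq_nt), unname(seq_nt))
  reps <- vapply(groups, `[[`, character(1), 1L)
  rep_nt <- c(stats::setNames(unname(seq_nt[reps]), reps), nt[glab])
  names(rep_nt)[length(rep_nt)] <- glab

  tr <- withr::with_seed(seed, {
    if (length(reps) == 1L) {
      # all sequences identical: star of zero branches below the germline
      d <- nt_hamming(rep_nt[[1]], nt[[glab]]) / n_codons
      ape::read.tree(text = sprintf("(%s:%g,%s:%g);", glab, d / 2,
                                    reps[1], d / 2))
    } else if (length(reps) == 2L) {
      tr0 <- ape::read.tree(text = sprintf("(%s,%s,%s);", glab, reps[1], reps[2]))
      parsimony_lengths(tr0, rep_nt, n_codons)
    } else {
      mat <- do.call(rbind, lapply(rep_nt, function(s) strsplit(s, "")[[1]]))
      pd <- phangorn::phyDat(mat, type = "DNA")
      start <- ape::nj(phangorn::dist.hamming(pd))
      best <- phangorn::optim.parsimony(start, pd, method = "fitch",
                                        rearrangements = "NNI", trace = 0)
      parsimony_lengths(best, rep_nt, n_codons)
    }
  })
  tr <- ape::root(tr, outgroup = glab, resolve.root = TRUE)
  tr <- ape::multi2di(tr, random = FALSE)
  tr$edge.length[is.na(tr$edge.length)] <- 0

  # re-attach collapsed duplicates as zero-length children
  for (g in groups) {
    if (length(g) > 1L) {
      for (extra in g[-1L]) {
        where <- match(g[1L], tr$tip.label)
        tr <- phytools::bind.tip(tr, extra, edge.length = 0, where = where,
                                 position = 0)
      }
    }
  }
  tr
}

nt_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ok <- av %in% NUC & bv %in% NUC
  sum(av[ok] != bv[ok])
}

# ACCTRAN change counts per edge, scaled to substitutions per codon site.
parsimony_lengths <- function(tr, named_seqs, n_codons) {
  mat <- do.call(rbind, lapply(named_seqs, function(s) strsplit(s, "")[[1]]))
  pd <- phangorn::phyDat(mat, type = "DNA")
  tr <- phangorn::acctran(tr, pd)
  tr$edge.length <- tr$edge.length / n_codons
  tr
}

#' ML branch lengths (and optional NNI) under GY94
#'
#' Re-optimizes every branch length of a fixed topology by univariate ML
#' under the GY94 model with repertoire-shared kappa/omega and empirical
#' codon frequencies, sweeping until the log-likelihood improves by less
#' than `tol`. With `nni = TRUE`, nearest-neighbour-interchange candidates
#' are evaluated after each sweep and accepted when they improve the
#' log-likelihood by more than `tol`.
#'
#' @param lineage A [lineage_data()].
#' @param tree Starting tree (defaults to `lineage$tree`).
#' @param params A [model_params()] holding the shared kappa/omega and the
#'   empirical codon frequencies pi.
#' @param nni Also try NNI topology moves.
#' @param tol Acceptance / convergence threshold on the log-likelihood.
#' @param max_sweeps Cap on branch-optimization sweeps.
#' @return The tree with refined branch lengths (and possibly topology),
#'   with the achieved log-likelihood in `attr(, "loglik")`.
#' @export
gy94_branch_refine <- function(lineage, tree = lineage$tree, params,
                               nni = FALSE, tol = 1e-4, max_sweeps = 20L) {
  if (is.null(tree)) stop("no tree to refine", call. = FALSE)
  lineage$tree <- check_lineage_tree(tree, names(lineage$sequences),
                                     lineage$germline_label, lineage$id)
  prep <- prep_lineage(lineage)
  mats <- build_model_matrices(params, "gy94", fwr_weight_of(list(prep)))

  refine_bl <- function(prep, bl) {
    sw <- cpp_branch_sweep(mats$eigF, mats$eigC, prep$cdata, bl, 0L,
                           unname(mats$pi_bar), max_sweeps, 10, 1e-7)
    list(bl = sw$bl, ll = sw$ll)
  }

  res <- refine_bl(prep, prep$plan$bl)
  best_tree <- lineage$tree
  best_tree$edge.length[prep$plan$orig_edge] <- res$bl
  best_ll <- res$ll

  if (nni && length(lineage$sequences) >= 3L) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      nbs <- tryCatch(phangorn::nni(best_tree), error = function(e) NULL)
      if (is.null(nbs)) break
      for (cand in nbs) {
        cand$edge.length[is.na(cand$edge.length)] <- 0.01
        lin2 <- lineage
        lin2$tree <- tryCatch(
          check_lineage_tree(cand, names(lineage$sequences),
                             lineage$germline_label, lineage$id),
          error = function(e) NULL)
        if (is.null(lin2$tree)) next
        p2 <- prep_lineage(lin2)
        r2 <- refine_bl(p2, p2$plan$bl)
        if (r2$ll > best_ll + tol) {
          best_ll <- r2$ll
          best_tree <- lin2$tree
          best_tree$edge.length[p2$plan$orig_edge] <- r2$bl
          improved <- TRUE
          break
        }
      }
    }
  }
  attr(best_tree, "loglik") <- best_ll
  best_tree
}

#' Add parsimony trees to every lineage of a repertoire
#'
#' Convenience wrapper running [parsimony_topology()] over all lineages
#' (stage one of the two-stage protocol).
#'
#' @param rep A [repertoire()].
#' @param seed Integer seed (each lineage uses `seed + its index`).
#' @return The repertoire with trees attached.
#' @export
add_parsimony_trees <- function(rep, seed = 1L) {
  for (i in seq_along(rep$lineages)) {
    rep$lineages[[i]]$tree <- parsimony_topology(rep$lineages[[i]],
                                                 seed = seed + i)
  }
  rep
}
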