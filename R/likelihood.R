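# Per-lineage and repertoire log-likelihoods on germline-rooted trees.
# The germline is the known state of the root (the model is nonreversible and
# nonstationary, so the root is identifiable and carries real information);
# an alternative mode sums root partials against pi, which restores
# comparability with reversible-model conventions for AIC.

`%||%` <- function(a, b) if (is.null(a)) b else a

GERMLINE_LABEL <- "GERMLINE"

#' One clonal lineage: alignment, germline, mask, tree
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (the observed BCR sequences of one clone). All must share the germline's
#'   alignment length, a multiple of 3. Codons containing gaps (`-`, `.`),
#'   ambiguity characters or stops are treated as missing data (partial
#'   likelihood one), never silently dropped.
#' @param germline Aligned germline (unmutated ancestor) sequence.
#' @param mask A [region_mask()] with one label per codon site; defaults to
#'   all-FWR.
#' @param tree Optional `phylo` tree containing every sequence name as a tip
#'   plus a tip labelled `germline_label` for the germline outgroup.
#' @param id Lineage (clone) identifier.
#' @param germline_label Reserved tip label identifying the germline in
#'   `tree` and in Newick files.
#' @return An object of class `bcr_lineage`.
#' @export
lineage_data <- function(sequences, germline, mask = NULL, tree = NULL,
                         id = "lineage", germline_label = GERMLINE_LABEL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("`sequences` must be uniquely named", call. = FALSE)
  }
  sequences <- toupper(unlist(sequences))
  germline <- toupper(germline)
  n <- nchar(germline)
  if (n %% 3 != 0) {
    stop("lineage ", id, ": alignment length ", n, " is not a multiple of 3",
         call. = FALSE)
  }
  bad <- names(sequences)[nchar(sequences) != n]
  if (length(bad) > 0L) {
    stop("lineage ", id, ": sequences with alignment length != germline: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(mask)) mask <- region_mask(rep("FWR", n / 3L))
  if (length(mask) != n / 3L) {
    stop("lineage ", id, ": mask length ", length(mask),
         " != alignment codon length ", n / 3L, call. = FALSE)
  }
  if (!is.null(tree)) tree <- check_lineage_tree(tree, names(sequences),
                                                 germline_label, id)
  structure(list(sequences = sequences, germline = germline,
                 mask = region_mask(mask), tree = tree, id = id,
                 germline_label = germline_label),
            class = "bcr_lineage")
}

check_lineage_tree <- function(tree, seq_names, germline_label, id) {
  if (!inherits(tree, "phylo")) {
    stop("lineage ", id, ": tree must be a phylo object", call. = FALSE)
  }
  tl <- tree$tip.label
  if (!germline_label %in% tl) {
    stop("lineage ", id, ": tree lacks the germline tip '", germline_label,
         "'", call. = FALSE)
  }
  others <- setdiff(tl, germline_label)
  if (!setequal(others, seq_names)) {
    stop("lineage ", id, ": tree/sequence label mismatch (missing from tree: ",
         paste(setdiff(seq_names, others), collapse = ", "),
         "; unknown tips: ", paste(setdiff(others, seq_names), collapse = ", "),
         ")", call. = FALSE)
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (any(tree$edge.length < 0)) {
    stop("lineage ", id, ": negative branch lengths", call. = FALSE)
  }
  tree
}

#' @export
print.bcr_lineage <- function(x, ...) {
  cat(sprintf("<bcr_lineage> %s: %d sequences, %d codon sites (%d CDR, %d ignored)%s\n",
              x$id, length(x$sequences), length(x$mask),
              sum(x$mask == "CDR"), sum(x$mask == "IGNORED"),
              if (is.null(x$tree)) ", no tree" else ", tree present"))
  invisible(x)
}

#' A repertoire: lineages sharing one set of substitution parameters
#'
#' @param lineages List of [lineage_data()] objects (at least one).
#' @return An object of class `bcr_repertoire` (list with element
#'   `lineages`).
#' @export
repertoire <- function(lineages) {
  if (inherits(lineages, "bcr_lineage")) lineages <- list(lineages)
  if (length(lineages) == 0L) stop("repertoire needs at least one lineage",
                                   call. = FALSE)
  ok <- vapply(lineages, inherits, logical(1), what = "bcr_lineage")
  if (!all(ok)) stop("all elements must be bcr_lineage objects", call. = FALSE)
  ids <- vapply(lineages, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids)
    for (i in seq_along(lineages)) lineages[[i]]$id <- ids[i]
  }
  names(lineages) <- ids
  structure(list(lineages = lineages), class = "bcr_repertoire")
}

#' @export
print.bcr_repertoire <- function(x, ...) {
  ns <- vapply(x$lineages, function(l) length(l$sequences), integer(1))
  cat(sprintf("<bcr_repertoire> %d lineages, %d sequences (%d singleton clones)\n",
              length(x$lineages), sum(ns), sum(ns == 1L)))
  invisible(x)
}

# ---- tree plan: reroot at the germline tip, renumber, postorder --------------

plan_tree <- function(tree, germline_label, seq_names) {
  tl <- tree$tip.label
  g <- match(germline_label, tl)
  n_orig_tips <- length(tl)
  ne <- nrow(tree$edge)
  el <- tree$edge.length %||% rep(0, ne)
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (i in seq_len(ne)) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, el[i], i))
    adj[[b]] <- rbind(adj[[b]], c(a, el[i], i))
  }
  Tn <- length(seq_names)
  newid <- rep(NA_integer_, nn)
  for (i in seq_len(n_orig_tips)) {
    if (i != g) newid[i] <- match(tl[i], seq_names) - 1L
  }
  next_int <- Tn
  newid[g] <- next_int
  next_int <- next_int + 1L

  edges <- matrix(0L, ne, 2L)
  bl <- numeric(ne)
  orig_edge <- integer(ne)
  k <- 0L
  # iterative postorder DFS from the germline tip (now the root); internal
  # nodes receive their new ids at expansion (preorder) time so parent ids
  # are always resolved when a child edge is emitted at pop time.
  stack <- list(list(node = g, parent = 0L, len = NA_real_, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- length(stack)
    fr <- stack[[top]]
    if (!fr$expanded) {
      stack[[top]]$expanded <- TRUE
      if (is.na(newid[fr$node])) {
        newid[fr$node] <- next_int
        next_int <- next_int + 1L
      }
      nb <- adj[[fr$node]]
      if (!is.null(nb)) {
        for (j in rev(seq_len(nrow(nb)))) {
          if (nb[j, 1] != fr$parent) {
            stack[[length(stack) + 1L]] <-
              list(node = as.integer(nb[j, 1]), parent = fr$node,
                   len = nb[j, 2], orig = as.integer(nb[j, 3]),
                   expanded = FALSE)
          }
        }
      }
    } else {
      stack[[top]] <- NULL
      if (fr$parent != 0L) {
        k <- k + 1L
        edges[k, ] <- c(newid[fr$parent], newid[fr$node])
        bl[k] <- fr$len
        orig_edge[k] <- fr$orig
      }
    }
  }
  if (k != ne) stop("tree traversal failed (disconnected tree?)", call. = FALSE)
  list(edges = edges, bl = bl, orig_edge = orig_edge, n_nodes = next_int,
       root = newid[g], n_tips = Tn)
}

# ---- data prep ---------------------------------------------------------------

# Encode a lineage for the C++ engine: codon indices at scored (non-IGNORED)
# sites, 0-based; -1 for missing codons. Sites whose germline codon is not a
# sense codon are dropped with a message (the root state must be known).
prep_lineage <- function(lineage) {
  cs <- codon_space()
  mask <- as.character(lineage$mask)
  scored <- which(mask != "IGNORED")
  germ_cod <- codon_strings(lineage$germline)
  germ_idx <- unname(cs$index[germ_cod]) # NA for non-sense
  bad_germ <- scored[is.na(germ_idx[scored])]
  if (length(bad_germ) > 0L) {
    message("lineage ", lineage$id, ": ", length(bad_germ),
            " site(s) with unresolvable germline codon treated as ignored")
    scored <- setdiff(scored, bad_germ)
  }
  if (length(scored) == 0L) {
    stop("lineage ", lineage$id, ": no scorable sites", call. = FALSE)
  }
  S <- length(scored)
  Tn <- length(lineage$sequences)
  tips <- matrix(-1L, Tn, S)
  for (i in seq_len(Tn)) {
    cod <- codon_strings(lineage$sequences[[i]])[scored]
    idx <- unname(cs$index[cod])
    idx[is.na(idx)] <- 0L  # missing -> -1 after 0-base shift
    tips[i, ] <- idx - 1L
  }
  plan <- if (!is.null(lineage$tree)) {
    plan_tree(lineage$tree, lineage$germline_label, names(lineage$sequences))
  }
  list(
    tips = tips,
    germ = as.integer(germ_idx[scored] - 1L),
    maskcode = as.integer(mask[scored] == "CDR"),
    n_fwr = sum(mask[scored] == "FWR"),
    n_cdr = sum(mask[scored] == "CDR"),
    seq_names = names(lineage$sequences),
    plan = plan,
    cdata = if (!is.null(plan)) {
      list(tips = tips, germ = as.integer(germ_idx[scored] - 1L),
           mask = as.integer(mask[scored] == "CDR"),
           edges = plan$edges, n_nodes = plan$n_nodes, root = plan$root)
    }
  )
}

# ---- model build: jointly normalized region matrices -------------------------

# FWR and CDR sites share branch lengths, so the two region matrices must be
# scaled by a single constant (the mask-weighted mean rate); otherwise the
# total-rate contrast induced by omega_cdr/omega_fwr would be absorbed
# silently. Returns eigendecompositions ready for the pruning engine.
build_model_matrices <- function(params, model = c("hlp19", "gy94", "hlp17"),
                                 fwr_weight, pi_bar = NULL, context = NULL) {
  model <- match.arg(model)
  if (is.null(pi_bar)) pi_bar <- params$pi
  pi_bar <- validate_pi(pi_bar)
  use_pi_b <- model %in% c("gy94", "hlp17")
  use_motifs <- model %in% c("hlp17", "hlp19")
  if (use_motifs && is.null(context)) context <- mean_field_context(pi_bar)
  qf <- raw_q(params, "FWR", context, pi_b_factor = use_pi_b,
              use_motifs = use_motifs)
  qc <- raw_q(params, "CDR", context, pi_b_factor = use_pi_b,
              use_motifs = use_motifs)
  norm_pi <- if (model == "gy94") params$pi else pi_bar
  sc <- fwr_weight * mean_rate(qf, norm_pi) +
    (1 - fwr_weight) * mean_rate(qc, norm_pi)
  list(eigF = cpp_eig_q(qf / sc), eigC = cpp_eig_q(qc / sc),
       pi_bar = norm_pi, scale = sc, model = model)
}

fwr_weight_of <- function(preps) {
  nf <- sum(vapply(preps, `[[`, numeric(1), "n_fwr"))
  nc <- sum(vapply(preps, `[[`, numeric(1), "n_cdr"))
  if (nf + nc == 0) 1 else nf / (nf + nc)
}

lineage_ll_engine <- function(prep, mats, bl = NULL, root_mode = 0L) {
  if (is.null(prep$cdata)) stop("lineage has no tree", call. = FALSE)
  cpp_lineage_loglik(mats$eigF, mats$eigC, prep$cdata, bl %||% prep$plan$bl,
                     as.integer(root_mode), unname(mats$pi_bar))
}

#' Log-likelihood of one lineage tree
#'
#' Felsenstein pruning from the tips to the germline root. In the default
#' mode the root's partial likelihood is evaluated at the known germline
#' codon at each site (no frequency multiplication); in `root_mode = "pi"`
#' the germline is attached to the root as a zero-length tip and root
#' partials are summed against the model's codon frequencies — the
#' reversible-model convention, used only to make AIC comparable across
#' models.
#'
#' @param lineage A [lineage_data()] with a tree.
#' @param params A [model_params()].
#' @param model `"hlp19"`, `"gy94"` or `"hlp17"`.
#' @param root_mode `"germline"` (default) or `"pi"`.
#' @param pi_bar Frequencies for normalization/context of the HLP models
#'   (midpoint frequencies; defaults to `params$pi`).
#' @return The log-likelihood (a single number).
#' @export
lineage_loglik <- function(lineage, params, model = c("hlp19", "gy94", "hlp17"),
                           root_mode = c("germline", "pi"), pi_bar = NULL) {
  model <- match.arg(model)
  root_mode <- match.arg(root_mode)
  prep <- prep_lineage(lineage)
  mats <- build_model_matrices(params, model, fwr_weight_of(list(prep)),
                               pi_bar = pi_bar)
  lineage_ll_engine(prep, mats, root_mode = as.integer(root_mode == "pi"))
}

#' Repertoire log-likelihood
#'
#' The repertoire likelihood is the product of the lineage likelihoods with
#' substitution parameters constrained to be identical across lineages
#' (lineages are assumed to mutate independently); this returns its log, the
#' sum of [lineage_loglik()] over lineages under the shared `params`.
#'
#' @param rep A [repertoire()]; every lineage must carry a tree.
#' @inheritParams lineage_loglik
#' @return The repertoire log-likelihood, with attribute `per_lineage`.
#' @export
repertoire_loglik <- function(rep, params,
                              model = c("hlp19", "gy94", "hlp17"),
                              root_mode = c("germline", "pi"), pi_bar = NULL) {
  model <- match.arg(model)
  root_mode <- match.arg(root_mode)
  preps <- lapply(rep$lineages, prep_lineage)
  mats <- build_model_matrices(params, model, fwr_weight_of(preps),
                               pi_bar = pi_bar)
  per <- vapply(seq_along(preps), function(i) {
    ll <- tryCatch(
      lineage_ll_engine(preps[[i]], mats,
                        root_mode = as.integer(root_mode == "pi")),
      error = function(e) {
        stop("lineage ", rep$lineages[[i]]$id, ": ", conditionMessage(e),
             call. = FALSE)
      })
    ll
  }, numeric(1))
  structure(sum(per),
            per_lineage = stats::setNames(per, names(rep$lineages)))
}
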