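# Readers and writers for the standard interchange formats: AIRR
# Rearrangement TSV (sequence/germline alignments grouped by clone), Newick
# lineage trees, per-codon region masks, 5-mer mutability tables and fit
# results as JSON.

AIRR_COLUMNS <- c("sequence_id", "clone_id", "sequence_alignment",
                  "germline_alignment")

#' Read an AIRR Rearrangement TSV into a repertoire
#'
#' Groups rows by `clone_id` into lineages; each clone's germline is taken
#' from its `germline_alignment` (which must be consistent within the
#' clone). IMGT gap characters (`.`) and `-` are both treated as gaps, i.e.
#' the codons containing them become missing data. Trees are not part of the
#' AIRR file; attach them with [attach_trees()] or estimate them with
#' [add_parsimony_trees()].
#'
#' @param path TSV file with at least the columns `sequence_id`, `clone_id`,
#'   `sequence_alignment`, `germline_alignment`.
#' @param mask Optional [region_mask()] applied to every clone (lengths must
#'   match each clone's codon alignment length).
#' @return A [repertoire()].
#' @export
read_airr <- function(path, mask = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(AIRR_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("AIRR file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sequence_id)) {
    dup <- unique(df$sequence_id[duplicated(df$sequence_id)])
    stop("duplicate sequence_id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  lineages <- lapply(split(df, df$clone_id), function(cl) {
    germ <- unique(toupper(cl$germline_alignment))
    if (length(germ) > 1L) {
      warning("clone ", cl$clone_id[1],
              ": inconsistent germline_alignment; using the first")
      germ <- germ[1]
    }
    m <- mask
    if (!is.null(m) && length(m) != nchar(germ) / 3) {
      stop("clone ", cl$clone_id[1], ": mask length ", length(m),
           " does not match alignment codon length ", nchar(germ) / 3,
           call. = FALSE)
    }
    lineage_data(stats::setNames(toupper(cl$sequence_alignment), cl$sequence_id),
                 germline = germ, mask = m, id = cl$clone_id[1])
  })
  repertoire(lineages)
}

#' Write a repertoire as AIRR Rearrangement TSV
#'
#' @param rep A [repertoire()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  rows <- dplyr::bind_rows(lapply(rep$lineages, function(lin) {
    tibble::tibble(sequence_id = names(lin$sequences),
                   clone_id = lin$id,
                   sequence_alignment = unname(lin$sequences),
                   germline_alignment = lin$germline)
  }))
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read / write a per-codon region mask
#'
#' Two-column TSV: `codon_index` (0-based) and `label` (FWR / CDR / IGNORED).
#' CDR3 exclusion is expressed as IGNORED labels.
#'
#' @param path TSV path.
#' @return For the reader, a [region_mask()].
#' @export
read_region_mask <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("codon_index", "label") %in% names(df))) {
    stop("mask file needs columns codon_index and label", call. = FALSE)
  }
  n <- max(df$codon_index) + 1L
  if (!setequal(df$codon_index, 0:(n - 1L))) {
    stop("mask file must cover codon indices 0..", n - 1L, " exactly",
         call. = FALSE)
  }
  region_mask(df$label[order(df$codon_index)])
}

#' @rdname read_region_mask
#' @param mask A [region_mask()].
#' @export
write_region_mask <- function(mask, path) {
  utils::write.table(
    data.frame(codon_index = seq_along(mask) - 1L, label = as.character(mask)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write lineage trees (Newick)
#'
#' One Newick tree per line; the germline node is the tip with the reserved
#' label (default `GERMLINE`). [attach_trees()] matches each tree to the
#' clone whose sequence ids equal the tree's non-germline tip labels, so the
#' file order need not match the repertoire order.
#'
#' @param path Newick file path.
#' @return For the reader, a `multiPhylo` list of trees.
#' @export
read_lineage_trees <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees
}

#' @rdname read_lineage_trees
#' @param rep A [repertoire()] whose lineages carry trees.
#' @export
write_lineage_trees <- function(rep, path) {
  trees <- lapply(rep$lineages, `[[`, "tree")
  has <- !vapply(trees, is.null, logical(1))
  if (!all(has)) {
    warning(sum(!has), " lineage(s) without trees skipped")
  }
  trees <- unname(trees[has])
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Attach trees to a repertoire
#'
#' @param rep A [repertoire()].
#' @param trees `multiPhylo` or list of `phylo`; each tree is matched to the
#'   clone whose sequence ids equal its non-germline tip labels.
#' @param germline_label Reserved germline tip label.
#' @return The repertoire with trees attached; errors if any lineage ends up
#'   without a matching tree.
#' @export
attach_trees <- function(rep, trees, germline_label = GERMLINE_LABEL) {
  key_of <- function(labs) paste(sort(labs), collapse = "\r")
  want <- vapply(rep$lineages, function(l) key_of(names(l$sequences)),
                 character(1))
  have <- vapply(trees, function(tr) {
    key_of(setdiff(tr$tip.label, germline_label))
  }, character(1))
  pos <- match(want, have)
  if (anyNA(pos)) {
    stop("no matching tree for lineage(s): ",
         paste(names(rep$lineages)[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(rep$lineages)) {
    rep$lineages[[i]]$tree <- check_lineage_tree(
      trees[[pos[i]]], names(rep$lineages[[i]]$sequences), germline_label,
      rep$lineages[[i]]$id)
  }
  rep
}

#' Read / write a 5-mer mutability table
#'
#' TSV with columns `fivemer`, `mutability`, `sub_A`, `sub_C`, `sub_G`,
#' `sub_T`. Substitution profiles must sum to 1 across the three replacement
#' bases (the current base's own column is 0).
#'
#' @param path TSV path.
#' @return For the reader, a tibble in the layout of
#'   [synthetic_mutability_table()].
#' @export
read_mutability_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("fivemer", "mutability", "sub_A", "sub_C", "sub_G", "sub_T")
  if (!all(need %in% names(df))) {
    stop("mutability table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  prof_sum <- rowSums(df[, c("sub_A", "sub_C", "sub_G", "sub_T")])
  if (any(abs(prof_sum - 1) > 1e-6)) {
    stop("substitution profiles must sum to 1", call. = FALSE)
  }
  n_full <- sum(grepl("^[ACGT]{5}$", df$fivemer))
  if (n_full < 1024L) {
    message("mutability table covers ", n_full,
            "/1024 fully determined 5-mers; missing entries fall back to ",
            "averages over matching entries")
  }
  df
}

#' @rdname read_mutability_table
#' @param table Mutability table to write.
#' @export
write_mutability_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Serialize a fit result as JSON
#'
#' Writes the parameter estimates (flat names `kappa`, `omega_fwr`,
#' `omega_cdr`, `h_wrc`, ..., or `kappa`/`omega` for GY94), `loglik`, `aic`,
#' `mean_tree_length`, any stored profile CIs, and convergence metadata.
#'
#' @param fit A `bcr_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- c(as.list(fit$flat),
           list(mean_tree_length = fit$mean_tree_length,
                loglik = fit$loglik,
                aic = fit$aic,
                model = fit$model,
                root_mode = fit$root_mode,
                n_free_params = fit$n_free_params,
                n_lineages = fit$n_lineages,
                converged = fit$converged,
                cis = lapply(fit$cis, function(ci) {
                  list(lower = unname(ci[1]), upper = unname(ci[2]),
                       at_bound = as.logical(attr(ci, "at_bound")))
                })))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
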