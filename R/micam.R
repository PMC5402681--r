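# MiCAM: scan every taxon at every taxonomic rank with the appropriate test
# configuration, control FDR per rank, and render the hierarchical map.

utils::globalVariables(c("rank", "otu", "status", "sign"))

#' Partition OTUs into taxa at every taxonomic rank
#'
#' The kingdom rank holds the single entire-community group (labelled by
#' the unique kingdom name when one covers all OTUs).  At every lower rank
#' OTUs are grouped by their lineage label; OTUs unassigned at a rank are
#' not formed into a pseudo-taxon and are simply not tested at that rank,
#' while remaining members of their named higher-rank taxa.
#'
#' @param taxonomy character matrix from [read_taxonomy()] (OTUs x 7 ranks).
#' @param otu_ids OTU identifiers to scan (must be rownames of `taxonomy`).
#' @return Named list (one element per rank) of lists of `taxon_group`s,
#'   each with fields `rank`, `label`, `members`.
#' @export
build_taxa_groups <- function(taxonomy, otu_ids = rownames(taxonomy)) {
  missing <- setdiff(otu_ids, rownames(taxonomy))
  if (length(missing)) {
    stop2("taxonomy missing for OTU(s): ",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  tax <- taxonomy[otu_ids, , drop = FALSE]
  out <- vector("list", length(TAXONOMIC_RANKS))
  names(out) <- TAXONOMIC_RANKS

  kl <- unique(tax[, "kingdom"])
  kl <- kl[!is.na(kl)]
  community_label <- if (length(kl) == 1L && !anyNA(tax[, "kingdom"])) {
    kl
  } else "(entire community)"
  out$kingdom <- list(taxon_group("kingdom", community_label, otu_ids))

  for (rank in TAXONOMIC_RANKS[-1L]) {
    # lineage-qualified keys so that, e.g., two genera with the same name in
    # different families stay distinct
    r_idx <- match(rank, TAXONOMIC_RANKS)
    labels <- tax[, rank]
    keys <- apply(tax[, seq_len(r_idx), drop = FALSE], 1L, paste, collapse = "|")
    keep <- !is.na(labels)
    groups <- split(otu_ids[keep], keys[keep])
    out[[rank]] <- unname(lapply(groups, function(members) {
      taxon_group(rank, tax[members[1L], rank], members)
    }))
  }
  out
}

taxon_group <- function(rank, label, members) {
  structure(list(rank = rank, label = label, members = members,
                 size = length(members)),
            class = "taxon_group")
}

#' Prune a tree to a member set
#'
#' Minimal spanning subtree; degree-2 internal nodes are collapsed with
#' their branch lengths summed, so leaf-to-leaf path lengths are preserved.
#' A single-member set returns `NULL` (no tree is needed for a single-OTU
#' test).
#'
#' @param tree an `ape::phylo` tree.
#' @param members tip labels to keep (subset of `tree$tip.label`).
#' @return A `phylo` tree over `members`, or `NULL` for one member.
#' @export
prune_tree <- function(tree, members) {
  if (length(members) == 0L) stop2("empty member set")
  bad <- setdiff(members, tree$tip.label)
  if (length(bad)) {
    stop2("member(s) not on tree: ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (length(members) == 1L) return(NULL)
  if (length(members) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, members)
}

#' Choose the test configuration for a taxon
#'
#' Single-OTU taxa get the single-OTU score test; groups whose UniFrac
#' distances are degenerate (no phylogenetic disparity between any sample
#' pair) get the SPU pool plus the Bray-Curtis kernel only; all other
#' groups get the full candidate pool.
#'
#' @param group a `taxon_group`.
#' @param unifrac_degenerate logical degeneracy flag for the group.
#' @return `"single_otu"`, `"spu_bray"`, or `"full"`.
#' @export
select_test_config <- function(group, unifrac_degenerate = FALSE) {
  if (group$size == 1L) return("single_otu")
  if (isTRUE(unifrac_degenerate)) return("spu_bray")
  "full"
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement, via [stats::p.adjust()].
#'
#' @param p vector of p-values.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Comprehensive association mapping across all taxonomic ranks
#'
#' Fits the null model once, draws one shared permutation set, tests every
#' taxon at every rank with its configuration, applies BH FDR control
#' within each rank (discovery means `q <= fdr`), and records per-OTU
#' effect signs.
#'
#' @param dataset a harmonized `micam_dataset` (see [harmonize()]) with
#'   taxonomy and design.
#' @param method group analytic method: `"omiat"` (default),
#'   `"optimal_mirkat"`, `"aspu"`, or `"aggregate"`.
#' @param n_perm number of shared permutations (default 50000; a few
#'   thousand suffice for smoke tests).
#' @param seed permutation seed.
#' @param fdr per-rank FDR level (default 0.05).
#' @param grid SPU exponent grid.
#' @return A `micam_report`: `results` (one data frame per rank with
#'   columns rank, taxon, size, config, p, q, discovered), `signs` (per-OTU
#'   effect directions), plus the scan metadata.
#' @export
micam_scan <- function(dataset, method = c("omiat", "optimal_mirkat",
                                           "aspu", "aggregate"),
                       n_perm = 50000L, seed = 1L, fdr = 0.05,
                       grid = GAMMA_GRID) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "micam_dataset"))
  if (is.null(dataset$design)) stop2("dataset has no study design")
  if (is.null(dataset$taxonomy)) stop2("dataset has no taxonomy")
  otu <- dataset$otu
  P <- to_composition(otu)
  Zstd <- standardize_composition(P)
  fit <- fit_null(dataset$design)
  perms <- make_permutations(fit$n, n_perm, seed)
  U <- score_vector(fit, Zstd)
  signs <- stats::setNames(effect_sign(U), colnames(otu))
  groups <- build_taxa_groups(dataset$taxonomy, colnames(otu))

  results <- lapply(names(groups), function(rank) {
    rows <- lapply(groups[[rank]], function(g) {
      res <- tryCatch(
        scan_one_taxon(g, method, fit, P, Zstd, dataset$tree, perms, grid),
        error = function(e) {
          warning("taxon '", g$label, "' at rank ", rank, " failed: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(res)) return(NULL)
      data.frame(rank = rank, taxon = g$label, size = g$size,
                 config = res$config, p = res$p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df$q <- bh_adjust(df$p)
    df$discovered <- df$q <= fdr
    df
  })
  names(results) <- names(groups)

  structure(list(results = results, signs = signs, method = method,
                 n_perm = n_perm, seed = seed, fdr = fdr,
                 taxonomy = dataset$taxonomy[colnames(otu), , drop = FALSE]),
            class = "micam_report")
}

# Run the configured test for one taxon group; returns list(p, config).
scan_one_taxon <- function(g, method, fit, P, Zstd, tree, perms, grid) {
  if (g$size == 1L) {
    res <- single_otu_test(fit, Zstd[, g$members], perms)
    return(list(p = res$p, config = "single_otu"))
  }
  Psub <- P[, g$members, drop = FALSE]
  Zsub <- Zstd[, g$members, drop = FALSE]
  subtree <- if (is.null(tree)) NULL else prune_tree(tree, g$members)
  kernels <- kernel_candidates(Psub, subtree)
  config <- select_test_config(g, attr(kernels, "unifrac_degenerate"))
  p <- switch(method,
    omiat = omiat_test(fit, Zsub, kernels, perms, grid)$p,
    aspu = aspu_test(fit, Zsub, perms, grid)$p,
    optimal_mirkat = optimal_mirkat_test(fit, kernels, perms)$p,
    aggregate = aggregate_test(fit, Zsub, perms)$p)
  list(p = p, config = config)
}

#' @export
print.micam_report <- function(x, ...) {
  cat("MiCAM scan (", x$method, ", B = ", x$n_perm, ", seed = ", x$seed,
      ")\n", sep = "")
  for (rank in names(x$results)) {
    df <- x$results[[rank]]
    if (is.null(df)) next
    cat(sprintf("  %-8s %3d taxa, %d discovered\n", rank, nrow(df),
                sum(df$discovered)))
  }
  invisible(x)
}

#' Flatten a MiCAM report to one table
#'
#' @param report a `micam_report`.
#' @return Data frame with columns rank, taxon, size, config, p, q,
#'   discovered.
#' @export
micam_table <- function(report) {
  stopifnot(inherits(report, "micam_report"))
  do.call(rbind, c(Filter(Negate(is.null), report$results),
                   make.row.names = FALSE))
}

#' Convergence diagnostic between two scans
#'
#' Largest absolute q-value change per rank between two reports of the
#' same dataset (e.g. run at different permutation counts with the same
#' seed): small values indicate the permutation budget has stabilized the
#' discovery calls.
#'
#' @param report1,report2 `micam_report`s over the same taxa.
#' @return Named numeric vector: max |q1 - q2| per rank.
#' @export
micam_qdiff <- function(report1, report2) {
  stopifnot(inherits(report1, "micam_report"),
            inherits(report2, "micam_report"))
  vapply(names(report1$results), function(rank) {
    a <- report1$results[[rank]]
    b <- report2$results[[rank]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    m <- match(a$taxon, b$taxon)
    max(abs(a$q - b$q[m]))
  }, numeric(1))
}

#' Hierarchical discovery map
#'
#' Stacks all OTUs vertically and taxonomic ranks horizontally; each cell
#' is the taxon the OTU belongs to at that rank, colored red when the
#' taxon was discovered (`q <= fdr`), gray when tested but not discovered,
#' and white when untested (unassigned at that rank).  The right-hand
#' column shows each OTU's effect direction sign.
#'
#' @param report a `micam_report`.
#' @return A ggplot object; the companion flat table is available from
#'   [micam_table()].
#' @export
render_map <- function(report) {
  stopifnot(inherits(report, "micam_report"))
  tax <- report$taxonomy
  lineage_key <- apply(tax, 1L, function(r) paste(ifelse(is.na(r), "~", r),
                                                  collapse = "|"))
  otus <- rownames(tax)[order(lineage_key)]
  flat <- micam_table(report)

  cells <- list()
  for (rank in names(report$results)) {
    df <- report$results[[rank]]
    labels <- if (rank == "kingdom") {
      rep(df$taxon[1L], length(otus))
    } else {
      tax[otus, rank]
    }
    status <- rep("untested", length(otus))
    if (!is.null(df)) {
      m <- match(labels, df$taxon)
      status[!is.na(m)] <- ifelse(df$discovered[m[!is.na(m)]],
                                  "discovered", "undiscovered")
    }
    cells[[rank]] <- data.frame(otu = otus, rank = rank,
                                taxon = ifelse(is.na(labels), "", labels),
                                status = status, stringsAsFactors = FALSE)
  }
  grid_df <- do.call(rbind, cells)
  lv <- c(names(report$results), "effect")
  grid_df$rank <- factor(grid_df$rank, levels = lv)
  grid_df$otu <- factor(grid_df$otu, levels = rev(otus))
  sign_df <- data.frame(otu = factor(otus, levels = rev(otus)),
                        rank = factor("effect", levels = lv),
                        sign = unname(report$signs[otus]))

  ggplot2::ggplot(grid_df, ggplot2::aes(x = rank, y = otu)) +
    ggplot2::geom_tile(ggplot2::aes(fill = status), color = "white",
                       linewidth = 0.2) +
    ggplot2::geom_text(data = sign_df,
                       ggplot2::aes(x = rank, y = otu, label = sign),
                       size = 2.5) +
    ggplot2::scale_fill_manual(values = c(discovered = "#c0392b",
                                          undiscovered = "gray70",
                                          untested = "white")) +
    ggplot2::labs(x = "taxonomic rank", y = "OTU", fill = "status") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Write a MiCAM report to disk
#'
#' Writes per-rank TSV tables, the flat companion table, and the discovery
#' map as a PDF.
#'
#' @param report a `micam_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_micam_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- micam_table(report)
  write.table(flat, file.path(dir, "micam_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (rank in names(report$results)) {
    df <- report$results[[rank]]
    if (is.null(df)) next
    write.table(df, file.path(dir, paste0("rank_", rank, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  signs <- data.frame(otu = names(report$signs), sign = unname(report$signs))
  write.table(signs, file.path(dir, "effect_signs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- render_map(report)
  ggplot2::ggsave(file.path(dir, "micam_map.pdf"), g, width = 7,
                  height = max(3, length(report$signs) * 0.08))
  invisible(dir)
}
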