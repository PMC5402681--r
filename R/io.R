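# Reading, validation and harmonization of the three input artifacts
# (counts, tree, taxonomy) plus the outcome/covariate design.

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")
RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Construct a validated OTU table
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns.
#' @param sample_ids,otu_ids optional identifier vectors; defaults taken from
#'   `dimnames(counts)`.
#' @return An object of class `otu_table`: the count matrix with unique
#'   sample and OTU identifiers as dimnames.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop2("OTU table is empty")
  if (!is.numeric(counts)) stop2("OTU table must be numeric")
  if (anyNA(counts)) stop2("OTU table contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop2("negative count at sample row ", bad[1L], ", OTU column ", bad[2L])
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("otu", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(sample_ids)) {
    stop2("duplicated sample id(s): ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(otu_ids)) {
    stop2("duplicated OTU id(s): ",
          paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x), "samples x", ncol(x), "OTUs\n")
  invisible(x)
}

#' Read an OTU count table from TSV or BIOM
#'
#' TSV layout: header row of OTU ids, first column sample ids, one row per
#' sample (use `transpose = TRUE` for the OTU-by-sample dialect).  BIOM files
#' (JSON or HDF5, read through the biomformat package) are stored
#' OTU-by-sample and are transposed on read.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose for TSV input, set `TRUE` when rows are OTUs.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, row.names = NULL)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (transpose) m <- t(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
  }
  otu_table(m)
}

#' Write an OTU table as TSV (samples x OTUs)
#'
#' @param otu an [otu_table()].
#' @param path output path.
#' @export
write_otu_table <- function(otu, path) {
  df <- data.frame(sample_id = rownames(otu), as.data.frame(unclass(otu)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Branch lengths are required unless `assume_unit_branch_lengths = TRUE`,
#' in which case every edge is assigned length 1.  Trees with missing or
#' negative edge lengths are rejected: UniFrac distances depend on them and
#' silent defaults would corrupt every downstream kernel.
#'
#' @param path Newick file path.
#' @param assume_unit_branch_lengths assign unit lengths when absent.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path, assume_unit_branch_lengths = FALSE) {
  if (!file.exists(path)) stop2("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop2("unparseable Newick: ",
                                             conditionMessage(e)))
  if (is.null(tree)) stop2("unparseable Newick in ", path)
  validate_tree(tree, assume_unit_branch_lengths)
}

validate_tree <- function(tree, assume_unit_branch_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop2("not a phylo tree")
  if (is.null(tree$edge.length)) {
    if (!assume_unit_branch_lengths) {
      stop2("tree has no branch lengths; pass ",
            "assume_unit_branch_lengths = TRUE to use unit lengths")
    }
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop2("tree has missing or negative branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) stop2("tree has duplicated tip labels")
  tree
}

#' Parse Greengenes-style lineage strings into a taxonomy table
#'
#' Accepts either a two-column TSV file (OTU id, lineage string) or a named
#' character vector of lineage strings.  Lineages are split on `;`, rank
#' prefixes (`k__` ... `s__`) stripped, and padded/truncated to the seven
#' canonical ranks.  An empty label after the prefix means unassigned.
#'
#' @param x path to a two-column TSV, or a named character vector.
#' @return A character matrix, OTUs x 7 ranks, with `NA` for unassigned.
#' @export
read_taxonomy <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    df <- read.delim(x, header = TRUE, check.names = FALSE,
                     colClasses = "character")
    lineages <- df[[2L]]
    names(lineages) <- df[[1L]]
  } else {
    lineages <- x
  }
  if (is.null(names(lineages))) stop2("taxonomy lineages must be named by OTU id")
  parse_lineages(lineages)
}

parse_lineages <- function(lineages) {
  out <- matrix(NA_character_, length(lineages), 7L,
                dimnames = list(names(lineages), TAXONOMIC_RANKS))
  for (i in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[[i]], ";", fixed = TRUE)[[1L]])
    for (j in seq_along(parts)) {
      if (j > 7L) break
      lab <- sub("^[kpcofgs]__", "", parts[j])
      if (nzchar(lab)) out[i, j] <- lab
    }
  }
  out
}

#' Construct a study design (outcome + covariates)
#'
#' @param y outcome vector: numeric (continuous) or two-class 0/1 (binary).
#' @param X optional numeric covariate matrix / data frame, samples in rows.
#' @param trait `"continuous"`, `"binary"`, or `"auto"` (binary iff `y` takes
#'   exactly the values 0 and 1).
#' @param sample_ids optional sample identifiers.
#' @return A `study_design` list with elements `y`, `X`, `trait`,
#'   `sample_ids`.
#' @export
study_design <- function(y, X = NULL, trait = c("auto", "continuous", "binary"),
                         sample_ids = names(y)) {
  trait <- match.arg(trait)
  y <- as.numeric(y)
  if (anyNA(y)) stop2("outcome contains missing values")
  if (trait == "auto") {
    trait <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  }
  if (trait == "binary") {
    if (!all(y %in% c(0, 1))) stop2("binary outcome must be coded 0/1")
    if (length(unique(y)) < 2L) stop2("binary outcome must contain both classes")
  }
  if (is.null(X)) {
    X <- matrix(numeric(0), length(y), 0L)
  } else {
    X <- as.matrix(as.data.frame(X))
    storage.mode(X) <- "double"
    if (nrow(X) != length(y)) stop2("covariate rows must match outcome length")
    if (anyNA(X)) stop2("covariates contain missing values")
  }
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  structure(list(y = y, X = X, trait = trait,
                 sample_ids = if (is.null(sample_ids)) NULL
                              else as.character(sample_ids)),
            class = "study_design")
}

#' Read a study design from a TSV file
#'
#' @param path TSV with a header and one row per sample; first column is the
#'   sample id.
#' @param outcome_col name of the outcome column.
#' @param covariate_cols character vector of covariate column names (may be
#'   empty).
#' @param trait trait type passed to [study_design()].
#' @return A `study_design`.
#' @export
read_design <- function(path, outcome_col, covariate_cols = character(),
                        trait = "auto") {
  df <- read.delim(path, check.names = FALSE)
  if (!outcome_col %in% names(df)) stop2("outcome column not found: ", outcome_col)
  missing_cov <- setdiff(covariate_cols, names(df))
  if (length(missing_cov)) {
    stop2("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  X <- if (length(covariate_cols)) df[, covariate_cols, drop = FALSE] else NULL
  study_design(df[[outcome_col]], X, trait = trait,
               sample_ids = as.character(df[[1L]]))
}

#' Harmonize counts, tree, taxonomy and design into one aligned dataset
#'
#' Restricts the OTU set to the intersection of the count table, the tree
#' leaves and (when given) the taxonomy; drops zero-total samples with a
#' warning; and aligns sample order between the counts and the design.
#' Extra tree leaves are tolerated (the tree may cover a superset of the
#' analyzed OTUs).
#'
#' @param otu an [otu_table()].
#' @param tree an `ape::phylo` tree or `NULL`.
#' @param taxonomy a taxonomy matrix from [read_taxonomy()] or `NULL`.
#' @param design a [study_design()] or `NULL`.
#' @return A `micam_dataset` list: `otu`, `tree`, `taxonomy`, `design`,
#'   `dropped_otus`, `dropped_samples`.
#' @export
harmonize <- function(otu, tree = NULL, taxonomy = NULL, design = NULL) {
  stopifnot(inherits(otu, "otu_table"))
  keep <- colnames(otu)
  if (!is.null(tree)) keep <- intersect(keep, tree$tip.label)
  if (!is.null(taxonomy)) keep <- intersect(keep, rownames(taxonomy))
  dropped <- setdiff(colnames(otu), keep)
  if (length(keep) == 0L) stop2("no OTUs shared between counts, tree and taxonomy")
  if (length(dropped)) {
    warning(length(dropped), " OTU(s) absent from tree/taxonomy dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "", call. = FALSE)
  }
  counts <- unclass(otu)[, keep, drop = FALSE]

  if (!is.null(design) && !is.null(design$sample_ids) &&
      !is.null(rownames(counts))) {
    common <- intersect(rownames(counts), design$sample_ids)
    if (length(common) == 0L) stop2("no samples shared between counts and design")
    if (length(common) < nrow(counts) ||
        length(common) < length(design$sample_ids)) {
      warning("restricting to ", length(common),
              " samples present in both counts and design", call. = FALSE)
    }
    counts <- counts[common, , drop = FALSE]
    ord <- match(common, design$sample_ids)
    design <- study_design(design$y[ord],
                           if (ncol(design$X)) design$X[ord, , drop = FALSE]
                           else NULL,
                           trait = design$trait, sample_ids = common)
  }

  zero <- rowSums(counts) <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-total sample(s) dropped: ",
            paste(utils::head(rownames(counts)[zero], 5L), collapse = ", "),
            call. = FALSE)
    counts <- counts[!zero, , drop = FALSE]
    if (!is.null(design)) {
      design <- study_design(design$y[!zero],
                             if (ncol(design$X)) design$X[!zero, , drop = FALSE]
                             else NULL,
                             trait = design$trait,
                             sample_ids = design$sample_ids[!zero])
    }
  }
  if (nrow(counts) == 0L) stop2("no samples left after dropping zero totals")

  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, colnames(counts))
    if (length(extra)) tree <- ape::keep.tip(tree, colnames(counts))
  }
  if (!is.null(taxonomy)) taxonomy <- taxonomy[colnames(counts), , drop = FALSE]

  structure(list(otu = otu_table(counts), tree = tree, taxonomy = taxonomy,
                 design = design, dropped_otus = dropped,
                 dropped_samples = if (exists("zero")) sum(zero) else 0L),
            class = "micam_dataset")
}

#' Filter OTUs by mean relative abundance
#'
#' Computes per-sample proportions, then the per-OTU mean proportion across
#' samples, and keeps OTUs whose mean is strictly greater than `threshold`.
#' Samples whose total becomes zero after filtering are dropped with a
#' warning.
#'
#' @param otu an [otu_table()].
#' @param threshold mean-proportion cutoff in `[0, 1)`; default `1e-3`.
#' @return A filtered [otu_table()].
#' @export
filter_by_mean_proportion <- function(otu, threshold = 1e-3) {
  stopifnot(inherits(otu, "otu_table"), threshold >= 0, threshold < 1)
  P <- to_composition(otu)
  keep <- colMeans(P) > threshold
  if (!any(keep)) stop2("all OTUs filtered out at threshold ", threshold)
  counts <- unclass(otu)[, keep, drop = FALSE]
  zero <- rowSums(counts) <= 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero total after filtering dropped",
            call. = FALSE)
    counts <- counts[!zero, , drop = FALSE]
  }
  otu_table(counts)
}
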