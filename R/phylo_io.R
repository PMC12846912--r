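#' Parse a Newick string into a validated phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. Trees must carry branch
#' lengths; negative lengths and duplicated tip labels are rejected, and an
#' unbalanced parenthesis is reported with its character position.
#'
#' @param text a single Newick string (terminated by `;`).
#' @return an object of class `phylo` (rooted, with `edge.length`).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unmatched ')' at position %d", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf(
      "malformed Newick: %d unclosed '(' (last opened at position %d)",
      depth, max(which(chars == "("))
    ))
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf("malformed Newick: missing terminal ';' at position %d",
                 nchar(text)))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop(sprintf("malformed Newick: %s",
                                                    conditionMessage(e))))
  if (is.null(tree)) stop("malformed Newick: ape could not parse the string")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) {
    stop(sprintf("negative branch length(s): %s",
                 paste(signif(tree$edge.length[tree$edge.length < 0], 4),
                       collapse = ", ")))
  }
  if (anyDuplicated(tree$tip.label)) {
    stop(sprintf("duplicated tip labels: %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  tree
}

#' Write a phylogeny as a Newick string
#'
#' @param tree a `phylo` object.
#' @param digits number of significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Load a posterior tree sample from file and downsample it
#'
#' Reads either a NEXUS trees block or a one-Newick-per-line file and draws
#' `n` trees uniformly without replacement, mirroring the downsampling of a
#' large posterior tree sample (for example 902 trees down to 100) used to
#' integrate over phylogenetic uncertainty.
#'
#' @param path file containing at least `n` trees.
#' @param n number of trees to keep (default 100).
#' @param seed integer seed making the draw reproducible.
#' @return a `tree_sample` object: list with elements `trees` (list of
#'   `phylo`), `source_size`, `sample_size`, `seed`, `indices`.
#' @export
load_tree_sample <- function(path, n = 100, seed = 1) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) && grepl("^#NEXUS", trimws(first[1]), ignore.case = TRUE)) {
    trees <- ape::read.nexus(path)
  } else {
    trees <- ape::read.tree(path)
  }
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  src <- length(trees)
  if (src < n) {
    stop(sprintf("requested %d trees but only %d available in '%s'",
                 n, src, path))
  }
  idx <- with_seed(seed, sample.int(src, n, replace = FALSE))
  sampled <- lapply(trees[idx], validate_tree)
  gc_log("loaded %d trees from '%s', sampled %d (seed %d)", src, path, n, seed)
  tree_sample(sampled, source_size = src, seed = seed, indices = idx)
}

#' Construct a tree sample
#'
#' @param trees list of `phylo` objects over the same taxon set.
#' @param source_size size of the source posterior (defaults to the number
#'   of trees supplied).
#' @param seed seed recorded for provenance.
#' @param indices indices of the sampled trees in the source.
#' @return a `tree_sample` object.
#' @export
tree_sample <- function(trees, source_size = length(trees), seed = NA_integer_,
                        indices = seq_along(trees)) {
  stopifnot(length(trees) >= 1, length(trees) <= source_size)
  taxa <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), taxa)) {
      stop(sprintf("tree %d has a different taxon set from tree 1", i))
    }
  }
  structure(
    list(trees = trees, source_size = source_size,
         sample_size = length(trees), seed = seed, indices = indices),
    class = "tree_sample"
  )
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("tree_sample: %d trees (of %d) over %d taxa\n",
              x$sample_size, x$source_size, length(x$trees[[1]]$tip.label)))
  invisible(x)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "tree_sample")) return(trees$trees)
  if (inherits(trees, "phylo")) return(list(trees))
  if (is.list(trees)) return(trees)
  stop("expected a tree_sample, phylo, or list of phylo")
}

#' Phylogenetic covariance matrix (shared path lengths)
#'
#' Entry (i, j) is the summed branch length on the path from the root to the
#' most recent common ancestor of tips i and j, i.e. the shared history of
#' the two lineages; the diagonal holds root-to-tip distances. Computed with
#' [ape::vcv.phylo()] and optionally restricted to a taxon subset, which by
#' construction equals the corresponding submatrix of the full covariance.
#'
#' @param tree a `phylo` object.
#' @param taxa optional character vector of tips to keep (in this order).
#' @param standardize divide by the maximum diagonal entry so that variance
#'   components are comparable across trees (default FALSE).
#' @return a symmetric PSD matrix with taxon dimnames.
#' @export
phylo_covariance <- function(tree, taxa = NULL, standardize = FALSE) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(C))
    if (length(missing)) {
      stop(sprintf("taxa not in tree: %s", paste(missing, collapse = ", ")))
    }
    C <- C[taxa, taxa, drop = FALSE]
  }
  if (standardize) C <- C / max(diag(C))
  C
}

#' Read per-language metadata (coordinates, macro-area, family)
#'
#' @param path CSV with columns `taxon`, `longitude`, `latitude`,
#'   `macroarea`, `family`.
#' @return a data.frame with one validated row per taxon.
#' @export
read_language_metadata <- function(path) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("taxon", "longitude", "latitude", "macroarea", "family")
  if (nrow(df) == 0) {
    warning(sprintf("metadata file '%s' contains no rows", path))
    return(data.frame(taxon = character(), longitude = numeric(),
                      latitude = numeric(), macroarea = character(),
                      family = character(), stringsAsFactors = FALSE))
  }
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("metadata missing columns: %s",
                                 paste(miss, collapse = ", ")))
  validate_metadata(df[req])
}

validate_metadata <- function(df) {
  if (anyDuplicated(df$taxon)) {
    stop(sprintf("duplicate taxa in metadata: %s",
                 paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", ")))
  }
  bad_lat <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
  if (length(bad_lat)) {
    stop(sprintf("latitude outside [-90, 90] for taxa: %s",
                 paste(df$taxon[bad_lat], collapse = ", ")))
  }
  bad_lon <- which(!is.na(df$longitude) & abs(df$longitude) > 180)
  if (length(bad_lon)) {
    stop(sprintf("longitude outside [-180, 180] for taxa: %s",
                 paste(df$taxon[bad_lon], collapse = ", ")))
  }
  df
}

#' Read a taxa-by-features binary trait matrix
#'
#' @param path CSV whose first column (`taxon`) holds taxon ids and whose
#'   remaining columns hold 0/1/empty feature values.
#' @return an integer matrix with taxa as rownames; missing entries are NA.
#' @export
read_trait_matrix <- function(path) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"taxon" %in% names(df)) stop("trait CSV must have a 'taxon' column")
  if (anyDuplicated(df$taxon)) stop("duplicate taxa in trait matrix")
  m <- as.matrix(df[setdiff(names(df), "taxon")])
  storage.mode(m) <- "integer"
  rownames(m) <- df$taxon
  bad <- !(is.na(m) | m == 0L | m == 1L)
  if (any(bad)) stop("trait values must be 0, 1 or missing")
  gc_log("read trait matrix: %d taxa x %d features (%.1f%% missing)",
         nrow(m), ncol(m), 100 * mean(is.na(m)))
  m
}

#' Write a trait matrix to CSV
#' @param m integer matrix with taxon rownames.
#' @param path output path.
#' @export
write_trait_matrix <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv_stable(df, path)
}

## write.csv with stable formatting (no row names, no quotes for numerics)
write.csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
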