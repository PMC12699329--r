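# Readers/writers for profile matrices and ancestral-state tables.

#' Read a binary presence/absence profile matrix
#'
#' Tab-separated file: first row holds OG ids, first column genome ids,
#' entries 0 or 1.
#'
#' @param path Path to the TSV file.
#' @param tree Optional `phylo`; when given, genome ids must match the leaf
#'   set exactly and rows are returned in tree leaf-name order.
#' @return Integer matrix, rows = genomes, columns = OGs.
#' @export
read_profile <- function(path, tree = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  storage.mode(mat) <- "integer"
  validate_profile(mat, tree = tree)
}

#' Validate (and align) a profile matrix
#'
#' @param mat Matrix with genome rownames and OG colnames, entries 0/1.
#' @inheritParams read_profile
#' @return The validated matrix, row-aligned to `tree$tip.label` if a tree is
#'   given.
#' @export
validate_profile <- function(mat, tree = NULL) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("profile matrix must have genome rownames and OG colnames")
  if (anyNA(mat) || !all(mat %in% c(0L, 1L)))
    stop("profile entries must all be 0 or 1 with no missing values")
  if (!is.null(tree)) {
    tips <- tree$tip.label
    missing_in_profile <- setdiff(tips, rownames(mat))
    missing_in_tree <- setdiff(rownames(mat), tips)
    if (length(missing_in_profile) || length(missing_in_tree))
      stop("profile/tree mismatch; leaves without profile rows: {",
           paste(missing_in_profile, collapse = ", "),
           "}; profile rows without leaves: {",
           paste(missing_in_tree, collapse = ", "), "}")
    mat <- mat[tips, , drop = FALSE]
  }
  mat
}

#' Write a profile matrix as TSV
#' @param mat Profile matrix (genomes x OGs).
#' @param path Output path.
#' @export
write_profile <- function(mat, path) {
  df <- data.frame(genome = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ancestral-state table
#'
#' Tab-separated: first column node id (leaf names and internal node labels),
#' one column per OG. Entries are `0`, `1`, or several states joined by `|`
#' (e.g. `0|1`), which denote an uncertain state and are mapped to `NA`.
#' This accepts the combined marginal-reconstruction table layout produced by
#' pastML-style tools (one row per node, possibly repeated rows for
#' multi-state nodes: repeated node ids with differing states also collapse
#' to uncertain).
#'
#' @param path Path to the TSV file.
#' @param tree A prepared `phylo`; node ids must be leaf names or internal
#'   labels of this tree.
#' @param profile Optional profile matrix; leaf rows of the table are checked
#'   against it.
#' @return Integer matrix of states (0/1, `NA` = uncertain), one row per tree
#'   node (leaves first, then internal nodes), one column per OG.
#' @export
read_ancestral_table <- function(path, tree, profile = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  node_ids <- df[[1L]]
  ogs <- colnames(df)[-1L]
  idx <- tree_index(tree)
  known <- idx$labels
  bad <- setdiff(unique(node_ids), known)
  if (length(bad))
    stop("unknown node ids in ancestral table: ", paste(bad, collapse = ", "))
  states <- matrix(NA_integer_, nrow = idx$nn, ncol = length(ogs),
                   dimnames = list(known, ogs))
  parse_state <- function(s) {
    parts <- unique(strsplit(s, "|", fixed = TRUE)[[1L]])
    parts <- parts[parts != ""]
    if (length(parts) == 1L && parts %in% c("0", "1"))
      return(as.integer(parts))
    if (!all(parts %in% c("0", "1")))
      stop("non-binary ancestral state entry: ", s)
    NA_integer_  # multi-valued = uncertain
  }
  seen <- matrix(FALSE, nrow = idx$nn, ncol = length(ogs))
  for (r in seq_along(node_ids)) {
    v <- match(node_ids[r], known)
    for (j in seq_along(ogs)) {
      s <- parse_state(df[r, j + 1L])
      if (!seen[v, j]) {
        states[v, j] <- s
        seen[v, j] <- TRUE
      } else if (!identical(states[v, j], s)) {
        states[v, j] <- NA_integer_  # repeated node rows disagree
      }
    }
  }
  if (!is.null(profile)) {
    common <- intersect(rownames(profile), tree$tip.label)
    for (g in common) {
      for (og in intersect(ogs, colnames(profile))) {
        s <- states[g, og]
        if (!is.na(s) && s != profile[g, og])
          stop(sprintf(
            "ancestral table conflicts with profile at leaf %s, OG %s", g, og))
      }
    }
  }
  states
}

#' Write pair-scoring results as TSV
#'
#' @param results Data frame from [run_method].
#' @param path Output path.
#' @param header_comments Optional character vector written as `#`-prefixed
#'   comment lines before the table (method, options, seeds).
#' @export
write_results <- function(results, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop OGs outside a prevalence band
#'
#' Retains OGs present in at least `lower` and at most `upper` (inclusive
#' fractions) of the genomes; OGs carried by (almost) none or (almost) all
#' genomes are uninformative for co-evolution scoring.
#'
#' @param profile Profile matrix (genomes x OGs).
#' @param lower,upper Inclusive prevalence bounds as fractions of genomes.
#' @return The filtered profile matrix; dropped OG ids are attached as
#'   `attr(, "dropped")`.
#' @export
prevalence_filter <- function(profile, lower = 0.01, upper = 0.99) {
  frac <- colMeans(profile)
  keep <- frac >= lower & frac <= upper
  out <- profile[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(profile)[!keep]
  out
}
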