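#' Gene-interaction network
#'
#' Container for an undirected, unweighted gene-interaction network: the
#' adjacency matrix `W` consumed by the GeneRank system together with the
#' per-gene degrees that form the diagonal of `D`.
#'
#' @param genes Character vector of unique gene identifiers (defines the row
#'   and column order of the adjacency matrix).
#' @param adjacency A p x p symmetric binary matrix (dense or any
#'   [Matrix::Matrix] flavour); stored sparse. The diagonal must be zero.
#'
#' @return An object of class `gene_network`: a list with elements `genes`
#'   (character), `adjacency` (a `dgCMatrix`) and `degree` (named integer
#'   vector, the row sums of the adjacency).
#' @examples
#' net <- gene_network(c("A", "B", "C"),
#'                     rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' net$degree
#' @export
gene_network <- function(genes, adjacency) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  adjacency <- methods::as(methods::as(methods::as(
    Matrix::Matrix(adjacency, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  p <- length(genes)
  if (!all(dim(adjacency) == c(p, p))) {
    stop("adjacency must be ", p, " x ", p, " to match 'genes'")
  }
  if (!all(adjacency@x %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1")
  }
  if (any(Matrix::diag(adjacency) != 0)) {
    stop("adjacency diagonal must be zero (no self-interactions)")
  }
  if (!Matrix::isSymmetric(adjacency)) {
    stop("adjacency must be symmetric (undirected network)")
  }
  adjacency <- Matrix::drop0(adjacency)
  dimnames(adjacency) <- list(genes, genes)
  deg <- as.integer(round(Matrix::rowSums(adjacency)))
  names(deg) <- genes
  structure(list(genes = genes, adjacency = adjacency, degree = deg),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  n_edges <- sum(x$degree) / 2
  cat(sprintf("gene_network: %d genes, %d undirected edges\n",
              length(x$genes), n_edges))
  if (length(x$degree)) {
    cat(sprintf("  degree: min %d, median %s, max %d; isolated genes: %d\n",
                min(x$degree), format(stats::median(x$degree)),
                max(x$degree), sum(x$degree == 0)))
  }
  invisible(x)
}

#' Read a gene-interaction edge list
#'
#' Parses a two-column whitespace- or tab-delimited edge list (one
#' interaction per line, HPRD-style gene symbols) into a [gene_network()].
#' Edges are undirected: reversed duplicates collapse onto a single edge and
#' self-loops are dropped with a warning, since a self-interaction has no
#' meaning in the adjacency/degree formulation. Lines starting with `#` are
#' skipped.
#'
#' @param path Path to the edge-list file.
#' @param dedupe Duplicate (and reversed-duplicate) edges always collapse to
#'   one undirected edge because the adjacency is binary; with
#'   `dedupe = FALSE` a warning reports how many duplicate lines were
#'   collapsed, so silently redundant input can be flagged.
#' @param sif Tolerate a three-column SIF dialect (`node relation node`):
#'   columns 1 and 3 are used, column 2 is ignored.
#'
#' @return A [gene_network()] over the union of all genes mentioned, in
#'   first-appearance order.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path, dedupe = TRUE, sif = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty edge list: returning a network with 0 genes")
    return(gene_network(character(0), Matrix::sparseMatrix(
      i = integer(0), j = integer(0), dims = c(0, 0))))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  want <- if (sif) 3L else 2L
  bad <- which(vapply(fields, length, 1L) != want)
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d: expected %d columns, got %d",
                 line_no[bad[1]], want, length(fields[[bad[1]]])))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", if (sif) 3L else 2L)
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]
    to <- to[!loops]
  }
  genes <- unique(c(rbind(from, to)))
  i <- match(from, genes)
  j <- match(to, genes)
  key <- paste(pmin(i, j), pmax(i, j))
  dup <- duplicated(key)
  if (any(dup) && !dedupe) {
    warning(sum(dup), " duplicate edge line(s) collapsed ",
            "(adjacency is binary)")
  }
  i <- i[!dup]
  j <- j[!dup]
  p <- length(genes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(p, p))
  gene_network(genes, adj)
}

#' Align a network to a gene universe
#'
#' Reconciles a network's gene set with the gene axis of an expression
#' matrix. Under `isolated_policy = "keep"` the result spans the whole
#' universe and genes absent from the network become isolated (degree 0, so
#' their GeneRank reduces to `(1-d)` times their expression); under `"drop"`
#' the result is restricted to the intersection. Identifiers are matched as
#' exact case-sensitive strings; no alias resolution is attempted, so make
#' sure both inputs use the same symbol namespace.
#'
#' @param net A [gene_network()].
#' @param gene_universe Character vector of unique identifiers, typically
#'   `rownames()` of an expression matrix. Its order is preserved.
#' @param isolated_policy `"keep"` (default) or `"drop"`, see above.
#'
#' @return A [gene_network()] whose gene axis is `gene_universe` (keep) or
#'   the ordered intersection (drop).
#' @export
align_to_genes <- function(net, gene_universe,
                           isolated_policy = c("keep", "drop")) {
  isolated_policy <- match.arg(isolated_policy)
  stopifnot(inherits(net, "gene_network"))
  gene_universe <- as.character(gene_universe)
  if (anyDuplicated(gene_universe)) {
    stop("gene_universe has duplicated identifiers")
  }
  target <- if (isolated_policy == "drop") {
    gene_universe[gene_universe %in% net$genes]
  } else {
    gene_universe
  }
  if (isolated_policy == "drop" && length(target) == 0L) {
    stop("no genes shared between network and gene_universe; ",
         "check that both use the same identifier namespace ",
         "(matching is exact and case-sensitive)")
  }
  p <- length(target)
  idx <- match(target, net$genes)  # NA for genes absent from net
  adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(p, p))
  present <- which(!is.na(idx))
  if (length(present) > 1) {
    sub <- net$adjacency[idx[present], idx[present], drop = FALSE]
    sub <- methods::as(methods::as(sub, "generalMatrix"), "TsparseMatrix")
    adj <- Matrix::sparseMatrix(i = present[sub@i + 1L],
                                j = present[sub@j + 1L],
                                x = sub@x, dims = c(p, p))
  }
  gene_network(target, adj)
}
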