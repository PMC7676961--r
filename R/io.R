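#' Read a gene x sample expression matrix
#'
#' Tab-delimited text: first row sample identifiers, first column gene
#' identifiers, numeric cells on a log-like scale (microarray summaries or
#' log2(FPKM+1)). Count-like input (e.g. raw FPKM) can be transformed at
#' read time with `log2_shift`, which stores `log2(x + 1)`.
#'
#' @param path Path to the matrix file.
#' @param log2_shift Apply `log2(x + 1)` to every cell.
#'
#' @return Numeric matrix with gene rownames, sample colnames and a
#'   `scale_note` attribute.
#' @export
read_expression <- function(path, log2_shift = FALSE) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a gene column plus ",
                         "at least one sample column")
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(df)[-1][bad[1, 2]]))
  }
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample identifier")
  if (log2_shift) num <- log2(num + 1)
  dimnames(num) <- list(genes, colnames(df)[-1])
  attr(num, "scale_note") <- if (log2_shift) "log2(x + 1)" else "as read"
  num
}

#' Write an expression (or GeneRank-weighted) matrix
#'
#' Inverse of [read_expression()]: tab-delimited, `gene` as first column.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample stage assignments
#'
#' Tab-delimited with a header: column 1 sample identifier, column 2
#' integer stage code (0 = normal control), optional column 3 display label
#' (IA, IB, ...). When `samples` is supplied (the expression matrix's
#' columns), samples missing from the file are an error; samples in the
#' file but not in `samples` are dropped with a warning reporting the
#' count.
#'
#' @param path Path to the stage file.
#' @param samples Optional character vector of expected sample identifiers.
#'
#' @return A [stage_design()].
#' @export
read_stages <- function(path, samples = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("stage file needs sample and stage columns")
  st_raw <- df[[2]]
  st <- suppressWarnings(as.numeric(st_raw))
  if (any(is.na(st)) || any(st != round(st))) {
    stop("non-integer stage code: ",
         paste(utils::head(st_raw[is.na(st) | st != round(st)], 3),
               collapse = ", "))
  }
  ids <- as.character(df[[1]])
  labels <- if (ncol(df) >= 3) as.character(df[[3]])
  if (!is.null(samples)) {
    missing <- setdiff(samples, ids)
    if (length(missing)) {
      stop("samples missing from stage file: ",
           paste(missing, collapse = ", "))
    }
    extra <- !(ids %in% samples)
    if (any(extra)) {
      warning(sum(extra), " stage-file sample(s) absent from the ",
              "expression matrix were dropped")
      ids <- ids[!extra]
      st <- st[!extra]
      if (!is.null(labels)) labels <- labels[!extra]
    }
  }
  stage_design(ids, as.integer(st), labels)
}

#' Write a stage design
#' @param design A [stage_design()].
#' @param path Output path.
#' @export
write_stages <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network as an edge list
#'
#' One undirected edge per line (each pair once), tab-delimited; readable
#' by [read_edge_list()]. Isolated genes do not appear.
#'
#' @param net A [gene_network()].
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  adj <- methods::as(methods::as(net$adjacency, "generalMatrix"),
                     "TsparseMatrix")
  keep <- adj@i < adj@j
  writeLines(paste(net$genes[adj@i[keep] + 1L],
                   net$genes[adj@j[keep] + 1L], sep = "\t"), path)
  invisible(path)
}

#' Write a MEG or MFSelector result table
#'
#' Tab-delimited, one row per gene, in the table's own (input gene) order
#' unless `sort_by_p` reorders by adjusted p-value.
#'
#' @param tab A `meg_table` or `mf_table`.
#' @param path Output path.
#' @param sort_by_p Order rows by increasing `p_adjusted`.
#' @export
write_result_table <- function(tab, path, sort_by_p = FALSE) {
  df <- as.data.frame(tab)
  if (sort_by_p) df <- df[order(df$p_adjusted), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run one of the three monotone-gene screens end to end
#'
#' File-level front end tying the modules together. `method = "weighted"`
#' is the network-weighted procedure (GeneRank then Kruskal-Wallis +
#' monotone filter), `"raw"` the conventional screen on unweighted values,
#' `"mfselector"` the DEtotal comparator. The summary reports MI/MD (or
#' significant, for MFSelector) gene counts over the significance grid
#' `alpha_grid`. Gene counts at each attrition point (read, aligned to the
#' network, tested) are logged via [message()].
#'
#' @param expr_path Expression matrix file (see [read_expression()]).
#' @param stages_path Stage file (see [read_stages()]).
#' @param network_path Edge-list file; required for `method = "weighted"`.
#' @param method `"weighted"`, `"raw"` or `"mfselector"`.
#' @param d Damping parameter for the weighted method.
#' @param alpha Significance threshold on adjusted p-values.
#' @param adjust Multiple-testing method for the KW screens.
#' @param direction MFSelector direction (`"both"` tests each gene both
#'   ways and keeps the smaller DEtotal).
#' @param n_perm Permutations for MFSelector.
#' @param seed Single seed from which all randomness in the run flows.
#' @param isolated_policy How to align expression genes absent from the
#'   network, see [align_to_genes()].
#' @param log2_shift Apply log2(x+1) at read time (FPKM-like input).
#' @param alpha_grid Thresholds for the summary counts.
#' @param out_dir If non-NULL, write `result_table.tsv` and `summary.tsv`
#'   there.
#'
#' @return List with `table` (the per-gene result), `summary` (counts per
#'   alpha) and `config` (parameter echo).
#' @export
run_pipeline <- function(expr_path, stages_path, network_path = NULL,
                         method = c("weighted", "raw", "mfselector"),
                         d = 0.5, alpha = 0.1,
                         adjust = c("BH", "bonferroni", "none"),
                         direction = "both", n_perm = 1000, seed = 1,
                         isolated_policy = c("keep", "drop"),
                         log2_shift = FALSE,
                         alpha_grid = c(0.05, 0.1, 0.15, 0.2),
                         out_dir = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  isolated_policy <- match.arg(isolated_policy)
  if (method == "weighted" && is.null(network_path)) {
    stop("method = 'weighted' requires a network edge-list file")
  }
  config <- list(method = method, d = d, alpha = alpha, adjust = adjust,
                 direction = direction, n_perm = n_perm, seed = seed,
                 isolated_policy = isolated_policy, log2_shift = log2_shift)
  message("config: ", paste(names(config), unlist(config), sep = "=",
                            collapse = " "))

  expr <- read_expression(expr_path, log2_shift = log2_shift)
  message("genes read: ", nrow(expr), "; samples: ", ncol(expr))
  design <- read_stages(stages_path, samples = colnames(expr))
  design <- design[match(colnames(expr), design$sample), , drop = FALSE]
  class(design) <- c("stage_design", "data.frame")

  x <- expr
  if (method == "weighted") {
    net <- align_to_genes(read_edge_list(network_path), rownames(expr),
                          isolated_policy = isolated_policy)
    if (isolated_policy == "drop") {
      expr <- expr[net$genes, , drop = FALSE]
    }
    message("genes aligned to network: ", length(net$genes))
    x <- generank_matrix(net, expr, d = d)
  }
  message("genes tested: ", nrow(x))

  if (method == "mfselector") {
    tab <- mfselect(x, design, direction = direction, alpha = alpha,
                    n_perm = n_perm, seed = seed)
    summary <- data.frame(
      alpha = alpha_grid,
      significant = vapply(alpha_grid, function(a)
        sum(tab$p_adjusted <= a), 0L))
  } else {
    tab <- identify_megs(x, design, alpha = alpha, adjust = adjust)
    summary <- meg_summary(tab, alpha_grid)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_table(tab, file.path(out_dir, "result_table.tsv"))
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, summary = summary, config = config)
}
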